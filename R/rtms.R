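#' rTMS session protocol arithmetic
#'
#' Derives the structure of a high-frequency rTMS session from its dose
#' parameters: pulses per train, number of trains, and session duration for
#' a protocol of `pulse_freq` Hz trains of `train_s` seconds separated by
#' `iti_s` seconds, delivering `total_pulses` pulses. The session label is
#' all this package uses downstream (pre vs post); no hardware is driven.
#'
#' @param pulse_freq Stimulation frequency, Hz.
#' @param train_s Train duration, seconds.
#' @param iti_s Inter-train interval, seconds.
#' @param total_pulses Pulses per session.
#' @return List: pulses_per_train, n_trains, session_s, session_min,
#'   total_pulses.
#' @export
rtms_protocol <- function(pulse_freq = 10, train_s = 10, iti_s = 20,
                          total_pulses = 3000) {
  stopifnot(pulse_freq > 0, train_s > 0, iti_s >= 0, total_pulses > 0)
  pulses_per_train <- pulse_freq * train_s
  n_trains <- total_pulses / pulses_per_train
  if (n_trains != round(n_trains)) {
    stop("total_pulses is not a whole number of trains")
  }
  session_s <- n_trains * train_s + (n_trains - 1) * iti_s
  list(pulses_per_train = pulses_per_train,
       n_trains = as.integer(n_trains),
       session_s = session_s,
       session_min = session_s / 60,
       total_pulses = pulses_per_train * n_trains)
}
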