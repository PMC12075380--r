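#' Write a recording as a BrainVision triplet
#'
#' Produces `<base>.vhdr` (INI-style header), `<base>.vmrk` (markers; event
#' codes become `Stimulus` markers) and `<base>.eeg` (multiplexed binary).
#' `INT_16` data are stored with a per-channel resolution field in
#' microvolts; `IEEE_FLOAT_32` stores microvolts directly.
#'
#' @param recording An [eeg_recording].
#' @param base Path prefix without extension.
#' @param format "INT_16" or "IEEE_FLOAT_32".
#' @param resolution Microvolts per digital unit for INT_16.
#' @return Invisibly, the three file paths.
#' @export
write_brainvision <- function(recording, base, format = c("INT_16",
                                                          "IEEE_FLOAT_32"),
                              resolution = 0.1) {
  format <- match.arg(format)
  paths <- paste0(base, c(".vhdr", ".vmrk", ".eeg"))
  stem <- basename(base)
  n_ch <- nrow(recording$samples)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / recording$sampling_rate,
                                       scientific = FALSE)),
    "[Binary Infos]",
    paste0("BinaryFormat=", format),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,uV", seq_len(n_ch), recording$channel_names,
            if (format == "INT_16") format(resolution, scientific = FALSE)
            else "1")
  )
  writeLines(hdr, paths[1])

  ev <- recording$events
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    if (nrow(ev)) sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(ev)) + 1L, ev$code, ev$sample)
  )
  writeLines(mrk, paths[2])

  con <- file(paths[3], "wb")
  on.exit(close(con))
  if (format == "INT_16") {
    dig <- as.integer(round(as.vector(recording$samples) / resolution))
    if (any(abs(dig) > 32767)) {
      stop("samples exceed the INT_16 range at resolution ", resolution,
           " uV; increase the resolution")
    }
    writeBin(dig, con, size = 2, endian = "little")
  } else {
    writeBin(as.vector(recording$samples), con, size = 4, endian = "little")
  }
  invisible(paths)
}

#' Read a BrainVision recording
#'
#' Supports multiplexed binary data in `INT_16` (scaled by the per-channel
#' resolution) or `IEEE_FLOAT_32`; `Stimulus` markers become the event
#' table.
#'
#' @param vhdr Path to the `.vhdr` header file.
#' @return An [eeg_recording].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  get_key <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("BrainVision header missing key ", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  data_file <- file.path(dirname(vhdr), get_key("DataFile"))
  marker_file <- file.path(dirname(vhdr), get_key("MarkerFile"))
  if (toupper(get_key("DataFormat")) != "BINARY" ||
      toupper(get_key("DataOrientation")) != "MULTIPLEXED") {
    stop("only BINARY MULTIPLEXED BrainVision data are supported")
  }
  fmt <- toupper(get_key("BinaryFormat"))
  n_ch <- as.integer(get_key("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_key("SamplingInterval"))

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  ch_names <- vapply(ch_parts, `[`, character(1), 1)
  res <- vapply(ch_parts, function(p) {
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1
  }, numeric(1))
  if (length(ch_names) != n_ch) stop("channel info count mismatch")

  sz <- file.info(data_file)$size
  if (fmt == "INT_16") {
    raw_n <- sz / 2
    dig <- readBin(data_file, "integer", n = raw_n, size = 2,
                   endian = "little")
  } else if (fmt == "IEEE_FLOAT_32") {
    raw_n <- sz / 4
    dig <- readBin(data_file, "numeric", n = raw_n, size = 4,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  n_t <- floor(length(dig) / n_ch)
  X <- matrix(dig[seq_len(n_ch * n_t)], nrow = n_ch)
  X <- X * res   # resolution recycles down columns = per channel

  mlines <- readLines(marker_file, warn = FALSE)
  stim <- grep("^Mk[0-9]+=Stimulus,", mlines, value = TRUE)
  if (length(stim)) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", stim), ",")
    events <- data.frame(
      sample = as.integer(vapply(parts, `[`, character(1), 3)),
      code = vapply(parts, `[`, character(1), 2),
      stringsAsFactors = FALSE
    )
  } else {
    events <- data.frame(sample = integer(0), code = character(0))
  }
  eeg_recording(X, fs, ch_names, events)
}

#' Write a recording as EDF
#'
#' Standard EDF: 1-s data records of little-endian 16-bit integers with
#' per-signal physical scaling chosen from the data range. The final
#' partial record is zero-padded. EDF itself carries no event channel here;
#' events are written to a `<base>_events.csv` sidecar that [read_edf()]
#' picks up when present.
#'
#' @param recording An [eeg_recording]; sampling rate must be an integer.
#' @param base Path prefix without extension.
#' @return Invisibly, the `.edf` path.
#' @export
write_edf <- function(recording, base) {
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  X <- recording$samples
  n_ch <- nrow(X)
  n_rec <- ceiling(ncol(X) / fs)
  if (ncol(X) < n_rec * fs) {
    X <- cbind(X, matrix(0, n_ch, n_rec * fs - ncol(X)))
  }
  pmax_ <- max(1e-6, max(abs(X)))
  dig_max <- 32767
  scale <- pmax_ / dig_max

  pad <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    formatC(x, width = width, flag = "-")
  }
  path <- paste0(base, ".edf")
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    pad("0", 8), pad("synthetic EEG", 80), pad("tgcwm export", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (1 + n_ch), 8), pad("", 44), pad(n_rec, 8), pad("1", 8),
    pad(n_ch, 4),
    paste0(vapply(recording$channel_names, pad, character(1), 16),
           collapse = ""),
    paste0(rep(pad("", 80), n_ch), collapse = ""),
    paste0(rep(pad("uV", 8), n_ch), collapse = ""),
    paste0(rep(pad(sprintf("%.6g", -pmax_), 8), n_ch), collapse = ""),
    paste0(rep(pad(sprintf("%.6g", pmax_), 8), n_ch), collapse = ""),
    paste0(rep(pad(-dig_max, 8), n_ch), collapse = ""),
    paste0(rep(pad(dig_max, 8), n_ch), collapse = ""),
    paste0(rep(pad("", 80), n_ch), collapse = ""),
    paste0(rep(pad(fs, 8), n_ch), collapse = ""),
    paste0(rep(pad("", 32), n_ch), collapse = "")
  )
  writeChar(header, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- t(X[, idx, drop = FALSE])          # samples x channels
    writeBin(as.integer(round(as.vector(block) / scale)), con,
             size = 2, endian = "little")
  }
  if (nrow(recording$events)) {
    utils::write.csv(recording$events, paste0(base, "_events.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads standard EDF with equal per-signal sampling rates; physical values
#' are reconstructed from the digital/physical ranges. Events are restored
#' from a `<base>_events.csv` sidecar if one exists.
#'
#' @param path Path to the `.edf` file.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), character(1))
  for (i in seq_len(n_ch)) rd(80)                 # transducer
  for (i in seq_len(n_ch)) rd(8)                  # dimension
  pmin_ <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(n_ch)) rd(80)                 # prefiltering
  spr <- vapply(seq_len(n_ch), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(n_ch)) rd(32)
  stopifnot(header_bytes == 256 * (1 + n_ch))
  if (length(unique(spr)) != 1) {
    stop("EDF files with mixed per-signal rates are not supported")
  }
  fs <- spr[1] / rec_dur

  X <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      X[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <- phys
    }
  }
  sidecar <- paste0(sub("\\.edf$", "", path), "_events.csv")
  events <- if (file.exists(sidecar)) {
    utils::read.csv(sidecar, stringsAsFactors = FALSE)
  } else data.frame(sample = integer(0), code = character(0))
  eeg_recording(X, fs, labels, events)
}

#' Write / read the behaviour trial-log CSV
#'
#' Columns: subject, session, condition, trial, truth, response, rt_ms.
#'
#' @param log Trial-log data.frame.
#' @param path CSV path.
#' @return `write_behavior_csv` the path invisibly; `read_behavior_csv` the
#'   data.frame.
#' @export
write_behavior_csv <- function(log, path) {
  need <- c("subject", "session", "condition", "trial", "truth",
            "response", "rt_ms")
  stopifnot(all(need %in% names(log)))
  utils::write.csv(log[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
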