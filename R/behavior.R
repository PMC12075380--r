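#' Cowan's K working-memory capacity
#'
#' `K = load * (hit rate - false alarm rate)`: the number of items
#' effectively held in memory in a change-detection task with `load` items
#' to remember.
#'
#' @param load Memory load (number of items), one of `allowed_loads`.
#' @param hit_rate P(respond "match" | arrays match), in \[0, 1\].
#' @param fa_rate P(respond "match" | arrays differ), in \[0, 1\].
#' @param allowed_loads Whitelist of valid loads.
#' @return K, in \[-load, load\].
#' @export
cowan_k <- function(load, hit_rate, fa_rate, allowed_loads = c(2, 4)) {
  if (!load %in% allowed_loads) {
    stop("load must be one of: ", paste(allowed_loads, collapse = ", "))
  }
  if (hit_rate < 0 || hit_rate > 1 || fa_rate < 0 || fa_rate > 1) {
    stop("hit_rate and fa_rate must lie in [0, 1]")
  }
  load * (hit_rate - fa_rate)
}

#' Summarise a trial log into accuracy, mean RT and Cowan's K
#'
#' Per (subject, session, condition): hit rate is P(respond match | truth
#' match) and false-alarm rate P(respond match | truth mismatch), both over
#' responded trials; accuracy is the proportion correct among responded
#' trials (omissions excluded from the denominator); mean reaction time is
#' taken over correct responded trials by default; K comes from
#' [cowan_k()] with the load implied by the condition label.
#'
#' @param log data.frame with columns subject, session, condition (`2T` or
#'   `4T`), trial, truth (`match`/`mismatch`), response (`match`,
#'   `mismatch` or `none`), rt_ms.
#' @param rt_correct_only Use only correct trials for mean RT (default);
#'   FALSE uses all responded trials.
#' @param loads Named map from condition label to load.
#' @return data.frame with columns subject, session, condition, n_trials,
#'   n_responded, accuracy, mean_rt, hit_rate, fa_rate, k.
#' @export
summarize_behavior <- function(log, rt_correct_only = TRUE,
                               loads = c("2T" = 2, "4T" = 4)) {
  need <- c("subject", "session", "condition", "truth", "response", "rt_ms")
  if (!all(need %in% names(log))) {
    stop("trial log missing column(s): ", paste(setdiff(need, names(log)),
                                                collapse = ", "))
  }
  cells <- unique(log[c("subject", "session", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    d <- log[log$subject == cell$subject & log$session == cell$session &
               log$condition == cell$condition, ]
    if (!cell$condition %in% names(loads)) {
      stop("unknown condition label: ", cell$condition)
    }
    responded <- d$response != "none"
    r <- d[responded, ]
    if (!nrow(r)) stop("no responded trials in cell ", cell$subject, "/",
                       cell$session, "/", cell$condition)
    if (!any(r$truth == "mismatch")) {
      stop("false-alarm rate undefined: no mismatch trials in cell ",
           cell$subject, "/", cell$session, "/", cell$condition)
    }
    if (!any(r$truth == "match")) {
      stop("hit rate undefined: no match trials in cell ",
           cell$subject, "/", cell$session, "/", cell$condition)
    }
    hit <- mean(r$response[r$truth == "match"] == "match")
    fa <- mean(r$response[r$truth == "mismatch"] == "match")
    correct <- r$response == r$truth
    rt_pool <- if (rt_correct_only) r$rt_ms[correct] else r$rt_ms
    data.frame(
      subject = cell$subject, session = cell$session,
      condition = cell$condition,
      n_trials = nrow(d), n_responded = nrow(r),
      accuracy = mean(correct),
      mean_rt = if (length(rt_pool)) mean(rt_pool) else NA_real_,
      hit_rate = hit, fa_rate = fa,
      k = cowan_k(loads[[cell$condition]], hit, fa),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
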