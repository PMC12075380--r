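#' Run one group or paired contrast
#'
#' Dispatches to the test named in `test`: Mann-Whitney U, two-sample t,
#' paired t, Pearson chi-square, or Spearman correlation; `"auto"` picks
#' between Mann-Whitney and two-sample t via a Shapiro-Wilk normality check
#' in each group at alpha = 0.05. All tests are two-sided.
#'
#' @param data data.frame holding the outcome and grouping columns.
#' @param outcome Name of the numeric outcome column (for `chi_square`, a
#'   categorical column).
#' @param group Name of the two-level grouping column (for `spearman`, the
#'   second numeric column).
#' @param test One of `auto`, `mann_whitney`, `two_sample_t`, `paired_t`,
#'   `chi_square`, `spearman`.
#' @param subject Subject-id column, required for `paired_t`; rows are
#'   matched within subject across the two group levels.
#' @param contrast Label copied into the result row.
#' @param family Analysis family label for later FDR adjustment.
#' @return One-row data.frame: contrast, family, test, statistic, p_raw, n,
#'   direction (sign of the level-2 minus level-1 effect, or of rho).
#' @export
run_contrast <- function(data, outcome, group,
                         test = c("auto", "mann_whitney", "two_sample_t",
                                  "paired_t", "chi_square", "spearman"),
                         subject = NULL, contrast = outcome,
                         family = "default") {
  test <- match.arg(test)
  y <- data[[outcome]]
  g <- data[[group]]
  if (is.null(y) || is.null(g)) stop("outcome or group column not found")

  if (test == "spearman") {
    ok <- stats::complete.cases(y, g)
    y <- y[ok]; g <- g[ok]
    if (length(y) < 4) stop("Spearman correlation needs n >= 4")
    ct <- suppressWarnings(stats::cor.test(y, g, method = "spearman"))
    return(result_row(contrast, family, "spearman", unname(ct$estimate),
                      ct$p.value, length(y), sign(unname(ct$estimate))))
  }
  if (test == "chi_square") {
    tab <- table(y, g)
    if (any(dim(tab) < 2)) stop("chi-square needs at least 2 levels per margin")
    ct <- suppressWarnings(stats::chisq.test(tab))
    return(result_row(contrast, family, "chi_square",
                      unname(ct$statistic), ct$p.value, sum(tab), NA_real_))
  }

  lv <- sort(unique(as.character(g)))
  if (length(lv) != 2) stop("grouping column must have exactly 2 levels")
  y1 <- y[g == lv[1]]; y2 <- y[g == lv[2]]

  if (test == "paired_t") {
    if (is.null(subject)) stop("paired_t requires a subject column")
    s <- data[[subject]]
    s1 <- s[g == lv[1]]; s2 <- s[g == lv[2]]
    common <- intersect(s1, s2)
    if (length(common) < 3) stop("paired_t needs >= 3 matched subjects")
    d <- y2[match(common, s2)] - y1[match(common, s1)]
    if (stats::sd(d) == 0) {
      stop("paired differences have zero variance; paired t undefined")
    }
    tt <- stats::t.test(d)
    return(result_row(contrast, family, "paired_t", unname(tt$statistic),
                      tt$p.value, length(d), sign(mean(d))))
  }

  if (length(y1) < 3 || length(y2) < 3) stop("need n >= 3 per group")
  if (stats::sd(y1) == 0 && stats::sd(y2) == 0) {
    stop("zero variance in both groups; test degenerate")
  }
  if (test == "auto") {
    normal <- function(v) {
      length(unique(v)) > 2 && stats::shapiro.test(v)$p.value > 0.05
    }
    test <- if (normal(y1) && normal(y2)) "two_sample_t" else "mann_whitney"
  }
  direction <- sign(mean(y2) - mean(y1))
  if (test == "two_sample_t") {
    tt <- stats::t.test(y1, y2)
    result_row(contrast, family, "two_sample_t", unname(tt$statistic),
               tt$p.value, length(y), direction)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(y1, y2))
    result_row(contrast, family, "mann_whitney", unname(wt$statistic),
               wt$p.value, length(y), direction)
  }
}

result_row <- function(contrast, family, test, statistic, p, n, direction) {
  data.frame(contrast = contrast, family = family, test = test,
             statistic = statistic, p_raw = p, n = n,
             direction = direction, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`p * m / rank`, monotone-enforced from the
#' largest rank down, capped at 1).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Adjust p-values within analysis families
#'
#' Applies [bh_fdr()] separately within each level of the `family` column
#' and appends a `p_fdr` column.
#'
#' @param results data.frame with columns `family` and `p_raw`.
#' @return The input with a `p_fdr` column.
#' @export
adjust_families <- function(results) {
  stopifnot(all(c("family", "p_raw") %in% names(results)))
  results$p_fdr <- NA_real_
  for (f in unique(results$family)) {
    idx <- results$family == f
    results$p_fdr[idx] <- bh_fdr(results$p_raw[idx])
  }
  results
}

#' Correlate neural change with behavioural change
#'
#' Spearman correlation between per-subject changes (post minus pre) in a
#' neural measure and in a behavioural measure, matched by subject.
#'
#' @param delta_neuro data.frame with columns `subject` and `delta`.
#' @param delta_behavior data.frame with columns `subject` and `delta`.
#' @param contrast,family Labels for the result row.
#' @return One-row data.frame as in [run_contrast()]; statistic is rho.
#' @export
correlate_change <- function(delta_neuro, delta_behavior,
                             contrast = "delta_neuro_vs_delta_behavior",
                             family = "correlations") {
  m <- merge(delta_neuro, delta_behavior, by = "subject",
             suffixes = c("_neuro", "_behav"))
  if (nrow(m) < 4) stop("need >= 4 matched subjects for a change correlation")
  run_contrast(data.frame(x = m$delta_neuro, yv = m$delta_behav),
               outcome = "x", group = "yv", test = "spearman",
               contrast = contrast, family = family)
}
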