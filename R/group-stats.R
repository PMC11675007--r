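MEASURES <- c("mi", "te_l2r", "te_r2l")

bind_series <- function(series) {
  if (inherits(series, "data.frame")) return(series)
  do.call(rbind, lapply(series, as.data.frame))
}

#' Pooled baseline mean of each connectivity measure
#'
#' Arithmetic mean over every baseline window of every recording (e.g. 240
#' windows for 8 recordings of 30 baseline windows each). The standard error
#' of this pooled mean is reported alongside but deliberately not propagated
#' into the min-max test, where the pooled mean is treated as the expected
#' value.
#'
#' @param series A `connectivity_series` (or list of them / row-bound frame).
#' @return Named numeric vector of per-measure means, with attributes `sem`
#'   (per-measure standard error) and `n_windows`.
#' @export
pooled_baseline_mean <- function(series) {
  df <- bind_series(series)
  df <- df[df$segment == "baseline", , drop = FALSE]
  if (nrow(df) == 0) stop("size error: no baseline windows")
  avail <- MEASURES[colSums(!is.na(df[MEASURES])) > 0]
  means <- vapply(avail, function(m) mean(df[[m]]), numeric(1))
  sems <- vapply(avail, function(m) sd(df[[m]]) / sqrt(nrow(df)), numeric(1))
  structure(means, sem = sems, n_windows = nrow(df))
}

#' Per-window group summary across recordings
#'
#' For each post-event window, the mean, minimum and maximum of each measure
#' across the L recordings, together with the pooled baseline mean — the
#' ingredients of the min-max criterion and of the group dynamics figures.
#'
#' @param series List of `connectivity_series` (one per recording) or a
#'   row-bound frame with an `animal` column.
#' @return A list of class `group_summary`: `L`, `K`, `window_start_s`, and
#'   per-measure matrices `mean`, `min`, `max` (K x measures), plus
#'   `baseline_mean`.
#' @export
group_summary <- function(series) {
  df <- bind_series(series)
  animals <- unique(df$animal)
  L <- length(animals)
  if (L < 1) stop("size error: no recordings")
  post <- df[df$segment == "post", , drop = FALSE]
  ks <- tapply(post$window, post$animal, max)
  if (length(unique(ks)) != 1)
    stop("recordings have differing post window counts")
  K <- as.integer(ks[[1]])
  avail <- MEASURES[colSums(!is.na(post[MEASURES])) > 0]
  stat <- function(f) {
    m <- sapply(avail, function(meas)
      tapply(post[[meas]], post$window, f))
    matrix(m, nrow = K, dimnames = list(NULL, avail))
  }
  start_s <- tapply(post$window_start_s, post$window, function(v) v[1])
  structure(
    list(L = L, K = K, animals = animals,
         window_start_s = as.numeric(start_s),
         window_length = if (K > 1) diff(as.numeric(start_s))[1] else NA_real_,
         mean = stat(mean), min = stat(min), max = stat(max),
         baseline_mean = pooled_baseline_mean(df)),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> L = %d recordings, K = %d post windows\n",
              x$L, x$K))
  cat("  baseline means:",
      paste(sprintf("%s = %.4g", names(x$baseline_mean), x$baseline_mean),
            collapse = ", "), "\n")
  invisible(x)
}

#' Min-max criterion per window
#'
#' The group test: a post-event window is called significantly above baseline
#' when the minimum of the measure across all L recordings exceeds the pooled
#' baseline mean, and significantly below when the maximum falls under it.
#' Under the null (each recording equally likely to lie on either side) the
#' one-sided per-window p-value is `(1/2)^L` — e.g. < 0.004 for L = 8 and
#' < 0.032 for L = 5.
#'
#' @param summary A [group_summary()].
#' @param measure One of `"mi"`, `"te_l2r"`, `"te_r2l"`.
#' @return A `data.frame` of class `minmax_report` with columns `window`,
#'   `window_start_s`, `direction` ("above"/"below"/"none") and `p_raw`
#'   (`(1/2)^L` where significant, `NA` otherwise); attributes `L`, `K`,
#'   `measure`, `baseline_mean`.
#' @export
minmax_window_test <- function(summary, measure = c("mi", "te_l2r", "te_r2l")) {
  measure <- match.arg(measure)
  if (summary$L < 2) stop("min-max test needs L >= 2 recordings")
  if (!measure %in% colnames(summary$min))
    stop("measure not present in the summary")
  base <- summary$baseline_mean[[measure]]
  above <- summary$min[, measure] > base
  below <- summary$max[, measure] < base
  direction <- ifelse(above, "above", ifelse(below, "below", "none"))
  p <- ifelse(direction == "none", NA_real_, 0.5^summary$L)
  out <- data.frame(window = seq_len(summary$K),
                    window_start_s = summary$window_start_s,
                    direction = direction, p_raw = p, row.names = NULL)
  attr(out, "L") <- summary$L
  attr(out, "K") <- summary$K
  attr(out, "measure") <- measure
  attr(out, "baseline_mean") <- base
  class(out) <- c("minmax_report", "data.frame")
  out
}

#' Bonferroni correction over the K tested windows
#'
#' @param report A [minmax_window_test()] report.
#' @param K Number of tested windows (defaults to the report's K).
#' @return The report with a `p_bonferroni = p_raw * K` column.
#' @export
bonferroni_correct <- function(report, K = attr(report, "K")) {
  if (is.null(K) || K < 1) stop("K must be >= 1")
  report$p_bonferroni <- report$p_raw * K
  report
}

#' Consecutive-interval (grouped) correction
#'
#' Sharpens the Bonferroni correction by requiring M consecutive significant
#' windows in the same direction: a run of M windows each significant at p is
#' significant at `p^M`, and only `K' = ceiling(K / M)` independent grouped
#' intervals need correcting, giving `p' = p^M * K'`. With M = 1 this reduces
#' exactly to [bonferroni_correct()]. Runs of at least M windows qualify;
#' each maximal run is reported once.
#'
#' @param report A [minmax_window_test()] report.
#' @param M Required run length (>= 1).
#' @param K Number of tested windows (defaults to the report's K).
#' @param convention `"ceiling"` (default) uses `K' = ceiling(K / M)`;
#'   `"fractional"` uses `K' = K / M` unrounded.
#' @return A `data.frame` with one row per qualifying run: `run_id`,
#'   `direction`, `first_window`, `last_window`, `run_length`, `M`, `kprime`,
#'   `p_grouped`; zero rows when no run of length M exists.
#' @export
grouped_correction <- function(report, M, K = attr(report, "K"),
                               convention = c("ceiling", "fractional")) {
  convention <- match.arg(convention)
  M <- as.integer(M)
  if (M < 1) stop("M must be >= 1")
  if (is.null(K) || K < 1) stop("K must be >= 1")
  kprime <- switch(convention, ceiling = ceiling(K / M), fractional = K / M)
  L <- attr(report, "L")
  p_single <- 0.5^L

  sig <- report$direction != "none"
  r <- rle(paste0(sig, ".", report$direction))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(sig[starts] & r$lengths >= M)
  out <- data.frame(
    run_id = seq_along(keep),
    direction = report$direction[starts[keep]],
    first_window = report$window[starts[keep]],
    last_window = report$window[ends[keep]],
    run_length = r$lengths[keep],
    M = rep(M, length(keep)),
    kprime = rep(kprime, length(keep)),
    p_grouped = rep(p_single^M * kprime, length(keep)),
    row.names = NULL)
  attr(out, "measure") <- attr(report, "measure")
  out
}

#' One-sided comparison of per-recording baseline means
#'
#' Compares the per-recording mean baseline levels of a measure between two
#' groups with an equal-variance two-sample t test, one-sided. Each value
#' should be the mean over that recording's baseline windows (central limit
#' grounds for approximate normality of the means).
#'
#' @param means_a,means_b Numeric vectors of per-recording means (>= 2 each).
#' @param alternative `"greater"` tests mean(a) > mean(b); `"less"` the
#'   reverse.
#' @return One-sided p-value.
#' @export
compare_baselines <- function(means_a, means_b,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(means_a) < 2 || length(means_b) < 2)
    stop("size error: need at least 2 recordings per group")
  t.test(means_a, means_b, alternative = alternative,
         var.equal = TRUE)$p.value
}

#' Fisher exact test on event incidence
#'
#' Two-sided Fisher exact test comparing success proportions between two
#' groups (e.g. CSD elicited in 5/8 treated vs 13/14 untreated animals,
#' p = 0.1167), with the standard two-sided convention summing the
#' probabilities of all tables no more likely than the observed one.
#'
#' @param success_a,total_a Successes and trials in group A.
#' @param success_b,total_b Successes and trials in group B.
#' @return Two-sided exact p-value.
#' @examples
#' incidence_fisher(5, 8, 13, 14)
#' @export
incidence_fisher <- function(success_a, total_a, success_b, total_b) {
  counts <- c(success_a, total_a, success_b, total_b)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("domain error: counts must be nonnegative integers")
  if (success_a > total_a || success_b > total_b)
    stop("domain error: successes exceed totals")
  tab <- matrix(c(success_a, total_a - success_a,
                  success_b, total_b - success_b), 2, byrow = TRUE)
  fisher.test(tab)$p.value
}
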