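#' Nonoverlapping analysis window grid
#'
#' Defines the contiguous nonoverlapping windows in which connectivity is
#' evaluated: `baseline_windows` windows counting backward from the event
#' marker t = 0 and `post_windows` windows counting forward from it. With the
#' defaults (20-s windows, 600-s segments) the baseline holds 30 windows and
#' the post-event segment 29 complete windows after the final partial window
#' is dropped.
#'
#' @param window_length Window length in seconds (default 20).
#' @param baseline_windows Number of baseline windows (default 30).
#' @param post_windows Number of post-event windows K (default 29).
#' @return A list of class `window_grid`.
#' @export
window_grid <- function(window_length = 20, baseline_windows = 30L,
                        post_windows = 29L) {
  if (window_length <= 0) stop("window_length must be positive")
  baseline_windows <- as.integer(baseline_windows)
  post_windows <- as.integer(post_windows)
  if (baseline_windows < 0 || post_windows < 1)
    stop("window counts out of range")
  structure(list(window_length = window_length,
                 baseline_windows = baseline_windows,
                 post_windows = post_windows),
            class = "window_grid")
}

#' Default grid for a recording
#'
#' Builds the [window_grid()] that fits a recording: all complete windows
#' before t = 0 and all complete windows after it (partial windows dropped).
#'
#' @param rec A `raw_recording` or `detrended_recording`.
#' @param window_length Window length in seconds.
#' @return A [window_grid()].
#' @export
grid_for_recording <- function(rec, window_length = 20) {
  n <- length(rec$left)
  nb <- floor((rec$t0_index - 1) * rec$dt / window_length)
  np <- floor((n - rec$t0_index + 1) * rec$dt / window_length)
  window_grid(window_length, nb, np)
}

#' Windowed connectivity series
#'
#' Evaluates mutual information and transfer entropy in both directions in
#' each nonoverlapping window of the grid, on the detrended residuals. Each
#' window is processed independently; `decimate > 1` keeps every
#' `decimate`-th sample within a window before estimation.
#'
#' @param rec A `detrended_recording` (or a `raw_recording`, taken as-is).
#' @param grid A [window_grid()]; defaults to the grid fitting `rec`.
#' @param params An [estimator_params()].
#' @param measures Which measures to compute; any of `"mi"`, `"te_l2r"`,
#'   `"te_r2l"`.
#' @param decimate Integer decimation factor (default 1 = full rate).
#' @param animal,treatment Labels copied into the output.
#' @param artifact_spans Optional list of `c(start, end)` spans (seconds,
#'   relative to t = 0); windows overlapping a span are flagged, not removed.
#' @return A `data.frame` of class `connectivity_series` with columns
#'   `animal`, `treatment`, `segment` ("baseline"/"post"), `window`,
#'   `window_start_s`, `mi`, `te_l2r`, `te_r2l`, `flagged`. `te_l2r` is the
#'   transfer entropy with the left channel driving the right one.
#' @examples
#' cfg <- synth_config(duration_baseline = 60, duration_post = 60,
#'                     csd_onset = 2, csd_offset = 4, ac_hyper_start = 5,
#'                     ac_hyper_end = 50, decouple_start = 5,
#'                     decouple_end = 45, drive_start = 10, drive_end = 40)
#' det <- detrend(generate_csd_pair(cfg))
#' head(compute_series(det, window_grid(20, 3, 3), decimate = 10))
#' @export
compute_series <- function(rec, grid = grid_for_recording(rec),
                           params = estimator_params(),
                           measures = c("mi", "te_l2r", "te_r2l"),
                           decimate = 1L, animal = "a1",
                           treatment = "none", artifact_spans = NULL) {
  measures <- match.arg(measures, several.ok = TRUE)
  decimate <- as.integer(decimate)
  if (decimate < 1L) stop("decimate must be >= 1")
  w <- round(grid$window_length / rec$dt)
  n <- length(rec$left)
  first <- rec$t0_index - grid$baseline_windows * w
  last <- rec$t0_index - 1 + grid$post_windows * w
  if (first < 1 || last > n)
    stop("size error: grid exceeds the recording")

  starts <- rec$t0_index +
    w * c(seq(-grid$baseline_windows, -1), seq(0, grid$post_windows - 1))
  segment <- rep(c("baseline", "post"),
                 c(grid$baseline_windows, grid$post_windows))
  window <- c(seq_len(grid$baseline_windows), seq_len(grid$post_windows))
  start_s <- (starts - rec$t0_index) * rec$dt

  rows <- lapply(seq_along(starts), function(i) {
    sel <- seq(starts[i], starts[i] + w - 1L, by = decimate)
    l <- rec$left[sel]
    r <- rec$right[sel]
    out <- c(mi = NA_real_, te_l2r = NA_real_, te_r2l = NA_real_)
    if ("mi" %in% measures) out["mi"] <- mi_ksg(l, r, params)
    if ("te_l2r" %in% measures) out["te_l2r"] <- te_ksg(l, r, params)
    if ("te_r2l" %in% measures) out["te_r2l"] <- te_ksg(r, l, params)
    out
  })
  vals <- do.call(rbind, rows)

  flagged <- rep(FALSE, length(starts))
  if (!is.null(artifact_spans)) {
    for (sp in artifact_spans) {
      flagged <- flagged |
        (start_s < sp[2] & (start_s + grid$window_length) > sp[1])
    }
  }

  out <- data.frame(animal = animal, treatment = treatment,
                    segment = segment, window = window,
                    window_start_s = start_s,
                    mi = vals[, "mi"], te_l2r = vals[, "te_l2r"],
                    te_r2l = vals[, "te_r2l"], flagged = flagged,
                    row.names = NULL)
  class(out) <- c("connectivity_series", "data.frame")
  out
}
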