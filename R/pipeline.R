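#' Write a recording to CSV
#'
#' Canonical interchange format: a header row and columns `time_s`, `left_V`,
#' `right_V`, with time zero at the event marker.
#'
#' @param rec A [raw_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "raw_recording")) stop("rec must be a raw_recording")
  df <- data.frame(time_s = recording_time(rec),
                   left_V = rec$left, right_V = rec$right)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Expects the format written by [write_recording()]: header `time_s`,
#' `left_V`, `right_V`; a uniform time step; t = 0 present in (or adjacent
#' to) the time column.
#'
#' @param path CSV file path.
#' @param tol Relative tolerance on time-step uniformity.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  need <- c("time_s", "left_V", "right_V")
  if (!all(need %in% names(df)))
    stop("format error: expected columns time_s, left_V, right_V")
  if (ncol(df) != 3)
    stop("format error: recording must have exactly two signal channels")
  dtv <- diff(df$time_s)
  dt <- stats::median(dtv)
  if (dt <= 0 || any(abs(dtv - dt) > tol * dt))
    stop("format error: nonuniform time step")
  t0_index <- which.min(abs(df$time_s))
  if (abs(df$time_s[t0_index]) > dt / 2 + tol)
    stop("format error: no sample at the event time t = 0")
  raw_recording(df$left_V, df$right_V, dt = dt, t0_index = t0_index)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param synth A [synth_config()] describing the synthetic group, or `NULL`
#'   when `input_paths` is given.
#' @param input_paths Character vector of recording CSVs (alternative to
#'   `synth`).
#' @param n_animals Number of synthetic recordings (per-animal seeds are
#'   `seed + 0:(n_animals-1)`).
#' @param params An [estimator_params()].
#' @param grid A [window_grid()] (default: 30 baseline + 29 post windows of
#'   20 s, the canonical grid for 600-s segments) or `NULL` to fit each
#'   recording.
#' @param M Run length for the grouped correction.
#' @param kprime_convention Passed to [grouped_correction()].
#' @param alpha Significance threshold applied to the grouped p-values.
#' @param decimate Estimator decimation factor.
#' @param rail Rail voltage for saturation repair.
#' @param exclude_flagged Drop artifact-flagged windows from pooling.
#' @param output_dir Directory for run artifacts, or `NULL` to skip writing.
#' @param seed Master seed of the run.
#' @param treatment Treatment label recorded in the series.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), input_paths = NULL,
                       n_animals = 8L, params = estimator_params(),
                       grid = window_grid(), M = 2L,
                       kprime_convention = "ceiling", alpha = 0.0003,
                       decimate = 1L, rail = 10,
                       exclude_flagged = FALSE, output_dir = NULL,
                       seed = 1L, treatment = "none") {
  if (is.null(synth) && is.null(input_paths))
    stop("configuration error: either synth or input_paths is required")
  structure(list(synth = synth, input_paths = input_paths,
                 n_animals = as.integer(n_animals), params = params,
                 grid = grid, M = as.integer(M),
                 kprime_convention = kprime_convention, alpha = alpha,
                 decimate = as.integer(decimate), rail = rail,
                 exclude_flagged = exclude_flagged, output_dir = output_dir,
                 seed = as.integer(seed), treatment = treatment),
            class = "run_config")
}

#' Run the full connectivity pipeline
#'
#' Synthesize (or load) a group of two-channel recordings, repair saturation
#' offsets, screen and detrend each recording, evaluate windowed MI and
#' bidirectional TE, and apply the min-max group statistics with Bonferroni
#' and grouped-interval corrections. Deterministic given the configuration
#' seed. When `output_dir` is set, writes the long-format series CSV, a
#' significance report CSV and a manifest of all parameters.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `series` (row-bound
#'   `connectivity_series`), `summary` ([group_summary()]), `window_tests`
#'   (per-measure min-max reports with Bonferroni column), `runs`
#'   (per-measure grouped-correction tables), `screened` (per-animal
#'   accept flags), and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  recs <- load_or_synthesize(config)

  series <- vector("list", length(recs))
  screened <- logical(length(recs))
  for (i in seq_along(recs)) {
    rec <- repair_saturation(recs[[i]], rail = config$rail)
    screened[i] <- screen_recording(rec, rail = config$rail)
    det <- detrend(rec)
    grid <- if (is.null(config$grid)) grid_for_recording(det) else config$grid
    series[[i]] <- compute_series(det, grid, config$params,
                                  decimate = config$decimate,
                                  animal = names(recs)[i],
                                  treatment = config$treatment)
  }
  names(screened) <- names(recs)

  all_series <- do.call(rbind, series)
  pool <- if (config$exclude_flagged)
    all_series[!all_series$flagged, , drop = FALSE] else all_series
  gsum <- group_summary(pool)

  window_tests <- list()
  runs <- list()
  for (m in MEASURES) {
    rep_m <- bonferroni_correct(minmax_window_test(gsum, m))
    window_tests[[m]] <- rep_m
    runs[[m]] <- grouped_correction(rep_m, config$M,
                                    convention = config$kprime_convention)
    runs[[m]]$significant <- runs[[m]]$p_grouped < config$alpha
  }

  result <- structure(list(series = all_series, summary = gsum,
                           window_tests = window_tests, runs = runs,
                           screened = screened, config = config),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) write_run_artifacts(result)
  result
}

load_or_synthesize <- function(config) {
  if (!is.null(config$input_paths)) {
    recs <- lapply(config$input_paths, read_recording)
    names(recs) <- paste0("a", seq_along(recs))
    return(recs)
  }
  recs <- lapply(seq_len(config$n_animals), function(i) {
    cfg <- config$synth
    cfg$seed <- config$seed + i - 1L
    generate_csd_pair(cfg)
  })
  names(recs) <- paste0("a", seq_len(config$n_animals))
  recs
}

write_run_artifacts <- function(result) {
  dir.create(result$config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(result$config$output_dir, f)
  write.csv(result$series, out("connectivity_series.csv"), row.names = FALSE)
  reports <- do.call(rbind, lapply(names(result$window_tests), function(m) {
    r <- result$window_tests[[m]]
    cbind(measure = m, as.data.frame(r))
  }))
  write.csv(reports, out("window_tests.csv"), row.names = FALSE)
  run_tab <- do.call(rbind, lapply(names(result$runs), function(m) {
    r <- result$runs[[m]]
    if (nrow(r) == 0) return(NULL)
    cbind(measure = m, r)
  }))
  if (!is.null(run_tab))
    write.csv(run_tab, out("grouped_runs.csv"), row.names = FALSE)
  cfg <- result$config
  manifest <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("n_animals: %d", cfg$n_animals),
    sprintf("M: %d", cfg$M),
    sprintf("kprime_convention: %s", cfg$kprime_convention),
    sprintf("alpha: %g", cfg$alpha),
    sprintf("decimate: %d", cfg$decimate),
    sprintf("estimator_k: %d", cfg$params$k),
    sprintf("estimator_tau: %d", cfg$params$tau),
    if (!is.null(cfg$synth))
      sprintf("synth_%s: %s", names(cfg$synth),
              vapply(cfg$synth, function(v) paste(format(v), collapse = " "),
                     character(1))))
  writeLines(manifest, out("manifest.txt"))
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d recordings, K = %d post windows\n",
              x$summary$L, x$summary$K))
  for (m in names(x$runs)) {
    r <- x$runs[[m]]
    sig <- r[r$significant, , drop = FALSE]
    if (nrow(sig) == 0) {
      cat(sprintf("  %s: no significant grouped runs\n", m))
    } else {
      for (i in seq_len(nrow(sig)))
        cat(sprintf(
          "  %s: %s baseline over windows %d-%d (p' = %.2e)\n",
          m, sig$direction[i], sig$first_window[i], sig$last_window[i],
          sig$p_grouped[i]))
    }
  }
  invisible(x)
}

#' Plot group connectivity dynamics
#'
#' Mean across recordings per post-event window with min-max error bars and
#' the pooled baseline mean as a horizontal dashed line — the standard
#' group-dynamics display for these analyses.
#'
#' @param x A [group_summary()].
#' @param measure Which measure to draw.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.group_summary <- function(x, measure = c("mi", "te_l2r", "te_r2l"),
                               ...) {
  measure <- match.arg(measure)
  mid <- x$window_start_s +
    (if (is.na(x$window_length)) 0 else x$window_length / 2)
  ylim <- range(x$min[, measure], x$max[, measure],
                x$baseline_mean[[measure]])
  graphics::plot(mid, x$mean[, measure], pch = 15, ylim = ylim,
                 xlab = "time after induction (s)",
                 ylab = sprintf("%s (nats)", measure), ...)
  graphics::arrows(mid, x$min[, measure], mid, x$max[, measure],
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = x$baseline_mean[[measure]], lty = 2)
  invisible(x)
}
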