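#' Remove the slow trend with a centered moving average
#'
#' Splits each channel into a slow trend (the DC component, a centered
#' moving-average over a ~2-s window) and the residual AC component
#' `v'_n = v_n - mean(v_{n-m} .. v_{n+m})`, which carries frequencies above
#' roughly 0.5 Hz and is the input to all connectivity estimators.
#'
#' With `convention = "semilength"` (default) the half-window is
#' `m = floor(semilength_T / dt)`, giving a full window of `2m + 1` samples
#' (~2 s at the 1-s default semilength). `convention = "printed"` instead sets
#' `2m = floor(semilength_T / dt)` (~1-s full window). At the record edges the
#' window shrinks symmetrically, so trend + residual reconstructs the input
#' everywhere.
#'
#' @param rec A [raw_recording()].
#' @param semilength_T Window semilength in seconds (default 1).
#' @param convention Half-window convention, see Details.
#' @return A `detrended_recording` with per-channel `left`/`right` residuals
#'   and `trend_left`/`trend_right`.
#' @examples
#' rec <- raw_recording(sin(2 * pi * 10 * (1:5000) / 1000), rnorm(5000))
#' det <- detrend(rec)
#' @export
detrend <- function(rec, semilength_T = 1.0,
                    convention = c("semilength", "printed")) {
  if (!inherits(rec, "raw_recording")) stop("rec must be a raw_recording")
  convention <- match.arg(convention)
  # guard against representation noise in dt (e.g. after a CSV round trip)
  # flipping the floor at exact-integer ratios
  guard <- 1e-8
  m <- switch(convention,
              semilength = floor(semilength_T / rec$dt + guard),
              printed = floor(semilength_T / rec$dt / 2 + guard))
  n <- length(rec$left)
  if (2 * m + 1 > n) stop("size error: window longer than the recording")
  trend_l <- moving_mean(rec$left, m)
  trend_r <- moving_mean(rec$right, m)
  new_detrended_recording(rec$left - trend_l, rec$right - trend_r,
                          trend_l, trend_r, rec$dt, rec$t0_index, rec$labels)
}

# centered moving mean with half-width m; the window shrinks symmetrically
# at the edges (mean over min(i-1, m, n-i) samples each side)
moving_mean <- function(x, m) {
  n <- length(x)
  if (m == 0) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  half <- pmin(m, i - 1L, n - i)
  (cs[i + half + 1L] - cs[i - half]) / (2 * half + 1)
}

#' Repair ADC rail-saturation offsets
#'
#' Analog-to-digital saturation shows up as contiguous runs offset by
#' approximately plus or minus the rail voltage. Step changes whose magnitude
#' lies within 20% of `rail` open or close an offset run; the cumulative
#' offset (in whole rail units) is subtracted. Samples outside detected runs
#' are untouched, and applying the repair twice is a no-op.
#'
#' @param rec A [raw_recording()].
#' @param rail Rail magnitude in volts (default 10).
#' @return A [raw_recording()] with an attribute `repaired_fraction` giving,
#'   per channel, the fraction of samples that were shifted back.
#' @export
repair_saturation <- function(rec, rail = 10) {
  if (!inherits(rec, "raw_recording")) stop("rec must be a raw_recording")
  if (rail <= 0) stop("rail must be positive")
  frac <- c(left = 0, right = 0)
  for (ch in c("left", "right")) {
    x <- rec[[ch]]
    d <- diff(x)
    hit <- which(abs(abs(d) - rail) <= 0.2 * rail)
    if (length(hit)) {
      delta <- numeric(length(x))
      delta[hit + 1L] <- rail * sign(d[hit])
      offset <- cumsum(delta)
      x <- x - offset
      frac[ch] <- mean(offset != 0)
      rec[[ch]] <- x
    }
  }
  attr(rec, "repaired_fraction") <- frac
  rec
}

#' Screen a recording for irreparable artifacts
#'
#' Recordings dominated by artifacts that the rail repair cannot fix are
#' excluded from analysis. A sample counts as an unrepaired excursion when,
#' after [repair_saturation()], its magnitude still exceeds half the rail
#' voltage; the recording is rejected when the flagged fraction on either
#' channel exceeds `max_artifact_fraction`.
#'
#' @param rec A [raw_recording()] (ideally already repaired).
#' @param max_artifact_fraction Maximum tolerated flagged fraction.
#' @param rail Rail magnitude in volts.
#' @return `TRUE` (accept) or `FALSE` (reject), with attribute
#'   `artifact_fraction`.
#' @export
screen_recording <- function(rec, max_artifact_fraction = 0.05, rail = 10) {
  if (!inherits(rec, "raw_recording")) stop("rec must be a raw_recording")
  repaired <- repair_saturation(rec, rail = rail)
  bad <- pmax(abs(repaired$left), abs(repaired$right)) > rail / 2
  frac <- mean(bad)
  structure(frac <= max_artifact_fraction, artifact_fraction = frac)
}
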