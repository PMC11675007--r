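#' Configuration for synthetic CSD recordings
#'
#' Bundles the timing, coupling and noise parameters of the two-channel
#' synthetic LFP generator. Defaults follow the phenomenology of a unilateral
#' CSD recorded from homotopic frontal sites: the negative DC shift reaches
#' the recording site at ~46.8 s and ends at ~85.7 s; ipsilateral AC
#' hyperactivity spans ~106.5-328.5 s; interhemispheric decoupling spans
#' ~100-280 s; and an extra unidirectional drive from the unaffected (right)
#' to the affected (left) hemisphere spans ~120-240 s. All event times are
#' seconds after the induction marker t = 0.
#'
#' @param duration_baseline,duration_post Segment lengths in seconds.
#' @param dt Sampling interval in seconds (1 kHz default).
#' @param csd_onset,csd_offset DC-shift start/end, seconds post induction.
#' @param ac_hyper_start,ac_hyper_end Ipsilateral AC hyperactivity span (s).
#' @param decouple_start,decouple_end Span over which the shared drive is
#'   switched off (s).
#' @param drive_start,drive_end Span of the right-to-left lagged drive (s).
#' @param shared_coupling Baseline mixing weight of the shared drive, in
#'   \[0, 1\]; the instantaneous left-right correlation of the band-limited
#'   part is its square.
#' @param drive_gain Gain of the lagged right-to-left drive term. The default
#'   produces roughly a threefold elevation of the right-to-left transfer
#'   entropy over its baseline, the magnitude characteristic of the
#'   post-CSD drive increase.
#' @param drive_lag Drive delay in samples (default 1, about one millisecond
#'   of callosal conduction at 1 kHz).
#' @param noise_floor SD of the broadband (white) measurement-noise floor,
#'   relative to the unit-SD band-limited AC component. Besides realism
#'   (amplifier/ADC noise), this floor is what keeps the lag-1 drive
#'   unidirectional for the estimators: the transferred samples are
#'   unpredictable from the receiving channel's own echo.
#' @param dc_amplitude DC-shift amplitude in volts (negative deflection).
#' @param ac_sd Standard deviation of the AC component in volts.
#' @param ac_gain Amplitude gain of the ipsilateral AC component during the
#'   hyperactivity span.
#' @param noise_band Band (Hz) of the band-limited Gaussian noise processes.
#' @param rail ADC rail voltage used by [inject_rail_artifact()].
#' @param seed Integer seed; a fixed seed yields bit-identical recordings.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_baseline = 600, duration_post = 600,
                         dt = 0.001,
                         csd_onset = 46.8, csd_offset = 85.7,
                         ac_hyper_start = 106.5, ac_hyper_end = 328.5,
                         decouple_start = 100, decouple_end = 280,
                         drive_start = 120, drive_end = 240,
                         shared_coupling = 0.85, drive_gain = 0.7,
                         drive_lag = 1L, noise_floor = 0.3,
                         dc_amplitude = -0.01, ac_sd = 1e-4, ac_gain = 3,
                         noise_band = c(0.5, 45), rail = 10, seed = 1L) {
  cfg <- list(
    duration_baseline = duration_baseline, duration_post = duration_post,
    dt = dt, csd_onset = csd_onset, csd_offset = csd_offset,
    ac_hyper_start = ac_hyper_start, ac_hyper_end = ac_hyper_end,
    decouple_start = decouple_start, decouple_end = decouple_end,
    drive_start = drive_start, drive_end = drive_end,
    shared_coupling = shared_coupling, drive_gain = drive_gain,
    drive_lag = as.integer(drive_lag), noise_floor = noise_floor,
    dc_amplitude = dc_amplitude,
    ac_sd = ac_sd, ac_gain = ac_gain, noise_band = noise_band, rail = rail,
    seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$dt <= 0) stop("dt must be positive")
  if (!(cfg$csd_onset < cfg$csd_offset))
    stop("configuration error: csd_onset must precede csd_offset")
  if (!(cfg$csd_offset < cfg$ac_hyper_start))
    stop("configuration error: DC shift must end before AC hyperactivity")
  if (!(cfg$ac_hyper_start <= cfg$ac_hyper_end))
    stop("configuration error: ac_hyper_start must not exceed ac_hyper_end")
  if (cfg$ac_hyper_end > cfg$duration_post)
    stop("configuration error: AC hyperactivity extends past the recording")
  if (cfg$decouple_start > cfg$decouple_end ||
      cfg$drive_start > cfg$drive_end)
    stop("configuration error: spans must have start <= end")
  if (cfg$shared_coupling < 0 || cfg$shared_coupling > 1)
    stop("shared_coupling must lie in [0, 1]")
  if (cfg$drive_lag < 0) stop("drive_lag must be nonnegative")
  if (cfg$noise_floor < 0) stop("noise_floor must be nonnegative")
  if (length(cfg$noise_band) != 2 || cfg$noise_band[1] <= 0 ||
      cfg$noise_band[2] <= cfg$noise_band[1])
    stop("noise_band must be an increasing positive Hz pair")
  invisible(cfg)
}

# white Gaussian noise band-passed with a zero-phase Butterworth filter and
# rescaled to unit variance
band_noise <- function(n, dt, band) {
  nyq <- 1 / (2 * dt)
  w <- pmin(band / nyq, 0.999)
  bf <- signal::butter(2, w, type = "pass")
  x <- signal::filtfilt(bf, rnorm(n + 2000))
  x <- x[1001:(1000 + n)]     # drop filter edge transients
  x / sd(x)
}

# 1-s linear on/off ramps between 0 and 1 over [start, end], evaluated at
# times t (seconds); piecewise linear, exactly reproducible
ramped_indicator <- function(t, start, end, ramp = 1) {
  up <- pmin(pmax((t - start) / ramp, 0), 1)
  down <- pmin(pmax((end - t) / ramp, 0), 1)
  pmin(up, down)
}

#' Generate a synthetic two-channel CSD recording
#'
#' Simulates left (CSD-affected) and right (unaffected) cortical LFP channels
#' as band-limited Gaussian noise sharing a common drive plus a broadband
#' measurement-noise floor, with four scripted events after induction: a
#' negative DC trapezoid on the left channel, a gain increase plus sparse
#' biphasic transients of the left AC component (ipsilateral hyperactivity),
#' a span in which the shared drive is switched off (interhemispheric
#' decoupling), and a span in which the right channel additionally drives the
#' left one at a fixed sample lag (directional coupling). Output is
#' bit-identical for a fixed seed.
#'
#' @param config A [synth_config()].
#' @return A [raw_recording()] whose `t0_index` marks the induction time.
#' @examples
#' cfg <- synth_config(duration_baseline = 20, duration_post = 20,
#'                     csd_onset = 2, csd_offset = 4, ac_hyper_start = 5,
#'                     ac_hyper_end = 15, decouple_start = 5,
#'                     decouple_end = 15, drive_start = 6, drive_end = 12)
#' rec <- generate_csd_pair(cfg)
#' @export
generate_csd_pair <- function(config) {
  validate_synth_config(config)
  with_local_seed(config$seed, function() {
    dt <- config$dt
    n_base <- round(config$duration_baseline / dt)
    n_post <- round(config$duration_post / dt)
    n <- n_base + n_post
    t0_index <- n_base + 1L
    t <- (seq_len(n) - t0_index) * dt

    p_left <- band_noise(n, dt, config$noise_band)
    p_right <- band_noise(n, dt, config$noise_band)
    shared <- band_noise(n, dt, config$noise_band)
    w_left <- rnorm(n) * config$noise_floor
    w_right <- rnorm(n) * config$noise_floor

    # shared-drive weight: piecewise constant, exactly zero while decoupled
    alpha <- rep(config$shared_coupling, n)
    alpha[t >= config$decouple_start & t < config$decouple_end] <- 0

    right_ac <- sqrt(1 - alpha^2) * p_right + alpha * shared + w_right
    left_ac <- sqrt(1 - alpha^2) * p_left + alpha * shared + w_left

    # lagged unidirectional drive from the unaffected to the affected side
    gamma <- numeric(n)
    gamma[t >= config$drive_start & t < config$drive_end] <- config$drive_gain
    lag <- config$drive_lag
    right_lagged <- c(rep(0, lag), right_ac[seq_len(n - lag)])
    left_ac <- left_ac + gamma * right_lagged

    # ipsilateral AC hyperactivity: amplitude gain with 1-s ramps plus
    # sparse high-amplitude biphasic transients
    hyper <- ramped_indicator(t, config$ac_hyper_start, config$ac_hyper_end)
    left_ac <- left_ac * (1 + (config$ac_gain - 1) * hyper)
    if (config$ac_gain > 1) {  # sparse biphasic epileptiform transients
      hyper_len <- config$ac_hyper_end - config$ac_hyper_start
      n_events <- max(1L, round(hyper_len / 5))  # about one per 5 s
      ev_t <- sort(runif(n_events, config$ac_hyper_start,
                         config$ac_hyper_end))
      ev_amp <- 6 * runif(n_events, 0.5, 1.5) *
        sample(c(-1, 1), n_events, TRUE)
      width <- 0.05                              # 50-ms biphasic wavelet
      for (j in seq_len(n_events)) {
        u <- (t - ev_t[j]) / width
        sel <- which(abs(u) < 6)
        left_ac[sel] <- left_ac[sel] + ev_amp[j] * u[sel] * exp(-u[sel]^2 / 2)
      }
    }

    # negative DC trapezoid over the depolarization phase
    dc <- config$dc_amplitude *
      ramped_indicator(t, config$csd_onset, config$csd_offset)

    left <- left_ac * config$ac_sd + dc
    right <- right_ac * config$ac_sd
    raw_recording(left, right, dt = dt, t0_index = t0_index)
  })
}

#' Bivariate Gaussian validation pair
#'
#' I.i.d. draws from a standard bivariate Gaussian with correlation `rho`;
#' the true mutual information is `-log(1 - rho^2) / 2` nats
#' (see [gaussian_mi_theory()]).
#'
#' @param rho Correlation, |rho| < 1.
#' @param n Number of samples (>= 100).
#' @param seed Integer seed.
#' @return A [raw_recording()] with `x` in the left and `y` in the right
#'   channel (`dt = 1`).
#' @export
generate_gaussian_pair <- function(rho, n, seed = 1L) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (n < 100) stop("n must be >= 100")
  with_local_seed(seed, function() {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    raw_recording(z1, rho * z1 + sqrt(1 - rho^2) * z2, dt = 1,
                  t0_index = 1L, labels = c("x", "y"))
  })
}

#' Unidirectionally coupled autoregressive validation pair
#'
#' Simulates a driver `y` (AR(1) with coefficient `a_driver`) and a target
#' `x(t+1) = a x(t) + c y(t) + eps(t)`. The transfer entropy from driver to
#' target at lag 1 has the linear-Gaussian closed form returned by
#' [ar_te_theory()]; the reverse direction carries none.
#'
#' @param a Target AR coefficient, |a| < 1.
#' @param c_gain Coupling gain from driver to target.
#' @param n Number of retained samples (>= 1000).
#' @param seed Integer seed.
#' @param a_driver Driver AR coefficient (defaults to `a`).
#' @param sd_eps,sd_eta Innovation SDs of target and driver.
#' @return A [raw_recording()] with the target `x` in the left channel and
#'   the driver `y` in the right channel.
#' @export
generate_coupled_ar <- function(a, c_gain, n, seed = 1L, a_driver = a,
                                sd_eps = 1, sd_eta = 1) {
  if (abs(a) >= 1 || abs(a_driver) >= 1) stop("AR coefficients must satisfy |a| < 1")
  if (n < 1000) stop("n must be >= 1000")
  with_local_seed(seed, function() {
    burn <- 1000L
    m <- n + burn
    eta <- rnorm(m, sd = sd_eta)
    eps <- rnorm(m, sd = sd_eps)
    y <- numeric(m)
    x <- numeric(m)
    for (i in 2:m) {
      y[i] <- a_driver * y[i - 1] + eta[i]
      x[i] <- a * x[i - 1] + c_gain * y[i - 1] + eps[i]
    }
    raw_recording(x[(burn + 1):m], y[(burn + 1):m], dt = 1,
                  t0_index = 1L, labels = c("target", "driver"))
  })
}

#' Inject ADC rail-saturation offsets
#'
#' Adds `sign * rail` volts over the given time spans of one channel,
#' emulating an analog-to-digital converter pinned at the end of its dynamic
#' range. The inverse operation is [repair_saturation()].
#'
#' @param rec A [raw_recording()].
#' @param windows List of `c(start, end)` spans in seconds relative to t = 0.
#' @param sign +1 or -1.
#' @param rail Rail magnitude in volts.
#' @param channel `"left"` or `"right"`.
#' @return The modified [raw_recording()].
#' @export
inject_rail_artifact <- function(rec, windows, sign = -1, rail = 10,
                                 channel = c("left", "right")) {
  channel <- match.arg(channel)
  if (!inherits(rec, "raw_recording")) stop("rec must be a raw_recording")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (length(windows) == 0) return(rec)
  spans <- do.call(rbind, lapply(windows, function(w) {
    if (length(w) != 2 || w[1] >= w[2]) stop("each window must be c(start, end)")
    w
  }))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  if (nrow(spans) > 1 && any(spans[-1, 1] < spans[-nrow(spans), 2]))
    stop("configuration error: overlapping artifact spans")
  tm <- recording_time(rec)
  if (min(spans) < tm[1] || max(spans) > tm[length(tm)])
    stop("artifact span outside the recording")
  x <- rec[[channel]]
  for (i in seq_len(nrow(spans))) {
    sel <- tm >= spans[i, 1] & tm < spans[i, 2]
    x[sel] <- x[sel] + sign * rail
  }
  rec[[channel]] <- x
  rec
}

#' Closed-form mutual information of a bivariate Gaussian
#'
#' @param rho Correlation, |rho| < 1.
#' @return MI in nats: `-log(1 - rho^2) / 2`.
#' @export
gaussian_mi_theory <- function(rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  -0.5 * log(1 - rho^2)
}

#' Closed-form transfer entropy of the coupled AR pair
#'
#' For the process of [generate_coupled_ar()], the lag-1 transfer entropy
#' driver -> target (conditioning on the target's current value, matching the
#' three-dimensional estimator) is the Gaussian conditional mutual
#' information of (x_{t+1}; y_t | x_t), computed here from the stationary
#' covariance equations.
#'
#' @inheritParams generate_coupled_ar
#' @return TE in nats.
#' @export
ar_te_theory <- function(a, c_gain, a_driver = a, sd_eps = 1, sd_eta = 1) {
  if (abs(a) >= 1 || abs(a_driver) >= 1) stop("AR coefficients must satisfy |a| < 1")
  sy2 <- sd_eta^2 / (1 - a_driver^2)
  sxy <- c_gain * a_driver * sy2 / (1 - a * a_driver)
  sx2 <- (c_gain^2 * sy2 + 2 * a * c_gain * sxy + sd_eps^2) / (1 - a^2)
  var_y_given_x <- sy2 * (1 - sxy^2 / (sx2 * sy2))
  0.5 * log((c_gain^2 * var_y_given_x + sd_eps^2) / sd_eps^2)
}

#' CSD propagation speed from distance and arrival latency
#'
#' @param distance_mm Distance between induction and recording sites (mm).
#' @param latency_s Arrival latency of the DC shift (s).
#' @return Speed in mm/min.
#' @examples
#' propagation_speed(4.7, 46.8)  # ~6 mm/min
#' @export
propagation_speed <- function(distance_mm, latency_s) {
  if (any(distance_mm <= 0) || any(latency_s <= 0))
    stop("distance and latency must be positive")
  distance_mm / latency_s * 60
}
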