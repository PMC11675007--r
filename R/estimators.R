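#' Estimator parameters for the nearest-neighbor information measures
#'
#' @param k Neighbor order (default 1; higher k trades variance for bias).
#' @param tau Transfer-entropy prediction lag in samples (default 1).
#' @param jitter_scale Amplitude of the tie-breaking jitter, as a fraction of
#'   each channel's standard deviation (default 1e-10). Quantized voltages
#'   produce exact ties that break the strict neighbor-count logic; the
#'   jitter is far below any physical signal scale.
#' @param seed Integer seed for the jitter draws; estimates are deterministic
#'   given the seed.
#' @return A list of class `estimator_params`.
#' @export
estimator_params <- function(k = 1L, tau = 1L, jitter_scale = 1e-10,
                             seed = 1L) {
  k <- as.integer(k); tau <- as.integer(tau)
  if (k < 1L) stop("k must be >= 1")
  if (tau < 1L) stop("tau must be >= 1")
  if (jitter_scale < 0) stop("jitter_scale must be nonnegative")
  structure(list(k = k, tau = tau, jitter_scale = jitter_scale,
                 seed = as.integer(seed)),
            class = "estimator_params")
}

# One uniform jitter vector per call, applied to every coordinate scaled by
# that channel's SD. Using the same underlying draws for all channels keeps
# mi_ksg exactly symmetric in its arguments and exactly invariant under
# affine maps of either channel, while still breaking ties between samples.
jitter_vector <- function(n, seed) {
  with_local_seed(seed, function() runif(n, -0.5, 0.5))
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("size error: series lengths differ")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("series must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: constant channel")
}

#' Nearest-neighbor (KSG) mutual information
#'
#' Estimates MI between two real-valued series in nats with the
#' k-nearest-neighbor digamma estimator: for every point the distance
#' `eps_i` to its k-th neighbor under the max-norm is found in the joint
#' space, strict marginal neighbor counts `n_x(i)`, `n_y(i)` (distance
#' `< eps_i`) are taken, and
#' `MI = psi(N) + psi(k) - < psi(n_x + 1) + psi(n_y + 1) >`.
#' Channels are standardized (z-scored) before the neighbor search, so
#' estimates are exactly invariant under affine maps of either channel and
#' exactly symmetric in the two arguments; small negative values can occur
#' and are reported as computed.
#'
#' @param x,y Numeric series of equal length.
#' @param params An [estimator_params()].
#' @return MI estimate in nats.
#' @examples
#' pair <- generate_gaussian_pair(0.9, 2000, seed = 7)
#' mi_ksg(pair$left, pair$right)          # close to gaussian_mi_theory(0.9)
#' @export
mi_ksg <- function(x, y, params = estimator_params()) {
  check_pair(x, y)
  n <- length(x)
  if (n < params$k + 2) stop("size error: need at least k + 2 samples")
  x <- (x - mean(x)) / sd(x)
  y <- (y - mean(y)) / sd(y)
  if (params$jitter_scale > 0) {
    u <- jitter_vector(n, params$seed) * params$jitter_scale
    x <- x + u
    y <- y + u
  }
  ksg_mi_cpp(x, y, params$k)
}

#' Binned (plug-in) mutual information
#'
#' Histogram-based MI in nats from a two-dimensional equal-width histogram:
#' `MI = sum p(i,j) log(p(i,j) / (p(i) p(j)))`. Used as an independent
#' cross-check of [mi_ksg()]; it carries the usual positive plug-in bias,
#' decreasing as the sample grows with `bins ~ N^(1/3)`.
#'
#' @param x,y Numeric series of equal length.
#' @param bins Number of equal-width bins per axis (>= 2).
#' @return MI estimate in nats.
#' @export
mi_binned <- function(x, y, bins = 16L) {
  if (length(x) == 0) stop("size error: empty input")
  check_pair(x, y)
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  cut_idx <- function(v) {
    b <- seq(min(v), max(v), length.out = bins + 1L)
    i <- findInterval(v, b, rightmost.closed = TRUE)
    pmin.int(pmax.int(i, 1L), bins)
  }
  joint <- table(factor(cut_idx(x), levels = seq_len(bins)),
                 factor(cut_idx(y), levels = seq_len(bins)))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Nearest-neighbor transfer entropy
#'
#' Estimates the transfer entropy from a driver series to a target series in
#' nats, i.e. the reduction of uncertainty about the target's value `tau`
#' samples ahead given the driver's present value beyond the target's own
#' present value. Points `(x_{n+tau}, x_n, y_n)` are formed, the k-th-neighbor
#' distance is taken under the max-norm in 3-D, and strict neighbor counts in
#' the `x` margin and the `(x, y)` and `(x_{n+tau}, x)` planes give
#' `TE = psi(k) + < psi(n_x + 1) - psi(n_xy + 1) - psi(n_xxf + 1) >`.
#'
#' @param driver Numeric series of the putative source (Y).
#' @param target Numeric series of the putative sink (X).
#' @param params An [estimator_params()]; `tau` sets the prediction lag.
#' @return TE estimate in nats (small negative values possible).
#' @examples
#' pair <- generate_coupled_ar(0.5, 0.5, 5000, seed = 3)
#' te_ksg(pair$right, pair$left)   # driver -> target, close to ar_te_theory
#' te_ksg(pair$left, pair$right)   # no reverse coupling, close to 0
#' @export
te_ksg <- function(driver, target, params = estimator_params()) {
  check_pair(driver, target)
  n <- length(target)
  tau <- params$tau
  if (n < tau + params$k + 2) stop("size error: need at least tau + k + 2 samples")
  m <- n - tau
  target <- (target - mean(target)) / sd(target)
  driver <- (driver - mean(driver)) / sd(driver)
  xf <- target[(1 + tau):n]
  x <- target[1:m]
  y <- driver[1:m]
  if (params$jitter_scale > 0) {
    u <- jitter_vector(m, params$seed) * params$jitter_scale
    xf <- xf + u
    x <- x + u
    y <- y + u
  }
  ksg_te_cpp(xf, x, y, params$k)
}
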