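# Brute-force O(N^2) nearest-neighbor estimators, used as independent oracles
# for the tree-based implementations. Max-norm, strict counts.

brute_mi_ksg <- function(x, y, k = 1L) {
  n <- length(x)
  nx <- ny <- integer(n)
  for (i in seq_len(n)) {
    d <- pmax(abs(x - x[i]), abs(y - y[i]))
    d[i] <- Inf
    eps <- sort(d)[k]
    nx[i] <- sum(abs(x - x[i]) < eps) - 1L
    ny[i] <- sum(abs(y - y[i]) < eps) - 1L
  }
  digamma(n) + digamma(k) - mean(digamma(nx + 1) + digamma(ny + 1))
}

brute_te_ksg <- function(driver, target, k = 1L, tau = 1L) {
  n <- length(target)
  m <- n - tau
  xf <- target[(1 + tau):n]
  x <- target[1:m]
  y <- driver[1:m]
  nX <- nXY <- nXXf <- integer(m)
  for (i in seq_len(m)) {
    d <- pmax(abs(xf - xf[i]), abs(x - x[i]), abs(y - y[i]))
    d[i] <- Inf
    eps <- sort(d)[k]
    nX[i] <- sum(abs(x - x[i]) < eps) - 1L
    nXY[i] <- sum(pmax(abs(x - x[i]), abs(y - y[i])) < eps) - 1L
    nXXf[i] <- sum(pmax(abs(xf - xf[i]), abs(x - x[i])) < eps) - 1L
  }
  digamma(k) + mean(digamma(nX + 1) - digamma(nXY + 1) - digamma(nXXf + 1))
}

# Fabricate a connectivity_series frame with prescribed per-window values,
# for exercising the group statistics in isolation.
fake_series <- function(animal, baseline_mi, post_mi,
                        baseline_te = baseline_mi, post_te = post_mi) {
  nb <- length(baseline_mi); np <- length(post_mi)
  out <- data.frame(
    animal = animal, treatment = "none",
    segment = rep(c("baseline", "post"), c(nb, np)),
    window = c(seq_len(nb), seq_len(np)),
    window_start_s = c(seq(-nb, -1) * 20, seq(0, np - 1) * 20),
    mi = c(baseline_mi, post_mi),
    te_l2r = c(baseline_te, post_te),
    te_r2l = c(baseline_te, post_te),
    flagged = FALSE)
  class(out) <- c("connectivity_series", "data.frame")
  out
}

# A short-duration CSD configuration for fast structural tests; any
# synth_config field may be overridden through `...`.
small_csd_config <- function(seed = 1L, ...) {
  args <- list(duration_baseline = 40, duration_post = 40,
               csd_onset = 2, csd_offset = 4,
               ac_hyper_start = 5, ac_hyper_end = 35,
               decouple_start = 6, decouple_end = 30,
               drive_start = 10, drive_end = 25, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}
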