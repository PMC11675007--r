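test_that("tree-based MI agrees exactly with the brute-force oracle", {
  set.seed(11)
  for (trial in 1:5) {
    x <- rnorm(80)
    y <- 0.5 * x + rnorm(80)
    for (k in c(1L, 4L)) {
      expect_equal(csdconn:::ksg_mi_cpp(x, y, k), brute_mi_ksg(x, y, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("tree-based TE agrees exactly with the brute-force oracle", {
  set.seed(12)
  for (trial in 1:4) {
    y <- as.numeric(arima.sim(list(ar = 0.6), 90))
    x <- c(0, 0.5 * y[-90]) + rnorm(90)
    for (k in c(1L, 3L)) {
      xs <- scale(x)[, 1]; ys <- scale(y)[, 1]
      m <- 89
      expect_equal(
        csdconn:::ksg_te_cpp(xs[2:90], xs[1:m], ys[1:m], k),
        brute_te_ksg(ys, xs, k = k, tau = 1L),
        tolerance = 1e-12)
    }
  }
})

test_that("MI estimates match closed forms on independent and Gaussian data", {
  set.seed(21)
  u <- runif(10000); v <- runif(10000)
  expect_lt(abs(mi_ksg(u, v)), 0.02)

  p <- generate_gaussian_pair(0.9, 20000, seed = 5L)
  expect_lt(abs(mi_ksg(p$left, p$right) - gaussian_mi_theory(0.9)), 0.03)
})

test_that("MI is exactly symmetric and affine invariant", {
  p <- generate_gaussian_pair(0.6, 5000, seed = 6L)
  expect_identical(mi_ksg(p$left, p$right), mi_ksg(p$right, p$left))
  ref <- mi_ksg(p$left, p$right)
  expect_lt(abs(mi_ksg(p$left, 2 * p$right + 3) - ref), 1e-3)
  expect_lt(abs(mi_ksg(-0.1 * p$left + 7, p$right) - ref), 1e-3)
})

test_that("MI is stable across neighbor orders k = 1, 6, 10", {
  p <- generate_gaussian_pair(0.5, 20000, seed = 8L)
  ests <- vapply(c(1, 6, 10), function(k)
    mi_ksg(p$left, p$right, estimator_params(k = k)), numeric(1))
  expect_lt(diff(range(ests)), 0.05)
})

test_that("degenerate and undersized inputs raise errors", {
  expect_error(mi_ksg(rep(1, 100), rnorm(100)), "degenerate")
  expect_error(mi_ksg(rnorm(3), rnorm(3), estimator_params(k = 2)), "size")
  expect_error(mi_ksg(rnorm(5), rnorm(6)), "lengths differ")
  expect_error(te_ksg(rnorm(4), rnorm(4), estimator_params(tau = 2)), "size")
  expect_error(mi_binned(numeric(0), numeric(0)), "size")
})

test_that("binned MI reproduces ln(B) for identical equal-occupancy channels", {
  n <- 1600L; bins <- 8L
  x <- (seq_len(n) - 0.5) / n
  expect_equal(mi_binned(x, x, bins), log(bins), tolerance = 1e-12)
  set.seed(31)
  expect_lt(mi_binned(runif(50000), runif(50000), 16), 0.01)
})

test_that("binned MI cross-checks the KSG estimate on Gaussian data", {
  p <- generate_gaussian_pair(0.8, 50000, seed = 9L)
  ksg <- mi_ksg(p$left, p$right)
  binned <- mi_binned(p$left, p$right, bins = 32)
  expect_lt(abs(ksg - binned), 0.05)
})

test_that("binned MI error shrinks with N at bins ~ N^(1/3)", {
  true <- gaussian_mi_theory(0.8)
  errs <- vapply(c(500, 4000, 32000), function(n) {
    p <- generate_gaussian_pair(0.8, n, seed = 40L)
    abs(mi_binned(p$left, p$right, bins = round(n^(1 / 3))) - true)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("TE matches the linear-Gaussian closed form and is directional", {
  set.seed(51)
  x <- rnorm(20000); y <- rnorm(20000)
  expect_lt(abs(te_ksg(y, x)), 0.01)

  ar <- generate_coupled_ar(0.5, 0.5, 20000, seed = 1L)
  expect_lt(abs(te_ksg(ar$right, ar$left) - ar_te_theory(0.5, 0.5)), 0.02)
  expect_lt(abs(te_ksg(ar$left, ar$right)), 0.01)
})

test_that("time reversal swaps the dominant TE direction", {
  ar <- generate_coupled_ar(0.5, 0.8, 10000, seed = 13L)
  fwd <- te_ksg(ar$right, ar$left)
  rev_fwd <- te_ksg(rev(ar$left), rev(ar$right))
  expect_gt(fwd, 0.05)
  expect_gt(rev_fwd, 0.05)
  expect_lt(te_ksg(ar$left, ar$right), fwd / 3)
})

test_that("tau is honored and large tau decouples smooth signals", {
  ar <- generate_coupled_ar(0.5, 0.8, 10000, seed = 14L)
  te1 <- te_ksg(ar$right, ar$left, estimator_params(tau = 1))
  te15 <- te_ksg(ar$right, ar$left, estimator_params(tau = 15))
  expect_gt(te1, te15)   # coupling acts at lag 1
})
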