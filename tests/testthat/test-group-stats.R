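test_that("pooled baseline mean averages every baseline window of the group", {
  set.seed(61)
  series <- lapply(1:8, function(i)
    fake_series(paste0("a", i), baseline_mi = rnorm(30, 0.45, 0.05),
                post_mi = rnorm(29, 0.45, 0.05)))
  pooled <- pooled_baseline_mean(series)
  expect_equal(attr(pooled, "n_windows"), 240L)
  df <- do.call(rbind, series)
  expect_equal(pooled[["mi"]],
               mean(df$mi[df$segment == "baseline"]))

  five <- pooled_baseline_mean(series[1:5])
  expect_equal(attr(five, "n_windows"), 150L)

  const <- fake_series("a1", rep(0.3, 30), rep(0.3, 29))
  expect_equal(pooled_baseline_mean(const)[["mi"]], 0.3)
  expect_error(pooled_baseline_mean(const[const$segment == "post", ]),
               "size error")
})

test_that("group summary tracks per-window min/mean/max across recordings", {
  series <- lapply(1:4, function(i)
    fake_series(paste0("a", i), rep(0.4, 3), c(0.1 * i, 0.4, 0.4 + 0.1 * i)))
  gs <- group_summary(series)
  expect_equal(gs$L, 4L)
  expect_equal(gs$K, 3L)
  expect_equal(gs$min[, "mi"], c(0.1, 0.4, 0.5))
  expect_equal(gs$max[, "mi"], c(0.4, 0.4, 0.8))
  expect_equal(unname(gs$mean[2, "mi"]), 0.4)
  expect_true(all(gs$min <= gs$mean & gs$mean <= gs$max))
})

test_that("min-max criterion calls directions with p = (1/2)^L", {
  mk <- function(L, post_fun) {
    series <- lapply(seq_len(L), function(i)
      fake_series(paste0("a", i), rep(0.4, 30), post_fun(i)))
    group_summary(series)
  }
  # all L = 8 recordings above baseline in window 2, mixed elsewhere
  gs8 <- mk(8, function(i) c(0.4, 0.6 + 0.01 * i, if (i == 1) 0.2 else 0.5))
  rep8 <- minmax_window_test(gs8, "mi")
  expect_equal(rep8$direction, c("none", "above", "none"))
  expect_equal(rep8$p_raw[2], 0.00390625)
  expect_lt(rep8$p_raw[2], 0.004)

  gs5 <- mk(5, function(i) c(0.2 - 0.01 * i, 0.5, 0.5))
  rep5 <- minmax_window_test(gs5, "mi")
  expect_equal(rep5$direction[1], "below")
  expect_equal(rep5$p_raw[1], 0.03125)
  expect_lt(rep5$p_raw[1], 0.032)

  expect_error(minmax_window_test(mk(1, function(i) rep(0.5, 3)), "mi"),
               "L >= 2")
})

test_that("Bonferroni correction reproduces the printed group levels", {
  mk_sig <- function(L, K) {
    series <- lapply(seq_len(L), function(i)
      fake_series(paste0("a", i), rep(0.4, 30), rep(0.6 + 0.01 * i, K)))
    minmax_window_test(group_summary(series), "mi")
  }
  r8 <- bonferroni_correct(mk_sig(8, 29))
  expect_equal(round(r8$p_bonferroni[1], 3), 0.113)
  r5 <- bonferroni_correct(mk_sig(5, 29))
  expect_equal(round(r5$p_bonferroni[1], 3), 0.906)
  r1 <- bonferroni_correct(mk_sig(8, 29), K = 1)
  expect_equal(r1$p_bonferroni, r1$p_raw)
})

test_that("grouped correction reproduces printed levels and edge cases", {
  mk_report <- function(L, directions) {
    K <- length(directions)
    series <- lapply(seq_len(L), function(i) {
      post <- ifelse(directions == "above", 0.6 + 0.01 * i,
                     ifelse(directions == "below", 0.2 - 0.01 * i, 0.4))
      fake_series(paste0("a", i), rep(0.4, 30), post)
    })
    minmax_window_test(group_summary(series), "mi")
  }
  dirs <- rep("none", 29); dirs[5:9] <- "above"
  r8 <- mk_report(8, dirs)
  g2 <- grouped_correction(r8, M = 2)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$kprime, 15)
  expect_equal(g2$p_grouped, 0.00390625^2 * 15)
  expect_lt(g2$p_grouped, 0.0003)
  expect_equal(g2$first_window, 5L)
  expect_equal(g2$run_length, 5L)

  r5 <- mk_report(5, dirs)
  g5 <- grouped_correction(r5, M = 2)
  expect_lt(g5$p_grouped, 0.015)

  dirs3 <- rep("none", 29); dirs3[10:12] <- "below"
  r3 <- mk_report(3, dirs3)
  expect_equal(r3$p_raw[10], 0.125)
  g3 <- grouped_correction(r3, M = 3)
  expect_equal(g3$kprime, 10)
  expect_equal(g3$p_grouped, 0.125^3 * 10)
  expect_lt(g3$p_grouped, 0.02)

  # M = 1 reduces exactly to the Bonferroni correction
  g1 <- grouped_correction(r8, M = 1)
  bc <- bonferroni_correct(r8)
  expect_equal(g1$p_grouped[1], bc$p_bonferroni[5])
  # runs shorter than M yield no result
  expect_equal(nrow(grouped_correction(r8, M = 6)), 0L)
  # fractional K' convention
  gf <- grouped_correction(r8, M = 2, convention = "fractional")
  expect_equal(gf$kprime, 14.5)
})

test_that("direction changes split runs in the grouped correction", {
  dirs <- rep("none", 10); dirs[3:4] <- "above"; dirs[5:6] <- "below"
  series <- lapply(1:8, function(i) {
    post <- ifelse(dirs == "above", 0.6 + 0.01 * i,
                   ifelse(dirs == "below", 0.2 - 0.01 * i, 0.4))
    fake_series(paste0("a", i), rep(0.4, 30), post)
  })
  rep_ <- minmax_window_test(group_summary(series), "mi")
  g <- grouped_correction(rep_, M = 2)
  expect_equal(nrow(g), 2L)
  expect_equal(g$direction, c("above", "below"))
})

test_that("baseline comparison is a one-sided equal-variance t test", {
  a <- c(0.4, 0.45, 0.5, 0.42, 0.47)
  expect_equal(compare_baselines(a, a), 0.5)
  b <- a + 10 * sd(a)
  expect_lt(compare_baselines(b, a, "greater"), 1e-3)
  expect_error(compare_baselines(0.4, a), "size error")

  # power against a direct Monte-Carlo oracle
  set.seed(71)
  delta <- 0.5; n <- 8
  rejections <- replicate(2000, {
    compare_baselines(rnorm(n, delta), rnorm(n), "greater") < 0.05
  })
  oracle <- stats::power.t.test(n = n, delta = delta, sd = 1,
                                sig.level = 0.05, type = "two.sample",
                                alternative = "one.sided")$power
  expect_lt(abs(mean(rejections) - oracle), 0.03)
})

test_that("Fisher incidence test reproduces the printed p and is exact", {
  expect_equal(round(incidence_fisher(5, 8, 13, 14), 4), 0.1167)
  expect_equal(incidence_fisher(5, 8, 5, 8), 1)
  expect_equal(incidence_fisher(5, 8, 13, 14),
               incidence_fisher(13, 14, 5, 8))
  expect_error(incidence_fisher(9, 8, 3, 14), "domain error")
  expect_error(incidence_fisher(-1, 8, 3, 14), "domain error")

  # enumeration oracle: sum hypergeometric probabilities <= observed table
  enum_fisher <- function(sa, ta, sb, tb) {
    s <- sa + sb
    ks <- max(0, s - tb):min(ta, s)
    probs <- dhyper(ks, ta, tb, s)
    obs <- dhyper(sa, ta, tb, s)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  expect_equal(incidence_fisher(0, 8, 14, 14), enum_fisher(0, 8, 14, 14),
               tolerance = 1e-9)
  expect_equal(incidence_fisher(5, 8, 13, 14), enum_fisher(5, 8, 13, 14),
               tolerance = 1e-9)
})
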