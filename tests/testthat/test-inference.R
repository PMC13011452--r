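test_that("plug-in moments follow the population convention", {
  s <- abundance_series("a", 1:2, c(5, 5), c(10, 10))
  pm <- plugin_moments(s)
  expect_equal(pm$mean, 0.5)
  expect_equal(pm$cv, 0)
  expect_true(pm$constant)

  # ratios 0.1 and 0.3: mean 0.2, population sd 0.1, cv 0.5
  s2 <- abundance_series("a", 1:2, c(1, 3), c(10, 10))
  pm2 <- plugin_moments(s2)
  expect_equal(pm2$mean, 0.2)
  expect_equal(pm2$cv, 0.5)
})

test_that("sampling-aware MLE recovers gamma-Poisson generating parameters", {
  s <- make_gp_series(n = 300, mean = 1e-3, cv = 1, depth = 1e4, seed = 42)
  f <- fit_gamma_sampling_mle(s)
  expect_lt(abs(f$mean - 1e-3) / 1e-3, 0.1)
  expect_lt(abs(f$cv - 1), 0.1)
  expect_equal(f$beta, 1 / f$cv^2, tolerance = 1e-10)
  expect_false(f$censored)
})

test_that("the likelihood is order-invariant and dominates the plug-in point", {
  s <- make_gp_series(n = 60, mean = 5e-4, cv = 0.8, depth = 5e3, seed = 7)
  set.seed(8)
  perm <- sample(60)
  s_perm <- abundance_series("a", 1:60, s$counts[perm], s$depths[perm])
  f <- fit_gamma_sampling_mle(s)
  f_perm <- fit_gamma_sampling_mle(s_perm)
  expect_equal(f$mean, f_perm$mean, tolerance = 1e-8)
  expect_equal(f$cv, f_perm$cv, tolerance = 1e-8)

  for (seed in 1:5) {
    si <- make_gp_series(n = 50, mean = 2e-4, cv = 1.5, depth = 2e3,
                         seed = seed)
    fi <- fit_gamma_sampling_mle(si)
    pm <- plugin_moments(si)
    ll_plug <- sum(dnbinom(si$counts, size = 1 / max(pm$cv, 0.01)^2,
                           mu = si$depths * pm$mean, log = TRUE))
    expect_gte(fi$loglik, ll_plug - 1e-8)
  }
})

test_that("a variance-free series is censored at the lower CV bound", {
  # constant ratio 0.01 with (slightly) varying depths: no abundance
  # variance beyond sampling, so the CV estimate collapses to the box edge
  set.seed(9)
  N <- as.integer(round(runif(50, 9.9e5, 1.01e6)))
  s <- abundance_series("a", 1:50, as.integer(round(0.01 * N)), N)
  f <- fit_gamma_sampling_mle(s)
  expect_lt(abs(f$mean - 0.01) / 0.01, 0.01)
  expect_true(f$censored)
  expect_equal(f$cv, 0.01, tolerance = 1e-3)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(fit_gamma_sampling_mle(
    abundance_series("a", 1:20, rep(0L, 20), rep(100L, 20))), "no signal")
  expect_error(fit_gamma_sampling_mle(
    abundance_series("a", 1:5, c(1, 2, 1, 2, 1), rep(10L, 5))),
    "at least 10")
})

test_that("log-rescaling is exact on constructed cases and depth-invariant", {
  # series identically at the mean: y = 0 everywhere
  s <- abundance_series("a", 1:12, rep(50L, 12), rep(1000L, 12))
  fit <- list(mean = 0.05)
  rs <- rescale_log(s, fit)
  expect_equal(rs$y, rep(0, 12))
  expect_equal(rs$y_bar, 0)

  # one day at xbar * e gives y = 1 there
  cnt <- rep(50L, 12); cnt[5] <- as.integer(round(50 * exp(1)))
  s2 <- abundance_series("a", 1:12, cnt, rep(1000L, 12))
  rs2 <- rescale_log(s2, fit)
  expect_equal(rs2$y[5], log((cnt[5] / 1000) / 0.05))
  expect_lt(abs(rs2$y[5] - 1), 0.01)

  # doubling counts and depths changes nothing
  s3 <- abundance_series("a", 1:12, 2L * cnt, rep(2000L, 12))
  expect_equal(rescale_log(s3, fit)$y, rs2$y)

  # zero-count days are dropped and recorded
  cnt2 <- rep(40L, 15); cnt2[c(3, 9)] <- 0L
  s4 <- abundance_series("a", 1:15, cnt2, rep(1000L, 15))
  rs4 <- rescale_log(s4, fit)
  expect_identical(rs4$dropped_days, c(3L, 9L))
  expect_length(rs4$y, 13)
  expect_equal(mean(rs4$y), rs4$y_bar)

  expect_error(rescale_log(
    abundance_series("a", 1:12, c(rep(0L, 8), rep(5L, 4)), rep(100L, 12)),
    fit), "insufficient")
})

test_that("occupancy filtering keeps exactly the consistently observed taxa", {
  n <- 40
  counts <- rbind(full = rep(3L, n), near = rep(3L, n), half = rep(3L, n))
  counts["near", 1:2] <- 0L                       # occupancy 0.95
  counts["half", 1:20] <- 0L                      # occupancy 0.5
  fl <- filter_asvs(counts, 1:n, rep(100L, n), occupancy_min = 0.9,
                    n_obs_min = 10)
  expect_setequal(names(fl$series), c("full", "near"))
  expect_equal(fl$discarded$asv_id, "half")

  fl_strict <- filter_asvs(counts, 1:n, rep(100L, n), occupancy_min = 1.0,
                           n_obs_min = 10)
  expect_setequal(names(fl_strict$series), "full")

  fl_all <- filter_asvs(counts, 1:n, rep(100L, n), occupancy_min = 0,
                        n_obs_min = 10)
  expect_length(fl_all$series, 3)
})
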