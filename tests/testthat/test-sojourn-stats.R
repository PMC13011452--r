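test_that("boundary runs are discarded and interior runs kept", {
  # signs + + - - - +  ->  only the '-' run of length 3 is interior
  rs <- make_rescaled(c(1, 1, -1, -1, -1, 1), y_bar = 0)
  soj <- extract_sojourns(rs)
  expect_length(soj, 1)
  expect_equal(soj[[1]]$sign, -1)
  expect_equal(soj[[1]]$T, 3)
  expect_equal(soj[[1]]$start_day, 3)
  expect_equal(soj[[1]]$end_day, 5)

  # strictly alternating signs of length 10: 8 interior one-point runs
  rs2 <- make_rescaled(rep(c(1, -1), 5), y_bar = 0)
  soj2 <- extract_sojourns(rs2)
  expect_length(soj2, 8)
  expect_true(all(vapply(soj2, `[[`, 0, "T") == 1))
})

test_that("the scanner agrees with brute force on every length-12 sign sequence", {
  grid <- expand.grid(rep(list(c(-1, 1)), 12))
  for (r in seq_len(nrow(grid))) {
    s <- as.numeric(grid[r, ])
    ours <- extract_sojourns(make_rescaled(s, y_bar = 0))
    ref <- brute_force_runs(s)
    expect_equal(length(ours), length(ref))
    if (length(ref)) {
      expect_equal(vapply(ours, function(x) as.integer(x$T), 0L),
                   vapply(ref, function(x) as.integer(x$len), 0L))
      expect_equal(vapply(ours, `[[`, 0, "sign"),
                   vapply(ref, function(x) x$sign, 0))
    }
  }
})

test_that("gap and tie rules terminate runs as documented", {
  # a 2-day gap with unchanged sign is bridged: one T = 4 interior run
  rs <- make_rescaled(c(-1, 1, 1, 1, 1, -1), days = c(1, 2, 3, 5, 6, 7))
  soj <- extract_sojourns(rs, max_gap_days = 2)
  expect_length(soj, 1)
  expect_equal(soj[[1]]$T, 4)

  # the same gap with a sign change discards the runs on both sides
  rs2 <- make_rescaled(c(-1, 1, 1, -1, -1, 1), days = c(1, 2, 3, 5, 6, 7))
  expect_length(extract_sojourns(rs2, max_gap_days = 2), 0)

  # a gap beyond max_gap_days breaks even with unchanged sign
  rs3 <- make_rescaled(c(-1, 1, 1, 1, 1, -1), days = c(1, 2, 3, 7, 8, 9))
  expect_length(extract_sojourns(rs3, max_gap_days = 2), 0)

  # a dropped (zero-count) day inside a run discards it
  rs4 <- make_rescaled(c(-1, 1, 1, 1, 1, -1), days = c(1, 2, 3, 5, 6, 7),
                       dropped = 4L)
  expect_length(extract_sojourns(rs4, max_gap_days = 2), 0)

  # an exact tie with the reference terminates runs and joins none
  rs5 <- make_rescaled(c(-1, 1, 1, 0, 1, 1, -1, 1), y_bar = 0)
  soj5 <- extract_sojourns(rs5)
  expect_length(soj5, 1)           # only the '-' at day 7 is interior
  expect_equal(soj5[[1]]$sign, -1)
})

test_that("run lengths, heights and areas are internally consistent", {
  set.seed(5)
  for (rep in 1:20) {
    y <- rnorm(60)
    soj <- extract_sojourns(make_rescaled(y))
    for (tr in soj) {
      expect_equal(tr$T, length(tr$deviations))
      expect_true(all(sign(tr$deviations) == tr$sign))
      expect_equal(tr$H, max(abs(tr$deviations)))
      expect_equal(tr$area, sum(abs(tr$deviations)))
      expect_gt(tr$H, 0)
    }
    # conservation: interior + two boundary runs cover the gap-free series
    r <- rle(sign(y - mean(y)))
    interior_total <- sum(vapply(soj, function(x) as.integer(x$T), 0L))
    expect_equal(interior_total + r$lengths[1] + r$lengths[length(r$lengths)],
                 length(y))
  }
})

test_that("the run-length pmf and its mean follow hand counts", {
  sm <- sojourn_time_distribution(c(1L, 1L, 2L))
  expect_equal(sm$pmf$prob, c(2 / 3, 1 / 3))
  expect_equal(sm$mean_T, 4 / 3)
  expect_equal(sm$n_runs, 3)
  expect_equal(sum(sm$pmf$prob), 1, tolerance = 1e-12)

  # pooling is order-invariant
  t1 <- list(make_traj(c(0.5)), make_traj(c(-0.2, -0.4), sign = -1))
  expect_equal(sojourn_time_distribution(t1)$pmf,
               sojourn_time_distribution(rev(t1))$pmf)
})

test_that("fair iid signs give the geometric run-length law", {
  set.seed(31)
  Tv <- integer(0)
  for (i in 1:40) {
    s <- sample(c(-1, 1), 3000, replace = TRUE)
    runs <- brute_force_runs(s)
    ours <- extract_sojourns(make_rescaled(s, y_bar = 0))
    expect_equal(vapply(ours, function(x) as.integer(x$T), 0L),
                 vapply(runs, function(x) as.integer(x$len), 0L))
    Tv <- c(Tv, vapply(ours, function(x) as.integer(x$T), 0L))
  }
  sm <- sojourn_time_distribution(Tv)
  expect_lt(abs(sm$mean_T - 2), 0.05)
  for (TT in 1:5)
    expect_lt(abs(sm$pmf$prob[sm$pmf$T == TT] - 2^-TT), 0.01)
})

test_that("deviation profiles fold signs and average positions correctly", {
  tr1 <- make_traj(c(0.2, 0.6))
  expect_equal(mean_deviation_profile(list(tr1), 2), c(0.2, 0.6),
               ignore_attr = TRUE)

  # mirror-image pair folds onto the same profile
  tr2 <- make_traj(c(-0.2, -0.6), sign = -1)
  expect_equal(mean_deviation_profile(list(tr1, tr2), 2), c(0.2, 0.6),
               ignore_attr = TRUE)

  # three hand-written T = 2 trajectories
  tr3 <- make_traj(c(0.4, 0.3))
  prof <- mean_deviation_profile(list(tr1, tr2, tr3), 2)
  expect_equal(prof, c((0.2 + 0.2 + 0.4) / 3, (0.6 + 0.6 + 0.3) / 3),
               ignore_attr = TRUE)
  expect_equal(attr(prof, "n"), 3)

  expect_error(mean_deviation_profile(list(tr1), 5), "no trajectory")
})

test_that("the scaling exponent is recovered from constructed profiles", {
  # deviations constant at c * T^0.5: profile magnitude is exactly c*T^0.5
  mk <- function(expo, c0 = 0.3) {
    out <- list()
    for (TT in 2:6)
      for (k in 1:25)
        out[[length(out) + 1L]] <- make_traj(rep(c0 * TT^expo, TT))
    out
  }
  fa <- fit_alpha(mk(0.5), T_range = 2:6, n_boot = 50, seed = 1)
  expect_equal(fa$alpha, 0.5, tolerance = 0.02)

  # identical profiles for every T: exponent 0
  fa0 <- fit_alpha(mk(0), T_range = 2:6, n_boot = 50, seed = 2)
  expect_equal(fa0$alpha, 0, tolerance = 1e-10)

  # scale invariance
  fa2 <- fit_alpha(mk(0.5, c0 = 3), T_range = 2:6, n_boot = 50, seed = 3)
  expect_equal(fa2$alpha, fa$alpha, tolerance = 1e-10)

  expect_error(fit_alpha(mk(0.5)[1:10], T_range = 2:6), "insufficient")
})

test_that("residence and return runs match hand scans and brute force", {
  s <- abundance_series("a", 1:7, c(0L, 3L, 5L, 0L, 0L, 2L, 0L),
                        rep(10L, 7))
  rr <- residence_return_times(s)
  expect_setequal(rep(rr$residence$pmf$T,
                      round(rr$residence$pmf$prob * rr$residence$n_runs)),
                  c(2L, 1L))
  expect_equal(rr$return$pmf$T, 2L)
  expect_equal(rr$return$n_runs, 1)

  # all-positive counts: the single run touches both ends, nothing interior
  s2 <- abundance_series("a", 1:10, rep(4L, 10), rep(10L, 10))
  rr2 <- residence_return_times(s2)
  expect_null(rr2$residence)
  expect_null(rr2$return)

  # exhaustive length-10 presence/absence sequences against brute force
  grid <- expand.grid(rep(list(c(0L, 2L)), 10))
  for (r in seq_len(nrow(grid))) {
    cnt <- as.integer(grid[r, ])
    if (all(cnt == 0) || all(cnt > 0)) next
    rrg <- residence_return_times(
      abundance_series("a", 1:10, cnt, rep(10L, 10)))
    ref <- brute_force_runs(ifelse(cnt > 0, 1, -1))
    ref_res <- vapply(Filter(function(x) x$sign > 0, ref),
                      function(x) as.integer(x$len), 0L)
    ref_ret <- vapply(Filter(function(x) x$sign < 0, ref),
                      function(x) as.integer(x$len), 0L)
    got_res <- if (is.null(rrg$residence)) integer() else
      rep(rrg$residence$pmf$T,
          round(rrg$residence$pmf$prob * rrg$residence$n_runs))
    got_ret <- if (is.null(rrg$return)) integer() else
      rep(rrg$return$pmf$T, round(rrg$return$pmf$prob * rrg$return$n_runs))
    expect_equal(sort(got_res), sort(ref_res))
    expect_equal(sort(got_ret), sort(ref_ret))
  }
})

test_that("per-taxon mean sojourn times respect the minimum-run rule", {
  trs <- c(lapply(c(2, 2, 4, 3, 1), function(TT)
    make_traj(rep(0.3, TT), asv_id = "a")),
    lapply(c(2, 2, 4), function(TT) make_traj(rep(0.3, TT), asv_id = "b")))
  mt <- mean_sojourn_time(trs, n_min = 5)
  expect_equal(mt$asv_id, "a")
  expect_equal(mt$mean_T, mean(c(2, 2, 4, 3, 1)))
  expect_equal(attr(mt, "excluded")$asv_id, "b")

  mt2 <- mean_sojourn_time(trs, n_min = 3)
  expect_equal(mt2$mean_T[mt2$asv_id == "b"], 8 / 3)
})
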