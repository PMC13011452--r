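make_summary <- function(T, prob, kind = "sojourn") {
  structure(list(kind = kind, pmf = data.frame(T = T, prob = prob),
                 mean_T = sum(T * prob), n_runs = NA_integer_),
            class = "run_length_summary")
}

test_that("the divergence statistic satisfies identity, a hand value and Gibbs", {
  p1 <- make_summary(1:3, c(0.5, 0.3, 0.2))
  expect_lt(distribution_divergence(p1, p1)$divergence, 1e-5)

  # point mass vs fair split: KL = ln 2 (up to epsilon smoothing)
  pe <- make_summary(1L, 1)
  pn <- make_summary(1:2, c(0.5, 0.5))
  expect_equal(distribution_divergence(pe, pn)$divergence, log(2),
               tolerance = 1e-4)

  set.seed(13)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    a <- rgamma(k, 1); a <- a / sum(a)
    b <- rgamma(k, 1); b <- b / sum(b)
    d <- distribution_divergence(make_summary(1:k, a), make_summary(1:k, b))
    expect_gte(d$divergence, 0)
  }

  # Jensen-Shannon variant is symmetric-bounded and zero on identity
  expect_lt(distribution_divergence(p1, p1, method = "js")$divergence, 1e-12)
  expect_lte(distribution_divergence(pe, pn, method = "js")$divergence,
             log(2))
})

test_that("permuting an exchangeable series stays inside its own null band", {
  # the original ordering of an iid series is exchangeable with its
  # permutations, so ~95% of series sit inside the mean + 3 sd band
  set.seed(14)
  inside <- logical(20)
  for (rep in 1:20) {
    y <- log(rgamma(200, shape = 1, scale = 1))
    rs <- rescaled_series(y)
    emp <- sojourn_time_distribution(extract_sojourns(rs))
    nl <- permutation_null(rs, 100, seed = rep)
    d <- distribution_divergence(emp, nl)
    inside[rep] <- d$divergence < d$null_mean + 3 * d$null_sd
  }
  expect_gte(sum(inside), 16)
})

test_that("a persistent series is flagged against its permutation null", {
  # one long excursion: permutations destroy it, leaving short runs
  y <- c(-1, rep(1, 60), -1, rep(-0.5, 60), 1, rep(0.8, 60), -1)
  rs <- rescaled_series(y + rnorm(length(y), 0, 1e-3))
  emp <- sojourn_time_distribution(extract_sojourns(rs))
  nl <- permutation_null(rs, 100, seed = 3)
  expect_gt(emp$mean_T, 3 * nl$mean_T)
  d <- distribution_divergence(emp, nl)
  expect_true(d$exceeds_band)
})

test_that("permutation-null pmfs are stable in the number of permutations", {
  set.seed(15)
  rs <- rescaled_series(log(rgamma(150, 2, 1)))
  n1 <- permutation_null(rs, 200, seed = 1)
  n2 <- permutation_null(rs, 2000, seed = 2)
  al <- rbind(merge(n1$pmf, n2$pmf, by = "T", all = TRUE))
  al[is.na(al)] <- 0
  expect_lt(max(abs(al$prob.x - al$prob.y)), 0.02)
})

test_that("the stationary-gamma null reduces to the geometric law at high shape", {
  # small CV and deep sampling: y is nearly symmetric about its mean, so
  # successive draws are fair coin flips and runs are geometric
  fit <- list(mean = 1e-2, cv = 0.05)
  nl <- gamma_iid_null(fit, n_timepoints = 300, depths = 1e5,
                       n_replicates = 300, seed = 16)
  expect_lt(abs(nl$mean_T - 2), 0.05)
  expect_lt(abs(nl$pmf$prob[nl$pmf$T == 1] - 0.5), 0.02)
  expect_lt(abs(nl$pmf$prob[nl$pmf$T == 2] - 0.25), 0.02)

  # seed-fixed reproducibility, and one replicate equals one manual pass
  nl2 <- gamma_iid_null(fit, 300, 1e5, n_replicates = 300, seed = 16)
  expect_identical(nl$pmf, nl2$pmf)

  one <- gamma_iid_null(fit, 200, 1e4, n_replicates = 1, seed = 17)
  set.seed(17)
  x <- rgamma(200, shape = 1 / 0.05^2, scale = 1e-2 * 0.05^2)
  counts <- rpois(200, rep_len(1e4, 200) * x)
  y <- log(counts[counts > 0] / 1e4 / 1e-2)
  manual <- extract_sojourns(rescaled_series(
    y, days = which(counts > 0), dropped_days = which(counts == 0)))
  expect_identical(sort(unlist(one$replicate_T)),
                   sort(vapply(manual, function(t) as.integer(t$T), 0L)))
})

test_that("the host-level divergence table has the expected layout", {
  comm <- generate_community(8, c(5e-4, 5e-3), c(0.4, 1.2), tau = 1,
                             sampling_scheme(n_days = 120, depth_mean = 5e3,
                                             seed = 18))
  all_series <- lapply(seq_len(nrow(comm$counts)), function(i)
    abundance_series(rownames(comm$counts)[i], comm$days, comm$counts[i, ],
                     comm$depths))
  fl <- filter_asvs(comm$counts, comm$days, comm$depths,
                    occupancy_min = 0.9, n_obs_min = 50)
  fits <- lapply(fl$series, fit_gamma_sampling_mle)
  resc <- mapply(rescale_log, fl$series, fits, SIMPLIFY = FALSE)
  tab <- compare_quantities(all_series, resc, fits, n_permutations = 20,
                            host_id = "hostZ", seed = 19)
  expect_true(all(c("host_id", "kind", "null_kind", "divergence",
                    "null_mean", "null_sd", "exceeds_band",
                    "sojourn_greatest") %in% names(tab)))
  expect_true(all(tab$divergence >= 0))
  expect_equal(sum(tab$kind == "sojourn" & tab$null_kind == "permutation"), 1)
  expect_equal(sum(tab$kind == "sojourn" & tab$null_kind == "gamma_iid"), 1)
  expect_true(all(tab$host_id == "hostZ"))
  expect_type(tab$sojourn_greatest, "logical")
})
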