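#' Stationary-gamma null for the sojourn-time distribution
#'
#' Generates the run-length distribution expected when a taxon has no
#' temporal dynamics at all: abundances are drawn i.i.d. from the gamma
#' distribution with the taxon's fitted mean and CV (the stationary
#' distribution of the SLM), pushed through the same observation layer as
#' the data (Poisson reads at the observed depths), the same log-rescaling,
#' and the same sojourn extraction. Run lengths are pooled over replicates;
#' per-replicate summaries are kept for calibration of the divergence
#' statistic.
#'
#' @param fit a `"gamma_fit"` (needs `mean` and `cv`).
#' @param n_timepoints observations per replicate (>= 10).
#' @param depths per-observation sequencing depths, recycled to
#'   `n_timepoints`.
#' @param n_replicates number of independent replicate series.
#' @param seed optional seed.
#' @return A `"run_length_summary"` (kind `"sojourn"`, null pooled over
#'   replicates) with extra fields `replicate_T` (list of per-replicate run
#'   lengths) and `null_kind = "gamma_iid"`.
#' @export
gamma_iid_null <- function(fit, n_timepoints, depths, n_replicates = 100,
                           seed = NULL) {
  stopifnot(fit$mean > 0, fit$cv > 0, n_timepoints >= 10)
  if (!is.null(seed)) set.seed(seed)
  depths <- rep_len(depths, n_timepoints)
  shape <- 1 / fit$cv^2
  scale <- fit$mean * fit$cv^2
  per_rep <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    x <- stats::rgamma(n_timepoints, shape = shape, scale = scale)
    counts <- stats::rpois(n_timepoints, depths * x)
    keep <- counts > 0
    if (sum(keep) < 3) { per_rep[[r]] <- integer(); next }
    y <- log((counts[keep] / depths[keep]) / fit$mean)
    days <- seq_len(n_timepoints)[keep]
    runs <- scan_runs(y, days, reference = mean(y), max_gap_days = 2,
                      dropped_days = seq_len(n_timepoints)[!keep])
    per_rep[[r]] <- vapply(runs, function(x) as.integer(x$T), 0L)
  }
  Tall <- unlist(per_rep)
  if (length(Tall) == 0) stop("null produced no interior runs")
  out <- sojourn_time_distribution(Tall, "sojourn")
  out$replicate_T <- per_rep
  out$null_kind <- "gamma_iid"
  out
}

#' Time-permutation null for run-length distributions
#'
#' Destroys temporal ordering while keeping the marginal distribution of
#' the observed values: each permutation shuffles the retained `y` values
#' uniformly over the observed days (missing days stay missing), then runs
#' the identical sojourn extraction. Run lengths are pooled over
#' permutations.
#'
#' @param series a `"rescaled_series"` with >= 10 retained observations.
#' @param n_permutations number of shuffles.
#' @param max_gap_days passed to the run scanner (as for the data).
#' @param seed optional seed.
#' @return A `"run_length_summary"` with `replicate_T` and
#'   `null_kind = "permutation"`, as for [gamma_iid_null()].
#' @export
permutation_null <- function(series, n_permutations = 100, max_gap_days = 2,
                             seed = NULL) {
  stopifnot(inherits(series, "rescaled_series"), length(series$y) >= 10)
  if (!is.null(seed)) set.seed(seed)
  per_rep <- vector("list", n_permutations)
  for (r in seq_len(n_permutations)) {
    yp <- sample(series$y)
    runs <- scan_runs(yp, series$days, reference = series$y_bar,
                      max_gap_days = max_gap_days,
                      dropped_days = series$dropped_days)
    per_rep[[r]] <- vapply(runs, function(x) as.integer(x$T), 0L)
  }
  Tall <- unlist(per_rep)
  if (length(Tall) == 0) stop("null produced no interior runs")
  out <- sojourn_time_distribution(Tall, "sojourn")
  out$replicate_T <- per_rep
  out$null_kind <- "permutation"
  out
}

# align two pmf data frames on a common support, with T values above
# `cap` pooled into one tail bin
align_pmfs <- function(p_emp, p_null, cap = Inf) {
  bin <- function(df) {
    Tb <- pmin(df$T, cap)
    tapply(df$prob, Tb, sum)
  }
  pe <- bin(p_emp); pn <- bin(p_null)
  supp <- sort(unique(as.integer(c(names(pe), names(pn)))))
  e <- pe[as.character(supp)]; e[is.na(e)] <- 0
  n <- pn[as.character(supp)]; n[is.na(n)] <- 0
  list(support = supp, emp = as.numeric(e), null = as.numeric(n))
}

# KL(p||q) with pseudo-mass eps added to the (renormalized) q;
# JS uses the 0.5 mixture and needs no smoothing of p
kl_div <- function(p, q, eps = 1e-6) {
  q <- q + eps; q <- q / sum(q)
  p <- p / sum(p)
  sum(ifelse(p > 0, p * log(p / q), 0))
}
js_div <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  0.5 * sum(ifelse(p > 0, p * log(p / m), 0)) +
    0.5 * sum(ifelse(q > 0, q * log(q / m), 0))
}

#' Divergence between an empirical and a null run-length distribution
#'
#' Computes the Kullback-Leibler divergence D(empirical || null) on the
#' union support, after pooling durations above the null's 99th percentile
#' into a single tail bin and adding a pseudo-mass of `eps` to the null
#' (renormalized). When the null carries per-replicate run lengths, a
#' calibration band is reported: the mean and SD of the divergence of each
#' null replicate's own distribution from the pooled null, against which
#' the empirical divergence can be judged.
#'
#' @param p_emp a `"run_length_summary"` for the data.
#' @param p_null a `"run_length_summary"` for the null (from
#'   [gamma_iid_null()] or [permutation_null()], or any summary).
#' @param method `"kl"` (default) or `"js"` (Jensen-Shannon).
#' @param eps pseudo-mass added to the null before renormalizing.
#' @return An object of class `"divergence_result"`: list with `kind`,
#'   `null_kind`, `divergence`, `null_mean`, `null_sd`,
#'   `n_null_replicates`, `exceeds_band` (divergence > null_mean +
#'   3 null_sd, NA when no calibration), `method`.
#' @export
distribution_divergence <- function(p_emp, p_null, method = c("kl", "js"),
                                    eps = 1e-6) {
  stopifnot(inherits(p_emp, "run_length_summary"),
            inherits(p_null, "run_length_summary"),
            nrow(p_emp$pmf) > 0, nrow(p_null$pmf) > 0)
  method <- match.arg(method)
  ord <- order(p_null$pmf$T)
  cap <- p_null$pmf$T[ord][which(cumsum(p_null$pmf$prob[ord]) >= 0.99)[1]]
  al <- align_pmfs(p_emp$pmf, p_null$pmf, cap = cap)
  dfun <- if (method == "kl") function(p, q) kl_div(p, q, eps) else js_div
  div <- dfun(al$emp, al$null)
  null_mean <- null_sd <- NA_real_
  n_rep <- 0L
  if (!is.null(p_null$replicate_T)) {
    reps <- Filter(function(v) length(v) > 0, p_null$replicate_T)
    n_rep <- length(reps)
    self <- vapply(reps, function(Tv) {
      pr <- sojourn_time_distribution(Tv, p_null$kind)
      a <- align_pmfs(pr$pmf, p_null$pmf, cap = cap)
      dfun(a$emp, a$null)
    }, 0)
    null_mean <- mean(self)
    null_sd <- stats::sd(self)
  }
  structure(list(kind = p_emp$kind,
                 null_kind = if (is.null(p_null$null_kind)) "custom"
                 else p_null$null_kind,
                 divergence = div, null_mean = null_mean, null_sd = null_sd,
                 n_null_replicates = n_rep,
                 exceeds_band = if (n_rep > 0)
                   div > null_mean + 3 * null_sd else NA,
                 method = method),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("%s divergence (%s vs %s null): %.4f", x$method, x$kind,
              x$null_kind, x$divergence))
  if (x$n_null_replicates > 0)
    cat(sprintf("  [null %.4f +/- %.4f, %s band]", x$null_mean, x$null_sd,
                if (isTRUE(x$exceeds_band)) "EXCEEDS" else "within"))
  cat("\n")
  invisible(x)
}

#' Divergence table for sojourn, residence and return times in one host
#'
#' For each run-length kind, compares the host's empirical distribution
#' with the time-permutation null (and, for sojourns, also the
#' stationary-gamma null), pooling runs and permutation replicates across
#' the host's taxa. Flags whether the sojourn divergence exceeds both the
#' residence and the return divergence — the signature that sojourn times
#' carry more temporal information than presence/absence run lengths.
#'
#' @param series_list list of [abundance_series()] for the host's taxa
#'   (all taxa; used for residence/return).
#' @param rescaled_list list of `"rescaled_series"` for the consistently
#'   observed taxa (used for sojourns).
#' @param fits list of `"gamma_fit"` matching `rescaled_list` (used for the
#'   stationary-gamma null).
#' @param n_permutations permutation replicates per taxon.
#' @param max_gap_days run-scanner gap rule.
#' @param method divergence flavour, see [distribution_divergence()].
#' @param host_id host label for the output rows.
#' @param seed optional seed.
#' @return Data frame with columns `host_id`, `kind`, `null_kind`,
#'   `divergence`, `null_mean`, `null_sd`, `exceeds_band`,
#'   `sojourn_greatest` (flag, same value on all rows of the host).
#' @export
compare_quantities <- function(series_list, rescaled_list, fits,
                               n_permutations = 100, max_gap_days = 2,
                               method = "kl", host_id = "host1",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # empirical pooled distributions
  soj <- do.call(c, lapply(rescaled_list, extract_sojourns,
                           max_gap_days = max_gap_days))
  rr <- lapply(series_list, residence_return_times,
               max_gap_days = max_gap_days)
  res_T <- unlist(lapply(rr, function(z)
    if (is.null(z$residence)) integer() else
      rep(z$residence$pmf$T, round(z$residence$pmf$prob * z$residence$n_runs))))
  ret_T <- unlist(lapply(rr, function(z)
    if (is.null(z$return)) integer() else
      rep(z$return$pmf$T, round(z$return$pmf$prob * z$return$n_runs))))
  emp <- list(
    sojourn = sojourn_time_distribution(soj, "sojourn"),
    residence = if (length(res_T))
      sojourn_time_distribution(res_T, "residence") else NULL,
    return = if (length(ret_T))
      sojourn_time_distribution(ret_T, "return") else NULL)

  # permutation nulls, per taxon, pooled within the host; replicate r of
  # the pooled null joins replicate r of every taxon, so each calibration
  # replicate has the same size as the empirical pooled sample
  pool_null <- function(per_taxon) {
    n_rep <- min(vapply(per_taxon, function(p) length(p$replicate_T), 0L))
    reps <- lapply(seq_len(n_rep), function(r)
      unlist(lapply(per_taxon, function(p) p$replicate_T[[r]])))
    Tall <- unlist(reps)
    out <- sojourn_time_distribution(Tall, "sojourn")
    out$replicate_T <- reps
    out$null_kind <- per_taxon[[1]]$null_kind
    out
  }
  perm_soj <- pool_null(lapply(rescaled_list, permutation_null,
                               n_permutations = n_permutations,
                               max_gap_days = max_gap_days))
  # presence/absence permutation null for residence and return
  perm_rr <- lapply(series_list, function(s) {
    pres <- ifelse(s$counts > 0, 1, -1)
    if (length(unique(pres)) < 2) return(NULL)
    reps_res <- vector("list", n_permutations)
    reps_ret <- vector("list", n_permutations)
    for (r in seq_len(n_permutations)) {
      pp <- sample(pres)
      runs <- scan_runs(pp, s$days, reference = 0,
                        max_gap_days = max_gap_days)
      Tv <- vapply(runs, function(x) as.integer(x$T), 0L)
      sg <- vapply(runs, function(x) x$sign, 0)
      reps_res[[r]] <- Tv[sg > 0]
      reps_ret[[r]] <- Tv[sg < 0]
    }
    list(res = reps_res, ret = reps_ret)
  })
  perm_rr <- Filter(Negate(is.null), perm_rr)
  make_null <- function(per_taxon, kind) {
    if (length(per_taxon) == 0) return(NULL)
    reps <- lapply(seq_len(n_permutations), function(r)
      unlist(lapply(per_taxon, `[[`, r)))
    Tall <- unlist(reps)
    if (length(Tall) == 0) return(NULL)
    out <- sojourn_time_distribution(Tall, kind)
    out$replicate_T <- reps
    out$null_kind <- "permutation"
    out
  }
  perm_res <- make_null(lapply(perm_rr, `[[`, "res"), "residence")
  perm_ret <- make_null(lapply(perm_rr, `[[`, "ret"), "return")

  # stationary-gamma null for sojourns
  gam_soj <- pool_null(lapply(seq_along(rescaled_list), function(i) {
    s0 <- series_list[[match(rescaled_list[[i]]$asv_id,
                             vapply(series_list, `[[`, "", "asv_id"))]]
    gamma_iid_null(fits[[i]], length(s0$counts), s0$depths,
                   n_replicates = max(10L, ceiling(n_permutations / 5)))
  }))

  rows <- list()
  add <- function(kind, emp_s, null_s) {
    if (is.null(emp_s) || is.null(null_s)) return()
    d <- distribution_divergence(emp_s, null_s, method = method)
    rows[[length(rows) + 1L]] <<- data.frame(
      host_id = host_id, kind = kind, null_kind = d$null_kind,
      divergence = d$divergence, null_mean = d$null_mean,
      null_sd = d$null_sd, exceeds_band = d$exceeds_band)
  }
  add("sojourn", emp$sojourn, perm_soj)
  add("sojourn", emp$sojourn, gam_soj)
  add("residence", emp$residence, perm_res)
  add("return", emp$return, perm_ret)
  tab <- do.call(rbind, rows)
  perm <- tab[tab$null_kind == "permutation", ]
  soj_div <- perm$divergence[perm$kind == "sojourn"]
  others <- perm$divergence[perm$kind != "sojourn"]
  tab$sojourn_greatest <- length(soj_div) == 1 && length(others) > 0 &&
    all(soj_div > others)
  tab
}
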