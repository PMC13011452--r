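# Simulation-based SLM predictions for sojourn statistics.
#
# All quantities here act on y = ln(x / xbar), so the carrying capacity K
# drops out: predictions are functions of (tau, sigma, delta_t) only. K is
# fixed internally at 1. Sojourns are extracted with the identical run
# machinery used on data, guaranteeing internal consistency between theory
# and measurement.

# interior sojourns of one long stationary SLM trajectory, as signed run
# lengths (sign = above/below the mean log abundance)
slm_run_lengths <- function(tau, sigma, delta_t, t_total,
                            dt_int = min(tau, delta_t) / 100,
                            burn = 100 * max(tau, delta_t)) {
  p <- slm_params(tau = tau, K = 1, sigma = sigma, delta_t = delta_t)
  n_burn <- ceiling(burn / delta_t)
  n <- as.integer(round(t_total / delta_t)) + n_burn
  x <- slm_observed_path(p, n, dt_int = dt_int)
  y <- log(x[-seq_len(n_burn)])
  .interior_run_lengths_cpp(y, mean(y))
}

#' SLM-predicted sojourn-time distribution
#'
#' Simulates one long stationary SLM trajectory, records the abundance
#' every `delta_t` days, log-rescales it by its own time average, and
#' extracts interior sojourns exactly as for data. The carrying capacity
#' cancels in the rescaling, so the prediction depends only on `tau`,
#' `sigma` and `delta_t`. As `tau/delta_t` shrinks, successive samples
#' decorrelate and the pmf approaches the geometric law
#' \eqn{p(T) = 2^{-T}} with mean 2.
#'
#' @param tau growth timescale (days).
#' @param sigma environmental noise strength, in (0, 2).
#' @param delta_t sampling interval (days).
#' @param t_total simulated span in days after burn-in (default
#'   `1e4 * max(tau, delta_t)`).
#' @param seed optional seed.
#' @return A `"run_length_summary"` (kind `"sojourn"`) with extra fields
#'   `tau`, `sigma`, `delta_t`.
#' @export
predict_sojourn_pmf <- function(tau, sigma, delta_t = 1,
                                t_total = 1e4 * max(tau, delta_t),
                                seed = NULL) {
  stopifnot(tau > 0, delta_t > 0, t_total >= 1e3 * max(tau, delta_t))
  if (sigma <= 0 || sigma >= 2)
    stop("sigma must lie in (0, 2)")
  if (!is.null(seed)) set.seed(seed)
  Tv <- abs(slm_run_lengths(tau, sigma, delta_t, t_total))
  out <- sojourn_time_distribution(Tv, "sojourn")
  out$tau <- tau; out$sigma <- sigma; out$delta_t <- delta_t
  out
}

#' Fit the SLM growth timescale to a sojourn-time distribution
#'
#' Grid search: for each candidate `tau`, simulates the SLM-predicted
#' sojourn pmf and measures its divergence from the target distribution;
#' returns the candidate minimizing the divergence (ties broken toward the
#' smaller timescale).
#'
#' @param p_target a `"run_length_summary"` to match.
#' @param tau_grid candidate timescales (days).
#' @param sigma noise strength used for the predictions.
#' @param delta_t sampling interval (days).
#' @param t_total simulated span per candidate (days); longer spans give a
#'   less noisy divergence profile.
#' @param method divergence flavour, see [distribution_divergence()].
#' @param seed optional seed (independent simulation per candidate).
#' @return List with `tau` (selected), `divergence` (at the optimum), and
#'   `profile` (data frame `tau`, `divergence` over the grid).
#' @export
fit_tau <- function(p_target, tau_grid = 1:10, sigma = 1, delta_t = 1,
                    t_total = 1e5 * delta_t, method = "kl", seed = NULL) {
  stopifnot(inherits(p_target, "run_length_summary"),
            length(tau_grid) >= 1, nrow(p_target$pmf) > 0)
  if (!is.null(seed)) set.seed(seed)
  divs <- vapply(tau_grid, function(tg) {
    pred <- predict_sojourn_pmf(tg, sigma, delta_t, t_total)
    distribution_divergence(p_target, pred, method = method)$divergence
  }, 0)
  best <- tau_grid[which.min(divs)]  # which.min takes the first = smallest
  list(tau = best, divergence = min(divs),
       profile = data.frame(tau = tau_grid, divergence = divs))
}

#' SLM-predicted mean sojourn time as a function of the CV
#'
#' Computes \eqn{\langle T\rangle} from the predicted sojourn pmf over a
#' grid of noise strengths and reports it against the corresponding
#' coefficient of variation \eqn{CV = \sqrt{\sigma/(2-\sigma)}}. The curve
#' is free of the carrying capacity by construction: mean abundance plays
#' no role in sojourn statistics, while the CV (equivalently `sigma`) sets
#' them.
#'
#' @param tau growth timescale (days).
#' @param sigma_grid noise strengths in (0, 2).
#' @param delta_t sampling interval (days).
#' @param t_total simulated span per grid point (days).
#' @param seed optional seed.
#' @return Data frame with `sigma`, `cv`, `mean_T`, `n_runs`.
#' @export
predict_mean_T <- function(tau, sigma_grid, delta_t = 1,
                           t_total = 1e4 * max(tau, delta_t), seed = NULL) {
  stopifnot(all(sigma_grid > 0), all(sigma_grid < 2))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(sigma_grid, function(sg) {
    s <- predict_sojourn_pmf(tau, sg, delta_t, t_total)
    data.frame(sigma = sg, cv = sqrt(sg / (2 - sg)), mean_T = s$mean_T,
               n_runs = s$n_runs)
  })
  do.call(rbind, rows)
}

#' SLM-predicted scaling of sojourn height with the CV
#'
#' Simulates sojourns over a grid of noise strengths, measures the mean
#' height (peak absolute log deviation within a sojourn), and fits the
#' exponent of mean height against the CV by least squares on log-log
#' scale. In the small-noise limit the log abundance is approximately
#' Gaussian with standard deviation proportional to the CV, so the
#' exponent approaches 1.
#'
#' @param tau growth timescale (days).
#' @param sigma_grid at least 4 noise strengths; the implied CVs should
#'   span at least a decade for a stable exponent.
#' @param delta_t sampling interval (days).
#' @param t_total simulated span per grid point (days).
#' @param seed optional seed.
#' @return List with `curve` (data frame `sigma`, `cv`, `mean_H`,
#'   `n_runs`) and `exponent` (slope of log mean H on log CV).
#' @export
predict_height_cv_scaling <- function(tau, sigma_grid, delta_t = 1,
                                      t_total = 1e4 * max(tau, delta_t),
                                      seed = NULL) {
  stopifnot(length(sigma_grid) >= 4, all(sigma_grid > 0),
            all(sigma_grid < 2))
  cvs <- sqrt(sigma_grid / (2 - sigma_grid))
  if (max(cvs) / min(cvs) < 10)
    warning("CV grid spans less than a decade; the exponent may be unstable")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(sigma_grid, function(sg) {
    p <- slm_params(tau = tau, K = 1, sigma = sg, delta_t = delta_t)
    n_burn <- ceiling(100 * max(tau, delta_t) / delta_t)
    n <- as.integer(round(t_total / delta_t)) + n_burn
    x <- slm_observed_path(p, n)
    y <- log(x[-seq_len(n_burn)])
    ybar <- mean(y)
    rs <- structure(list(asv_id = "slm", host_id = "slm",
                         days = seq_along(y), y = y, y_bar = ybar,
                         dropped_days = integer(), reference = "mle"),
                    class = "rescaled_series")
    soj <- extract_sojourns(rs, max_gap_days = 1)
    data.frame(sigma = sg, cv = sqrt(sg / (2 - sg)),
               mean_H = mean(vapply(soj, `[[`, 0, "H")),
               n_runs = length(soj))
  })
  curve <- do.call(rbind, rows)
  expo <- unname(stats::coef(stats::lm(log(mean_H) ~ log(cv),
                                       data = curve))[2])
  list(curve = curve, exponent = expo)
}

#' Map a fitted CV to the SLM noise strength
#'
#' Inverts \eqn{CV^2 = \sigma/(2-\sigma)}: \eqn{\sigma = 2CV^2/(1+CV^2)}.
#' Used to evaluate taxon-specific SLM predictions at each taxon's fitted
#' coefficient of variation.
#'
#' @param cv coefficient of variation (positive).
#' @return Noise strength `sigma` in (0, 2).
#' @export
sigma_from_cv <- function(cv) 2 * cv^2 / (1 + cv^2)
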