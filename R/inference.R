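#' One taxon's read-count time series in one host
#'
#' @param asv_id taxon label.
#' @param days strictly increasing integer observation days.
#' @param counts non-negative integer reads assigned to the taxon.
#' @param depths positive integer total reads per sample; `counts <= depths`.
#' @param host_id host label.
#' @return An object of class `"abundance_series"`.
#' @export
abundance_series <- function(asv_id, days, counts, depths, host_id = "host1") {
  days <- as.integer(days); counts <- as.integer(counts)
  depths <- as.integer(depths)
  stopifnot(length(days) == length(counts), length(counts) == length(depths),
            all(diff(days) > 0), all(counts >= 0), all(depths >= 1),
            all(counts <= depths))
  structure(list(asv_id = as.character(asv_id), days = days, counts = counts,
                 depths = depths, host_id = as.character(host_id)),
            class = "abundance_series")
}

# negative binomial log-likelihood of counts given (mean, cv):
# latent gamma abundance with mean xbar and shape beta = 1/cv^2, Poisson
# reads at depth N, marginally NB(size = beta, mu = N * xbar)
nb_loglik <- function(log_mean, log_beta, counts, depths) {
  mu <- depths * exp(log_mean)
  sum(stats::dnbinom(counts, size = exp(log_beta), mu = mu, log = TRUE))
}

#' Sampling-aware maximum-likelihood fit of a gamma abundance distribution
#'
#' Estimates a taxon's mean relative abundance and coefficient of variation
#' from read counts, integrating over the sequencing sampling process:
#' abundances are gamma distributed with mean \eqn{\bar{x}} and shape
#' \eqn{\beta = 1/\mathrm{CV}^2}, reads are Poisson at the sample's depth, so
#' counts are marginally negative binomial with mean \eqn{N_t \bar{x}} and
#' shape \eqn{\beta}. The likelihood is maximized in
#' \eqn{(\log\bar{x}, \log\beta)} with L-BFGS-B from a 3x3 grid of starts
#' around the plug-in moments; the CV is boxed to `[cv_min, cv_max]` and a
#' fit on the box edge is flagged as censored.
#'
#' @param series an [abundance_series()] with at least 10 observations and
#'   at least 2 distinct count values.
#' @param cv_min,cv_max box for the coefficient of variation.
#' @return An object of class `"gamma_fit"`: list with `mean`, `cv`,
#'   `beta` (`= cv^-2`), `loglik`, `n_obs`, `censored` (logical),
#'   `asv_id`, `host_id`.
#' @examples
#' set.seed(1)
#' x <- rgamma(300, shape = 1, scale = 1e-3)      # true mean 1e-3, CV 1
#' s <- abundance_series("a", 1:300, rpois(300, 1e4 * x), rep(1e4L, 300))
#' fit_gamma_sampling_mle(s)
#' @export
fit_gamma_sampling_mle <- function(series, cv_min = 0.01, cv_max = 50) {
  stopifnot(inherits(series, "abundance_series"))
  n <- length(series$counts)
  if (n < 10) stop("need at least 10 observations to fit")
  if (all(series$counts == 0))
    stop("no signal: all counts are zero for ", series$asv_id)
  if (length(unique(series$counts)) < 2)
    stop("need at least 2 distinct count values to fit")
  pm <- plugin_moments(series)
  cv0 <- min(max(pm$cv, cv_min * 2, 0.1), cv_max / 2)
  # beta box follows the cv box (beta = cv^-2)
  lb <- c(log(1e-12), -2 * log(cv_max))
  ub <- c(log(1), -2 * log(cv_min))
  starts <- expand.grid(lm = log(pm$mean) + log(c(0.5, 1, 2)),
                        lbta = -2 * log(cv0) + log(c(0.25, 1, 4)))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[k, ]), lb + 1e-8), ub - 1e-8)
    opt <- tryCatch(
      stats::optim(p0, function(p) -nb_loglik(p[1], p[2], series$counts,
                                              series$depths),
                   method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("fit failure: optimizer did not converge from any start for ",
         series$asv_id)
  mean_hat <- exp(best$par[1])
  beta_hat <- exp(best$par[2])
  cv_hat <- beta_hat^(-0.5)
  censored <- cv_hat <= cv_min * (1 + 1e-6) || cv_hat >= cv_max * (1 - 1e-6)
  structure(list(mean = mean_hat, cv = cv_hat, beta = beta_hat,
                 loglik = -best$value, n_obs = n, censored = censored,
                 asv_id = series$asv_id, host_id = series$host_id),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("gamma fit [%s]: mean = %.3g, CV = %.3g (beta = %.3g), logLik = %.2f, n = %d%s\n",
              x$asv_id, x$mean, x$cv, x$beta, x$loglik, x$n_obs,
              if (x$censored) ", CV censored at box edge" else ""))
  invisible(x)
}

#' Plug-in moment estimates of mean and CV
#'
#' Sample mean and coefficient of variation of the raw count/depth ratios,
#' with no correction for sampling noise. Population (divide-by-n) moment
#' convention throughout. Serves as the naive comparator and the
#' initialization for the sampling-aware MLE.
#'
#' @param series an [abundance_series()] with at least 2 observations.
#' @return List with `mean`, `cv`, and `constant` (TRUE when all ratios are
#'   equal, in which case `cv` is 0).
#' @export
plugin_moments <- function(series) {
  stopifnot(inherits(series, "abundance_series"),
            length(series$counts) >= 2)
  r <- series$counts / series$depths
  m <- mean(r)
  v <- mean((r - m)^2)
  if (m <= 0) stop("no signal: all counts are zero for ", series$asv_id)
  cv <- sqrt(v) / m
  list(mean = m, cv = cv, constant = v == 0)
}

#' Log-rescale an abundance series by its mean
#'
#' Computes \eqn{y(t) = \ln(x(t)/\bar{x})} with \eqn{x(t) = n_t/N_t}, the
#' log abundance rescaled by the taxon's fitted mean. Zero-count days have
#' no defined log abundance; they are excluded from `y` and recorded in
#' `dropped_days` so that downstream run extraction treats them as
#' run-breaking missing observations. The steady-state reference for
#' sojourn analysis is `y_bar`, the arithmetic mean of the retained `y`
#' (the time average of log abundance, not the log of the average).
#'
#' @param series an [abundance_series()].
#' @param fit a `"gamma_fit"` for the same taxon (or any object with a
#'   positive `mean` element).
#' @param reference `"mle"` or `"plugin"`: recorded provenance of the mean
#'   used.
#' @return An object of class `"rescaled_series"`: list with `asv_id`,
#'   `host_id`, `days`, `y`, `y_bar`, `dropped_days`, `reference`.
#' @export
rescale_log <- function(series, fit, reference = c("mle", "plugin")) {
  stopifnot(inherits(series, "abundance_series"), fit$mean > 0)
  reference <- match.arg(reference)
  keep <- series$counts > 0
  if (sum(keep) < 10)
    stop("insufficient data: fewer than 10 non-zero days for ",
         series$asv_id)
  y <- log((series$counts[keep] / series$depths[keep]) / fit$mean)
  structure(list(asv_id = series$asv_id, host_id = series$host_id,
                 days = series$days[keep], y = y, y_bar = mean(y),
                 dropped_days = series$days[!keep], reference = reference),
            class = "rescaled_series")
}

#' Construct a rescaled log-abundance series directly
#'
#' Builds the `"rescaled_series"` container from an already log-rescaled
#' vector `y` (for example the log of a simulated latent trajectory).
#' [rescale_log()] is the constructor for count data; this one serves
#' simulation studies where the latent abundance is known exactly.
#'
#' @param y log-rescaled abundances (finite).
#' @param days integer observation days (default `1:length(y)`).
#' @param dropped_days days treated as run-breaking missing observations.
#' @param asv_id,host_id labels.
#' @param reference provenance label for the mean used (default
#'   `"latent"`).
#' @return A `"rescaled_series"` with `y_bar = mean(y)`.
#' @export
rescaled_series <- function(y, days = seq_along(y),
                            dropped_days = integer(), asv_id = "sim",
                            host_id = "sim", reference = "latent") {
  stopifnot(all(is.finite(y)), length(days) == length(y),
            all(diff(days) > 0))
  structure(list(asv_id = asv_id, host_id = host_id,
                 days = as.integer(days), y = y, y_bar = mean(y),
                 dropped_days = as.integer(dropped_days),
                 reference = reference),
            class = "rescaled_series")
}

#' Filter taxa by occupancy and sample count
#'
#' Retains the consistently observed taxa on which sojourn statistics are
#' computed: those detected (non-zero count) in at least a fraction
#' `occupancy_min` of samples and present in at least `n_obs_min` samples.
#'
#' @param counts taxa-by-samples integer matrix (rows named by ASV id).
#' @param days integer collection days for the columns.
#' @param depths per-sample total depths (defaults to column sums).
#' @param occupancy_min minimum fraction of samples with non-zero count.
#' @param n_obs_min minimum number of samples.
#' @param host_id host label attached to the resulting series.
#' @return List with `series` (list of [abundance_series()] for retained
#'   taxa) and `discarded` (data frame of ASV id and reason).
#' @export
filter_asvs <- function(counts, days, depths = colSums(counts),
                        occupancy_min = 0.9, n_obs_min = 50,
                        host_id = "host1") {
  stopifnot(is.matrix(counts), ncol(counts) == length(days),
            length(depths) == length(days))
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("ASV%03d", seq_len(nrow(counts)))
  series <- list()
  disc <- list()
  for (i in seq_len(nrow(counts))) {
    occ <- mean(counts[i, ] > 0)
    if (ncol(counts) < n_obs_min) {
      disc[[ids[i]]] <- "fewer samples than n_obs_min"
    } else if (occ < occupancy_min) {
      disc[[ids[i]]] <- sprintf("occupancy %.3f below %.3f", occ,
                                occupancy_min)
    } else {
      series[[ids[i]]] <- abundance_series(ids[i], days, counts[i, ],
                                           depths, host_id)
    }
  }
  discarded <- if (length(disc))
    data.frame(asv_id = names(disc), reason = unlist(disc),
               row.names = NULL)
  else data.frame(asv_id = character(), reason = character())
  list(series = series, discarded = discarded)
}

#' Write per-taxon gamma fits as CSV
#'
#' @param fits list of `"gamma_fit"` objects.
#' @param path output CSV path (optional; omit to just get the data frame).
#' @return Data frame with one row per fit.
#' @export
fits_table <- function(fits, path = NULL) {
  df <- data.frame(
    asv_id = vapply(fits, `[[`, "", "asv_id"),
    host_id = vapply(fits, `[[`, "", "host_id"),
    mean = vapply(fits, `[[`, 0, "mean"),
    cv = vapply(fits, `[[`, 0, "cv"),
    beta = vapply(fits, `[[`, 0, "beta"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    n_obs = vapply(fits, function(f) as.integer(f$n_obs), 0L),
    censored_flag = vapply(fits, `[[`, FALSE, "censored"))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
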