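#' Stochastic logistic model parameters
#'
#' Bundle the three parameters of the stochastic logistic model (SLM) of
#' growth, \deqn{dx/dt = (x/\tau)(1 - x/K) + \sqrt{\sigma/\tau}\, x\, \eta(t),}
#' where \eqn{\eta(t)} is Gaussian white noise with zero mean and
#' delta-function time correlation, together with the sampling interval
#' `delta_t` at which the process is observed.
#'
#' The stationary distribution of the SLM is a gamma with shape
#' \eqn{2/\sigma - 1} and scale \eqn{K\sigma/2}; it exists only for
#' \eqn{0 < \sigma < 2}. Its mean is \eqn{K(1 - \sigma/2)} and its squared
#' coefficient of variation is \eqn{\sigma/(2 - \sigma)}.
#'
#' @param tau growth timescale in days (inverse of the maximum growth rate);
#'   must be positive.
#' @param K carrying capacity on the relative-abundance scale; must be
#'   positive.
#' @param sigma strength of environmental noise; must lie in (0, 2) for a
#'   stationary distribution to exist (`sigma = 0` is allowed and gives the
#'   deterministic logistic equation).
#' @param delta_t sampling interval in days (default 1, daily sampling).
#'
#' @return An object of class `"slm_params"`: a list with elements `tau`,
#'   `K`, `sigma`, `delta_t`.
#' @seealso [simulate_slm()], [sample_stationary_gamma()]
#' @export
slm_params <- function(tau, K, sigma, delta_t = 1) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0,
            is.numeric(K), length(K) == 1L, is.finite(K), K > 0,
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            sigma >= 0,
            is.numeric(delta_t), length(delta_t) == 1L, delta_t > 0)
  if (sigma >= 2)
    stop("sigma must be < 2: the SLM has no stationary distribution for sigma >= 2")
  structure(list(tau = tau, K = K, sigma = sigma, delta_t = delta_t),
            class = "slm_params")
}

#' @export
print.slm_params <- function(x, ...) {
  cat(sprintf("SLM parameters: tau = %g d, K = %g, sigma = %g (delta_t = %g d)\n",
              x$tau, x$K, x$sigma, x$delta_t))
  if (x$sigma > 0 && x$sigma < 2)
    cat(sprintf("  stationary gamma: shape %g, scale %g; mean %g, CV %g\n",
                2 / x$sigma - 1, x$K * x$sigma / 2,
                x$K * (1 - x$sigma / 2), sqrt(x$sigma / (2 - x$sigma))))
  invisible(x)
}

#' Simulate an SLM trajectory by Euler-Maruyama integration
#'
#' Integrates the stochastic logistic model under the Ito convention and
#' returns the latent trajectory on the integration grid. The
#' Euler-Maruyama update is applied to the exactly Ito-transformed log
#' abundance \eqn{y = \ln x},
#' \deqn{y \leftarrow y + \left[\frac{1 - e^y/K}{\tau} - \frac{\sigma}{2\tau}\right] dt + \sqrt{\sigma/\tau}\,\sqrt{dt}\,N(0,1),}
#' in which the multiplicative noise is additive and positivity is
#' automatic; this removes the near-zero discretization bias an abundance-
#' space update shows when `sigma` approaches 2 (the stationary gamma then
#' has shape < 1 and diverges at the origin).
#'
#' @param params an [slm_params()] object.
#' @param x0 initial abundance, positive. Default: a draw from the
#'   stationary gamma (or `K/2` when `sigma = 0`).
#' @param t_end total integration time in days.
#' @param dt_int integration step in days; must not exceed `tau/10`.
#'   Default `tau/100`.
#' @param seed optional integer seed (applied via [set.seed()]).
#'
#' @return Numeric vector of abundances at times `dt_int * (1:n)`,
#'   `n = round(t_end/dt_int)`.
#' @examples
#' p <- slm_params(tau = 1, K = 1e-3, sigma = 1)
#' x <- simulate_slm(p, t_end = 100, seed = 1)
#' mean(x) # close to K(1 - sigma/2) = 5e-4 for long t_end
#' @export
simulate_slm <- function(params, x0 = NULL, t_end, dt_int = params$tau / 100,
                         seed = NULL) {
  stopifnot(inherits(params, "slm_params"), t_end > 0, dt_int > 0)
  if (dt_int > params$tau / 10 + 1e-12)
    stop("dt_int must be <= tau/10 so the integration grid resolves the dynamics")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) {
    x0 <- if (params$sigma > 0)
      stats::rgamma(1L, shape = 2 / params$sigma - 1,
                    scale = params$K * params$sigma / 2)
    else params$K / 2
    x0 <- max(x0, 1e-12 * params$K)
  }
  stopifnot(x0 > 0)
  n <- as.integer(round(t_end / dt_int))
  .slm_path_cpp(x0, params$tau, params$K, params$sigma, n, dt_int, dt_int)
}

#' Simulate an SLM trajectory recorded on the observation grid
#'
#' Integrates the SLM as [simulate_slm()] but returns only the state every
#' `params$delta_t` days, the way a daily sampling scheme observes it.
#' Starts from a stationary draw by default, so long series are stationary
#' throughout.
#'
#' @param params an [slm_params()] object (its `delta_t` sets the
#'   recording interval).
#' @param n_obs number of recorded observations.
#' @param x0 initial abundance (default: stationary gamma draw).
#' @param dt_int integration step (default `min(tau, delta_t)/100`).
#' @param seed optional integer seed.
#' @return Numeric vector of `n_obs` abundances, `delta_t` apart.
#' @export
slm_observed_path <- function(params, n_obs, x0 = NULL,
                              dt_int = min(params$tau, params$delta_t) / 100,
                              seed = NULL) {
  stopifnot(inherits(params, "slm_params"), n_obs >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) {
    x0 <- if (params$sigma > 0)
      stats::rgamma(1L, shape = 2 / params$sigma - 1,
                    scale = params$K * params$sigma / 2)
    else params$K / 2
    x0 <- max(x0, 1e-12 * params$K)
  }
  .slm_path_cpp(x0, params$tau, params$K, params$sigma, as.integer(n_obs),
                params$delta_t, dt_int)
}

#' Draw from the stationary gamma distribution of the SLM
#'
#' The stationary abundance fluctuation distribution of the stochastic
#' logistic model is gamma with shape \eqn{2/\sigma - 1} and scale
#' \eqn{K\sigma/2}. This is the "no temporal structure" reference used by
#' the stationary null model.
#'
#' @param params an [slm_params()] object with `0 < sigma < 2`.
#' @param n number of independent draws (0 allowed).
#' @param seed optional integer seed.
#' @return Numeric vector of `n` i.i.d. abundance draws.
#' @export
sample_stationary_gamma <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "slm_params"), n >= 0)
  if (params$sigma <= 0 || params$sigma >= 2)
    stop("no stationary distribution: sigma must lie in (0, 2)")
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(as.integer(n), shape = 2 / params$sigma - 1,
                scale = params$K * params$sigma / 2)
}
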