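---
title: "Sojourn-trajectory macroecology under the stochastic logistic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sojourn-trajectory macroecology under the stochastic logistic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

Dense gut-microbiome time series show taxa that fluctuate around a
characteristic abundance for months: excursions away from the steady state
are followed by returns, not by drift to extinction or dominance.
`microsojourn` quantifies those excursions — *sojourn trajectories* — and
interprets them with a minimal ecological model, the stochastic logistic
model (SLM) of growth. This vignette is the package's methodological
account: the model and its assumptions, the statistics it computes, the
numerical and design choices that were genuinely open, and what the
simulation-based tests do and do not establish about real data.

## The model

Each taxon's relative abundance $x_i(t)$ is assumed to follow

$$\frac{dx_i}{dt} = \frac{x_i}{\tau_i}\Big(1 - \frac{x_i}{K_i}\Big)
  + \sqrt{\frac{\sigma_i}{\tau_i}}\, x_i\, \eta_i(t),$$

with three parameters: the growth timescale $\tau_i$ (days; the inverse of
the maximum growth rate), the carrying capacity $K_i$ (relative-abundance
scale), and the environmental noise strength $\sigma_i$. The noise
$\eta_i(t)$ is Gaussian and white: zero mean, delta-correlated in time.
Under the Itô convention the stationary distribution is a gamma with shape
$2/\sigma_i - 1$ and scale $K_i\sigma_i/2$; it exists only for
$\sigma_i < 2$. Two consequences organize everything downstream:

* the stationary mean is $\bar{x}_i = K_i(1 - \sigma_i/2)$ — a function of
  both $K_i$ and $\sigma_i$;
* the squared coefficient of variation is
  $\mathrm{CV}_i^2 = \sigma_i/(2 - \sigma_i)$ — a function of $\sigma_i$
  alone.

Because all sojourn statistics act on the log-rescaled abundance
$y_i(t) = \ln\!\big(x_i(t)/\bar{x}_i\big)$, the carrying capacity drops out
of every prediction: $K_i$ sets the scale of abundance, not the shape of
its fluctuations. The model is single-species — no interactions — and
treats all temporal variability beyond logistic self-limitation as
environmental noise; demographic noise and within-day dynamics are out of
scope.

## From reads to rescaled series

Sequencing observes $x_i(t)$ only through $n_t$ reads out of a depth
$N_t$. The inference module treats abundances as gamma distributed (mean
$\bar{x}$, shape $\beta = 1/\mathrm{CV}^2$) and reads as Poisson at depth
$N_t$, so counts are marginally negative binomial with mean $N_t\bar{x}$
and shape $\beta$. `fit_gamma_sampling_mle()` maximizes that likelihood in
$(\log\bar{x}, \log\beta)$ by L-BFGS-B from a $3\times 3$ grid of starts
around the plug-in moments. The CV is boxed to $[0.01, 50]$; a fit pinned
to the box edge is flagged `censored` rather than silently reported. The
choice of a Poisson (rather than binomial/hypergeometric) read layer
matches the standard sampling-aware treatment of abundance fluctuation
distributions at the depths of modern 16S libraries, where
$\bar{x} N_t \ll N_t$ makes the two indistinguishable.

`rescale_log()` forms $y(t) = \ln\!\big((n_t/N_t)/\bar{x}\big)$. Two
conventions matter:

* **The steady-state reference is $\bar{y}$, the time average of $y$,**
  not zero. For a gamma distribution the mean of the log differs from the
  log of the mean, and sojourns are defined by crossings of the *typical*
  log abundance.
* **Zero-count days carry no defined $y$.** They are excluded from the
  series and recorded, and they break (and discard) any run they
  interrupt downstream. The sojourn analysis is restricted to
  consistently observed taxa (`filter_asvs()`, default occupancy
  $\ge 0.9$ of samples and $\ge 50$ samples), so such days are rare by
  construction.

## Sojourns, residences, returns

A sojourn trajectory is a maximal run of consecutive observations with
$y(t) - \bar{y}$ of constant sign, bounded by *observed* crossings on both
sides. Runs touching either end of a series are discarded: their return
was never observed. Duration $T$ counts observations (days, at daily
sampling); height $H$ is the peak $|y - \bar{y}|$ within the run (the
summed absolute deviation is carried as `area` for users who prefer an
integral measure). Three rules handle imperfect sampling, chosen to avoid
ever fabricating dynamics inside unobserved windows:

* a sampling gap of at most `max_gap_days` (default 2) is bridged only if
  the sign is unchanged across it;
* a gap with a sign change, a gap longer than `max_gap_days`, or an
  excluded zero-count day terminates and discards the interrupted runs —
  the crossing time is unknowable;
* a value exactly equal to $\bar{y}$ (measure-zero for continuous
  abundances; a numerical coincidence in practice) terminates runs and
  joins none, and its neighbours cannot claim an observed opposite-sign
  crossing through it.

Residence and return times — interior runs of consecutive presences
($n_t > 0$) and absences ($n_t = 0$) — use the same scanner on the
presence indicator, over *all* taxa rather than the high-occupancy subset.
The scanner is deliberately simple (segment splitting plus run-length
encoding) and is tested exhaustively against an independent brute-force
reference over all 4,096 length-12 sign sequences and $10^4$ random longer
ones.

## Null models and the divergence statistic

Two nulls share the data's marginal structure but lack temporal ordering:
i.i.d. draws from the fitted stationary gamma pushed through the same
Poisson read layer (`gamma_iid_null()`), and uniform permutation of the
observed $y$ values over the observed days (`permutation_null()`). Both
are pushed through the identical run-extraction machinery, so they differ
from the data *only* in temporal structure.

`distribution_divergence()` reports the Kullback–Leibler divergence
$D(\hat{p}_{\mathrm{emp}} \,\|\, \hat{p}_{\mathrm{null}})$ on the union
support, after pooling durations above the null's 99th percentile into a
single tail bin and adding a pseudo-mass of $10^{-6}$ to the null. KL is
the default because "divergence" most often means KL and the orderings of
interest are insensitive to the choice; Jensen–Shannon is available via
`method = "js"` for users who want symmetry and boundedness. Because the
magnitude of an empirical KL is meaningless without a reference, every
null carries a calibration: the divergence of each null replicate's own
distribution from the pooled null, summarized as a mean and SD. Replicates
are pooled *by permutation index across taxa*, so each calibration
replicate has the same sample size as the empirical pooled distribution —
otherwise the band would be systematically too wide. A host-level
empirical divergence beyond mean $+ 3$ SD is flagged as exceeding the
band.

## Simulation-based SLM predictions

The analytic time-dependent solution of the SLM is deliberately not used:
predictions (`predict_sojourn_pmf()`, `predict_mean_T()`,
`predict_height_cv_scaling()`, `fit_tau()`) come from long simulations
pushed through the *identical* sojourn machinery as the data, which
guarantees that theory and measurement share every convention (reference
level, interior-run rule, gap handling). Two closed-form limits anchor the
simulations analytically:

* **i.i.d. limit.** As $\tau/\delta t \to 0$ successive observations
  decorrelate and $p(T)$ approaches the geometric law $2^{-T}$ with mean
  2 (up to a small asymmetry because $P(y > \bar{y}) \ne 1/2$ for the
  skewed log-gamma; at $\sigma = 1$ this shifts the mean run length to
  about 2.04).
* **Small-noise limit.** For $\sigma \to 0$, $y$ is an Ornstein–Uhlenbeck
  process; sampled every $\delta t$ it is a Gaussian AR(1) with
  $\rho = e^{-\delta t/\tau}$, whose sign persistence is
  $P = 1/2 + \arcsin(\rho)/\pi$ and whose mean run length is $1/(1-P)$.
  Simulated mean sojourn times match this within 5% for $\sigma \le 0.1$.

`fit_tau()` recovers the timescale by grid search, minimizing the
divergence between a target $p(T)$ and the simulated prediction, ties
broken toward the smaller $\tau$. For taxon-specific predictions the
fitted CV maps to $\sigma = 2\,\mathrm{CV}^2/(1 + \mathrm{CV}^2)$; when
one $\tau$ is fitted to a host's pooled $p(T)$, the abundance-weighted
median taxon $\sigma$ is used.

## Numerical integration

The integrator applies Euler–Maruyama to the exactly Itô-transformed log
abundance,
$dy = \big[(1 - e^{y}/K)/\tau - \sigma/(2\tau)\big]dt +
\sqrt{\sigma/\tau}\,dW$, rather than to $x$ itself. In $y$ the noise is
additive — the multiplicative factor is handled exactly and positivity is
automatic. This choice is load-bearing at large $\sigma$: with shape
$2/\sigma - 1 < 1$ the stationary density diverges at the origin, and an
abundance-space update with a reflection floor visibly distorts the
near-zero mass (one-sample KS against the exact gamma plateaus near
0.02–0.04 at $n = 5000$ for $\sigma = 1.5$ regardless of step size,
whereas the log-space update sits at the sampling floor of roughly 0.01).
The default step is $\min(\tau, \delta t)/100$; a step above $\tau/10$ is
refused. Stationarity is guarded by a distributional test across
$\sigma \in \{0.25, 0.5, 1, 1.5\}$.

## The synthetic-data generator

`generate_community()` emulates the structure of a daily 16S study:
independent SLM taxa with log-uniform $K \in [10^{-5}, 10^{-2}]$ and
uniform $\sigma \in [0.2, 1.5]$ (spanning weakly to strongly fluctuating
taxa while staying clear of the $\sigma = 2$ boundary), a shared
$\tau$, 300 scheduled days, and zero-truncated Poisson depths around
$10^4$ reads — typical of the dense time series this analysis targets.
Reads are multinomial given depth; focal abundances are normalized as
$x/(1 + \sum x)$ so a passive "everything else" slot absorbs the
remaining mass while each focal taxon's marginal dynamics are
approximately preserved (that residual is written as an `OTHER` row so
depths survive the round trip through TSV). One master seed drives
deterministic per-taxon child streams, so any single taxon is
reproducible in isolation.

What the generator does *not* emulate — and therefore what passing tests
cannot establish about real data: species interactions, demographic noise,
compositional coupling beyond the passive residual, day-to-day depth
correlations, taxonomic assignment error, and any non-stationarity
(diet shifts, travel, antibiotics). Tests on synthetic communities show
the machinery is correct and well calibrated under the model's own
assumptions, not that the gut obeys the SLM.

## Design choices on genuinely open points

* **Height.** $H$ is the peak deviation; "height" reads most naturally as
  a maximum, and the area alternative is exported alongside rather than
  chosen.
* **Folding.** Above- and below-reference trajectories are pooled after
  multiplying deviations by the run sign, treating excursion direction as
  exchangeable in the deviation-profile analysis.
* **Rescaling mean.** The MLE mean is the default reference for
  $y$; the plug-in mean is available (`reference = "plugin"`) since either
  convention is defensible and the deviation statistics subtract
  $\bar{y}$ anyway.
* **Permutation scope.** Permutations are per taxon, pooled afterwards;
  community-wide permutation would destroy cross-taxon depth structure
  as well as temporal order, conflating two kinds of signal.
* **CV convention.** Population (divide-by-$n$) moments everywhere, so
  the plug-in estimator and the MLE agree in their infinite-depth limits.

## A caution on discretely sampled excursion exponents

Two classical excursion results — height independent of duration and a
duration-scaling exponent $\alpha = 0$ for the mean within-sojourn
deviation — hold for the SLM in the regime where the growth timescale is
far below the typical sojourn time. They do **not** transfer verbatim to
discretely sampled runs at $\tau \approx \delta t$, the regime of daily
stool sampling. The package's own simulations (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`) show that
at $\tau = \delta t$, $\sigma = 1$ the folded estimator gives
$\alpha \approx 0.4$ over $T \in [2, 10]$, decaying to $\approx 0$ only
for $\tau \ll \delta t$ (the estimator is exact in the i.i.d. limit: a
Gaussian white-noise series yields $\alpha \approx 0$ to three decimals).
Likewise the rank correlation between $H$ and $T$ is mechanically
positive for *any* sampled process — the maximum of $T$ draws grows
stochastically with $T$, giving $\rho \approx 0.43$ even for i.i.d.
observations — so "$H$ independent of $T$" should be read as a statement
about the analytic excursion limit, not about the sampled max-of-run
statistic. Users comparing these exponents against empirical claims
should be explicit about which regime and which estimator they mean.

A third estimator effect concerns the $\langle T\rangle$–mean-abundance
relationship. Under the SLM, sojourn statistics are independent of the
carrying capacity, so no relationship is expected. But any taxon with
occasional zero-count days has runs broken *and discarded* at those days,
and long runs are hit more often than short ones: the surviving sojourns
of low-abundance taxa are length-biasedly short. At the default occupancy
threshold of 0.9 this induces a positive rank correlation of roughly
0.4–0.7 between fitted mean abundance and $\langle T\rangle$ on synthetic
communities where the true correlation is zero; restricting to taxa
detected in every sample removes it (at the price of far fewer taxa).
Any empirical claim about $\langle T\rangle$ versus mean abundance
should therefore be made on the zero-free subset, or at least checked
against it.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
keep Monte-Carlo error well inside each tolerance: 100 series of 5,000
days for the deviation-scaling exponent ($\sim 1.2\times 10^5$ pooled
sojourns); $5\times 10^5$ simulated days for a $\tau$-fit target and
$2\times 10^5$ per grid candidate, replicated over 20 seeds; $n = 5000$
thinned samples per stationarity check; 100 synthetic hosts for the
divergence calibration. The C++ integrator advances roughly $3\times 10^7$
steps per second, so the full suite completes in minutes on one core.

## Worked example

```{r, eval = FALSE}
library(microsojourn)

comm <- generate_community(30, K_range = c(1e-4, 1e-2),
                           sigma_range = c(0.3, 1.2), tau = 1,
                           sampling_scheme(n_days = 300, depth_mean = 1e4,
                                           seed = 7))
cfg <- run_config(seed = 7, out_dir = "sojourn_run")
res <- run_pipeline(cfg, community = comm)

res$relationships   # <T> vs mean (null), <T> vs CV (positive), H vs T
res$divergence      # empirical vs null divergences with calibration bands
res$tau_fit$tau     # grid-fitted growth timescale
```

## Known limitations

Beyond the generator's scope listed above: the gamma-Poisson likelihood
ignores overdispersion of the read layer itself (PCR amplification noise
would widen the negative binomial); $\tau$ is fitted per host, not per
taxon, because a single host rarely yields enough sojourns per taxon to
resolve taxon-level timescales; divergences across hosts are reported raw,
without multiple-testing correction; and the boundary-run discard makes
the longest observable sojourn scale with the series length, so $p(T)$
tails are censored in short studies.
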