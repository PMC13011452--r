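# microsojourn

Sojourn-trajectory macroecology for dense microbiome time series, under
the stochastic logistic model (SLM) of growth.

In healthy hosts, many gut taxa fluctuate around a characteristic
abundance for months: they leave their steady state and come back. Each
such excursion — a maximal run of consecutive observations with the
log-rescaled abundance $y_i(t) = \ln(x_i(t)/\bar{x}_i)$ on one side of its
time average, bounded by observed crossings — is a *sojourn trajectory*,
with a duration $T$ (number of observations) and a height $H$ (peak
$|y - \bar y|$). `microsojourn` is for microbial ecologists who have an
ASV-by-sample count table from daily or near-daily 16S sampling and want
to ask: do sojourn durations carry temporal signal beyond the abundance
distribution itself, and does a minimal model explain them?

The model is the SLM,

$$\frac{dx}{dt} = \frac{x}{\tau}\Big(1-\frac{x}{K}\Big) +
\sqrt{\frac{\sigma}{\tau}}\,x\,\eta(t),$$

whose stationary abundance distribution is a gamma with shape
$2/\sigma - 1$ and scale $K\sigma/2$, so the mean is $K(1-\sigma/2)$ and
the squared CV is $\sigma/(2-\sigma)$. Everything the package predicts
about sojourns depends on $(\tau, \sigma)$ and the sampling interval
$\delta t$ only — the carrying capacity cancels in the log-rescaling.

The package provides:

* **sampling-aware inference** of each taxon's mean and CV from read
  counts (gamma abundance + Poisson reads = negative binomial
  likelihood), with the naive plug-in moments as comparator;
* **run statistics**: sojourn extraction with explicit gap/missing-day
  rules, the sojourn-time distribution $p(T)$, per-taxon mean sojourn
  times, within-sojourn deviation profiles and their duration-scaling
  exponent, and residence/return times from presence/absence;
* **two null models** (i.i.d. stationary-gamma draws and time-label
  permutation) with a calibrated Kullback–Leibler divergence statistic;
* **simulation-based SLM predictions**: the predicted $p(T)$, a grid-search
  fit of $\tau$, the $\langle T\rangle$–CV curve, and the $H$–CV scaling
  exponent, all pushed through the identical run machinery as the data;
* **a synthetic-data generator** (SLM communities observed through
  finite-depth multinomial sequencing) so the whole pipeline is testable
  without any external data.

## Worked example

```r
library(microsojourn)

comm <- generate_community(50, K_range = c(1e-5, 1e-2),
                           sigma_range = c(0.2, 1.5), tau = 1,
                           sampling_scheme(n_days = 300, depth_mean = 1e4,
                                           seed = 42))
cfg <- run_config(seed = 42, out_dir = "sojourn_run")
res <- run_pipeline(cfg, community = comm)
#> loaded 50 taxa x 300 samples (host synthH1)
#> retained 19 / 50 taxa
#> found 1928 sojourns, <T> = 2.56
#> mean_T vs mean_abundance: rho = 0.665, p = 0.0050
#> mean_T vs cv: rho = 0.626, p = 0.0030
#> H vs T: rho = 0.578, p = 0.0010
#> fitted tau = 1 (sigma_host = 0.436)
```

Reading those numbers: 19 of 50 simulated taxa are observed consistently
enough (non-zero in ≥ 90% of samples) to analyze. Their pooled sojourns
have mean duration ≈ 2.6 days; the grid search recovers the generating
timescale τ = 1 day. The per-taxon mean sojourn time rises strongly with
the CV (ρ = 0.63, permutation p = 0.003) — the SLM's signature, since
$\langle T\rangle$ is set by the noise strength. The apparent correlation
with mean abundance (ρ = 0.67) is an estimator artifact worth knowing
about: taxa with occasional zero-count days have runs broken and
discarded at those days, which length-biasedly truncates the sojourns of
low-abundance taxa; among taxa observed in *every* sample the
correlation disappears (see the vignette's caveat section). And
`res$divergence` shows the pooled sojourn distribution diverging from
both temporal-structure-free nulls far beyond their calibration bands
(0.063 against a null of 0.0012 ± 0.0006), with the sojourn divergence
exceeding both the residence and the return divergence
(`sojourn_greatest = TRUE`) — sojourn times carry the most temporal
signal.

All outputs (fits, trajectories, pmfs, profiles, divergence table,
relationship tests, prediction curves, a summary figure) are written as
provenance-stamped CSVs under `cfg$out_dir`.

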