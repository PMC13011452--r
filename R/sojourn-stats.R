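#' @useDynLib microsojourn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Core run scanner. Splits an observation sequence into segments at
# break points, finds maximal runs of constant sign within each segment,
# and discards the first and last run of every segment: a valid sojourn
# must be bounded by observed crossings on both sides.
#
# Break rules between consecutive retained observations (days d1 < d2):
#   - any dropped (zero-count) day strictly between d1 and d2
#   - d2 - d1 > max_gap_days (too large a sampling gap to bridge)
#   - d2 - d1 > delta (an unsampled day) AND the sign changes across the
#     gap (the crossing time is unobserved, so neither run can be trusted)
# A gap <= max_gap_days with unchanged sign is bridged; T counts
# observations, not calendar days. A value exactly on the reference level
# (sign 0) is treated as a break of its own.
scan_runs <- function(values, days, reference = 0, max_gap_days = 2,
                      delta = 1, dropped_days = integer()) {
  n <- length(values)
  if (n < 1) return(list())
  dev <- values - reference
  s <- sign(dev)
  brk <- logical(n)  # brk[i]: segment break between obs i-1 and i
  if (n > 1) {
    gap <- diff(days)
    has_drop <- vapply(seq_len(n - 1L), function(i)
      any(dropped_days > days[i] & dropped_days < days[i + 1L]), FALSE)
    brk[-1] <- has_drop | gap > max_gap_days |
      (gap > delta + 1e-9 & s[-n] != s[-1])
  }
  seg_id <- cumsum(c(1L, as.integer(brk[-1])))
  out <- list()
  for (g in unique(seg_id)) {
    idx <- which(seg_id == g)
    ss <- s[idx]
    r <- rle(ss)
    m <- length(r$lengths)
    if (m < 3) next  # no interior run possible
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in 2:(m - 1L)) {
      if (r$values[k] == 0) next
      # neighbours must carry an actual (possibly zero) crossing; a
      # zero-valued neighbour run does not provide an opposite sign
      if (r$values[k - 1L] == 0 || r$values[k + 1L] == 0) next
      ii <- idx[starts[k]:ends[k]]
      out[[length(out) + 1L]] <-
        list(sign = r$values[k], start_day = days[ii[1]],
             end_day = days[ii[length(ii)]], T = length(ii),
             deviations = dev[ii])
    }
  }
  out
}

#' Extract sojourn trajectories from a rescaled series
#'
#' A sojourn trajectory is a maximal run of consecutive observations in
#' which the log-rescaled abundance stays on one side of its time-averaged
#' value `y_bar`, bounded by observed crossings on both sides. Runs touching
#' either end of the series (or a break) are discarded because the return to
#' steady state was not observed. Sampling gaps up to `max_gap_days` are
#' bridged only when the sign is unchanged across the gap; larger gaps,
#' gaps with a sign change, zero-count days, and values exactly at `y_bar`
#' all terminate and discard the runs they interrupt.
#'
#' @param series a [rescale_log()] result (`"rescaled_series"`).
#' @param max_gap_days largest bridgeable sampling gap in days (default 2).
#' @return List of `"sojourn_trajectory"` objects, each with `asv_id`,
#'   `host_id`, `sign` (+1 above / -1 below), `start_day`, `end_day`,
#'   `T` (number of observations), `H` (peak absolute deviation), `area`
#'   (summed absolute deviation), `deviations` (ordered `y - y_bar`).
#' @examples
#' s <- structure(list(asv_id = "a", host_id = "h", days = 1:8,
#'                     y = c(1, 1, -1, -2, -1, 1, 2, -1), y_bar = 0,
#'                     dropped_days = integer(), reference = "mle"),
#'                class = "rescaled_series")
#' length(extract_sojourns(s))  # the interior runs
#' @export
extract_sojourns <- function(series, max_gap_days = 2) {
  stopifnot(inherits(series, "rescaled_series"))
  if (length(series$y) < 3) return(list())
  runs <- scan_runs(series$y, series$days, reference = series$y_bar,
                    max_gap_days = max_gap_days,
                    dropped_days = series$dropped_days)
  lapply(runs, function(r) {
    structure(list(asv_id = series$asv_id, host_id = series$host_id,
                   sign = r$sign, start_day = r$start_day,
                   end_day = r$end_day, T = r$T,
                   H = max(abs(r$deviations)),
                   area = sum(abs(r$deviations)),
                   deviations = r$deviations),
              class = "sojourn_trajectory")
  })
}

#' Empirical run-length distribution
#'
#' Pools the durations of the given trajectories (or a bare integer vector
#' of run lengths) into an empirical probability mass function over T and
#' its mean.
#'
#' @param trajectories list of sojourn trajectories, or an integer vector of
#'   run lengths.
#' @param kind label: `"sojourn"`, `"residence"` or `"return"`.
#' @return An object of class `"run_length_summary"`: list with `kind`,
#'   `pmf` (data frame `T`, `prob`), `mean_T`, `n_runs`.
#' @export
sojourn_time_distribution <- function(trajectories, kind = "sojourn") {
  Tv <- if (is.numeric(trajectories)) as.integer(trajectories)
  else vapply(trajectories, function(tr) as.integer(tr$T), 0L)
  if (length(Tv) == 0)
    stop("empty summary: no trajectories to pool")
  tab <- table(Tv)
  pmf <- data.frame(T = as.integer(names(tab)),
                    prob = as.numeric(tab) / sum(tab))
  structure(list(kind = kind, pmf = pmf,
                 mean_T = sum(pmf$T * pmf$prob), n_runs = length(Tv)),
            class = "run_length_summary")
}

#' @export
print.run_length_summary <- function(x, ...) {
  cat(sprintf("%s run-length distribution: %d runs, <T> = %.3f, support %d..%d\n",
              x$kind, x$n_runs, x$mean_T, min(x$pmf$T), max(x$pmf$T)))
  invisible(x)
}

#' Mean within-sojourn deviation profile for a given duration
#'
#' Pools all trajectories of duration exactly `T` (after multiplying each
#' trajectory's deviations by its sign, so above- and below-mean excursions
#' fold onto positive deviations) and returns the position-wise arithmetic
#' mean deviation.
#'
#' @param trajectories list of sojourn trajectories.
#' @param T duration to pool.
#' @param fold fold below-mean trajectories by sign (default TRUE); with
#'   `fold = FALSE` only above-mean trajectories are pooled.
#' @return Numeric vector of length `T`: the mean deviation at each
#'   within-sojourn position, with attribute `n` (trajectories pooled).
#' @export
mean_deviation_profile <- function(trajectories, T, fold = TRUE) {
  sel <- Filter(function(tr) tr$T == T && (fold || tr$sign > 0),
                trajectories)
  if (length(sel) == 0)
    stop("no trajectory of duration T = ", T)
  mat <- vapply(sel, function(tr) tr$deviations * tr$sign, numeric(T))
  mat <- matrix(mat, nrow = T)
  prof <- rowMeans(mat)
  attr(prof, "n") <- length(sel)
  prof
}

#' Fit the duration-scaling exponent of the mean sojourn deviation
#'
#' For each duration T in `T_range` with at least `min_per_T` pooled
#' trajectories, computes the mean deviation profile and its mean over
#' positions, then estimates the exponent alpha as the least-squares slope
#' of log mean deviation against log T. An exponent of zero means sojourn
#' excursions have the same typical deviation whatever their duration, so
#' trajectories of different T need no rescaling to share a shape.
#'
#' @param trajectories list of sojourn trajectories.
#' @param T_range integer durations to include (default 2:10).
#' @param min_per_T minimum trajectories per duration (default 20).
#' @param n_boot bootstrap replicates (over trajectories) for the slope
#'   confidence interval.
#' @param fold see [mean_deviation_profile()].
#' @param seed optional seed for the bootstrap.
#' @return An object of class `"scaling_fit"`: list with `alpha`,
#'   `slope_ci` (2.5/97.5 percentile bootstrap), `n_points`, and the
#'   per-duration table `magnitudes` (`T`, `mag`, `n`).
#' @export
fit_alpha <- function(trajectories, T_range = 2:10, min_per_T = 20,
                      n_boot = 200, fold = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!fold) trajectories <- Filter(function(tr) tr$sign > 0, trajectories)
  Tv <- vapply(trajectories, function(tr) as.integer(tr$T), 0L)
  counts <- vapply(T_range, function(TT) sum(Tv == TT), 0L)
  use <- T_range[counts >= min_per_T]
  if (length(use) < 3)
    stop("insufficient T coverage: need >= 3 durations with >= ",
         min_per_T, " trajectories each")
  # the mean over positions of the position-wise mean profile equals the
  # mean over trajectories of each trajectory's own mean folded deviation,
  # so the magnitudes (and the bootstrap) reduce to vector arithmetic
  md <- vapply(trajectories, function(tr) mean(tr$deviations) * tr$sign, 0)
  mag_fun <- function(mdv, Tvv)
    vapply(use, function(TT) mean(mdv[Tvv == TT]), 0)
  slope <- function(m) unname(stats::coef(stats::lm(log(m) ~ log(use)))[2])
  mags <- mag_fun(md, Tv)
  alpha <- slope(mags)
  boots <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(md), length(md), replace = TRUE)
    mb <- mag_fun(md[idx], Tv[idx])
    if (any(!is.finite(mb)) || any(mb <= 0)) next
    boots[b] <- slope(mb)
  }
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(alpha = alpha, slope_ci = ci, n_points = length(use),
                 magnitudes = data.frame(T = use, mag = mags,
                                         n = counts[counts >= min_per_T])),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("deviation-vs-duration scaling: alpha = %.3f [%.3f, %.3f] over %d durations\n",
              x$alpha, x$slope_ci[1], x$slope_ci[2], x$n_points))
  invisible(x)
}

#' Residence and return time distributions
#'
#' Residence times are interior maximal runs of consecutive presences
#' (non-zero counts); return times are interior maximal runs of consecutive
#' absences (zero counts). As with sojourns, runs touching the series
#' boundary or interrupted by a sampling gap larger than `max_gap_days` are
#' discarded. These apply to all taxa, including intermittently observed
#' ones.
#'
#' @param series an [abundance_series()] (zero-count days included).
#' @param max_gap_days largest bridgeable sampling gap (default 2).
#' @return List with elements `residence` and `return`, each a
#'   `"run_length_summary"` (or NULL when no interior run exists).
#' @export
residence_return_times <- function(series, max_gap_days = 2) {
  stopifnot(inherits(series, "abundance_series"))
  pres <- ifelse(series$counts > 0, 1, -1)
  # presence/absence is never "on the reference", so delta-gap sign logic
  # reduces to: bridge gaps <= max_gap_days with unchanged state
  runs <- scan_runs(pres, series$days, reference = 0,
                    max_gap_days = max_gap_days)
  Tres <- vapply(Filter(function(r) r$sign > 0, runs), `[[`, 0L, "T")
  Tret <- vapply(Filter(function(r) r$sign < 0, runs), `[[`, 0L, "T")
  list(residence = if (length(Tres))
    sojourn_time_distribution(Tres, "residence") else NULL,
    return = if (length(Tret))
      sojourn_time_distribution(Tret, "return") else NULL)
}

#' Per-taxon mean sojourn time
#'
#' Arithmetic mean duration of each taxon's sojourn trajectories; taxa with
#' fewer than `n_min` trajectories are excluded and listed with a reason.
#'
#' @param trajectories list of sojourn trajectories (pooled across taxa).
#' @param n_min minimum trajectories per taxon (default 5).
#' @return Data frame with `asv_id`, `mean_T`, `n_runs` for retained taxa;
#'   excluded taxa in `attr(, "excluded")`.
#' @export
mean_sojourn_time <- function(trajectories, n_min = 5) {
  ids <- vapply(trajectories, `[[`, "", "asv_id")
  Tv <- vapply(trajectories, function(tr) as.integer(tr$T), 0L)
  sp <- split(Tv, ids)
  n <- vapply(sp, length, 0L)
  keep <- n >= n_min
  out <- data.frame(asv_id = names(sp)[keep],
                    mean_T = vapply(sp[keep], mean, 0),
                    n_runs = n[keep], row.names = NULL)
  attr(out, "excluded") <- data.frame(
    asv_id = names(sp)[!keep],
    reason = sprintf("only %d trajectories (n_min = %d)", n[!keep], n_min),
    row.names = NULL)
  out
}

#' Tabulate sojourn trajectories
#'
#' @param trajectories list of sojourn trajectories.
#' @param path optional CSV output path.
#' @return Data frame with one row per trajectory (`asv_id`, `host_id`,
#'   `sign`, `start_day`, `end_day`, `T`, `H`, `area`).
#' @export
trajectories_table <- function(trajectories, path = NULL) {
  df <- data.frame(
    asv_id = vapply(trajectories, `[[`, "", "asv_id"),
    host_id = vapply(trajectories, `[[`, "", "host_id"),
    sign = vapply(trajectories, function(tr) as.integer(tr$sign), 0L),
    start_day = vapply(trajectories, function(tr) as.integer(tr$start_day), 0L),
    end_day = vapply(trajectories, function(tr) as.integer(tr$end_day), 0L),
    T = vapply(trajectories, function(tr) as.integer(tr$T), 0L),
    H = vapply(trajectories, `[[`, 0, "H"),
    area = vapply(trajectories, `[[`, 0, "area"))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
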