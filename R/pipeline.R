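#' Spearman rank correlation with a permutation p-value
#'
#' Assesses a monotone relationship between two per-taxon quantities (for
#' example mean abundance versus mean sojourn time) with Spearman's rank
#' correlation; significance comes from a permutation test (shuffling `y`)
#' rather than the asymptotic approximation, which is unreliable at the
#' small number of taxa a single host provides.
#'
#' @param x,y paired numeric vectors, at least 10 pairs.
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed.
#' @param x_name,y_name labels carried in the result.
#' @return An object of class `"relationship_result"`: list with `x_name`,
#'   `y_name`, `rho`, `p_perm` (`(1 + #{|rho*| >= |rho|}) / (1 + n_perm)`),
#'   `n`.
#' @export
assess_relationship <- function(x, y, n_perm = 999, seed = NULL,
                                x_name = deparse(substitute(x)),
                                y_name = deparse(substitute(y))) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10) stop("need at least 10 paired taxa")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  if (!is.null(seed)) set.seed(seed)
  rho <- stats::cor(x, y, method = "spearman")
  rx <- rank(x)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    rstar <- stats::cor(rx, rank(sample(y)))
    if (abs(rstar) >= abs(rho) - 1e-12) exceed <- exceed + 1L
  }
  structure(list(x_name = x_name, y_name = y_name, rho = rho,
                 p_perm = (1 + exceed) / (1 + n_perm), n = length(x)),
            class = "relationship_result")
}

#' @export
print.relationship_result <- function(x, ...) {
  cat(sprintf("Spearman %s vs %s: rho = %.3f, permutation p = %.4f (n = %d)\n",
              x$y_name, x$x_name, x$rho, x$p_perm, x$n))
  invisible(x)
}

# short stable hash of the configuration for output provenance
# (polynomial rolling hash modulo a 31-bit prime); the output directory
# is not part of the scientific configuration
config_hash <- function(config) {
  config$out_dir <- NULL
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

write_csv_prov <- function(df, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param counts_path,meta_path input TSVs (as produced by
#'   [write_community()], or equivalently formatted empirical data); leave
#'   NULL to run on a synthetic community supplied to [run_pipeline()].
#' @param occupancy_min,n_obs_min taxon filter, see [filter_asvs()].
#' @param max_gap_days run-scanner gap rule.
#' @param divergence `"kl"` or `"js"`.
#' @param tau_grid candidate growth timescales for [fit_tau()].
#' @param n_permutations permutation-null replicates per taxon.
#' @param n_null_replicates stationary-gamma-null replicates per taxon.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return A `"run_config"` list.
#' @export
run_config <- function(counts_path = NULL, meta_path = NULL,
                       occupancy_min = 0.9, n_obs_min = 50,
                       max_gap_days = 2, divergence = "kl",
                       tau_grid = 1:10, n_permutations = 100,
                       n_null_replicates = 20, seed = 1L,
                       out_dir = tempfile("microsojourn_run")) {
  for (p in c(counts_path, meta_path))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  structure(list(counts_path = counts_path, meta_path = meta_path,
                 occupancy_min = occupancy_min, n_obs_min = n_obs_min,
                 max_gap_days = max_gap_days, divergence = divergence,
                 tau_grid = tau_grid, n_permutations = n_permutations,
                 n_null_replicates = n_null_replicates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full sojourn analysis pipeline
#'
#' Orchestrates one host end to end: taxon filtering, sampling-aware gamma
#' fits, log-rescaling, sojourn/residence/return extraction, the two null
#' models with the divergence table, SLM predictions (fitted timescale,
#' mean-T and height curves), and the per-taxon relationship tests (mean
#' sojourn time versus mean abundance, expected null; versus CV, expected
#' positive; height versus duration). Writes seven CSVs plus a log file to
#' `config$out_dir`, every CSV headed by the configuration hash and seed.
#'
#' @param config a [run_config()].
#' @param community optional `"synthetic_community"` to analyze instead of
#'   reading `counts_path`/`meta_path`.
#' @param fit_timescale run [fit_tau()] on the pooled sojourn distribution
#'   (default TRUE; the slowest stage).
#' @return Invisibly, a list with the principal in-memory results:
#'   `fits`, `trajectories`, `sojourn_dist`, `divergence`,
#'   `relationships`, `tau_fit`, `predictions`, `paths`.
#' @export
run_pipeline <- function(config, community = NULL, fit_timescale = TRUE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  logf("run %s seed %d", hash, config$seed)

  stage <- "load"
  result <- tryCatch({
    if (!is.null(community)) {
      counts <- rbind(community$counts, OTHER = community$other_counts)
      days <- community$days
      depths <- community$depths
      host <- "synthH1"
    } else {
      if (is.null(config$counts_path) || is.null(config$meta_path))
        stop("no input: supply counts_path/meta_path or a community")
      cm <- read_community(config$counts_path, config$meta_path)
      counts <- cm$counts; days <- cm$days; depths <- cm$depths
      host <- as.character(cm$metadata$host_id[1])
    }
    counts <- counts[rownames(counts) != "OTHER", , drop = FALSE]
    logf("loaded %d taxa x %d samples (host %s)", nrow(counts),
         ncol(counts), host)

    stage <- "filter"
    all_series <- lapply(seq_len(nrow(counts)), function(i)
      abundance_series(rownames(counts)[i], days, counts[i, ], depths,
                       host_id = host))
    fl <- filter_asvs(counts, days, depths,
                      occupancy_min = config$occupancy_min,
                      n_obs_min = config$n_obs_min, host_id = host)
    if (length(fl$series) == 0) stop("no taxa pass the occupancy filter")
    logf("retained %d / %d taxa", length(fl$series), nrow(counts))

    stage <- "fit"
    fits <- lapply(fl$series, fit_gamma_sampling_mle)
    fit_df <- fits_table(fits)
    write_csv_prov(fit_df, file.path(config$out_dir, "fits.csv"), hash,
                   config$seed)

    stage <- "rescale"
    resc <- mapply(rescale_log, fl$series, fits, SIMPLIFY = FALSE)

    stage <- "sojourns"
    traj <- do.call(c, lapply(resc, extract_sojourns,
                              max_gap_days = config$max_gap_days))
    if (length(traj) == 0) stop("no interior sojourn trajectories found")
    traj_df <- trajectories_table(traj)
    write_csv_prov(traj_df, file.path(config$out_dir, "trajectories.csv"),
                   hash, config$seed)
    soj_dist <- sojourn_time_distribution(traj)
    logf("found %d sojourns, <T> = %.2f", soj_dist$n_runs,
         soj_dist$mean_T)

    pmfs <- data.frame(kind = "sojourn", T = soj_dist$pmf$T,
                       prob = soj_dist$pmf$prob)
    rrs <- lapply(all_series, residence_return_times,
                  max_gap_days = config$max_gap_days)
    for (kind in c("residence", "return")) {
      Tk <- unlist(lapply(rrs, function(z) {
        s <- z[[kind]]
        if (is.null(s)) integer() else
          rep(s$pmf$T, round(s$pmf$prob * s$n_runs))
      }))
      if (length(Tk)) {
        sm <- sojourn_time_distribution(Tk, kind)
        pmfs <- rbind(pmfs, data.frame(kind = kind, T = sm$pmf$T,
                                       prob = sm$pmf$prob))
      }
    }
    write_csv_prov(pmfs, file.path(config$out_dir, "pmf.csv"), hash,
                   config$seed)

    stage <- "profiles"
    Tv <- vapply(traj, function(tr) as.integer(tr$T), 0L)
    prof_rows <- list()
    for (TT in sort(unique(Tv))) {
      if (sum(Tv == TT) < 5 || TT < 1) next
      pr <- mean_deviation_profile(traj, TT)
      prof_rows[[length(prof_rows) + 1L]] <-
        data.frame(T = TT, position = seq_len(TT), mean_deviation = pr,
                   n = attr(pr, "n"))
    }
    prof_df <- do.call(rbind, prof_rows)
    write_csv_prov(prof_df, file.path(config$out_dir, "profiles.csv"),
                   hash, config$seed)

    stage <- "nulls"
    div_tab <- compare_quantities(all_series, resc, fits,
                                  n_permutations = config$n_permutations,
                                  max_gap_days = config$max_gap_days,
                                  method = config$divergence,
                                  host_id = host)
    write_csv_prov(div_tab, file.path(config$out_dir, "divergence.csv"),
                   hash, config$seed)

    stage <- "relationships"
    mt <- mean_sojourn_time(traj)
    fit_sub <- fit_df[match(mt$asv_id, fit_df$asv_id), ]
    rels <- list()
    if (nrow(mt) >= 10) {
      rels <- list(
        assess_relationship(fit_sub$mean, mt$mean_T,
                            x_name = "mean_abundance", y_name = "mean_T"),
        assess_relationship(fit_sub$cv, mt$mean_T,
                            x_name = "cv", y_name = "mean_T"))
    } else {
      logf("relationship tests need >= 10 taxa with enough sojourns; have %d",
           nrow(mt))
    }
    if (length(traj) >= 10)
      rels <- c(rels, list(
        assess_relationship(Tv, vapply(traj, `[[`, 0, "H"),
                            x_name = "T", y_name = "H")))
    rel_df <- data.frame(
      x_name = vapply(rels, `[[`, "", "x_name"),
      y_name = vapply(rels, `[[`, "", "y_name"),
      rho = vapply(rels, `[[`, 0, "rho"),
      p_perm = vapply(rels, `[[`, 0, "p_perm"),
      n = vapply(rels, function(r) as.integer(r$n), 0L))
    write_csv_prov(rel_df, file.path(config$out_dir, "relationships.csv"),
                   hash, config$seed)
    for (r in rels)
      logf("%s vs %s: rho = %.3f, p = %.4f", r$y_name, r$x_name, r$rho,
           r$p_perm)

    stage <- "slm_predictions"
    # one tau for the pooled p(T), at the abundance-weighted median sigma
    sig_asv <- sigma_from_cv(fit_df$cv)
    w <- fit_df$mean / sum(fit_df$mean)
    ord <- order(sig_asv)
    sig_host <- sig_asv[ord][which(cumsum(w[ord]) >= 0.5)[1]]
    tau_fit <- NULL
    if (fit_timescale) {
      tau_fit <- fit_tau(soj_dist, tau_grid = config$tau_grid,
                         sigma = sig_host, t_total = 5e4)
      logf("fitted tau = %g (sigma_host = %.3f)", tau_fit$tau, sig_host)
    }
    sig_grid <- sort(unique(pmin(pmax(sig_asv, 0.05), 1.9)))
    if (length(sig_grid) > 8)
      sig_grid <- stats::quantile(sig_grid, seq(0.05, 0.95, length.out = 8),
                                  names = FALSE)
    mtc <- predict_mean_T(if (is.null(tau_fit)) 1 else tau_fit$tau,
                          sig_grid, t_total = 2e4)
    pred_df <- data.frame(sigma = mtc$sigma, cv = mtc$cv,
                          mean_T = mtc$mean_T)
    write_csv_prov(pred_df, file.path(config$out_dir, "predictions.csv"),
                   hash, config$seed)

    stage <- "figures"
    fig_path <- file.path(config$out_dir, "summary.png")
    grDevices::png(fig_path, width = 1200, height = 400)
    graphics::par(mfrow = c(1, 3))
    graphics::plot(soj_dist$pmf$T, soj_dist$pmf$prob, log = "y",
                   xlab = "sojourn time T (obs)", ylab = "p(T)",
                   main = "sojourn-time distribution", pch = 19)
    if (nrow(mt) > 0) {
      graphics::plot(fit_sub$mean, mt$mean_T, log = "x",
                     xlab = "mean relative abundance", ylab = "<T>",
                     main = "mean sojourn time vs mean", pch = 19)
      graphics::plot(fit_sub$cv, mt$mean_T, xlab = "CV", ylab = "<T>",
                     main = "mean sojourn time vs CV", pch = 19)
      graphics::lines(sqrt(pred_df$sigma / (2 - pred_df$sigma)),
                      pred_df$mean_T, col = 2, lwd = 2)
    }
    grDevices::dev.off()

    list(fits = fit_df, trajectories = traj_df, sojourn_dist = soj_dist,
         divergence = div_tab, relationships = rel_df, tau_fit = tau_fit,
         predictions = pred_df,
         paths = file.path(config$out_dir,
                           c("fits.csv", "trajectories.csv", "pmf.csv",
                             "profiles.csv", "divergence.csv",
                             "relationships.csv", "predictions.csv")))
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  logf("done")
  invisible(result)
}
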