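#' Observation scheme for synthetic sequencing
#'
#' Describes how a latent community is observed: the interval between
#' observations, the span of the study, the expected sequencing depth, and
#' the probability that a scheduled day yields no sample (missed stool
#' collection).
#'
#' @param delta_t days between scheduled observations (default 1, daily).
#' @param n_days total number of scheduled observation days.
#' @param depth_mean expected reads per sample (per-sample depths are drawn
#'   Poisson around this, truncated at 1, mimicking library-size variation).
#' @param missing_fraction probability in \[0, 1) that a scheduled day is
#'   unsampled.
#' @param seed integer RNG seed used by [observe_counts()] /
#'   [generate_community()].
#' @return An object of class `"sampling_scheme"`.
#' @export
sampling_scheme <- function(delta_t = 1, n_days = 300, depth_mean = 1e4,
                            missing_fraction = 0, seed = 1L) {
  stopifnot(delta_t > 0, n_days >= 1, depth_mean >= 1,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(delta_t = delta_t, n_days = as.integer(n_days),
                 depth_mean = depth_mean,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "sampling_scheme")
}

#' Observe a latent community through multinomial sequencing
#'
#' Converts a matrix of true relative abundances into read counts: each
#' scheduled day is retained with probability `1 - missing_fraction`, a
#' sequencing depth is drawn as zero-truncated Poisson around `depth_mean`,
#' and reads are drawn multinomially. The focal abundances are normalized as
#' `x / (1 + sum(x))` so that a passive "everything else" component absorbs
#' the remaining probability mass while each focal taxon's marginal dynamics
#' are approximately preserved.
#'
#' @param latent_x numeric matrix of true relative abundances, taxa in rows,
#'   scheduled days in columns. Column sums may not exceed 1.
#' @param scheme a [sampling_scheme()].
#' @param params_per_asv optional list of [slm_params()] recorded for truth
#'   bookkeeping (parameter-recovery tests).
#' @return An object of class `"synthetic_community"`: list with `counts`
#'   (taxa x sampled days, integer), `depths`, `days` (which scheduled days
#'   were sampled), `latent_x` (full latent matrix, all scheduled days),
#'   `params_per_asv`, `scheme`.
#' @export
observe_counts <- function(latent_x, scheme, params_per_asv = NULL) {
  stopifnot(is.matrix(latent_x), inherits(scheme, "sampling_scheme"))
  if (any(latent_x < 0)) stop("latent abundances must be non-negative")
  csum <- colSums(latent_x)
  if (any(csum > 1 + 1e-9))
    stop("composition error: latent abundances sum to > 1 on some day; ",
         "supply relative abundances whose residual component is non-negative")
  set.seed(scheme$seed)
  n_days <- ncol(latent_x)
  sampled <- which(stats::runif(n_days) >= scheme$missing_fraction)
  depths <- stats::rpois(length(sampled), scheme$depth_mean)
  depths[depths < 1] <- 1L
  n_asv <- nrow(latent_x)
  counts <- matrix(0L, n_asv, length(sampled))
  other <- integer(length(sampled))
  for (j in seq_along(sampled)) {
    x <- latent_x[, sampled[j]]
    # residual slot keeps the multinomial well defined
    p <- c(x, 1) / (1 + sum(x))
    draw <- stats::rmultinom(1L, size = depths[j], prob = p)
    counts[, j] <- draw[seq_len(n_asv), 1L]
    other[j] <- draw[n_asv + 1L, 1L]
  }
  if (is.null(rownames(latent_x)))
    rownames(latent_x) <- sprintf("ASV%03d", seq_len(n_asv))
  rownames(counts) <- rownames(latent_x)
  days <- as.integer(round(sampled * scheme$delta_t))
  colnames(counts) <- sprintf("S%04d", days)
  structure(list(counts = counts, other_counts = other,
                 depths = as.integer(depths), days = days,
                 latent_x = latent_x, params_per_asv = params_per_asv,
                 scheme = scheme),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("Synthetic community: %d taxa x %d sampled days (of %d scheduled), median depth %d\n",
              nrow(x$counts), ncol(x$counts), ncol(x$latent_x),
              as.integer(stats::median(x$depths))))
  invisible(x)
}

#' Generate a synthetic SLM community observed by sequencing
#'
#' Simulates `n_asvs` independent taxa (the SLM is a single-species model;
#' no interactions), each following stochastic logistic dynamics with its
#' own carrying capacity `K` drawn log-uniformly and noise strength `sigma`
#' drawn uniformly, then samples the community through
#' finite-depth multinomial sequencing via [observe_counts()]. Child RNG
#' streams per taxon are derived deterministically from the scheme's master
#' seed, so individual taxa are reproducible.
#'
#' @param n_asvs number of taxa.
#' @param K_range length-2 range for log-uniform carrying capacities.
#' @param sigma_range length-2 range (within (0,2)) for uniform noise
#'   strengths.
#' @param tau growth timescale in days, shared across taxa.
#' @param scheme a [sampling_scheme()]; its `seed` is the master seed.
#' @return A `"synthetic_community"` whose `params_per_asv` records each
#'   taxon's true `slm_params`.
#' @examples
#' comm <- generate_community(5, c(1e-4, 1e-2), c(0.3, 1.2), tau = 1,
#'                            sampling_scheme(n_days = 50, seed = 7))
#' dim(comm$counts)
#' @export
generate_community <- function(n_asvs, K_range = c(1e-5, 1e-2),
                               sigma_range = c(0.2, 1.5), tau = 1,
                               scheme = sampling_scheme()) {
  stopifnot(n_asvs >= 1, length(K_range) == 2, all(K_range > 0),
            length(sigma_range) == 2, inherits(scheme, "sampling_scheme"))
  if (any(sigma_range <= 0) || any(sigma_range >= 2))
    stop("sigma_range must lie within (0, 2)")
  set.seed(scheme$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_asvs + 1L)
  K <- exp(stats::runif(n_asvs, log(K_range[1]), log(K_range[2])))
  sigma <- stats::runif(n_asvs, sigma_range[1], sigma_range[2])
  params <- lapply(seq_len(n_asvs), function(i)
    slm_params(tau = tau, K = K[i], sigma = sigma[i],
               delta_t = scheme$delta_t))
  latent <- matrix(0, n_asvs, scheme$n_days,
                   dimnames = list(sprintf("ASV%03d", seq_len(n_asvs)), NULL))
  for (i in seq_len(n_asvs))
    latent[i, ] <- slm_observed_path(params[[i]], scheme$n_days,
                                     seed = child_seeds[i])
  obs_scheme <- scheme
  obs_scheme$seed <- child_seeds[n_asvs + 1L]
  comm <- observe_counts(latent, obs_scheme, params_per_asv = params)
  comm$scheme <- scheme
  comm
}

#' Write a synthetic community to disk
#'
#' Emits the same plain-text formats the empirical pipeline reads: a counts
#' TSV (rows = ASV ids, columns = sample ids), a metadata TSV with columns
#' `sample_id`, `host_id`, `collection_day`, and a truth JSON recording each
#' taxon's generating `tau`, `K` and `sigma`.
#'
#' @param comm a `"synthetic_community"`.
#' @param dir output directory (created if missing).
#' @param host_id host label written to the metadata (default `"synthH1"`).
#' @return Invisibly, the three file paths.
#' @export
write_community <- function(comm, dir, host_id = "synthH1") {
  stopifnot(inherits(comm, "synthetic_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  truth_path <- file.path(dir, "truth.json")
  # the passive residual is written as an OTHER row so that per-sample
  # depths can be reconstructed as column sums, as with empirical tables
  full <- rbind(comm$counts, OTHER = comm$other_counts)
  cnt <- data.frame(asv_id = rownames(full), full, check.names = FALSE)
  utils::write.table(cnt, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = colnames(comm$counts), host_id = host_id,
                     collection_day = comm$days)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- if (!is.null(comm$params_per_asv))
    data.frame(asv_id = rownames(comm$counts),
               tau = vapply(comm$params_per_asv, `[[`, 0, "tau"),
               K = vapply(comm$params_per_asv, `[[`, 0, "K"),
               sigma = vapply(comm$params_per_asv, `[[`, 0, "sigma"))
  else data.frame()
  jsonlite::write_json(truth, truth_path, digits = NA)
  invisible(c(counts = counts_path, metadata = meta_path, truth = truth_path))
}

#' Read a counts table and sample metadata
#'
#' Reads the TSV pair written by [write_community()] (or equivalently
#' formatted empirical data: a taxa-by-sample count TSV whose first column
#' is the ASV id, plus a metadata TSV with `sample_id`, `host_id`,
#' `collection_day`).
#'
#' @param counts_path path to the counts TSV.
#' @param meta_path path to the metadata TSV.
#' @return List with integer matrix `counts` (taxa x samples, columns
#'   ordered by day), data frame `metadata`, integer vector `days`, vector
#'   `depths` (per-sample column sums over all rows, including an `OTHER`
#'   residual row if present; that row is excluded from `counts`).
#' @export
read_community <- function(counts_path, meta_path) {
  cnt <- utils::read.delim(counts_path, check.names = FALSE)
  meta <- utils::read.delim(meta_path)
  stopifnot(all(c("sample_id", "host_id", "collection_day") %in% names(meta)))
  m <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(m) <- cnt[[1]]
  storage.mode(m) <- "integer"
  meta <- meta[match(colnames(m), meta$sample_id), ]
  ord <- order(meta$collection_day)
  m <- m[, ord, drop = FALSE]
  meta <- meta[ord, ]
  depths <- as.integer(colSums(m))
  m <- m[rownames(m) != "OTHER", , drop = FALSE]
  list(counts = m, metadata = meta,
       days = as.integer(meta$collection_day),
       depths = depths)
}
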