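# Independent brute-force run scanner: walks the sign sequence element by
# element, collecting maximal constant-sign runs, then keeps only runs
# whose immediate neighbours on both sides exist and have strictly
# opposite (non-zero) sign. Deliberately naive; the reference against
# which the package's segment/rle-based scanner is checked.
brute_force_runs <- function(s) {
  n <- length(s)
  runs <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1
    runs[[length(runs) + 1L]] <- list(sign = s[i], start = i, end = j,
                                      len = j - i + 1L)
    i <- j + 1
  }
  keep <- Filter(function(r) {
    if (r$sign == 0) return(FALSE)
    if (r$start == 1 || r$end == n) return(FALSE)
    before <- s[r$start - 1]
    after <- s[r$end + 1]
    before != 0 && after != 0 && before != r$sign && after != r$sign
  }, runs)
  keep
}

# rescaled_series fixture straight from a y vector (contiguous days)
make_rescaled <- function(y, days = seq_along(y), y_bar = mean(y),
                          dropped = integer()) {
  structure(list(asv_id = "fx", host_id = "hx", days = as.integer(days),
                 y = y, y_bar = y_bar, dropped_days = as.integer(dropped),
                 reference = "mle"),
            class = "rescaled_series")
}

# sojourn_trajectory fixture with prescribed deviations
make_traj <- function(deviations, sign = 1, asv_id = "fx") {
  structure(list(asv_id = asv_id, host_id = "hx", sign = sign,
                 start_day = 1L, end_day = length(deviations),
                 T = length(deviations),
                 H = max(abs(deviations)), area = sum(abs(deviations)),
                 deviations = deviations),
            class = "sojourn_trajectory")
}

# gamma-Poisson abundance series with known parameters
make_gp_series <- function(n = 300, mean = 1e-3, cv = 1, depth = 1e4,
                           seed = 1) {
  set.seed(seed)
  x <- rgamma(n, shape = 1 / cv^2, scale = mean * cv^2)
  counts <- rpois(n, depth * x)
  abundance_series("gp", seq_len(n), counts, rep(as.integer(depth), n))
}
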