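#' @keywords internal
"_PACKAGE"

# shared argument checks ------------------------------------------------------

stop_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_arg(sprintf("`%s` must be a single value in [0, 1]", name))
  as.numeric(x)
}

# Seed handling: functions that accept `seed` set the global RNG when it is
# non-NULL, the convention of breeding-simulation packages; passing NULL
# continues the current stream so composite pipelines stay reproducible from
# a single top-level seed.
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    seed <- check_count(seed, "seed", min = 0L)
    set.seed(seed)
  }
  invisible(seed)
}

# effective sample size from Geyer's initial positive sequence (sums of
# adjacent autocovariance pairs kept while positive)
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  maxlag <- min(n - 2L, 500L)
  rho <- stats::acf(x, lag.max = maxlag, plot = FALSE)$acf[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}
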