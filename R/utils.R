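# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream of sub-seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  x
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok)
    stop(sprintf("`%s` must be %s", name,
                 if (strict) "strictly positive and finite" else "non-negative and finite"),
         call. = FALSE)
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop(sprintf("`%s` must be an integer count >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# (mean, sd) pair used throughout the simulator configs
check_mean_sd <- function(x, name, sd_zero_ok = TRUE) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop(sprintf("`%s` must be a numeric (mean, sd) pair", name), call. = FALSE)
  x <- unname(x)
  if (x[1] <= 0) stop(sprintf("`%s` mean must be > 0", name), call. = FALSE)
  if (x[2] < 0 || (!sd_zero_ok && x[2] == 0))
    stop(sprintf("`%s` sd must be >= 0", name), call. = FALSE)
  c(mean = x[1], sd = x[2])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# truncated normal (mean, sd, +/- lim sd) by inverse-CDF; keeps amplitude
# draws bounded so detection SNR is controlled by config, not by tails
rnorm_trunc <- function(n, mean, sd, lim = 2.5) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(-lim)
  mean + sd * stats::qnorm(lo + (1 - 2 * lo) * stats::runif(n))
}
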