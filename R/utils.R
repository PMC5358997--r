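# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-generator sub-seed so each named stream is independent of
# the others while still controlled by one master seed.  Kept < 2^31 - 1.
seed_stream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  as.integer((abs(seed) + h * 7919) %% 2147483646) + 1L
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

assert_increasing <- function(x, name) {
  if (any(!is.finite(x)) || any(diff(x) <= 0))
    stop(sprintf("`%s` must be strictly increasing and finite", name),
         call. = FALSE)
  invisible(x)
}

# trapezoidal integral over (x, y)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

geomean <- function(x) exp(mean(log(x)))

# geometric SD: exp(sd of logs)
gsd <- function(x) exp(stats::sd(log(x)))

# coefficient of variation of a mean-1 log-normal -> sdlog
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# draws with arithmetic mean 1
rlnorm_mean1 <- function(n, cv) {
  if (cv < 0) stop("coefficient of variation must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  s <- cv_to_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}
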