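# Internal helpers shared across modules.

# Run `expr` under a reproducible RNG state without disturbing the caller's
# stream. `seed = NULL` leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower) {
    if (x <= lower) stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

# Cumulative trapezoidal integral of y over x (uniform or not); length(y).
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1L] + y[-n]) / 2 * diff(x)))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2 * diff(x))
}

# Biased (1/n) central sample moments used throughout morphometry.
moments_biased <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  sigma <- sqrt(m2)
  gamma <- if (m2 > 0) m3 / sigma^3 else 0
  list(mu = mu, sigma = sigma, gamma = gamma)
}
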