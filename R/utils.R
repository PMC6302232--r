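#' Round half away from zero
#'
#' Deterministic half-up rounding used for all reported counts and
#' percentages, so that printed tables can be reproduced exactly from the
#' underlying count tables (base [round()] rounds half to even).
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(2.5)        # 3, not 2
#' roundHalfUp(23.345, 2)  # 23.35
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count ratio, rounded half-up
#'
#' @param numerator,denominator counts.
#' @param digits decimal places (default 2, the reporting convention).
#' @return percentage, or `NA` where the denominator is zero.
#' @export
#' @examples
#' proportionPct(9139, 39156)  # 23.34
proportionPct <- function(numerator, denominator, digits = 2) {
  out <- roundHalfUp(100 * numerator / denominator, digits)
  out[denominator == 0] <- NA_real_
  out
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Dirichlet draw via normalized gammas; returns a length-n simplex.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x <- rep(1, length(alpha))
  x / sum(x)
}

# Stop with a field-naming message if any value lies outside [0, 1].
check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("'", field, "' must contain probabilities in [0, 1]", call. = FALSE)
  invisible(x)
}
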