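# Internal helpers: classed error conditions, fast simple OLS, half-up
# rounding, RNG scoping and seed splitting.

abort_aox <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(
    msg,
    class = c(paste0("aoxkinetics_error_", class), "aoxkinetics_error"),
    call = call
  ))
}

warn_aox <- function(msg, class) {
  warning(warningCondition(
    msg,
    class = c(paste0("aoxkinetics_warning_", class), "aoxkinetics_warning")
  ))
}

# Simple linear regression y ~ 1 + x through the stats QR path (.lm.fit),
# which is much cheaper than lm() for the thousands of 4-5 point fits the
# recovery studies perform. R^2 is the squared sample correlation,
# Sxy^2/(Sxx*Syy); a response with zero variance gets R^2 = 0 with a warning.
ols_xy <- function(x, y) {
  fit <- stats::.lm.fit(cbind(1, x), y)
  coefs <- fit$coefficients
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (syy <= 0) {
    warn_aox("response has zero variance; R^2 defined as 0", "zero_variance")
    r2 <- 0
  } else {
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    r2 <- sxy^2 / (sxx * syy)
  }
  list(intercept = coefs[[1]], slope = coefs[[2]], r_squared = r2,
       n = length(x))
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' ("half-up" for positive numbers), the convention used when rendering
#' estimates at the precision of the source tables. Base [round()] uses
#' round-half-to-even and would turn, e.g., 0.845 into 0.84. A relative
#' guard of a few ulps absorbs decimal values that sit just below a tie
#' after binary representation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.845, 0.843, -0.845))
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Evaluate `expr` with a private RNG state: seeds locally, restores the
# caller's .Random.seed on exit, so simulation helpers never perturb the
# global stream.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic seed splitting: child = f(master, sweep, level, replicate)
# via a fixed linear-congruential style mix modulo the Mersenne prime
# 2^31 - 1. Adding replicates or levels never perturbs existing children.
child_seed <- function(master, sweep_idx, level_idx, replicate_idx) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 %% m
  s <- (s + sweep_idx * 100003 + level_idx * 1009 + replicate_idx * 7919) %% m
  as.integer(s)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is_number(x)) {
    abort_aox(sprintf("`%s` must be a single finite number", name), "domain")
  }
  if (strict && x <= min) {
    abort_aox(sprintf("`%s` must be > %g", name, min), "domain")
  }
  if (!strict && x < min) {
    abort_aox(sprintf("`%s` must be >= %g", name, min), "domain")
  }
  invisible(x)
}
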