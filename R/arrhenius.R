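#' Log rate constant from a log rate
#'
#' Removes the concentration factors from a measured log10 rate so that
#' only the temperature-dependent rate constant remains:
#' `log10 k = log10(dW/dt) - a log10[H+] - b log10[ClO2] - c log10[C]`.
#' (The log of the power-law rate law; subtraction happens in log space,
#' which is the only dimensionally consistent reading.)
#'
#' @param log_rate log10 of the rate (mg l^-1 min^-1).
#' @param orders a [kinetic_parameters()] object or a list/vector with
#'   elements `a`, `b`, `c`.
#' @param cond an [condition()] with strictly positive concentrations.
#' @return `log10(k)`.
#' @export
log_k_from_rate <- function(log_rate, orders, cond) {
  stopifnot_number(log_rate, "log_rate")
  if (!inherits(cond, "aox_condition")) {
    abort_aox("`cond` must be an aox_condition", "domain")
  }
  if (cond$clo2_M <= 0 || cond$substrate_M <= 0) {
    abort_aox("concentrations must be > 0 to take logarithms", "domain")
  }
  a <- orders$a; b <- orders$b; c <- orders$c
  log_rate - a * log10(h_plus(cond)) - b * log10(cond$clo2_M) -
    c * log10(cond$substrate_M)
}

#' Arrhenius regression of log k on 1/T
#'
#' Ordinary least squares of `log10 k` on inverse temperature in K^-1.
#' From `log10 k = log10 A - E/(R T) * log10 e`, the slope (in kelvin) and
#' intercept give `E = -slope * R * ln(10)` and `A = 10^intercept`.
#'
#' @param inv_T inverse temperatures in K^-1 (>= 3 distinct values), or a
#'   data.frame with columns `inv_T` and `log_k`.
#' @param log_k log10 rate constants (ignored when `inv_T` is a
#'   data.frame).
#' @param block_id replicate label.
#' @return An object of class `arrhenius_fit` with fields `slope_K`,
#'   `intercept`, `E_J_per_mol`, `A`, `r_squared`, `n`, `block_id`.
#' @examples
#' p <- preset_parameters("VA")
#' Ts <- c(323, 333, 343)
#' fit_arrhenius(1 / Ts, log10(vapply(Ts, function(T) rate_constant(p, T), 1)))
#' @export
fit_arrhenius <- function(inv_T, log_k = NULL, block_id = "1") {
  if (is.data.frame(inv_T)) {
    log_k <- inv_T$log_k
    inv_T <- inv_T$inv_T
  }
  inv_T <- as.double(inv_T)
  log_k <- as.double(log_k)
  if (length(inv_T) != length(log_k)) {
    abort_aox("inv_T and log_k must have equal length", "domain")
  }
  if (any(inv_T <= 0) || any(!is.finite(inv_T)) || any(!is.finite(log_k))) {
    abort_aox("inv_T must be positive and all values finite", "domain")
  }
  if (length(unique(inv_T)) < 3L) {
    abort_aox("need >= 3 distinct temperatures for an Arrhenius fit",
              "degenerate_design")
  }
  fit <- ols_xy(inv_T, log_k)
  arrhenius_fit_from_coefs(fit$slope, fit$intercept, r_squared = fit$r_squared,
                           n = fit$n, block_id = block_id)
}

# Builds an arrhenius_fit from (slope in kelvin, intercept = log10 A);
# also used for printed regression coefficients from the reference tables.
arrhenius_fit_from_coefs <- function(slope_K, intercept, r_squared = NA_real_,
                                     n = NA_integer_, block_id = "1") {
  structure(
    list(slope_K = slope_K, intercept = intercept,
         E_J_per_mol = -slope_K * GAS_CONSTANT * log(10),
         A = 10^intercept, r_squared = r_squared, n = n,
         block_id = as.character(block_id)),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> block %s: slope %.4f K, intercept %.4f -> E = %.2f J/mol, A = %.4g\n",
    x$block_id, x$slope_K, x$intercept, x$E_J_per_mol, x$A))
  invisible(x)
}

#' Average replicate Arrhenius fits
#'
#' Averages slopes and intercepts across replicate fits with equal weight
#' and re-derives `E` and `A` from the means, matching how the per-block
#' regression lines of a temperature sweep are combined into a single
#' activation energy and pre-exponential factor.
#'
#' @param fits a list of [fit_arrhenius()] results (>= 1).
#' @return An `arrhenius_fit` whose `slope_K`/`intercept` are the means;
#'   `per_block` holds the input fits.
#' @export
average_arrhenius <- function(fits) {
  if (inherits(fits, "arrhenius_fit")) fits <- list(fits)
  if (length(fits) < 1L) {
    abort_aox("need at least one Arrhenius fit to average",
              "degenerate_design")
  }
  slopes <- vapply(fits, function(f) f$slope_K, numeric(1))
  ints <- vapply(fits, function(f) f$intercept, numeric(1))
  out <- arrhenius_fit_from_coefs(mean(slopes), mean(ints),
                                  block_id = "average")
  out$per_block <- fits
  out
}
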