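#' Evaluate the power-law AOX formation rate
#'
#' Computes `dW/dt = A exp(-E/(R T)) [H+]^a [ClO2]^b [C]^c` in
#' mg l^-1 min^-1 for one condition, with `[H+] = 10^-pH` and
#' concentrations in mol/l. A zero concentration raised to a negative
#' order is a domain error; `0^0` is taken as 1 so a factor with order
#' zero never switches the rate off.
#'
#' @param params a [kinetic_parameters()] object.
#' @param cond an [condition()] object.
#' @return The rate in mg l^-1 min^-1.
#' @examples
#' va <- preset_parameters("VA")
#' evaluate_rate(va, condition("VA", 3, 343, 0.124, 0.062))
#' @export
evaluate_rate <- function(params, cond) {
  if (!inherits(params, "kinetic_parameters")) {
    abort_aox("`params` must be kinetic_parameters", "domain")
  }
  if (!inherits(cond, "aox_condition")) {
    abort_aox("`cond` must be an aox_condition", "domain")
  }
  rate_constant(params, cond$temp_K) *
    pow_checked(h_plus(cond), params$a, "[H+]") *
    pow_checked(cond$clo2_M, params$b, "[ClO2]") *
    pow_checked(cond$substrate_M, params$c, "[C]")
}

pow_checked <- function(x, p, what) {
  if (x == 0 && p < 0) {
    abort_aox(sprintf("%s is zero with negative reaction order %g", what, p),
              "domain")
  }
  x^p
}

#' Arrhenius rate constant
#'
#' `k = A exp(-E/(R T))` with R = 8.314 J mol^-1 K^-1; strictly increasing
#' in temperature when `E > 0`.
#'
#' @param params a [kinetic_parameters()] object (only `A` and `E` used).
#' @param temp_K temperature in kelvin (> 0).
#' @return The rate constant `k` (same implicit units as `A`).
#' @export
rate_constant <- function(params, temp_K) {
  if (!inherits(params, "kinetic_parameters")) {
    abort_aox("`params` must be kinetic_parameters", "domain")
  }
  stopifnot_number(temp_K, "temp_K", min = 0, strict = TRUE)
  params$A * exp(-params$E / (GAS_CONSTANT * temp_K))
}
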