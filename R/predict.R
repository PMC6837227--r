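#' Forward simulation of an AOX formation curve
#'
#' Integrates the rate law coupled to reagent depletion,
#' \deqn{dW/dt = k_T [H+]^a [ClO_2](t)^b [C](t)^c}
#' \deqn{d[ClO_2]/dt = -\lambda\, dW/dt - k_{dec} [ClO_2]}
#' \deqn{d[C]/dt = -\mu\, dW/dt}
#' from `W(0) = 0`, with a fixed-step classical 4th-order Runge-Kutta
#' scheme. Each interval between requested output times is split into
#' equal substeps no longer than `step_min`, so output times are hit
#' exactly and the result is deterministic (no adaptive step control).
#' Concentrations are clamped at zero; with non-negative couplings the
#' returned `W(t)` is non-decreasing. With [no_depletion()] the rate is
#' constant and `W(t) = rate * t` exactly.
#'
#' @param params a [kinetic_parameters()] object.
#' @param cond an [condition()] object supplying pH, temperature and the
#'   initial concentrations.
#' @param depletion a [depletion_spec()]; default [no_depletion()].
#' @param times_min output times in minutes (strictly increasing, >= 0).
#' @param step_min internal integrator step in minutes (default 0.01).
#' @return An [aox_curve()] whose `times_min`/`aox_mg_L` hold the
#'   simulated curve; the tracked concentrations are attached as
#'   attributes `clo2_M_t` and `substrate_M_t`.
#' @examples
#' va <- preset_parameters("VA")
#' cond <- condition("VA", 3, 343, 0.124, 0.062)
#' predict_curve(va, cond, depletion_spec(), times_min = c(1, 2, 5, 10, 30))
#' @export
predict_curve <- function(params, cond, depletion = no_depletion(),
                          times_min, step_min = 0.01) {
  if (!inherits(depletion, "depletion_spec")) {
    abort_aox("`depletion` must be a depletion_spec", "domain")
  }
  stopifnot_number(step_min, "step_min", min = 0, strict = TRUE)
  times_min <- as.double(times_min)
  if (length(times_min) < 1L || any(!is.finite(times_min)) ||
      times_min[1] < 0 || any(diff(times_min) <= 0)) {
    abort_aox("`times_min` must be strictly increasing and start at >= 0",
              "domain")
  }
  # validates params/cond and the zero-concentration/negative-order case
  evaluate_rate(params, cond)
  kh <- rate_constant(params, cond$temp_K) *
    pow_checked(h_plus(cond), params$a, "[H+]")
  res <- tryCatch(
    rk4_aox(kh, params$b, params$c, cond$clo2_M, cond$substrate_M,
            depletion$lambda_clo2, depletion$mu_sub, depletion$k_dec,
            times_min, step_min),
    error = function(e) abort_aox(conditionMessage(e), "integration")
  )
  out <- aox_curve(cond, times_min, res$W)
  attr(out, "clo2_M_t") <- res$clo2_M
  attr(out, "substrate_M_t") <- res$substrate_M
  out
}
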