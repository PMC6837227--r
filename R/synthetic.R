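#' Factorial sweep design
#'
#' The one-factor-at-a-time design used throughout the package: four
#' sweeps around a base condition (pH 3.00, 343 K, 0.124 M ClO2, 0.062 M
#' substrate), each varying a single factor over five levels, with three
#' replicates and sampling at 1, 2, 3, 4, 6, 8, 10, 15 and 30 min.
#'
#' @param substrate_id `"VA"` or `"VE"`.
#' @param n_replicates replicate count per level (default 3).
#' @return An object of class `design_spec` with fields `substrate_id`,
#'   `pH_levels`, `clo2_levels_M`, `substrate_levels_M`, `temp_levels_K`,
#'   `base_condition`, `n_replicates`, `sample_times_min`.
#' @examples
#' d <- reference_design("VA")
#' length(d$pH_levels) * 4 * d$n_replicates  # 60 curves
#' @export
reference_design <- function(substrate_id = c("VA", "VE"),
                             n_replicates = 3L) {
  substrate_id <- match.arg(substrate_id)
  if (!is_number(n_replicates) || n_replicates < 1) {
    abort_aox("`n_replicates` must be >= 1", "domain")
  }
  structure(
    list(
      substrate_id = substrate_id,
      pH_levels = c(2.00, 2.50, 3.00, 3.50, 4.00),
      clo2_levels_M = c(24.80, 49.60, 73.40, 99.20, 124.00) / 1000,
      substrate_levels_M = c(31.00, 46.50, 62.00, 77.50, 93.00) / 1000,
      temp_levels_K = c(323, 328, 333, 338, 343),
      base_condition = condition(substrate_id, pH = 3.00, temp_K = 343,
                                 clo2_M = 0.124, substrate_M = 0.062),
      n_replicates = as.integer(n_replicates),
      sample_times_min = c(1, 2, 3, 4, 6, 8, 10, 15, 30)
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> %s: 4 sweeps x %d levels x %d replicates, %d sample times\n",
    x$substrate_id, length(x$pH_levels), x$n_replicates,
    length(x$sample_times_min)))
  invisible(x)
}

#' Generate one noisy AOX curve
#'
#' Simulates a curve with [predict_curve()] and applies multiplicative
#' Gaussian observation noise `W_obs = W (1 + eps)`, `eps ~ N(0, cv^2)`
#' truncated at -1. With `cv = 0` no random numbers are drawn and the
#' output is bit-identical to the deterministic prediction; for a fixed
#' seed the output is deterministic. The caller's RNG state is left
#' untouched.
#'
#' @inheritParams predict_curve
#' @param noise a [noise_spec()].
#' @param times_min output times in minutes.
#' @return An [aox_curve()].
#' @export
generate_curve <- function(params, cond, depletion = depletion_spec(),
                           noise = noise_spec(), times_min,
                           step_min = 0.01) {
  if (!inherits(noise, "noise_spec")) {
    abort_aox("`noise` must be a noise_spec", "domain")
  }
  clean <- predict_curve(params, cond, depletion, times_min, step_min)
  if (noise$cv == 0) return(clean)
  eps <- with_private_seed(noise$seed,
                           rnorm(length(times_min), 0, noise$cv))
  obs <- clean$aox_mg_L * (1 + pmax(eps, -1))
  out <- aox_curve(cond, clean$times_min, obs)
  attr(out, "clo2_M_t") <- attr(clean, "clo2_M_t")
  attr(out, "substrate_M_t") <- attr(clean, "substrate_M_t")
  out
}

#' Generate a full factorial dataset
#'
#' One curve per (sweep, level, replicate) of a [reference_design()],
#' generated under true power-law kinetics with reagent depletion and
#' multiplicative noise. Per-curve seeds are split from the master seed by
#' a fixed mixing rule over (sweep index, level index, replicate index),
#' so enlarging the design never perturbs existing curves.
#'
#' @param design a [reference_design()] design.
#' @param params the generating [kinetic_parameters()].
#' @param depletion a [depletion_spec()].
#' @param noise a [noise_spec()]; its `seed` is the master seed.
#' @param step_min integrator step passed to [predict_curve()].
#' @return A list of [aox_curve()]s with attributes `sweep` (one of
#'   `"H_plus"`, `"ClO2"`, `"substrate"`, `"temperature"`) and replicate
#'   `block_id` (`"r1"`, `"r2"`, ...).
#' @export
generate_dataset <- function(design, params, depletion = depletion_spec(),
                             noise = noise_spec(), step_min = 0.01) {
  if (!inherits(design, "design_spec")) {
    abort_aox("`design` must be a design_spec", "domain")
  }
  base <- design$base_condition
  sweeps <- list(
    H_plus = list(levels = design$pH_levels,
                  make = function(v) condition(base$substrate, v,
                                               base$temp_K, base$clo2_M,
                                               base$substrate_M)),
    ClO2 = list(levels = design$clo2_levels_M,
                make = function(v) condition(base$substrate, base$pH,
                                             base$temp_K, v,
                                             base$substrate_M)),
    substrate = list(levels = design$substrate_levels_M,
                     make = function(v) condition(base$substrate, base$pH,
                                                  base$temp_K, base$clo2_M,
                                                  v)),
    temperature = list(levels = design$temp_levels_K,
                       make = function(v) condition(base$substrate, base$pH,
                                                    v, base$clo2_M,
                                                    base$substrate_M))
  )
  out <- list()
  for (si in seq_along(sweeps)) {
    sw <- sweeps[[si]]
    for (li in seq_along(sw$levels)) {
      cond <- sw$make(sw$levels[[li]])
      for (ri in seq_len(design$n_replicates)) {
        child <- noise_spec(noise$cv,
                            child_seed(noise$seed, si, li, ri))
        crv <- generate_curve(params, cond, depletion, child,
                              design$sample_times_min, step_min)
        # sweep-qualified so the shared base condition stays unique in CSV
        crv$block_id <- paste0(names(sweeps)[[si]], "-r", ri)
        attr(crv, "sweep") <- names(sweeps)[[si]]
        out[[length(out) + 1L]] <- crv
      }
    }
  }
  out
}
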