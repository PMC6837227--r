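#' Experimental condition
#'
#' One experimental setting of the chlorine dioxide / lignin-model-compound
#' system: substrate identity, pH, temperature and the two reagent
#' concentrations. The hydrogen-ion concentration entering the rate law is
#' `10^-pH` mol/l (activity corrections are not applied).
#'
#' @param substrate `"VA"` (vanillyl alcohol, phenolic) or `"VE"`
#'   (veratryl alcohol, non-phenolic).
#' @param pH solution pH (dimensionless, finite).
#' @param temp_K reaction temperature in kelvin (> 0).
#' @param clo2_M chlorine dioxide concentration in mol/l (>= 0).
#' @param substrate_M lignin model compound concentration in mol/l (>= 0).
#' @return An object of class `aox_condition`.
#' @examples
#' condition("VA", pH = 3, temp_K = 343, clo2_M = 0.124, substrate_M = 0.062)
#' @export
condition <- function(substrate = c("VA", "VE"), pH, temp_K, clo2_M,
                      substrate_M) {
  substrate <- match.arg(substrate)
  stopifnot_number(pH, "pH")
  stopifnot_number(temp_K, "temp_K", min = 0, strict = TRUE)
  stopifnot_number(clo2_M, "clo2_M", min = 0)
  stopifnot_number(substrate_M, "substrate_M", min = 0)
  structure(
    list(substrate = substrate, pH = pH, temp_K = temp_K, clo2_M = clo2_M,
         substrate_M = substrate_M),
    class = "aox_condition"
  )
}

#' @export
print.aox_condition <- function(x, ...) {
  cat(sprintf(
    "<aox_condition> %s | pH %.2f | T %.1f K | [ClO2] %.4g M | [C] %.4g M\n",
    x$substrate, x$pH, x$temp_K, x$clo2_M, x$substrate_M
  ))
  invisible(x)
}

#' Hydrogen ion concentration of a condition
#'
#' @param cond an [condition()] object.
#' @return `10^-pH` in mol/l.
#' @export
h_plus <- function(cond) 10^(-cond$pH)

#' AOX formation curve
#'
#' A time series of adsorbable organic halogen content under one
#' experimental condition.
#'
#' @param cond an [condition()] object.
#' @param times_min sampling times in minutes, strictly increasing, first
#'   time >= 0.
#' @param aox_mg_L AOX content in mg/l at each time, all >= 0.
#' @param block_id optional replicate label carried through the pipeline.
#' @return An object of class `aox_curve`.
#' @export
aox_curve <- function(cond, times_min, aox_mg_L, block_id = NULL) {
  if (!inherits(cond, "aox_condition")) {
    abort_aox("`cond` must be an aox_condition", "domain")
  }
  times_min <- as.double(times_min)
  aox_mg_L <- as.double(aox_mg_L)
  if (length(times_min) != length(aox_mg_L) || length(times_min) < 1L) {
    abort_aox("times and AOX values must have equal, positive length",
              "domain")
  }
  if (any(!is.finite(times_min)) || any(!is.finite(aox_mg_L))) {
    abort_aox("times and AOX values must be finite", "domain")
  }
  if (times_min[1] < 0 || any(diff(times_min) <= 0)) {
    abort_aox("times must be strictly increasing and start at >= 0 min",
              "domain")
  }
  if (any(aox_mg_L < 0)) {
    abort_aox("AOX values must be non-negative", "domain")
  }
  structure(
    list(condition = cond, times_min = times_min, aox_mg_L = aox_mg_L,
         block_id = block_id),
    class = "aox_curve"
  )
}

#' @export
print.aox_curve <- function(x, ...) {
  cat(sprintf("<aox_curve> %d points, t = %g..%g min, W = %.3g..%.3g mg/l\n",
              length(x$times_min), min(x$times_min), max(x$times_min),
              min(x$aox_mg_L), max(x$aox_mg_L)))
  print(x$condition)
  invisible(x)
}
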