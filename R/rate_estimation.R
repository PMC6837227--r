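#' Estimate the initial AOX formation rate from a curve
#'
#' Extracts `dW/dt` at the start of the reaction, before reagent depletion
#' bends the curve, by one of three methods:
#' \describe{
#'   \item{`initial_window_ols`}{slope of an ordinary least-squares line
#'     (free intercept) through all points with `t <= window_end_min`
#'     (default 4 min, covering sampling at 1, 2, 3, 4 min).}
#'   \item{`two_point`}{finite difference over the first two samples.}
#'   \item{`spline_derivative`}{derivative at the first sample of a natural
#'     cubic spline interpolant through the whole curve (needs >= 4
#'     points).}
#' }
#' A negative estimate is returned but flagged, so downstream log
#' transforms can exclude it explicitly rather than silently.
#'
#' @param curve an [aox_curve()].
#' @param method one of `"initial_window_ols"`, `"two_point"`,
#'   `"spline_derivative"`.
#' @param window_end_min end of the fitting window in minutes (used by
#'   `initial_window_ols`).
#' @return An object of class `initial_rate` with fields `value`
#'   (mg l^-1 min^-1), `n_points_used`, `window_end_min`, `method` and
#'   `nonpositive` (logical flag).
#' @examples
#' cond <- condition("VA", 3, 343, 0.124, 0.062)
#' crv <- aox_curve(cond, 1:10, 5 * (1:10))
#' estimate_initial_rate(crv)
#' @export
estimate_initial_rate <- function(curve,
                                  method = c("initial_window_ols",
                                             "two_point",
                                             "spline_derivative"),
                                  window_end_min = 4) {
  if (!inherits(curve, "aox_curve")) {
    abort_aox("`curve` must be an aox_curve", "domain")
  }
  method <- match.arg(method)
  stopifnot_number(window_end_min, "window_end_min", min = 0, strict = TRUE)
  t <- curve$times_min
  w <- curve$aox_mg_L

  if (method == "initial_window_ols") {
    keep <- t <= window_end_min + 1e-12
    if (sum(keep) < 2L) {
      abort_aox(sprintf(
        "need >= 2 points with t <= %g min for the initial-rate window (%d found)",
        window_end_min, sum(keep)), "insufficient_data")
    }
    tw <- t[keep]
    ww <- w[keep]
    if (stats::var(ww) == 0) {
      value <- 0
    } else {
      value <- ols_xy(tw, ww)$slope
    }
    n_used <- length(tw)
  } else if (method == "two_point") {
    if (length(t) < 2L) {
      abort_aox("two_point needs at least 2 samples", "insufficient_data")
    }
    value <- (w[2] - w[1]) / (t[2] - t[1])
    n_used <- 2L
  } else {
    if (length(t) < 4L) {
      abort_aox("spline_derivative needs at least 4 samples",
                "insufficient_data")
    }
    f <- splinefun(t, w, method = "natural")
    value <- f(t[1], deriv = 1)
    n_used <- length(t)
  }

  structure(
    list(value = value, n_points_used = as.integer(n_used),
         window_end_min = window_end_min, method = method,
         nonpositive = value <= 0),
    class = "initial_rate"
  )
}

#' @export
print.initial_rate <- function(x, ...) {
  cat(sprintf("<initial_rate> %.6g mg/l/min (%s, %d points%s)\n", x$value,
              x$method, x$n_points_used,
              if (x$nonpositive) ", non-positive" else ""))
  invisible(x)
}
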