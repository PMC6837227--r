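#' One-factor sweep block
#'
#' One replicate block of a one-factor-at-a-time sweep: log10 of the
#' varied factor's levels paired with log10 of the measured initial rates,
#' with all other factors held fixed.
#'
#' @param varied_factor `"H_plus"`, `"ClO2"` or `"substrate"`.
#' @param log_levels log10 of the varied factor levels (for H+ this is
#'   `-pH`; concentrations in mol/l).
#' @param log_rates log10 of the initial rates (mg l^-1 min^-1).
#' @param block_id replicate label.
#' @param fixed optional [condition()] template recording the fixed
#'   factors.
#' @return An object of class `sweep_block`.
#' @export
sweep_block <- function(varied_factor = c("H_plus", "ClO2", "substrate"),
                        log_levels, log_rates, block_id = "1",
                        fixed = NULL) {
  varied_factor <- match.arg(varied_factor)
  log_levels <- as.double(log_levels)
  log_rates <- as.double(log_rates)
  if (length(log_levels) != length(log_rates) || length(log_levels) < 3L) {
    abort_aox("a sweep block needs >= 3 (level, rate) pairs of equal length",
              "degenerate_design")
  }
  if (length(unique(log_levels)) < 3L) {
    abort_aox("a sweep block needs >= 3 distinct levels",
              "degenerate_design")
  }
  if (any(!is.finite(log_rates)) || any(!is.finite(log_levels))) {
    abort_aox("log levels and log rates must be finite", "domain")
  }
  structure(
    list(varied_factor = varied_factor, log_levels = log_levels,
         log_rates = log_rates, block_id = as.character(block_id),
         fixed = fixed),
    class = "sweep_block"
  )
}

#' Log-log least-squares fit of one sweep block
#'
#' Ordinary least squares of `log10(dW/dt)` on the log10 level of the
#' varied factor, with free intercept. Under the power-law rate law the
#' slope is the reaction order of that factor and the intercept collects
#' the fixed factors. `R^2 = Sxy^2 / (Sxx Syy)`, the squared sample
#' correlation.
#'
#' @param block a [sweep_block()].
#' @return An object of class `loglog_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `n`, `varied_factor`, `block_id`.
#' @export
fit_loglog <- function(block) {
  if (!inherits(block, "sweep_block")) {
    abort_aox("`block` must be a sweep_block", "domain")
  }
  fit <- ols_xy(block$log_levels, block$log_rates)
  structure(
    list(slope = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, n = fit$n,
         varied_factor = block$varied_factor, block_id = block$block_id),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "<loglog_fit> %s block %s: y = %.4f x + %.4f, R^2 = %.4f (n = %d)\n",
    x$varied_factor, x$block_id, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Estimate a reaction order from replicate sweep blocks
#'
#' Fits each replicate block by [fit_loglog()] and averages the slopes
#' with equal weight. `order_mean` keeps full precision; `order_reported`
#' rounds half-up to 2 decimals, mirroring the reporting convention of the
#' reference tables.
#'
#' @param blocks list of [sweep_block()]s, all varying the same factor.
#' @return An object of class `order_estimate` with fields `factor`,
#'   `per_block_fits`, `slopes`, `order_mean`, `order_reported`.
#' @export
estimate_order <- function(blocks) {
  if (inherits(blocks, "sweep_block")) blocks <- list(blocks)
  if (length(blocks) < 1L) {
    abort_aox("need at least one sweep block", "degenerate_design")
  }
  factors <- vapply(blocks, function(b) b$varied_factor, character(1))
  if (length(unique(factors)) != 1L) {
    abort_aox(paste0("blocks vary different factors: ",
                     paste(unique(factors), collapse = ", ")),
              "inconsistent_blocks")
  }
  fits <- lapply(blocks, fit_loglog)
  slopes <- vapply(fits, function(f) f$slope, numeric(1))
  structure(
    list(factor = factors[[1]], per_block_fits = fits, slopes = slopes,
         order_mean = mean(slopes),
         order_reported = round_half_up(mean(slopes), 2)),
    class = "order_estimate"
  )
}

#' @export
print.order_estimate <- function(x, ...) {
  cat(sprintf("<order_estimate> %s: mean slope %.6g over %d blocks (reported %.2f)\n",
              x$factor, x$order_mean, length(x$slopes), x$order_reported))
  invisible(x)
}

#' Group rate records into sweep blocks
#'
#' Takes per-condition initial-rate records, applies the log10 transforms
#' and groups them into replicate [sweep_block()]s keyed by replicate
#' label. Records with non-positive rates are excluded with a warning
#' (they have no logarithm); within a block every non-varied factor must
#' be constant.
#'
#' @param records a list of records, each a list with elements `condition`
#'   (an [condition()]), `rate` (numeric or an `initial_rate` object) and
#'   `block_id`.
#' @param varied_factor `"H_plus"`, `"ClO2"` or `"substrate"`.
#' @return A list of [sweep_block()]s, one per replicate label (sorted).
#' @export
build_sweep_blocks <- function(records,
                               varied_factor = c("H_plus", "ClO2",
                                                 "substrate")) {
  varied_factor <- match.arg(varied_factor)
  if (length(records) < 1L) {
    abort_aox("no rate records supplied", "degenerate_design")
  }
  vals <- lapply(records, function(r) {
    rate <- if (inherits(r$rate, "initial_rate")) r$rate$value else r$rate
    list(cond = r$condition, rate = rate,
         block = as.character(r$block_id %||% "1"))
  })

  n_bad <- sum(vapply(vals, function(v) v$rate <= 0, logical(1)))
  if (n_bad > 0) {
    warn_aox(sprintf(
      "excluding %d record(s) with non-positive rate before log transform",
      n_bad), "nonpositive_rate")
    vals <- Filter(function(v) v$rate > 0, vals)
  }
  if (length(vals) == 0L) {
    abort_aox("no records with positive rate remain", "degenerate_design")
  }

  level_of <- switch(varied_factor,
    H_plus = function(cond) -cond$pH,
    ClO2 = function(cond) log10(cond$clo2_M),
    substrate = function(cond) log10(cond$substrate_M)
  )
  fixed_sig <- switch(varied_factor,
    H_plus = function(cond) c(cond$temp_K, cond$clo2_M, cond$substrate_M),
    ClO2 = function(cond) c(cond$pH, cond$temp_K, cond$substrate_M),
    substrate = function(cond) c(cond$pH, cond$temp_K, cond$clo2_M)
  )

  blocks <- split(vals, vapply(vals, function(v) v$block, character(1)))
  lapply(blocks[order(names(blocks))], function(vs) {
    sigs <- t(vapply(vs, function(v) fixed_sig(v$cond), numeric(3)))
    spread <- apply(sigs, 2, function(col) diff(range(col)))
    if (any(spread > 1e-9 * pmax(1, apply(abs(sigs), 2, max)))) {
      abort_aox(sprintf(
        "non-varied factor(s) change within block \"%s\" of the %s sweep",
        vs[[1]]$block, varied_factor), "design_violation")
    }
    lv <- vapply(vs, function(v) level_of(v$cond), numeric(1))
    lr <- log10(vapply(vs, function(v) v$rate, numeric(1)))
    ord <- order(lv, lr)  # tie-break on rate: order-independent summation
    sweep_block(varied_factor, lv[ord], lr[ord], block_id = vs[[1]]$block,
                fixed = vs[[1]]$cond)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
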