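#' Pipeline configuration
#'
#' @param rate_method initial-rate method, see [estimate_initial_rate()].
#' @param window_end_min initial-rate window end in minutes.
#' @param min_levels minimum distinct levels required per sweep.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(rate_method = "initial_window_ols",
                            window_end_min = 4, min_levels = 3L) {
  structure(list(rate_method = rate_method,
                 window_end_min = window_end_min,
                 min_levels = as.integer(min_levels)),
            class = "pipeline_config")
}

# Modal value of a numeric vector (most frequent level); ties broken by
# the smaller value so inference is order-independent.
modal_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Run the full kinetic fitting pipeline
#'
#' curves -> initial rates -> reaction orders (a from the pH sweep, b from
#' the ClO2 sweep, c from the substrate sweep) -> log k from the
#' temperature sweep using the just-estimated orders -> per-replicate
#' Arrhenius fits -> averaged activation energy and pre-exponential
#' factor.
#'
#' Sweep membership is inferred from the conditions themselves: the base
#' level of each factor is its modal value across curves, and a factor's
#' sweep consists of the curves whose other three factors sit at base.
#' The result is therefore invariant to input order. A factor with fewer
#' than `min_levels` distinct levels among its sweep curves raises a
#' missing-design error naming the factor. Replicates are grouped by
#' `block_id`; records with non-positive rates are excluded (with a
#' warning) before log transformation and counted in the report.
#'
#' @param curves list of [aox_curve()]s covering the four sweeps.
#' @param config a [pipeline_config()].
#' @return An object of class `fit_report` with elements `substrate`,
#'   `orders` (list `a`, `b`, `c` of order estimates), `arrhenius`
#'   (averaged fit with `per_block`), `parameters`
#'   ([kinetic_parameters()] with full-precision orders), `n_curves`,
#'   `n_excluded`, `config` and `package_version`.
#' @export
run_pipeline <- function(curves, config = pipeline_config()) {
  if (length(curves) < 4L) {
    abort_aox("too few curves for a factorial fit", "missing_design")
  }
  feats <- data.frame(
    pH = vapply(curves, function(k) k$condition$pH, 1),
    temp_K = vapply(curves, function(k) k$condition$temp_K, 1),
    clo2_M = vapply(curves, function(k) k$condition$clo2_M, 1),
    substrate_M = vapply(curves, function(k) k$condition$substrate_M, 1)
  )
  base <- vapply(feats, modal_value, 1)

  at_base <- function(cols) {
    ok <- rep(TRUE, nrow(feats))
    for (cl in cols) ok <- ok & abs(feats[[cl]] - base[[cl]]) < 1e-12
    ok
  }
  sweep_sel <- list(
    H_plus = at_base(c("temp_K", "clo2_M", "substrate_M")),
    ClO2 = at_base(c("pH", "temp_K", "substrate_M")),
    substrate = at_base(c("pH", "temp_K", "clo2_M")),
    temperature = at_base(c("pH", "clo2_M", "substrate_M"))
  )
  level_col <- c(H_plus = "pH", ClO2 = "clo2_M", substrate = "substrate_M",
                 temperature = "temp_K")
  for (fac in names(sweep_sel)) {
    nlev <- length(unique(feats[[level_col[[fac]]]][sweep_sel[[fac]]]))
    if (nlev < config$min_levels) {
      abort_aox(sprintf(
        "missing or underpopulated sweep for factor \"%s\" (%d distinct level(s), need >= %d)",
        fac, nlev, config$min_levels), "missing_design")
    }
  }

  rates <- vapply(curves, function(k) {
    estimate_initial_rate(k, method = config$rate_method,
                          window_end_min = config$window_end_min)$value
  }, numeric(1))
  blocks_of <- vapply(curves, function(k) k$block_id %||% "1", character(1))

  records_for <- function(sel, level_fun) {
    idx <- which(sel)
    recs <- lapply(idx, function(i) list(condition = curves[[i]]$condition,
                                         rate = rates[[i]],
                                         block_id = blocks_of[[i]]))
    # the base condition is shared by every sweep, so replicate groups
    # from other sweeps show up here with a single level; keep only
    # groups that actually sweep the factor
    groups <- split(recs, vapply(recs, function(r) r$block_id, ""))
    keep <- Filter(function(g) {
      length(unique(vapply(g, function(r) level_fun(r$condition), 1))) >=
        config$min_levels
    }, groups)
    unlist(unname(keep), recursive = FALSE)
  }

  n_excluded <- sum(rates[Reduce(`|`, sweep_sel)] <= 0)
  orders <- list(
    a = estimate_order(build_sweep_blocks(
      records_for(sweep_sel$H_plus, function(cond) cond$pH), "H_plus")),
    b = estimate_order(build_sweep_blocks(
      records_for(sweep_sel$ClO2, function(cond) cond$clo2_M), "ClO2")),
    c = estimate_order(build_sweep_blocks(
      records_for(sweep_sel$substrate, function(cond) cond$substrate_M),
      "substrate"))
  )
  ord_vec <- list(a = orders$a$order_mean, b = orders$b$order_mean,
                  c = orders$c$order_mean)

  # Arrhenius stage on the temperature sweep, per replicate block
  tidx <- which(sweep_sel$temperature & rates > 0)
  if (!length(tidx)) {
    abort_aox("no positive rates in the temperature sweep", "missing_design")
  }
  tsplit <- split(tidx, blocks_of[tidx])
  tsplit <- Filter(function(ids) {
    length(unique(vapply(ids, function(i) curves[[i]]$condition$temp_K,
                         1))) >= config$min_levels
  }, tsplit)
  if (!length(tsplit)) {
    abort_aox("no replicate block sweeps temperature over >= 3 levels",
              "missing_design")
  }
  arr_fits <- lapply(names(tsplit)[order(names(tsplit))], function(bl) {
    ids <- tsplit[[bl]]
    inv_T <- vapply(ids, function(i) 1 / curves[[i]]$condition$temp_K, 1)
    lk <- vapply(ids, function(i) {
      log_k_from_rate(log10(rates[[i]]), ord_vec, curves[[i]]$condition)
    }, 1)
    o <- order(inv_T, lk)
    fit_arrhenius(inv_T[o], lk[o], block_id = bl)
  })
  arrhenius <- average_arrhenius(arr_fits)

  params <- kinetic_parameters(A = arrhenius$A, E = arrhenius$E_J_per_mol,
                               a = ord_vec$a, b = ord_vec$b, c = ord_vec$c)
  substrate <- curves[[1]]$condition$substrate
  structure(
    list(substrate = substrate, orders = orders, arrhenius = arrhenius,
         parameters = params, n_curves = length(curves),
         n_excluded = n_excluded, config = unclass(config),
         package_version = as.character(utils::packageVersion("aoxkinetics"))),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s (%d curves, %d excluded records)\n",
              x$substrate, x$n_curves, x$n_excluded))
  cat(sprintf("  orders: a = %.4f, b = %.4f, c = %.4f\n",
              x$parameters$a, x$parameters$b, x$parameters$c))
  cat(sprintf("  E = %.2f J/mol, A = %.6g\n", x$parameters$E,
              x$parameters$A))
  invisible(x)
}

#' Validate model predictions against observed curves
#'
#' Predicts every observation with [predict_curve()] at the matching
#' condition and times, then reports the coefficient of determination of
#' the ordinary least-squares regression of observed on predicted AOX.
#'
#' @param params a [kinetic_parameters()] object.
#' @param curves list of observed [aox_curve()]s (>= 2 observations in
#'   total).
#' @param depletion [depletion_spec()] used for the predictions.
#' @param step_min integrator step.
#' @return The R^2 (a single number in `[0, 1]`).
#' @export
validate_predictions <- function(params, curves,
                                 depletion = no_depletion(),
                                 step_min = 0.01) {
  if (inherits(curves, "aox_curve")) curves <- list(curves)
  obs <- unlist(lapply(curves, function(k) k$aox_mg_L))
  pred <- unlist(lapply(curves, function(k) {
    predict_curve(params, k$condition, depletion, k$times_min,
                  step_min)$aox_mg_L
  }))
  if (length(obs) < 2L) {
    abort_aox("need >= 2 observations to compute R^2", "insufficient_data")
  }
  if (stats::var(pred) == 0) {
    abort_aox("predictions have zero variance; R^2 undefined",
              "undefined_r2")
  }
  if (stats::var(obs) == 0) {
    abort_aox("observations have zero variance; R^2 undefined",
              "undefined_r2")
  }
  ols_xy(pred, obs)$r_squared
}

curve_csv_columns <- c("substrate", "block_id", "pH", "temp_K",
                       "clo2_mmol_per_L", "substrate_mmol_per_L",
                       "time_min", "aox_mg_per_L")

#' Read and write AOX curve CSV files
#'
#' The on-disk format is one row per observation with header
#' `substrate,block_id,pH,temp_K,clo2_mmol_per_L,substrate_mmol_per_L,time_min,aox_mg_per_L`
#' (UTF-8, `.` decimal separator). Concentrations are in mmol/l on disk
#' and converted to mol/l on read; [write_curves()] performs the inverse
#' conversion and keeps 15 significant digits so a write/read round trip
#' preserves values.
#'
#' @param path CSV file path.
#' @return `read_curves()` returns a list of [aox_curve()]s (one per
#'   unique condition/block), ordered deterministically.
#' @export
read_curves <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  missing <- setdiff(curve_csv_columns, names(df))
  if (length(missing)) {
    abort_aox(paste0("curve CSV is missing column(s): ",
                     paste(missing, collapse = ", ")), "parse")
  }
  num_cols <- setdiff(curve_csv_columns, c("substrate", "block_id"))
  for (cl in num_cols) {
    vals <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      abort_aox(sprintf("non-numeric value in column \"%s\" at data row(s) %s",
                        cl, paste(bad, collapse = ", ")), "parse")
    }
    df[[cl]] <- vals
  }
  key <- do.call(paste, c(df[c("substrate", "block_id", "pH", "temp_K",
                               "clo2_mmol_per_L", "substrate_mmol_per_L")],
                          sep = "|"))
  dup <- duplicated(paste(key, df$time_min))
  if (any(dup)) {
    abort_aox(sprintf("duplicated (condition, time) at data row(s) %s",
                      paste(which(dup), collapse = ", ")), "parse")
  }
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    d <- df[idx, ]
    d <- d[order(d$time_min), ]
    cond <- condition(d$substrate[[1]], d$pH[[1]], d$temp_K[[1]],
                      d$clo2_mmol_per_L[[1]] / 1000,
                      d$substrate_mmol_per_L[[1]] / 1000)
    aox_curve(cond, d$time_min, d$aox_mg_per_L, block_id = d$block_id[[1]])
  })
  names(out) <- NULL
  out
}

#' @param curves list of [aox_curve()]s.
#' @rdname read_curves
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "aox_curve")) curves <- list(curves)
  rows <- lapply(curves, function(k) {
    cond <- k$condition
    data.frame(
      substrate = cond$substrate,
      block_id = k$block_id %||% "1",
      pH = fmt15(cond$pH), temp_K = fmt15(cond$temp_K),
      clo2_mmol_per_L = fmt15(cond$clo2_M * 1000),
      substrate_mmol_per_L = fmt15(cond$substrate_M * 1000),
      time_min = fmt15(k$times_min),
      aox_mg_per_L = fmt15(k$aox_mg_L),
      stringsAsFactors = FALSE
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt15 <- function(x) formatC(x, digits = 15, format = "g")

#' Write a fit report as JSON
#'
#' Canonical serialization with a stable key order and full numeric
#' precision; no timestamps, so output is byte-reproducible for a fixed
#' input and configuration.
#'
#' @param report a `fit_report` from [run_pipeline()].
#' @param path output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report <- function(report, path = NULL) {
  ord_json <- function(o) {
    list(factor = o$factor, slopes = o$slopes, order_mean = o$order_mean,
         order_reported = o$order_reported)
  }
  arr <- report$arrhenius
  obj <- list(
    substrate = report$substrate,
    parameters = list(A = report$parameters$A,
                      E_J_per_mol = report$parameters$E,
                      a = report$parameters$a, b = report$parameters$b,
                      c = report$parameters$c),
    orders = lapply(report$orders, ord_json),
    arrhenius = list(
      slope_K = arr$slope_K, intercept = arr$intercept,
      E_J_per_mol = arr$E_J_per_mol, A = arr$A,
      per_block = lapply(arr$per_block, function(f) {
        list(block_id = f$block_id, slope_K = f$slope_K,
             intercept = f$intercept, r_squared = f$r_squared, n = f$n)
      })
    ),
    n_curves = report$n_curves,
    n_excluded = report$n_excluded,
    config = report$config,
    package_version = report$package_version
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
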