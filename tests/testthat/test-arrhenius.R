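test_that("log_k_from_rate removes concentration factors in log space", {
  cond <- base_cond()
  # vanishing orders leave the log rate untouched
  expect_identical(log_k_from_rate(0.5, list(a = 0, b = 0, c = 0), cond),
                   0.5)
  # forward/inverse round trip: generated rate maps back to log10 k(T)
  p <- preset_parameters("VA")
  lr <- log10(evaluate_rate(p, cond))
  expect_equal(log_k_from_rate(lr, p, cond),
               log10(p$A) - p$E / (GAS_CONSTANT * cond$temp_K) * log10(exp(1)),
               tolerance = 1e-12)
  # doubling [ClO2] at fixed rate lowers log k by b log10(2)
  cond2 <- base_cond(clo2_M = 2 * cond$clo2_M)
  expect_equal(log_k_from_rate(lr, p, cond) - log_k_from_rate(lr, p, cond2),
               p$b * log10(2), tolerance = 1e-12)
  expect_error(log_k_from_rate(1, p, base_cond(clo2_M = 0)),
               class = "aoxkinetics_error_domain")
})

test_that("fit_arrhenius recovers exact Arrhenius parameters", {
  A <- 100; E <- 50000
  Ts <- c(300, 320, 340)
  lk <- log10(A) - E / (GAS_CONSTANT * Ts) * log10(exp(1))
  fit <- fit_arrhenius(1 / Ts, lk)
  expect_equal(fit$A, A, tolerance = 1e-8)
  expect_equal(fit$E_J_per_mol, E, tolerance = 1e-8 * E)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("a slope of -848.45 K converts to the reference activation energy", {
  inv_T <- 1 / c(323, 328, 333, 338, 343)
  lk <- 4.87 - 848.45 * inv_T
  fit <- fit_arrhenius(inv_T, lk)
  expect_equal(fit$slope_K, -848.45, tolerance = 1e-9)
  expect_equal(round_half_up(fit$E_J_per_mol), 16242.47)
})

test_that("fit_arrhenius matches the normal-equations oracle on jittered points", {
  withr::with_seed(19, {
    for (i in 1:10) {
      inv_T <- 1 / seq(300, 360, length.out = 5)
      lk <- 3 - 900 * inv_T + rnorm(5, 0, 0.01)
      fit <- fit_arrhenius(inv_T, lk)
      ref <- ols_oracle(inv_T, lk)
      expect_equal(fit$slope_K, ref$slope, tolerance = 1e-12 * abs(ref$slope))
      expect_equal(fit$intercept, ref$intercept, tolerance = 1e-10)
    }
  })
})

test_that("average_arrhenius averages slopes and intercepts and re-derives E and A", {
  mk <- function(slope, int) {
    inv_T <- 1 / c(323, 333, 343)
    fit_arrhenius(inv_T, int + slope * inv_T)
  }
  # printed VA slopes average to -848.45 at two decimals
  avg <- average_arrhenius(lapply(c(-899.55, -849.89, -795.92),
                                  mk, int = 4.87))
  expect_equal(round_half_up(avg$slope_K), -848.45)
  expect_equal(avg$E_J_per_mol, -mean(c(-899.55, -849.89, -795.92)) *
                 GAS_CONSTANT * log(10), tolerance = 1e-10)
  # printed VE slopes average to -14.54
  avg2 <- average_arrhenius(lapply(c(-14.70, -14.54, -14.37),
                                   mk, int = 4.65))
  expect_equal(round_half_up(avg2$slope_K), -14.54)
  # a single fit averages to itself
  one <- mk(-500, 2)
  avg3 <- average_arrhenius(list(one))
  expect_equal(avg3$slope_K, one$slope_K)
  expect_equal(avg3$A, one$A)
  expect_error(average_arrhenius(list()),
               class = "aoxkinetics_error_degenerate_design")
})

test_that("fewer than three distinct temperatures is a degenerate design", {
  expect_error(fit_arrhenius(c(1 / 300, 1 / 300, 1 / 320), c(1, 1, 2)),
               class = "aoxkinetics_error_degenerate_design")
})

test_that("rates at several temperatures round-trip to the generating A and E", {
  p <- preset_parameters("VA")
  Ts <- c(323, 328, 333, 338, 343)
  pts <- lapply(Ts, function(T) {
    cond <- base_cond(temp_K = T)
    crv <- predict_curve(p, cond, no_depletion(),
                         c(1, 2, 3, 4, 6, 8, 10, 15, 30))
    rate <- estimate_initial_rate(crv)$value
    c(inv_T = 1 / T, log_k = log_k_from_rate(log10(rate), p, cond))
  })
  m <- do.call(rbind, pts)
  fit <- fit_arrhenius(m[, "inv_T"], m[, "log_k"])
  expect_equal(fit$E_J_per_mol, p$E, tolerance = 1e-6 * p$E)
  expect_equal(fit$A, p$A, tolerance = 1e-6 * p$A)
})

test_that("E is invariant under a common rescaling of concentrations", {
  p <- preset_parameters("VA")
  Ts <- c(323, 333, 343)
  fit_for <- function(scale) {
    pts <- vapply(Ts, function(T) {
      cond <- base_cond(temp_K = T, clo2_M = 0.124 * scale,
                        substrate_M = 0.062 * scale)
      log_k_from_rate(log10(evaluate_rate(p, cond)), p, cond)
    }, 1)
    fit_arrhenius(1 / Ts, pts)
  }
  f1 <- fit_for(1); f2 <- fit_for(10)
  expect_equal(f1$E_J_per_mol, f2$E_J_per_mol, tolerance = 1e-9)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-9)
})

test_that("bundled Arrhenius table loads with the kelvin conversion and flag", {
  pts <- load_arrhenius_points()
  expect_equal(nrow(pts), 30)
  expect_equal(pts$inv_T, pts$inv_T_e3 / 1000)
  flagged <- pts[pts$flag == "printed_x_inconsistent", ]
  expect_equal(unique(flagged$inv_T_e3), 2.99)
  expect_true(all(flagged$block_id == "1"))
})
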