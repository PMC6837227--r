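test_that("refitting the first VA pH block reproduces its printed regression", {
  b <- sweep_block("H_plus", c(-4.00, -3.50, -3.00, -2.50, -2.00),
                   c(0.70, 0.76, 0.77, 0.82, 0.84))
  fit <- fit_loglog(b)
  expect_equal(round_half_up(fit$slope), 0.07)
  expect_equal(round_half_up(fit$intercept), 0.98)
  expect_equal(round_half_up(fit$r_squared), 0.96)
})

test_that("collinear input is fit exactly", {
  b <- sweep_block("ClO2", c(-2, -1.5, -1, -0.5), 2 * c(-2, -1.5, -1, -0.5) + 1)
  fit <- fit_loglog(b)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("fit_loglog matches the normal-equations oracle on random blocks", {
  withr::with_seed(11, {
    for (i in 1:25) {
      x <- sort(runif(6, -2, 0))
      y <- 0.8 * x + rnorm(6, 0, 0.05)
      fit <- fit_loglog(sweep_block("substrate", x, y))
      ref <- ols_oracle(x, y)
      expect_equal(fit$slope, ref$slope, tolerance = 1e-12)
      expect_equal(fit$intercept, ref$intercept, tolerance = 1e-12)
      expect_equal(fit$r_squared, ref$r_squared, tolerance = 1e-12)
      # R^2 equals the squared sample correlation
      expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)
    }
  })
})

test_that("slope is invariant under shifting all log levels", {
  withr::with_seed(3, {
    x <- sort(runif(5, -2, 0))
    y <- 0.5 * x + rnorm(5, 0, 0.02)
    f1 <- fit_loglog(sweep_block("ClO2", x, y))
    f2 <- fit_loglog(sweep_block("ClO2", x + 1.7, y))
    expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
    expect_equal(f2$intercept, f1$intercept - 1.7 * f1$slope,
                 tolerance = 1e-12)
  })
})

test_that("estimate_order averages per-block slopes with half-up reporting", {
  mk <- function(slope) {
    x <- c(-2, -1.5, -1, -0.5, 0)
    sweep_block("ClO2", x, slope * x + 1)
  }
  # printed VA ClO2 slopes
  est <- estimate_order(lapply(c(0.94, 0.94, 0.93), mk))
  expect_equal(est$order_reported, 0.94)
  # printed VA substrate slopes: mean 0.3567 -> 0.36
  est2 <- estimate_order(lapply(c(0.33, 0.35, 0.39),
                                function(s) {
                                  x <- c(-2, -1.5, -1)
                                  sweep_block("substrate", x, s * x)
                                }))
  expect_equal(est2$order_reported, 0.36)
  expect_equal(est2$order_mean, mean(c(0.33, 0.35, 0.39)),
               tolerance = 1e-12)
  # identical slopes pass through
  est3 <- estimate_order(lapply(rep(0.5, 3), mk))
  expect_equal(est3$order_mean, 0.5, tolerance = 1e-12)
  # mixed factors are rejected
  expect_error(
    estimate_order(list(mk(1), sweep_block("H_plus", c(-4, -3, -2),
                                           c(1, 2, 3)))),
    class = "aoxkinetics_error_inconsistent_blocks"
  )
})

test_that("build_sweep_blocks groups replicates and excludes non-positive rates", {
  recs <- list()
  for (r in 1:3) {
    for (pH in c(2, 2.5, 3, 3.5, 4)) {
      recs[[length(recs) + 1L]] <- list(
        condition = base_cond(pH = pH), rate = 5 + pH + r / 10,
        block_id = paste0("r", r)
      )
    }
  }
  blocks <- build_sweep_blocks(recs, "H_plus")
  expect_length(blocks, 3)
  expect_true(all(vapply(blocks, function(b) length(b$log_levels),
                         1L) == 5L))
  # one zero rate is dropped with a warning
  recs[[1]]$rate <- 0
  expect_warning(blocks2 <- build_sweep_blocks(recs, "H_plus"),
                 class = "aoxkinetics_warning_nonpositive_rate")
  expect_length(blocks2[[1]]$log_levels, 4)
  # a drifting fixed factor is a design violation
  recs[[2]]$condition <- base_cond(pH = 2.5, temp_K = 353)
  expect_error(suppressWarnings(build_sweep_blocks(recs, "H_plus")),
               class = "aoxkinetics_error_design_violation")
})

test_that("noise-free synthetic sweeps recover the generating order", {
  p <- preset_parameters("VA")
  for (fac in c("H_plus", "ClO2", "substrate")) {
    levels <- switch(fac,
      H_plus = c(2, 2.5, 3, 3.5, 4),
      ClO2 = c(24.8, 49.6, 73.4, 99.2, 124) / 1000,
      substrate = c(31, 46.5, 62, 77.5, 93) / 1000)
    recs <- lapply(levels, function(v) {
      cond <- switch(fac,
        H_plus = base_cond(pH = v),
        ClO2 = base_cond(clo2_M = v),
        substrate = base_cond(substrate_M = v))
      crv <- predict_curve(p, cond, no_depletion(),
                           c(1, 2, 3, 4, 6, 8, 10, 15, 30))
      list(condition = cond, rate = estimate_initial_rate(crv),
           block_id = "r1")
    })
    est <- estimate_order(build_sweep_blocks(recs, fac))
    truth <- switch(fac, H_plus = p$a, ClO2 = p$b, substrate = p$c)
    expect_equal(est$order_mean, truth, tolerance = 1e-9)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(sweep_block("ClO2", c(-1, -1, -2), c(1, 2, 3)),
               class = "aoxkinetics_error_degenerate_design")
  expect_error(sweep_block("ClO2", c(-1, -2), c(1, 2)),
               class = "aoxkinetics_error_degenerate_design")
  # zero variance in rates: R^2 defined as 0 with a warning
  expect_warning(
    fit <- fit_loglog(sweep_block("ClO2", c(-2, -1.5, -1), rep(1, 3))),
    class = "aoxkinetics_warning_zero_variance"
  )
  expect_identical(fit$r_squared, 0)
})
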