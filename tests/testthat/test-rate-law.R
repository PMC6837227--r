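test_that("rate law reduces to A when all exponents and E are zero", {
  p <- kinetic_parameters(A = 5, E = 0, a = 0, b = 0, c = 0)
  expect_identical(evaluate_rate(p, base_cond()), 5)
  expect_identical(evaluate_rate(p, base_cond(pH = -1, clo2_M = 0,
                                              substrate_M = 0)), 5)
})

test_that("rate scales as a power law in each concentration", {
  p <- preset_parameters("VA")
  cond <- base_cond()
  r0 <- evaluate_rate(p, cond)
  expect_equal(evaluate_rate(p, base_cond(clo2_M = 2 * cond$clo2_M)),
               2^p$b * r0, tolerance = 1e-14)
  withr::with_seed(42, {
    for (i in 1:20) {
      q <- random_params()
      alpha <- runif(1, 0.1, 10)
      expect_equal(
        evaluate_rate(q, base_cond(clo2_M = alpha * cond$clo2_M)),
        alpha^q$b * evaluate_rate(q, cond),
        tolerance = 1e-12
      )
    }
  })
})

test_that("VA preset rate at the base condition matches the frozen high-precision value", {
  # arbitrary-precision evaluation of A e^(-E/RT) 10^(-0.07*3) 0.124^0.94 0.062^0.36
  expect_equal(evaluate_rate(preset_parameters("VA"), base_cond()),
               7.900626460873034, tolerance = 1e-13)
})

test_that("log10 rate is exactly linear in pH with slope -a", {
  p <- preset_parameters("VA")
  pHs <- seq(2, 4, by = 0.5)
  lr <- vapply(pHs, function(x) log10(evaluate_rate(p, base_cond(pH = x))),
               1)
  fit <- ols_oracle(pHs, lr)
  expect_equal(fit$slope, -p$a, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("rate constant follows the Arrhenius form", {
  expect_identical(rate_constant(kinetic_parameters(1012.05, 0, 0, 0, 0),
                                 300), 1012.05)
  p <- preset_parameters("VA")
  # algebraic identity k(T2)/k(T1) = exp(-E/R (1/T2 - 1/T1))
  expect_equal(rate_constant(p, 353) / rate_constant(p, 313),
               exp(-p$E / GAS_CONSTANT * (1 / 353 - 1 / 313)),
               tolerance = 1e-14)
  # frozen arbitrary-precision ratio for the VA preset
  expect_equal(rate_constant(p, 343) / rate_constant(p, 323),
               1.4228694810746338, tolerance = 1e-13)
  # monotone in T when E > 0
  ks <- vapply(seq(300, 360, by = 10), function(T) rate_constant(p, T), 1)
  expect_true(all(diff(ks) > 0))
})

test_that("log10 k is exactly collinear in 1/T for any parameters", {
  withr::with_seed(7, {
    for (i in 1:10) {
      q <- random_params()
      Ts <- seq(300, 360, by = 12)
      lk <- vapply(Ts, function(T) log10(rate_constant(q, T)), 1)
      expect_equal(ols_oracle(1 / Ts, lk)$r_squared, 1, tolerance = 1e-12)
    }
  })
})

test_that("zero concentration with a negative order is a domain error", {
  p <- kinetic_parameters(A = 1, E = 0, a = 0, b = -0.5, c = 0)
  expect_error(evaluate_rate(p, base_cond(clo2_M = 0)),
               class = "aoxkinetics_error_domain")
  # zero concentration with order 0 is fine (0^0 = 1)
  expect_identical(evaluate_rate(kinetic_parameters(2, 0, 0, 0, 0),
                                 base_cond(clo2_M = 0)), 2)
})

test_that("presets carry the reference parameter values", {
  va <- preset_parameters("VA")
  expect_equal(unlist(va[c("A", "E", "a", "b", "c")]),
               c(A = 73824.40, E = 16242.47, a = 0.07, b = 0.94, c = 0.36))
  ve <- preset_parameters("VE")
  expect_equal(ve$E, 281.34)
  expect_equal(ve$b, 0.85)
  expect_equal(ve$c, 0.30)
  ve2 <- preset_parameters("VE", source = "printed_equation")
  expect_equal(c(ve2$b, ve2$c), c(0.98, 0.91))
  expect_error(preset_parameters("XX"), class = "aoxkinetics_error_lookup")
})

test_that("parameter JSON round-trips", {
  p <- preset_parameters("VE")
  path <- withr::local_tempfile(fileext = ".json")
  parameters_to_json(p, "VE", path)
  back <- parameters_from_json(path)
  expect_equal(back$substrate, "VE")
  expect_equal(back$params, p)
})
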