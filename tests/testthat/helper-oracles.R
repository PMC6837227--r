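# Independent oracles and small fixture builders shared across tests.

# Closed-form simple linear regression via the normal equations,
# independent of the QR path used inside the package.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2) - sx^2 / n
  syy <- sum(y^2) - sy^2 / n
  sxy <- sum(x * y) - sx * sy / n
  slope <- sxy / sxx
  list(slope = slope, intercept = sy / n - slope * sx / n,
       r_squared = sxy^2 / (sxx * syy))
}

base_cond <- function(substrate = "VA", pH = 3, temp_K = 343,
                      clo2_M = 0.124, substrate_M = 0.062) {
  condition(substrate, pH, temp_K, clo2_M, substrate_M)
}

# Saturating test curve W(t) = W_inf * (1 - exp(-lambda t)) on the
# standard sampling grid; true initial slope is W_inf * lambda.
saturating_curve <- function(W_inf = 30, lambda = 0.3,
                             times = c(1, 2, 3, 4, 6, 8, 10, 15, 30)) {
  aox_curve(base_cond(), times, W_inf * (1 - exp(-lambda * times)))
}

# Random-but-reproducible kinetic parameters for property loops.
random_params <- function() {
  kinetic_parameters(A = exp(runif(1, 0, 10)), E = runif(1, 0, 40000),
                     a = runif(1, -0.5, 1), b = runif(1, 0, 1.5),
                     c = runif(1, 0, 1))
}

# Generating truth used by the recovery tests.
TRUE_VA <- preset_parameters("VA")
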