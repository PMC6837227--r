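# aoxkinetics

Kinetic analysis of **adsorbable organic halogen (AOX)** formation when
lignin model compounds react with chlorine dioxide under pulp-bleaching
conditions. AOX — the pool of chlorinated organics produced by side
reactions of HClO/Cl2 during ClO2 (D0-stage) bleaching — is an
environmentally persistent byproduct, and its formation kinetics differ
between the phenolic and non-phenolic structural units of residual
lignin. The package works with the two standard model compounds for
those units: vanillyl alcohol (VA, phenolic) and veratryl alcohol (VE,
non-phenolic).

It is intended for bleaching chemists and kinetics-minded analysts who
want the full sweep-based estimation procedure as reusable, tested code:

* the empirical power-law rate model

  dW/dt = A·e^(−E/RT)·[H⁺]^a·[ClO₂]^b·[C]^c

  with W in mg l⁻¹, t in min, concentrations in mol l⁻¹,
  [H⁺] = 10^(−pH), and R = 8.314 J mol⁻¹ K⁻¹
  (`evaluate_rate()`, `rate_constant()`, `preset_parameters()`);
* initial-rate extraction from sampled AOX(t) curves
  (`estimate_initial_rate()`: early-window OLS, two-point, or spline
  derivative);
* reaction-order estimation by log₁₀–log₁₀ least squares over
  one-factor-at-a-time sweeps with replicate averaging
  (`fit_loglog()`, `estimate_order()`, `build_sweep_blocks()`);
* Arrhenius regression of log₁₀ k on 1/T, with
  E = −slope·R·ln 10 and A = 10^intercept
  (`log_k_from_rate()`, `fit_arrhenius()`, `average_arrhenius()`);
* deterministic forward simulation of saturating AOX curves (fixed-step
  RK4 with reagent depletion, `predict_curve()`) and a seeded synthetic
  factorial generator for parameter-recovery studies
  (`reference_design()`, `generate_dataset()`);
* an end-to-end pipeline with CSV/JSON interfaces
  (`run_pipeline()`, `read_curves()`, `write_report()`,
  `validate_predictions()`), plus the published sweep tables bundled as
  fixtures (`fit_reference_tables()`).

## Worked example

```r
library(aoxkinetics)

# Rate law at the base condition (pH 3.00, 343 K, 0.124 M ClO2, 0.062 M VA)
va   <- preset_parameters("VA")
cond <- condition("VA", pH = 3, temp_K = 343, clo2_M = 0.124, substrate_M = 0.062)
evaluate_rate(va, cond)
#> [1] 7.900626

# Reproduce the published sweep-table analysis from the bundled fixtures
fit_reference_tables("VA")
#> <reference_tables_fit> VA
#>   orders (reported): a = 0.07, b = 0.94, c = 0.36
#>   mean Arrhenius slope -848.45 K -> E = 16242.53 J/mol (printed precision 16242.47)

# Simulate the full factorial study (60 curves, 3% multiplicative noise)
# and refit it end to end
ds  <- generate_dataset(reference_design("VA"), va, depletion_spec(),
                        noise_spec(cv = 0.03, seed = 42))
rep <- run_pipeline(ds)
rep
#> <fit_report> VA (60 curves, 0 excluded records)
#>   orders: a = 0.0640, b = 0.9543, c = 0.3355
#>   E = 13658.32 J/mol, A = 20726.9

round(validate_predictions(va, ds, depletion_spec()), 4)
#> [1] 0.9967
```

Reading the numbers: the first call evaluates the VA rate law, 7.9
mg l⁻¹ min⁻¹ at the base condition. The reference-table path recovers
the published orders (a = 0.07, b = 0.94, c = 0.36) and activation
energy (16 242.47 J mol⁻¹ at printed precision, from the mean Arrhenius
slope −848.45 K). The synthetic refit recovers the orders to a few
hundredths; its activation energy is systematically low because
early-window initial rates are attenuated by reagent depletion — a
real bias of the initial-rate method that the methods vignette
(`vignettes/aox-formation-kinetics.Rmd`) quantifies and discusses. The
final R² compares all 540 simulated observations with the generating
model's predictions.

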