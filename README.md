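# patlaksim

Accuracy and precision of sparse-sampling Patlak linearization for
⁸⁹Zr-immuno-PET, by simulation.

## The problem

PET imaging of zirconium-89-labelled monoclonal antibodies
(⁸⁹Zr-immuno-PET) quantifies antibody uptake in organs and tumors. Because
⁸⁹Zr residualizes in tissue after antibody catabolism or target
engagement, uptake follows an irreversible two-tissue compartment model and
can be analysed with Patlak graphical analysis: once plasma and the
reversible tissue compartment are in equilibrium,

```
AC_t(t) / AC_p(t) = Ki · ( ∫₀ᵗ AC_p(x) dx / AC_p(t) ) + VT
```

is a straight line whose slope `Ki` (h⁻¹) is the net irreversible uptake
rate and whose intercept `VT` (unitless) is the reversible
tissue-to-plasma distribution volume. In patients, however, only a handful
of blood samples and PET scans can be acquired — typically a plasma sample
at injection plus three imaging days — so the plasma integral `AUC_p` must
be computed by the trapezoidal rule over four points, and the regression
uses only three points. Since the plasma input function (IF) of an
antibody is a convex, decaying bi-exponential

```
AC_p(t) = A·e^(a·t) + B·e^(b·t),     a < 0, b < 0,
```

the sparse trapezoid *over*-estimates `AUC_p`, stretching the Patlak
x-coordinates and systematically *under*-estimating `Ki`. This package
quantifies that bias, and the noise-driven variability around it, as a
function of the imaging schedule, the IF, the noise level and the
reference kinetics — so that imaging protocols (in particular, whether to
scan at 24 h post-injection) can be chosen rationally.

The package provides:

* bi-exponential IF objects with analytic integrals and a
  Levenberg–Marquardt fitter (`biexp()`, `auc()`, `fit_biexp()`), plus
  three bundled synthetic IF parameter sets spanning fast
  (`"huJ591-like"`), intermediate (`"trastuzumab-like"`) and slow
  (`"pertuzumab-like"`) antibody clearance (`input_function_library()`);
* the Patlak forward model for tissue activity curves (`simulate_tac()`)
  and a counting-statistics noise model in which the fractional SD grows
  as the non-decay-corrected signal decays (`noise_model()`,
  `percent_sd()`, `add_noise()`);
* the sparse-sampling estimator: trapezoidal plasma AUC
  (`trapezoid_auc()`), Patlak coordinates (`patlak_coordinates()`) and an
  OLS fit object with the usual methods (`patlak()`);
* a Monte-Carlo engine over condition grids (`condition()`,
  `run_condition()`, `run_grid()`, `enumerate_schedules()`), YAML/JSON
  configuration (`load_config()`) and a command-line front end
  (`inst/cli/patlaksim.R` with `simulate`, `fit`, `grid` and `schedules`
  subcommands).

## Worked example

Simulate one sparse study with the slow-clearing IF (`rKi` = 1·10⁻³ h⁻¹,
`rVT` = 0.2, scans at 24/48/96 h, 5% TAC noise) and fit it:

```r
library(patlaksim)

ifn <- input_function_library("pertuzumab-like")
ifn
#> Bi-exponential plasma input function (pertuzumab-like)
#>   AC_p(t) = 13 * exp(-0.08 t) + 22 * exp(-0.0045 t)   [%IA/L, t in h]
#>   half-lives: fast 8.66 h, slow 154.03 h;  AC_p(0) = 35.00 %IA/L

sch <- sampling_schedule(c(24, 48, 96))   # plasma also sampled at 0 h
sc  <- make_scenario(ifn, ki = 1e-3, vt = 0.2, schedule = sch,
                     noise0 = 0.05, seed = 42)
sc$tissue
#>   time_h conc_pia_per_l noisy_conc_pia_per_l
#> 1     24       4.969903             5.419463
#> 2     48       4.709865             4.509427
#> 3     96       4.735124             4.894905

fit <- patlak(patlak_coordinates(sc$plasma$time_h, sc$plasma$conc_pia_per_l,
                                 sc$tissue$time_h,
                                 sc$tissue$noisy_conc_pia_per_l))
fit
#> Patlak graphical analysis (3 points)
#>   Ki = 0.000955337 1/h   VT = 0.207629
```

A single noisy study underestimates `Ki` here by ~4.5%. Averaging over
1000 repetitions separates the systematic trapezoid bias from noise:

```r
cond <- condition(ifn, sch, ki = 1e-3, vt = 0.2, noise0 = 0.05,
                  n_reps = 1000, seed = 42)
run_condition(cond)[, c("bias_ki_pct", "variability_ki_pct",
                        "bias_vt_pct", "variability_vt_pct")]
#>   bias_ki_pct variability_ki_pct bias_vt_pct variability_vt_pct
#> 1   -1.318322           34.93164  -0.9632568           11.33156
```

so under this condition `Ki` carries a small negative systematic bias
(−1.3%) with a ~35% single-study spread, while `VT` is nearly unbiased
with ~11% spread. `run_grid(default_config())` sweeps the full canonical
design — 3 IFs × 10 three-point schedules from {24, 48, 96, 144, 192} h ×
rKi {1, 5, 20}·10⁻³ h⁻¹ × rVT {0.1, 0.2, 0.5} × noise {5, 10, 15}% — and
returns one bias/variability summary row per condition.

## Command line

```sh
Rscript inst/cli/patlaksim.R schedules --require 24
Rscript inst/cli/patlaksim.R simulate --fixture pertuzumab-like \
    --ki 0.001 --vt 0.2 --times 24,48,96 --noise 0.05 --seed 1 --out scenario.csv
Rscript inst/cli/patlaksim.R fit --in scenario.csv
Rscript inst/cli/patlaksim.R grid --reps 200 --seed 1 --out summary.csv
```
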