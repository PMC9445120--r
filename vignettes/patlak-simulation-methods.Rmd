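---
title: "Simulating sparse-sampling Patlak analysis for 89Zr-immuno-PET: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sparse-sampling Patlak analysis for 89Zr-immuno-PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patlaksim)
```

## The model

Zirconium-89-labelled antibodies residualize in tissue after catabolism or
irreversible target binding, so their tissue kinetics follow an
irreversible two-tissue compartment model. After the reversible
compartment equilibrates with plasma, the tissue activity concentration
decomposes as

$$AC_t(t) = K_i \int_0^t AC_p(x)\,dx + V_T\, AC_p(t),$$

and dividing by $AC_p(t)$ gives the Patlak line with slope $K_i$ (h$^{-1}$,
net irreversible uptake) and intercept $V_T$ (unitless, reversible
distribution volume). The plasma input function (IF) is modelled as a
bi-exponential $AC_p(t) = A e^{a t} + B e^{b t}$ with both rates strictly
negative; its integral is analytic, which gives the *exact* forward model
(`simulate_tac()`) and an exact reference against which numerical
integration errors can be measured.

In practice the IF is only sampled at injection plus each imaging day
(four points for a three-scan protocol), so $AUC_p$ must be computed by
the composite trapezoidal rule. Because a decaying bi-exponential is
convex, the trapezoid always *over*-estimates $AUC_p$; the Patlak
x-coordinates stretch while the y-coordinates are unaffected, and the OLS
slope — hence $\hat K_i$ — is biased *downward* in every condition. This
deterministic mechanism, not noise, sets the accuracy of sparse Patlak
analysis; noise only adds spread around it. Both effects are quantified by
the Monte-Carlo engine.

## Noise model

Counting statistics are Poisson, so the fractional SD of a measured
concentration scales as $1/\sqrt{N}$ with $N$ the collected counts. For
equal scan durations $N$ is proportional to the *non-decay-corrected*
tissue concentration $ncAC_t(t) = AC_t(t)\,2^{-t/T_{1/2}}$ with
$T_{1/2} = 78.41$ h for ⁸⁹Zr. Anchoring the model at a user-chosen
fractional SD at $t=0$ (`noise0`; 5, 10 and 15% in the canonical design)
gives

$$\%SD(t) = noise0 \cdot \sqrt{ncAC_t(0) / ncAC_t(t)},$$

which the package applies as a single multiplicative Gaussian perturbation
per imaging point per repetition (`add_noise()`), independent across
points and repetitions. Design choices worth stating explicitly:

* The square root is written so that the SD *grows* as the
  non-decay-corrected signal decays. The alternative algebraic placement
  (dividing by the ratio's square root) would make late frames *less*
  noisy than early ones, which contradicts counting statistics.
* The anchor $ncAC_t(0)$ is the noise-free model value
  $V_T (A + B)$ (decay factor 1). This requires reference $V_T > 0$, which
  the condition constructor enforces; the canonical grid starts at
  $V_T = 0.1$.
* The SD is *not* guaranteed to increase monotonically with time for every
  reference cell: at $K_i = 20\cdot10^{-3}$ h$^{-1}$ (and already at
  $5\cdot10^{-3}$ with $V_T = 0.1$) irreversible accumulation outpaces
  physical decay over part of the grid, the non-decay-corrected TAC rises
  and counting statistics genuinely improve. The implementation follows
  the formula, and the tests assert the exact equivalence "SD rises iff
  the non-decay-corrected TAC falls" rather than blanket monotonicity.
* Negative noisy concentrations are retained. Truncating at zero would
  bias the estimator, which is precisely the quantity under study.
* Plasma samples carry no noise: blood-sample counting errors (a fraction
  of a percent) are negligible next to TAC noise.
* One Gaussian deviate per value is the whole stochastic model; no
  second-level randomization of the SD itself is applied. A different
  noise model can be substituted by computing fractional SDs externally
  and calling `add_noise()` directly.

## The estimator

`patlak()` fits unweighted OLS through the (at least two, canonically
three) Patlak points, with no intercept or non-negativity constraint —
constraints would distort the bias/variability study that is the point of
the package. The $t=0$ plasma sample feeds only the trapezoidal AUC.
No equilibrium-onset cutoff is applied inside the estimator because
simulated tissue obeys the Patlak identity from $t=0$; for real data the
user must ensure all imaging points lie after plasma–tissue equilibrium
(roughly a day for IgG-sized antibodies), which is one reason the
candidate times start at 24 h.

Two exactness properties pin the implementation down and are enforced in
the tests: with zero noise and the *analytic* AUC in the x-coordinates the
estimator recovers the reference $(K_i, V_T)$ to $10^{-10}$ relative (the
forward model and estimator are mutual inverses), and with the
*trapezoidal* AUC the noise-free $\hat K_i$ falls strictly below the
reference for every bundled IF, schedule and reference cell.

## Bundled input functions

The three bundled parameter sets emulate the spread of plasma clearances
reported for ⁸⁹Zr-labelled therapeutic antibodies in patients — fast
("huJ591-like"), intermediate ("trastuzumab-like") and slow
("pertuzumab-like") — with plasma AUC at 192 h ordered huJ591 <
trastuzumab < pertuzumab. They are *synthetic*: published studies report
the curves graphically, not their fitted coefficients, so the package
ships parameter sets chosen once to reproduce (i) a plausible
$AC_p(0) \approx 35$ %IA/L (roughly 100% of injected activity in ~3 L of
plasma), (ii) fast-phase half-lives of 6–9 h and terminal half-lives of
2.5–6.5 days, and (iii) the qualitative bias behaviour that faster
clearance (more curved IF) produces larger trapezoid-induced Ki
underestimation, with the fast profile's worst-case systematic bias near
−16% for 24 h-containing schedules. Each fixture's provenance note in
`inst/extdata/input_functions.json` repeats this. Conclusions that depend
only on orderings, signs and ratios are insensitive to the exact
coefficients; absolute bias magnitudes are not, and should be read as
representative rather than reproductions of any specific published value.

`random_input_function()` draws additional IFs with half-lives and
amplitudes uniform in ranges bracketing these profiles
(fast 4–12 h, slow 40–170 h, $AC_p(0)$ 25–40 %IA/L, fast fraction
0.3–0.6), which the property tests use to show that the pipeline's
invariants are not artifacts of the three fixtures.

## Monte-Carlo design

A *condition* is one cell: IF × schedule × $(rK_i, rV_T)$ × noise level.
The canonical design crosses the three IFs, all $\binom{5}{3}=10$
three-point schedules from {24, 48, 96, 144, 192} h, $rK_i \in \{1, 5,
20\}\cdot10^{-3}$ h$^{-1}$, $rV_T \in \{0.1, 0.2, 0.5\}$ and noise
$\in \{5, 10, 15\}\%$ — 810 conditions, 1000 repetitions each by default.
Per condition the engine reports the mean and SD of $\hat K_i$ and
$\hat V_T$, percent bias $100(\overline{\hat\theta} - \theta_r)/\theta_r$
and percent variability $100\,\mathrm{sd}(\hat\theta)/\theta_r$.
Variability is the spread of a *single* simulated study expressed relative
to the reference value — the precision a clinical protocol would
experience — not the standard error of the Monte-Carlo mean. Normalising
by the reference (not the estimate mean) keeps bias and variability on a
common, noise-independent scale; all orderings and ratios the package's
conclusions rest on are invariant to this convention.

Because the OLS estimator is linear in the tissue values and the noise is
mean-zero, the expectation of $\hat K_i$ equals its noise-free (zero
deviate) value exactly; the engine therefore reports the deterministic
`ki_noise_free`/`vt_noise_free` alongside the Monte-Carlo moments, and the
repetitions are evaluated as one vectorised linear sweep that is
numerically identical to looping over single repetitions (asserted in the
tests). For the same reason the SD of both estimates is *exactly*
proportional to `noise0`, so tripling the noise level triples the
variability; the test suite demonstrates the factor 3 with common random
numbers across noise levels, which removes Monte-Carlo error from the
ratio without changing its expectation.

Reproducibility: each condition derives a private sub-seed from the master
seed by hashing its textual descriptor (IF label, imaging times, $rK_i$,
$rV_T$, noise level) with a small multiplicative hash mod $2^{31}-1$,
computed in doubles (exact below $2^{53}$). Identical master seeds give
bit-identical summary tables, and enlarging the grid never changes the
seeds — hence the results — of existing cells.

Degenerate repetitions (a regression with fewer than two distinct finite
points) are excluded from the moments and counted per condition; with the
canonical design none occur.

## Numerical choices and degenerate inputs

* Bi-exponential fitting (`fit_biexp()`) uses bounded Levenberg–Marquardt
  on untransformed concentrations, started by log-linear peeling (slow
  tail first, then the fast residual). Bounds keep amplitudes
  non-negative and rates below $-10^{-9}$ h$^{-1}$. Single-exponential
  data are handled gracefully: one amplitude goes to (near) zero and the
  returned object still satisfies every IF invariant. At least four
  distinct positive samples are required; non-convergence is an error
  carrying the starting values, never a silently invalid object.
* `biexp()` reorders its arguments so the "fast" phase is always the
  faster-decaying one, avoiding label-switching ambiguity downstream.
* `trapezoid_auc()` refuses upper limits that are not sample times: the
  sparse design never interpolates.
* The analytic AUC is validated against adaptive quadrature of the
  evaluated curve to $10^{-6}$ relative on every fixture and on random
  IFs.
* Simulation problem sizes in the tests were chosen to characterise the
  method well while keeping the default suite fast: the full 810-cell
  design is exercised at 200 repetitions (the estimator-mean identities
  above make 200 ample for sign and ordering checks, with
  simultaneous-inference bands for per-cell assertions), and single
  conditions at 1000–2000 repetitions where spread itself is under test.

## What the simulations do and do not show

The generator emulates sparse clinical sampling of an idealised tracer:
tissue exactly obeys the Patlak identity from $t=0$, receptor density is
constant, plasma is noiseless and the IF truly bi-exponential. Real data
violate all four to some degree — late equilibration of large antibodies,
target-mediated (nonlinear) clearance, plasma counting error, and IF
shapes beyond two exponentials. Passing tests therefore demonstrate the
properties of the *estimator under the stated model*, not the accuracy of
any particular clinical study. In particular the absolute bias magnitudes
depend on the synthetic IF coefficients; the robust findings are the sign
of the Ki bias (always negative), the benefit of including a 24 h time
point (smaller VT bias and variability, because the early sample pins
down the most curved part of the IF), the near-irrelevance of the exact
timing of the two later scans once 24 h is included, and the linear
scaling of variability with noise level. Image-domain effects (partial
volume, reconstruction, scan-duration optimisation) and SUV comparisons
are out of scope.
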