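---
title: "Models and methods behind mcpsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mcpsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpsim)
```

mcpsim simulates closed-loop medical cyber-physical systems at desk scale:
a patient model, device models (sensors and an insulin pump), a controller,
runtime safety monitors, and structural coverage measurement. This vignette
explains the models, the parameters that matter, the numerical choices, and
what the synthetic data does and does not establish.

## The vital-signs patient model

Each vital sign is generated by a generalized linear model over the other
signs, the blood glucose, a patient *group* factor, and two interactions.
The respiratory rate model is inverse-Gaussian with the canonical
inverse-square link, $\eta = \mu^{-2}$, so the predicted rate is
$\mu = |\eta|^{-1/2}$; heart rate, systolic pressure and temperature are
Gamma models with the canonical inverse link $\eta = \mu^{-1}$. The bundled
respiratory-rate model (`glm_rr()`) carries its published coefficients
verbatim, including the three group dummies and the `hr:sbp` and `hr:gl`
interaction terms; the companion models for the other signs are not
published, so the package fits them by IRLS on a synthetic cohort
(`default_vital_models()`) rather than inventing fixed coefficients.

Three post-link conventions matter. First, the fitted linear predictor of
the respiratory-rate model can cross zero on realistic inputs, so its
absolute value is taken before the link is inverted (`use_absolute`).
Second, predictions are rounded: integer rounding for `hr`, `rr`, `sbp`
(clinically integer-valued), one decimal for body temperature — an integer
body temperature would be clinically implausible, so the blanket
integer-rounding convention is deliberately relaxed for `pt`; both are
per-model flags. Third, every prediction is clamped into its sign's
threshold range (defaults are the observed ranges of the reference ICU
population, e.g. `rr` in [8, 38] breaths/min), which is what keeps the
model inside the region where the regressions were fitted.

A user intervention (`apply_intervention()`) holds one sign at a chosen
value and recomputes every other modeled sign **once** from the
post-intervention state. A fixed-point iteration was deliberately avoided:
the models are mutually dependent (rr depends on hr, hr on rr, ...), so
iterating could cycle or drift outside the fitted region; a single
synchronous pass matches the one-shot selector semantics of the original
patient model and is idempotent when the intervened value equals the
current prediction.

## Glucose–insulin kinetics and control

The diabetic patient couples the vitals model to the Bergman minimal
model, three compartments — glucose $G$ (mg/dL), remote insulin action $X$
(min$^{-1}$), plasma insulin $I$ ($\mu$U/mL):

$$\dot G = -p_1 (G - G_b) - X G + D + C, \quad
  \dot X = -p_2 X + p_3 (I - I_b), \quad
  \dot I = -n (I - I_b) + \tau r.$$

$D$ and $C$ are meal-absorption and glucagon disturbance rates, $r$ the
controller's insulin command. The endogenous-secretion term
$\gamma\,[G - h]^{+}\, t$ is available behind `include_gamma` but off by
default: the linearized model and the equilibrium algebra both omit it, and
its time-multiplied form only makes sense for the intravenous tolerance
test the minimal model was originally identified on. Parameter defaults
($p_1 = 0.028735$, $p_2 = 0.028344$, $p_3 = 5.035\times 10^{-5}$,
$n = 0.0926$ min$^{-1}$, $G_b = 81.3$ mg/dL, $I_b = 15\ \mu$U/mL,
$\tau = 1$) are canonical minimal-model literature values; they are this
package's documented defaults, all overridable through
`bergman_params()`.

`equilibrium_point()` solves the gamma-free rest point in closed form and
asserts the residual (the field at the claimed equilibrium must vanish to
$10^{-9}$); `linearize()` returns the exact Jacobian, upper triangular
with eigenvalues $(-p_1 - X_0, -p_2, -n)$ — always stable for positive
parameters. The only nonlinearity is the bilinear $XG$ term, so the
linearization error is exactly $\delta G\,\delta X$, which the tests
exploit: halving a perturbation divides the error by exactly four.

The PID controller $C(s) = K_p + K_i/s + K_d N s/(s+N)$ acts on the error
$e = G - G_{set}$ (rising glucose raises the insulin command) and is
discretized with a backward-Euler integral and a first-order filtered
derivative with pole $-N$; the command is clipped at $r \ge 0$ — insulin
cannot be withdrawn — with conditional integration as anti-windup (the
integral freezes while the output saturates). Default gains come from a
documented analytic procedure (`tune_pid()`): the linearized $r \to G$
channel, $G_0 p_3 \tau / ((s+p_1+X_0)(s+p_2)(s+n))$, is approximated as a
second-order-plus-delay process (two slowest poles kept, fastest pole's
time constant taken as the effective delay) and the SIMC rules applied
with closed-loop time constant $\tau_c = \theta/2$; the resulting series
PID is converted to parallel form and the derivative filter set at
$N = 10/\tau_D$. The choice $\tau_c = \theta/2$ buys a brisk but
well-damped response; `closed_loop_poles()` verifies that all closed-loop
poles lie in the open left half-plane before the gains are trusted.

## Simulation kernel

Continuous states advance by fixed-step classical RK4 with inputs held
over the step (zero-order hold), default `dt = 0.1` min; the minimal model
is non-stiff at these parameter scales, so RK4 at that step is far below
the accuracy that matters and the fixed step keeps every run bitwise
reproducible. Discrete components (sensors, the pump) fire on their period
grid *after* the continuous update at the same timestamp — sample-then-
react — and simultaneous events keep FIFO insertion order. One root seed
spawns per-component substreams (`component_seed()`) so adding a component
does not disturb the draws of the others. Traces are tibbles
(`time, component, signal, value`) exported with six-decimal times so
re-export is byte-identical.

## The insulin pump

The pump follows its technical specification: a 3.15 mL U100 cartridge
(315 U), basal rates bounded to [0.1, 25] U/h, standard boluses at most
25 U. The standard basal profile delivers one fixed dose per 3-minute slot
(480/day), the customized profile one flexible dose per hour (24/day); a
slot's dose is delivered at the end of the slot. Doses are atomic per
tick. Policy choices the specification leaves open: the LOW threshold
defaults to 10% of capacity, boundary inclusive (some threshold must exist
for the LOW warning to be reachable); the pump *stops* on LOW by default
(`warn_only_on_low` relaxes this to a warning, since the requirement text
lists LOW only as a warning while the verified state machine stops); a
dose that exceeds the remaining level is refused entirely — never
partially delivered — and stops the pump, because a partial dose would
break the administered-equals-programmed property. "Stop after a delay"
is implemented as exactly one scheduler tick, the smallest nonzero delay.
The cartridge level is derived from the running delivered total
(`level = initial - cumulative`), which makes insulin conservation exact
by construction rather than a property of accumulated floating-point
subtractions.

## Safety monitoring and coverage

Four trace properties are monitored: SR1 (level 0 implies EMPTY the same
tick and STOP within the configured delay, default 1 tick; the verdict
also reports the worst observed delay), SR2 (insufficient level implies
nothing delivered and STOP), SR3 (every executed basal delivery
administers exactly the programmed dose), and A1 (never EMPTY and LOW
simultaneously — unrepresentable in the pump's own single-valued status,
but still checked on the trace, which may come from elsewhere). An empty
trace satisfies everything vacuously; a failing verdict carries the
earliest witness rows.

Coverage is measured over instrumented decision sites
(`function/[decision]`): decision coverage counts the observed outcomes of
each decision against both possibilities; condition coverage does the same
per sub-condition; MC/DC holds for a condition when some observed pair of
evaluations differs only in that condition and flips the decision — the
masking-style pairwise check standard in avionics-grade coverage, chosen
because the criterion's flavor is otherwise unspecified. Sites with a
single condition report CC and MC/DC as NA (the condition *is* the
decision). Function-level rows aggregate sites with uniform weights and
report cyclomatic complexity as decision count + 1. A nominal healthy run
leaves `[level == 0]` forever false — 50% DC — which is exactly the kind
of uncovered outcome the report is meant to surface.

## The synthetic cohort and GLM fitting

No clinical database ships with the package. `generate_cohort()` draws
patients from a multivariate normal truncated (by rejection) to each
variable's observed range, calibrated to the reference ICU population
summary: means/SDs/ranges for `hr, sbp, rr, pt, gl, weight, height` and a
37.4% female fraction. Because a row is rejected when *any* variable
leaves its range, truncation biases not only bounded variables (the `rr`
lower bound sits two SDs from its mean) but also their correlated
partners; the generator therefore calibrates the underlying normal
moments — an analytic univariate truncated-normal correction followed by a
short deterministic Monte-Carlo fixed-point iteration — so the truncated
sample reproduces the targets. The correlation structure (mild positive
`hr`–`rr`, `hr`–`gl`, `hr`–`sbp`) is this package's choice, made so the
interaction terms of the regression designs are estimable; the reference
summary publishes no correlations. The group factor is likewise
undefined in the source material; the default rule scores each patient by
how many signs fall outside conventional guideline bands and maps the
score to four groups, matching the three group dummies of the published
design. Both are configurable.

What passing tests on this cohort show — and do not show: the generator
reproduces first and second moments and ranges, so fitting and simulation
pipelines are exercised on realistically scaled, realistically bounded
data; it does not reproduce the skewness, missingness, repeated measures
or case mix of real ICU admissions, so fitted coefficients are *not*
estimates of any real population's physiology.

`fit_glm_irls()` implements canonical-link IRLS for both families
(weights $\mu^3/4$ for inverse-Gaussian, $\mu^2$ for Gamma after
simplification), with step-halving back into the link domain
($\eta > 0$), convergence at $10^{-8}$ relative coefficient change, at
most 100 iterations, and Pearson-estimated dispersion. The test suite
cross-checks it against the reference GLM fitter and against direct
likelihood maximization with analytic gradients on tiny instances.
Diagnostics follow the standard GLM toolkit: Pearson/deviance residuals,
hat values (whose sum must equal the coefficient count), Cook's distances,
and a simulated envelope built from replicate refits of data resampled
from the fitted model.

## Scenarios and problem sizes

Three bundled scenarios exercise the composition: ICU monitoring (one
patient, five sensors, a pass-through centralizer and bedside monitor;
60 min at 1-min steps), an insulin-pump day (24 h at 1-min ticks, doses
programmed by the weight-based calculator, safety monitors and coverage
on), and the diabetic closed loop (600 min at 0.5-min steps, two meal
pulses, vitals co-adjusting through their regression models as the
controller moves glucose). These sizes keep every bundled scenario under a
minute on one CPU while leaving the dynamics fully visible; horizons,
steps and all device parameters are plain YAML fields. The cohort used to
fit scenario vitals models defaults to 200 patients — comfortably above
the 30-record floor the fitting pipeline enforces.

## Known limitations

The patient model is a statistical generator, not a physiological
simulator: interventions propagate through regression structure, not
mechanism. The minimal model omits meal dynamics beyond a rate pulse and
the endogenous secretion term is off by default. The pump model ignores
occlusion, battery and communication faults. Coverage is measured over
*observed* evaluations only — runtime verification, not model checking —
so an uncovered outcome means the scenario never exercised it, not that it
is unreachable.
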