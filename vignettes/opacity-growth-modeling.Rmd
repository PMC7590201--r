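---
title: "Modeling chick embryo growth from NIR egg opacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chick embryo growth from NIR egg opacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovogrowth)
```

## The measurement and its statistic

A chicken embryo grows several-hundred-fold in mass over the 21-day
incubation, most of it in the second half (the "growth phase"). Visible
light stops penetrating the egg after about day 10, so growth in that
window has to be observed with near-infrared light. An auto-ranging NIR
candling sensor shines LEDs (peak ~870 nm) through the egg onto a Si
photodiode; as the embryo, allantois and yolk sac grow, less light gets
through, and a larger LED drive current is needed to keep the photodiode's
amplified output voltage inside its linear window.

The package's central statistic is the **opacity** of an egg on incubation
day $t$:

$$\mathrm{opacity} = \frac{I_{\mathrm{LED}}\ \text{(mA)}}{V_{\mathrm{avg}}\ \text{(V)}},$$

where $V_{\mathrm{avg}}$ is the arithmetic mean of samples 11–300 of a
300-sample record (9 s at 33.3 Hz):

$$V_{\mathrm{avg}} = \frac{1}{290}\sum_{n=11}^{300} V_{\mathrm{out}}[n].$$

The first 10 samples are the auto-ranging settling ramp — the electronics
use them to pick one of 16 LED current steps (0.73–96.15 mA) so the output
lands in the 3–9.7 V detector window — and they never enter the average.
This 290-sample window is normative in `compute_vavg()`: traces with any
other length are rejected, and tests verify that permuting the averaging
window or rewriting the ramp leaves $V_{\mathrm{avg}}$ unchanged. Opacity
is invariant to which current step the auto-ranging selected, because
$I_{\mathrm{LED}}$ cancels for a clean signal.

A consequence of the hardware window worth knowing: with currents capped
at 96.15 mA and voltages required to reach 3 V, opacity is only measurable
in roughly the 0.075–32 mA/V band. The simulator flags traces outside it
as `out_of_range` rather than dropping them, so opacity tables stay
rectangular; fitting excludes flagged rows. With the default exponential
ground truth, day 16 of an average egg sits just above this band — the
flags are doing their job, not signalling a bug.

## Growth-model families

Opacity series over days 6–16 are fitted with four classical growth
families, parameterized as:

| family | form | free parameters |
|---|---|---|
| exponential | $y = a e^{bt}$ | $a, b$ |
| logistic | $y = A/(1 + a e^{-bt})$ | $A, a, b$ |
| power | $y = a^t$ | $a$ |
| Gompertz | $y = A e^{-a e^{-bt}}$ | $a, b$ ($A$ fixed) |

All are growth curves: $b > 0$, and $a > 1$ for the power family. Two
parameterizations deserve comment, because published equation strings for
this kind of sensor work often lose superscripts in typesetting:

* **Power** is implemented as $y = a^t$ (base raised to the day), not
  $y = a\,t$. A linear-in-$t$ reading is inconsistent with the magnitude
  such fits reach by day 16 (e.g. $1.26^{16} \approx 40$ mA/V, matching
  the exponential family's level, whereas $1.26 \times 16 \approx 20$
  would not be a competitive fit).
* **Logistic** is the standard three-parameter sigmoid
  $A/(1+a e^{-bt})$. A unit-amplitude sigmoid with a *growing* exponent,
  as sometimes printed, is a decaying curve and not a growth model; the
  three-parameter form is the conventional one for vertebrate growth. The
  packaged logistic reference curves carry $A = 70$ mA/V, the same
  opacity ceiling as the Gompertz rows, since the amplitude is otherwise
  unidentified.

Both interpretations are isolated in the model registry
(`growth_model()`, `eval_growth()`), so a user who disagrees can add a
variant without touching the fitting code.

The Gompertz asymptote is **fixed at $A = 70$ mA/V** by default
(`fix_asymptote = TRUE` in `fit_growth()`), the empirical opacity ceiling
of incubated eggs of this class; releasing it is an option. A fitted
fixed-$A$ Gompertz curve therefore never exceeds 70 mA/V at any time, a
property the test suite checks on noisy data.

## Fitting: algorithm, starting values, degenerate data

`fit_growth()` minimizes the residual sum of squares with the
Levenberg–Marquardt algorithm (damped least squares, via
`minpack.lm::nls.lm`), with relative tolerances of $10^{-10}$ on both the
cost and the parameter vector and a budget of 1000 iterations (the
function-evaluation cap is tied to the iteration budget so the tolerances,
not the evaluation count, normally terminate the fit).

Default starting values, used when `init` is not supplied:

* exponential and power: $a = 1$, $b = 0.1$ — a flat unit curve;
* logistic: $A = 1.2 \max(y)$, $a = 10$, $b = 0.3$;
* Gompertz: $a = 13$, $b = 0.2$, $A$ fixed at 70.

From these inits, noise-free data generated by any of the eight packaged
reference curves is recovered to well under $10^{-4}$ relative error —
the round-trip parameter-recovery suite pins this down, and an
independent oracle (ordinary least squares of $\log y$ on $t$) confirms
the exponential fits.

Degenerate situations are handled explicitly rather than left to the
optimizer:

* fewer than 3 points, or fewer than 3 distinct days, is an error (as is
  having fewer points than free parameters);
* non-convergence is *reported*, not thrown: `FitResult$converged` is
  `FALSE` and downstream steps (`calibration_report()`) skip the family
  with a warning. This matters scientifically: a logistic fitted to
  exponential-shaped data has its optimum at $A \to \infty$ (the
  exponential is the logistic's large-$A$ limit), so an honest flag is
  the right outcome, not a failure;
* a constant series drives the exponential rate to its $b \to 0$ limit
  and is covered by a test; its $R^2$ is undefined (reported `NA`)
  because $SS_{\mathrm{tot}} = 0$.

Goodness of fit is RMSE $= \sqrt{\sum r_i^2 / n}$ and
$R^2 = 1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$ about the series mean.
For non-linear fits this $R^2$ can be negative; that is the usual
convention and is deliberate.

`fit_all_growth()` fits the four families to the *pooled* point cloud of
a group (all eggs × days) and returns a comparison table sorted by RMSE.
Pooled fitting matches the one-curve-per-group presentation conventional
in this setting; per-day group means are available via
`mean_opacity_series()` for users who prefer fitting means.

## Cohort grouping

Eggs (or chicks) are split into two groups at the **midpoint threshold**

$$W_{\mathrm{thr}} = W_{\min} + \frac{W_{\max} - W_{\min}}{2},$$

values below going to the lower group (L / Small) and above to the upper
(XL / Large). The defining inequalities are strict in both directions and
leave equality unassigned; `assign_groups()` sends a value exactly at the
threshold to the **upper** group by default (`ties = "upper"`,
configurable). A fixed threshold (e.g. 67.1 g for eggs of this grading
window, 50.0 g for chicks) can be imposed instead of recomputing, to
reproduce an established grouping on a new cohort. The threshold is
translation- and scale-equivariant, which the property tests exercise.

## Calibration of opacity to embryo weight

After fitting, the *calculated* opacity $y = f(t)$ — the smooth fitted
curve, not the raw points — is evaluated on the days of a reference
embryo-weight table and regressed on weight by ordinary least squares:

$$y_{\mathrm{calc}} = a_c + b_c x
  \quad\Longrightarrow\quad
  x = \frac{y_{\mathrm{calc}} - a_c}{b_c}.$$

Regressing opacity **on** weight (not the reverse) is what makes the
inverse map reproduce the printed form of published
opacity-to-embryo-weight equations coefficient-for-coefficient; the other
regression direction would change $(a_c, b_c)$. `predict_weight()` applies
the inversion, which is exact to $10^{-9}$ on the fitting grid for a
linear relation. The reported $r^2_{\mathrm{weight}}$ is the squared
Pearson correlation, invariant under affine rescaling of either axis.

The package ships `published_calibrations()`, one $(a_c, b_c)$ pair per
family from the NIR opacity literature on graded broiler eggs, for use
with `predict_weight()` on matching sensor data. They are constants for
prediction and testing, never asserted against refit values: refitting
them would require the original (unpublished) opacity dataset and the
measured embryo-weight reference.

The packaged reference weight table is **synthetic**: a Gompertz-shaped
trajectory $W(t) = 30\,e^{-13 e^{-0.18 t}}$ g, rising from ≈0.36 g at day
6 to ≈14.5 g at day 16 — a realistic course for broiler embryos, chosen
once and documented here. Users calibrating against real embryology data
should supply their own `day, embryo_weight_g` CSV via
`read_reference_csv()`.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` draws egg attributes from the grading window of a
commercial broiler cohort: weight $68 \pm 5$ g, major axis
$59.5 \pm 3$ mm, minor axis $46 \pm 1$ mm, shell color
$r = 0.375 \pm 0.015$ (independent normals, with resampling to keep mass
positive and major > minor). Each egg's opacity trajectory is
`size_scale` × a ground-truth growth curve, with
`size_scale = weight / weight_mean`: larger eggs contain more internal
matter and have higher opacity, and a monotone linear map in relative
mass is the simplest defensible encoding of that fact. Chick weight is
`conversion_ratio × egg_weight` with the ratio drawn from a normal
(0.72, 0.03) truncated to (0.5, 0.9) — the conversion ratio is a defined
quantity, its between-egg distribution is not, so this is a documented
modeling choice.

The sensor model reproduces the acquisition protocol: 16 geometrically
spaced LED steps (a constant-ratio resistance ladder is the natural
reading of "16 variable series resistances" over a fixed current range),
smallest in-window step selected, 300 samples at 33.3 Hz with the 10-sample
ramp, additive Gaussian voltage noise (default sd 0.02 V), and a per-egg-day
multiplicative opacity jitter (default CV 5%). The noise magnitudes are
**placeholders, not measured values** — no noise model is published for
this sensor class — so both are configurable in `cohort_config()` and
default to values that leave the day-to-day growth signal clearly visible.
9 s × 33.3 Hz is 299.7 samples; records are stored as exactly 300 so the
$n = 11\ldots300$, divisor-290 averaging window holds literally.

What the generator deliberately does *not* model: physical optics
(scattering, pigment spectra — shell color is a passive scalar
attribute), embryo mortality or infertility, hatch failure, and any
day-to-day autocorrelation in the jitter. Passing tests on this
synthetic cohort therefore demonstrate that the *pipeline* — sensor
arithmetic, grouping, fitting, calibration — is correct and
self-consistent, not that real eggs obey any particular family: on real
data the deviation of opacity points from all four fitted curves around
days 7–12 (the allantois's contribution) is expected and carries
information the simulator does not generate.

## Determinism and problem sizes

Every stochastic step keys off the integer seed in `cohort_config()`; a
fixed seed makes cohorts, traces and tables byte-identical, which the
suite asserts. The shipped tests run at deliberately small sizes — 11-day
series, cohorts of 2–12 eggs for pipeline checks, one 10,000-egg cohort
for moment convergence (within three standard errors), and 200
Monte-Carlo replicates for the noise-recovery checks — enough to pin
each property down without turning the suite into a simulation study.

## Known limitations

* Opacity saturates against the sensor window near 32 mA/V under the
  default auto-ranging rule; trajectories that exceed it are flagged,
  and growth past that point is invisible to the simulated sensor.
* The technique itself is only meaningful to day 16: very late
  incubation reverses the opacity trend (drier internal structure,
  thinner shell), and no family in the registry models that.
* The calibration is a two-parameter line; it inherits whatever bias the
  chosen growth family has over the calibration days.
* `size_scale` linear in relative mass is an assumption; the exponent is
  a single place to change if evidence favors a different monotone map.
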