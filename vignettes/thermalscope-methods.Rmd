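---
title: "Methods: from oxygen traces to thermal performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oxygen traces to thermal performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalscope)
```

## The measurement model

Intermittent-flow respirometry alternates flush phases, in which the chamber
is open and oxygen returns toward saturation, with sealed measurement phases
in which the fish depletes oxygen. During a sealed phase of a chamber of
volume $v_R$ (L) holding a fish of mass $m$ (kg) and volume $v_F$ (L,
taking 1 kg to displace 1 L), mass-specific oxygen uptake is

$$\dot M_{O_2} = \frac{|\Delta O_2| \,(v_R - v_F)}{m}
\quad [\mathrm{mg\,O_2\,kg^{-1}\,min^{-1}}],$$

where $\Delta O_2$ is the slope of an ordinary least-squares regression of
oxygen concentration on time over the measurement window. Slopes are fit on
seconds (loggers sample in seconds) and reported per minute (the reporting
convention of the field). All rates in this package are standardized on
mg O2 kg⁻¹ min⁻¹ throughout; mixing minute and hour bases is a common source
of inconsistency in published tables.

Visual screening of regressions is replaced by three explicit flags so that
validation is reproducible:

* **negative** — the slope is below −10⁻¹⁰ mg L⁻¹ min⁻¹ (anything smaller in
  magnitude is numerical noise, not respiration);
* **linear** — r² at or above a threshold (0.85 by default for routine
  cycles);
* **artifact-free** — no single-sample residual jump larger than 6 robust
  residual SDs, with an absolute floor of 0.1 mg L⁻¹ so that perfectly
  linear windows are never flagged by their own rounding error.

Only windows passing all three are "validated" and contribute to resting
rates. Windows with fewer than 5 samples are marked invalid rather than
raising an error, because truncated final cycles are routine in overnight
recordings; trailing windows shorter than 60 % of the nominal measurement
length are discarded outright for slope stability.

## Metabolic-rate estimators

**Chase MMR.** After an exhaustive chase the highest uptake occurs within
the first sealed window, so MMR is the steepest qualifying slope found by a
sliding-window search in that window: every start offset at the sample
resolution, every window length of at least 90 s, keep slopes with
r² > 0.9, convert the steepest. The search space must be stated explicitly
for "steepest" to be well defined; we maximize over window *lengths* as well
as starts, and pin the choice with a brute-force enumeration oracle in the
test suite. The search is exact (closed-form OLS via cumulative sums), not a
heuristic.

**Overall MMR.** Exhaustive chases do not always elicit the maximum — some
fish peak spontaneously overnight — so the overall MMR is the maximum of the
chase estimates and every validated overnight value, computed only when more
than 60 overnight measurements exist.

**RMR.** The resting rate is the 0.10 quantile of all validated
measurements, requiring at least 60 of them. The quantile convention is
linear interpolation between order statistics (R type 7); the literature
rarely states one, so ours is documented and configurable, and the
alternative reading (mean of the lowest decile) is available behind a flag.
Note the two eligibility comparisons differ deliberately: *more than* 60 for
the overall maximum, *at least* 60 for the resting quantile.

**Scope and the mortality rule.** `AAS = MMR_overall − RMR` and
`FAS = MMR_overall / RMR` for survivors; fish that died during the protocol
are assigned zero for both, whatever their recorded rates, because a dead
fish has no aerobic scope and omitting mortalities overstates a
population's capacity. Group summaries average per-individual values, so a
group FAS is a mean of ratios, not a ratio of means.

**Allometry and Q10.** Mass-specific rates are adjusted to a 3.5 kg
reference fish by $(m/3.5)^{1-b}$ with $b = 0.67$ for RMR and $0.58$ for
MMR-family rates; the exponent estimator is a log10–log10 least-squares
slope with optional group intercepts. Mixed-model estimation of $b$ is out
of scope: single-level synthetic cohorts make random effects
unidentifiable. Temperature coefficients use
$Q_{10} = (R_X/R_{12})^{10/(T_X-T_{12})}$ on group means.

## Recovery metrics

Two time courses are pooled into 10-min blocks by measurement-window
midpoint (midpoints are unbiased under unequal cycle lengths):
$\%AAS(t) = 100\,(MMR_{overall} - \dot M_{O_2}(t))/AAS$ and
$\%MMR(t) = 100\,\dot M_{O_2}(t)/MMR_{chase}$. The %AAS reference is the
*overall* maximum while %MMR uses the *stage's chase* maximum; consequently
%AAS at time 0 need not start at zero when the chase failed to elicit the
overall peak — this asymmetry is intentional and is asserted in the tests.
The half-recovery time is the first measurement falling between 48 and 52 %
of the chase MMR; series that jump across the band are excluded rather than
interpolated, because interpolation would manufacture a measurement that
was never made.

EPOC is the area between a cubic smoothing spline through the MO2
measurements and the resting rate, integrated from the chase until the
spline first returns to RMR, reported cumulatively and in the first five
hourly blocks. Numerical choices: the smoothing parameter is chosen by
generalized cross-validation (the smoother is standard; its tuning is not,
so GCV with a configurable override), "returned to RMR" means the spline
drops below RMR × 1.02 (exact equality never happens on noisy data; 2 % is
well inside probe noise), and integration is trapezoidal on a 0.1-min grid.
Eligibility requires more than 60 measurements and completion of recovery
within the horizon (default 18 h). For mono-exponential recovery with
amplitude $A$ and rate $k$ the debt has the closed form $A/k$, which the
test suite uses as its oracle: at 10-min sampling the spline integral stays
within 2 % of $A/k$.

## Thermal performance and survival

AAS (and FAS) over temperature is fit with a second-order polynomial over
*all* fish, mortalities entered as zeros. For a concave fit
$c_0 + c_1 T + c_2 T^2$ the summaries are closed-form:
$T_{opt} = -c_1/2c_2$, $AAS_{max} = AAS(T_{opt})$, and the upper pejus
temperature — the highest temperature at which scope stays above a fraction
$\theta$ (default 0.80) of maximum —
$T_{pejus} = T_{opt} + \sqrt{(1-\theta)\,AAS_{max}/(-c_2)}$. Peak summaries
are reported only when $c_2 < 0$ and the vertex lies within the observed
temperature range ± 3 °C; otherwise they are missing with a reason, which
prevents extrapolated nonsense on degenerate fits. Uncertainty for
$T_{opt}$ and $T_{pejus}$ comes from a bootstrap over fish — resampling
individuals is the natural uncertainty for a curve summary, and published
± SD values for such summaries rarely name their procedure, so ours is
declared rather than claimed to match any particular one. Survivor-only
fits are available behind a flag but the headline analysis keeps the zeros.
Functional warming tolerance is simply the maximum environmental
temperature minus the upper pejus temperature.

Survival over temperature uses the two-parameter log-logistic dose-response
form on log temperature, $P(\mathrm{survive}\mid T) = 1/(1 + \exp(b(\ln T -
\ln M_{50})))$, fit by binomial maximum likelihood (Nelder–Mead then BFGS on
$(\ln M_{50}, \ln b)$). The log-temperature parameterization is the standard
dose-response convention and is scale-stable; a linear-temperature logistic
would not be. Confidence intervals for $M_{50}$ are profile-likelihood
(group counts are small and the likelihood asymmetric, where Wald intervals
mislead); Wald is available as an option. Cohorts in which every fish
survived or every fish died are reported as boundary cases with no finite
$M_{50}$ rather than as estimates. The population effect is a likelihood
ratio test of separate curves against a pooled one; a second two-parameter
curve adds two parameters, so the test reports 2 df per extra population —
published df for this comparison sometimes differ, and we report our own
parameter count rather than reproduce an unstated one.

## What the synthetic cohort emulates

The generator mirrors the study design end to end: two populations × four
test temperatures (12, 18, 21, 24 °C), 54.5 or 98 L chambers, 15-min cycles
of 9 min flush + 6 min sealed measurement with the first post-chase window
sealed immediately, probe noise as i.i.d. Gaussian on readings (optional
linear drift emulates the weekly two-point calibration regime), negligible
background respiration by default, and log-logistic mortality (defaults
M50 = 21 and 23.6 °C, slope 25, matching the two populations' survival
curves). Recovery kinetics are mono-exponential,
$\dot M_{O_2}(t) = RMR(T) + (MMR - RMR(T))e^{-kt}$ with
$RMR(T) = RMR_{12} \cdot Q_{10}^{(T-12)/10}$ — the simplest kinetics with a
closed-form oxygen debt, which is exactly what an oracle test needs.
Spontaneous overnight activity is modelled as rectangular burst excursions
with a per-cycle probability (default 0.08), letting tests force
`MMR_overall > MMR_chase` deterministically. Phenotype defaults (body mass
lognormal around 3.4 kg truncated to 1.4–7.2 kg; resting rate near
2.4 mg O2 kg⁻¹ min⁻¹ at 12 °C and maximum near 11.3 at 3.5 kg, each with
mild allometry and lognormal individual scatter; Q10 near 1.7; k near
0.045 min⁻¹; hematocrit ~N(57, 7) with a 4 % chance of a low-hematocrit
fish) are chosen once to be realistic for pre-spawning adult Chinook-sized
salmonids; within-individual MO2 variance is not reported in the
literature we target, so the noise default (0.02 mg L⁻¹) is a choice, not
an estimate.

One deliberate simplification: within each sealed window the generative MO2
is held constant at the recovery trajectory's value at the window midpoint.
Real uptake drifts within a window; holding it constant makes the noise-free
trace exactly linear, so the slope → MO2 round trip is exact to machine
precision and the ground-truth ledger can record a per-cycle truth that the
pipeline must recover to ≤ 10⁻⁶ relative. The ledger's "true MMR_1h" is
therefore the cycle-0 value of the trajectory, not the instantaneous $t=0$
maximum — no intermittent-flow protocol can observe the latter, and tests
that compared against it would be testing the protocol, not the code.

What the generator does **not** emulate: chamber mixing dynamics (flush is a
clean exponential relaxation), solubility/temperature corrections (O2 is
already in mg L⁻¹), multi-fish chambers, diurnal rhythms in RMR, or any
within-individual autocorrelation in probe noise. Passing tests on
synthetic cohorts therefore demonstrate that the estimators invert the
stated generative model correctly at realistic noise — not that real traces
satisfy that model.

## Problem sizes and determinism

Every stochastic component takes a seed, and cohort simulation derives
per-fish seeds deterministically from it, so a run is fully reproducible
from (inputs, configuration, seed). The test suite exercises: noise-free
round trips on cohorts with 66-cycle overnight records; sliding-window
versus brute-force equivalence on 100+ random fixtures; spline-EPOC versus
closed form at 10-min sampling; grid-search oracles for the survival MLE
(0.01 °C refinement) and the quadratic peak (10⁻⁶ °C refinement); M50
recovery at 500 fish per temperature across 100 seeds; and a Monte-Carlo
bias check for the thermal-performance peak over twenty 40-fish cohorts
against a 4000-fish reference. These sizes were chosen to make Monte-Carlo
error comfortably smaller than each stated tolerance while keeping a full
run in well under a minute.

## Known limitations

* Group inference (mixed-effects ANOVA, post-hoc contrasts, model selection)
  is out of scope by design; the package produces group summaries and the
  survival LRT only.
* The hematocrit threshold, recovery band, pejus threshold and both
  eligibility counts are conventions, not estimates; all are configurable
  and their defaults documented above.
* The artifact flag is one defensible operationalization of "no artificial
  irregularities"; a different jump rule will validate a slightly different
  set of cycles.
* Profile-likelihood intervals can be one-sided when a cohort is close to
  separation (e.g. mortality jumping from 0 to 100 % between adjacent
  temperatures); the fit then carries a finite point estimate with a wide or
  missing bound rather than failing.
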