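---
title: "Methods: simulating and analysing forward single-step initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing forward single-step initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepinit)
```

## The measurement problem

When a standing person initiates a forward step, the first observable
event is not the foot leaving the ground but a backward excursion of the
centre of pressure (CP): the anticipatory postural adjustment (APA) that
accelerates the centre of mass (CM) forward. On a force platform this
whole sequence is visible in three channels — the anteroposterior (AP)
shear force `Fy`, the vertical force `Fz`, and the moment about the
mediolateral axis `Mx` — sampled here at 1000 Hz.

`stepinit` implements the full analysis chain for a go/no-go
step-initiation experiment in which the go signal is a face
(fearful, angry or happy expression) and responses are withheld for
neutral faces (neutral-vs-emotional condition) or for one face gender
(face-gender condition). Six outcome variables are extracted per go
trial:

| variable | definition | unit |
|---|---|---|
| reaction time (RT) | face onset to APA onset `t0y` | ms |
| initial posture | mean AP CP over the 500 ms before face onset | cm |
| APA duration | `t0y` to the first backward CP peak | ms |
| APA amplitude | CP shift from `yP(t0y)` to that peak (negative = backward) | cm |
| V | peak forward CM velocity | m/s |
| tV | time of V from face onset | ms |

## Signal reduction

All raw channels are low-pass filtered at 10 Hz with a fourth-order
Butterworth filter applied forward and backward (zero net phase; the
magnitude response is the square of the single-pass response, so a
10 Hz sine passes with amplitude gain 0.5). The implementation extends
the signal by odd reflection (three filter-polynomial lengths at each
end) and starts each pass from steady-state initial conditions, keeping
edge transients out of the returned samples.

The AP centre of pressure is `yP = (Mx − Fy·z_offset)/Fz` with forward
positive and the plate origin at its geometric centre (`z_offset = 0`
for a surface-origin plate). CP velocity comes from central
differences. CM acceleration follows Newton's law,
`y''G = (Fy − baseline)/mass`, where the baseline is the mean of `Fy`
over the same 500 ms pre-onset window used for initial posture — this
enforces zero acceleration at rest and removes static channel bias. CM
velocity is the cumulative trapezoidal integral of `y''G` started at
the detected movement onset with `y'G(t0y) = 0`.

Filtering is applied to the raw channels *before* the CP division; the
alternative (filter the CP trajectory itself) is available through
`filter_stage = "cp"`. With a near-constant vertical force the two
orders are equivalent to first order; we default to filtering raw
channels because that is the natural reading of filtering "all
signals" from the platform.

## Event detection

`t0y` is the time at which CP velocity reaches 10 % of its first
backward peak. Peak qualification matters: the detector takes the first
negative local extremum of `y'P` after face onset whose magnitude
exceeds a noise floor. The floor is the maximum of (i) five times the
pre-onset standard deviation of `y'P`, (ii) an absolute 0.005 m/s (so
noise-free signals are not triggered by numerical ripple), and (iii)
20 % of the largest backward excursion in the search window. The third
term exists because zero-phase filtering of a brisk excursion produces
small symmetric ringing *before* the excursion; without a relative
floor such a dip (a few percent of the true peak) can masquerade as the
first peak. From the qualified peak the detector walks backward to the
last sample inside the 10 % band and locates the crossing by linear
interpolation, giving sub-sample onsets; searching backward from the
peak (rather than forward from the stimulus) keeps late baseline
wiggles from triggering spurious onsets.

The APA ends at the first local minimum of `yP` after `t0y` (earliest
sample on ties). The amplitude is referenced to `yP(t0y)` rather than
to the initial posture — the two differ only by the sub-threshold drift
before the 10 % crossing — and the choice is switchable in the event
code. `tV` is referenced to face onset, not to `t0y`: reported group
values of tV sit roughly 310–350 ms above RT, which is only coherent on
that reading. Both conventions are deliberate resolutions of genuinely
ambiguous definitions.

Degenerate inputs signal classed errors (`stepinit_no_onset`,
`stepinit_no_backward_peak`, `stepinit_no_forward_velocity`) that the
pipeline converts into QC rejections rather than run failures.

## Quality control

Four rejection rules run in a fixed order, the first failure being
reported: (a) movement omission — no qualifying CP-velocity onset within
the 2.5 s search horizon; (b) wrong stepping limb, taken from trial
metadata (an AP-only recording cannot detect the limb physically);
(c) reaction time outside 200–2000 ms, bounds inclusive; (d) peak-to-peak
pre-onset CP excursion above 1 cm. The 1 cm default quantifies the
otherwise unquantified "considerable" pre-onset motion: it sits an order
of magnitude below typical APA amplitudes while tolerating ordinary
postural sway (a few mm at 10 Hz bandwidth). Both thresholds are
configurable.

## The synthetic-trial generator

Human recordings are replaced by a generator that works *backwards from
the pipeline's own event definitions*, so that pipeline correctness can
be checked by parameter recovery. Each go trial draws latent outcomes
from a crossed mixed-effects model,

$$y = \mu_{\text{emotion} \times \text{condition}} + u_{\text{participant}}
      + w_{\text{face}} + \varepsilon,$$

with independent Gaussian random intercepts, and then constructs a
record whose extracted outcomes equal the latents at zero noise:

* **CP excursion.** The CP velocity descends through a $\sin^4$ attack
  lobe and returns through a quarter-cosine release that crosses zero
  with nonzero slope. The attack keeps CP *acceleration* continuous at
  the lobe start, so the 10 Hz filter does not smear the region where
  the 10 % crossing sits; the release gives the backward CP peak a
  sharp quadratic minimum. A flat-tailed trough is numerically
  ill-posed: under the ±0.1 mm ripple that zero-phase filtering leaves
  on brisk excursions, its argmin wanders by tens of milliseconds. The
  lobe scale, start time and peak velocity are closed-form functions of
  the latent RT, APA duration and amplitude (the 10 % crossing of a
  $\sin^4$ lobe sits at $\arcsin(0.1^{1/4})/\pi \approx 0.19$ of the
  lobe).
* **Filter pre-compensation.** The moment channel encodes
  $2\,y_P - F(y_P)$, where $F$ is the pipeline's zero-lag filter. The
  filtered CP then equals the intended trajectory to second order in
  the filter distortion. Without this, a 7 cm / 150 ms excursion
  shifts the detected onset by about 1 ms; with it, well under 0.5 ms.
* **CM kinematics.** The acceleration template is a single full-sine
  lobe starting at `t0y`, so the velocity integral rises from zero to
  exactly `V` at `tV` and the maximum has honest quadratic curvature
  (a raised-cosine pulse would give a quartically flat maximum whose
  argmax is unstable at 1 kHz). The AP shear force is mass times this
  template; the vertical force is `mass × g`.
* **Noise.** Additive Gaussian channel noise (defaults 0.5 N on forces,
  0.3 N·m on the moment); the moment channel additionally inherits
  CP-scaled vertical-force noise through the encoding, which is what a
  real plate does.
* **Artifacts.** One constructor per QC rule: flat records (omission),
  mismatching limb metadata, latent RTs of 150 and 2100 ms, and a
  smooth 2 cm pre-onset drift.

### Generative defaults

The emotion-by-condition cell means reproduce the published estimated
marginal means of the study design this package models: per-condition
means for all six outcomes, the angry/fearful APA-duration cells (238
and 260 ms) in the neutral-vs-emotional condition, and tV cells chosen
so both the condition means (948 / 994 ms) and the fearful/happy
emotion-level means (961 / 982 ms) are matched, with the emotion
structure confined to the neutral-vs-emotional condition as reported.
APA-amplitude cells by emotion are not published; the defaults
(−4.27 / −3.51 / −4.13 cm) preserve the −3.97 cm condition mean and the
reported fearful-and-happy-larger-than-angry pattern. Trial-level
standard deviations are *not* published (the tables give standard
errors of marginal means); the defaults (e.g. RT: 60 ms participant,
10 ms face, 90 ms residual) are plausible values back-derived from
those standard errors and should be read as such, not as estimates.
Body mass is not reported; the default is 70 ± 10 kg. `g` is
9.81 m/s².

The generator emulates quiet standing, a single APA and forward CM
acceleration, crossed random intercepts and stationary Gaussian channel
noise. It does not emulate vertical-force unloading during the step,
mediolateral mechanics (beyond the limb flag), postural sway
autocorrelation, multi-peaked APAs, or heteroscedastic participant
noise — so passing recovery tests validates the pipeline's event logic
and statistics, not its robustness to every pathology of real data.

## Statistical model

Each outcome is analysed on accepted go trials with

```
value ~ emotion * condition + (1 | participant) + (1 | face)
```

fitted by REML via `lme4`/`lmerTest` with sum-to-zero factor coding
(type-III marginality), F tests with Satterthwaite denominator degrees
of freedom, estimated marginal means with equal factor weights and
Tukey-adjusted pairwise contrasts via `emmeans` — the same stack the
study itself used. Effect sizes use the semi-partial formula
$R^2 = \frac{qF/d}{1 + qF/d}$ with the Satterthwaite $d$; the
Kenward-Roger version of $d$ would differ slightly in small samples,
and the degrees-of-freedom source is the one switchable divergence from
the reference analysis. Boundary fits (zero variance components) are
permitted and flagged; with both components at zero the Satterthwaite
denominator collapses to the fixed-effects residual $N - p$, which the
test suite checks against an ordinary-least-squares oracle.

The power procedure is simulation-based in the style of `simr`: inject
a standardized emotion effect (Cohen's *d* on the total-SD scale,
realized as a fearful-minus-angry shift), simulate from the crossed
model, refit, test the emotion term at α = 0.05, and report the
rejection fraction with its exact Clopper–Pearson interval. At effect
zero this doubles as a calibration check of the Satterthwaite F test.

## Problem sizes and numerical tolerances

The test suite and acceptance script run, as the package's own choice
of desk-scale study conditions: 500 zero-noise round-trip trials
spanning RT 250–900 ms, duration 150–400 ms, amplitude −7…−2 cm
(recovery demanded within 1 ms, 0.05 cm, 0.005 m/s); 20 artifact
fixtures per QC rule; 100 marginal-mean recovery replicates on the
24-participant × 10-face design at 2 trials per cell; 500 null
replicates for the type-I error of the emotion F test; and 200 + 3×100
power simulations. The REML optimizer is `lme4`'s default (bobyqa on
the profiled criterion); studentized-range probabilities come from R's
`ptukey`. Ties in extrema are resolved to the earliest sample
throughout.

## Known limitations

* Wrong-limb detection is metadata-only; a mediolateral channel would
  be required for a physical check.
* The Kenward-Roger covariance correction is approximated by
  Satterthwaite degrees of freedom in the effect-size formula.
* The generator's vertical force ignores body-weight unloading, so
  vertical-channel analyses would be meaningless on synthetic data.
* Published group-level F statistics cannot be reproduced without the
  human recordings; the statistics stage is validated by parameter
  recovery and calibration instead.

## Example

```{r example, eval = FALSE}
cfg <- default_config(n_participants = 24, seed = 7)
run <- run_pipeline(cfg, out_dir = "stepinit_run")
run$qc_summary$fraction_rejected
run$stats$apa_amplitude_cm$anova
```
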