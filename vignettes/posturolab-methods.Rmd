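---
title: "Analysing support-surface tilt posturography with posturolab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing support-surface tilt posturography with posturolab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturolab)
```

## The problem

Standing balance is usually probed by tilting the support surface under a
subject's feet and measuring how much the body sways along.  Two stimulus
families are common: long **pseudo-random ternary sequences** (PRTS), which
are practically unpredictable and characterise the balance-control loop as a
frequency response, and short **rhythmic sequences** that a subject can
memorise, used to study motor learning across many repetitions.  posturolab
implements the complete analysis chain for such an experiment — stimulus
construction, centre-of-mass (COM) calibration, frequency-response and
coherence estimation with cycle-bootstrap confidence bounds, per-trial
learning metrics, and a hierarchical Bayesian trend model — together with a
closed-loop sway simulator that generates cohorts with known ground truth,
so every stage of the chain can be validated without human data.

## Pseudo-random ternary stimuli

One PRTS cycle is built from 80 velocity steps of 0.25 s drawn from
$\{-v, 0, +v\}$, generated by the maximal-length ternary recurrence
$s_n = s_{n-1} + s_{n-4} \pmod 3$ (period $3^4 - 1 = 80$) with field symbols
$(0, 1, 2)$ mapped to $(0, +1, -1)$.  The sequence is balanced (27 positive,
27 negative, 26 zero steps), so the integrated tilt angle returns to its
start each cycle, and its cumulative sum spans exactly 9 steps, which makes
the step velocities 0.44, 0.89 and 1.78 °/s integrate to peak-to-peak tilt
amplitudes of 1, 2 and 4°:

```{r prts}
pp4 <- buildPRTS(ternaryDesign(), velocityMagnitude = 1.78, nCycles = 1)
diff(range(tiltAngle(pp4)))
```

This register configuration was selected by enumerating the primitive
degree-4 ternary recurrences and keeping one whose cumulative-sum excursion
is 9 steps; descriptions of such stimuli sometimes quote "81" steps, which
counts both endpoints of the staircase — a maximal-length ternary sequence
of degree 4 has 80.

A harmonic counts as *excited* when the velocity-staircase amplitude
spectrum reaches 10% of its maximum, capped at 2.2 Hz.  The threshold is
deliberately applied to the velocity staircase, not the integrated tilt
angle: the staircase spectrum is flat across the non-null harmonics (the
even harmonics of a ternary m-sequence are structurally zero), so the rule
excludes exactly the structural nulls, whereas the tilt-angle spectrum
falls off as $1/f$ and would confuse rolloff with nulls.  For the 20-s
cycle this yields the 22 odd harmonics 0.05–2.15 Hz.

The learning stimulus is an 8-s superposition of 1 Hz and 1.25 Hz sines
(8 and 10 whole cycles).  Its published description fixes only the two
extremes — 5.3° toes-down and 2.6° toes-up — which under-determines the
amplitudes, phases and offset.  `learningStimulusParams()` resolves this
deterministically: both phases are set to zero, the amplitude ratio is tied
by requiring the platform to start at rest ($a_1 f_1 + a_2 f_2 = 0$), and
$a_1$ and the offset are solved so the extremes match exactly.  The solved
parameters are stored in the stimulus configuration so the choice is
explicit.  Sign convention throughout: toes-up tilt and forward lean are
positive.

## The sway simulator

Subjects are modelled as a single inverted pendulum with delayed PID
feedback and weighted sensory reference — the standard independent-channel
view of stance control:

$$J\ddot\theta = mgh\,\theta + T(t-\tau), \qquad
T = K_p e + K_d \dot e + K_i \!\int\! e \, dt,$$

with error $e = w\,(u - \theta) + (1 - w)(0 - \theta) + r$: a fraction $w$
(`wProp`) of the orientation error is referenced to the platform
(proprioception), the rest to gravitational vertical, and $r$ is the lean
setpoint.  The closed-loop transfer from platform tilt to body angle is

$$H(f) = \frac{w\,PC}{1 + PC}, \quad P(s) = \frac{1}{Js^2 - mgh}, \quad
C(s) = \left(K_p + K_d s + \frac{K_i}{s}\right) e^{-\tau s},$$

available in closed form through `analyticFRF()` — the oracle every
empirical estimator is tested against.

Defaults describe a 66.8 kg, 1.73 m subject (COM height 0.97 m,
$mgh \approx 629$ N m/rad) with $K_p = 1.5\,mgh$, $K_d = 0.5\,mgh$ s,
$K_i = 0.06\,mgh$, $\tau = 0.15$ s and $w = 0.6$.  These were tuned against
the closed form so the gain curve peaks near 0.11 Hz with peak gain 1.9,
inside the 0.1–0.3 Hz band typical of tilt posturography; they are
simulator conventions, not fitted quantities.  Stability is verified at
construction by requiring a simulated impulse to decay.

Numerical scheme: fixed-step RK4 at the recording rate (100 Hz default,
chosen so all step and cycle boundaries fall on samples), with the
transport delay as an integer-sample ring buffer.  The smooth feedback
torque is linearly interpolated between command samples inside each step;
the velocity feedthrough $K_d w \dot u$ — discontinuous for the PRTS
staircase — is applied as a zero-order hold with the velocity sampled at
sample midpoints, which is exact for the staircase and $O(\Delta t^2)$ for
smooth stimuli.  (Linearly interpolating that term instead smears each
velocity jump half a sample early and biases phase by several degrees at
2 Hz.)  With this scheme the simulated frequency response matches the
continuous-time closed form to within 0.3% gain and 0.1° phase across the
excited band, an order of magnitude below the 2%/2° tolerances used in the
oracle tests.  Gravity is linearised ($mgh\,\theta$), matching the analytic
oracle; excursions beyond 30° raise a "simulated fall" error instead.

Torque noise is first-order low-pass filtered white noise (default sd 8 N m,
time constant 1 s), producing the 1/f-like random sway background of real
posturography.  Outputs follow a two-segment geometry (legs and
head-arms-trunk, Winter-style mass fractions stored in the parameter list):
hip and shoulder marker translations, the COM truth channel, and the centre
of pressure $x_{cop} = -T/(mg)$ plus sensor noise, which tracks the COM
projection in quasi-static segments.  An optional slow prescribed hip-angle
oscillation adds the second degree of freedom that makes the calibration
regression identifiable; it is off by default in dynamic trials and always
present in the dedicated calibration trial.

An optional sensory-reweighting exponent scales the effective weight with
stimulus amplitude; it is **off by default**, so the linear simulator does
*not* reproduce the amplitude-dependent gain reduction seen in human data —
a deliberate limitation, flagged here so that passing tests are not read as
evidence about that nonlinearity.

## Calibration

During slow ankle-and-hip movements on the static platform the centre of
pressure coincides with the vertical COM projection, so ordinary least
squares of `cop_x` on hip and shoulder translation yields the coefficients
mapping markers to COM translation (`fitCalibration()`); collinear markers
(no hip motion) are rejected.  `applyCalibration()` converts to angular COM
sway via $\arcsin(x_{com}/h_{com})$ — the inverse-sine rather than the
small-angle ratio, a negligible difference below 5° but fixed by
convention.  The simulator's geometry makes the COM translation an exact
linear combination of the two markers, so noise-free recovery is exact to
rounding, and the regression includes an intercept (harmless under
centring; the quasi-static premise makes it near zero).

## Frequency response and coherence

Pseudo-random recordings are cut into 20-s cycles; the first cycle of each
trial is discarded as transient.  All remaining cycles of one condition are
pooled across subjects into a `CycleSet` (19 subjects × 17 cycles = 323
rows at study scale).  Per-cycle DFTs give the spectral ratio
$R_k(f)/S_k(f)$; the FRF is their mean across cycles, gain its modulus and
phase its unwrapped argument (degrees, lag negative).  Coherence is the
squared cycle-averaged cross-spectrum over the product of cycle-averaged
auto-spectra: 1 for fully stimulus-locked sway, $\approx 1/N$ for sway
unrelated to the stimulus after averaging $N$ cycles.  Cycle means retain
the per-trial offset, which carries the mean body lean.  For display,
`bandAverage()` groups harmonics into logarithmic bands; raw per-harmonic
values are always retained.

## Learning-trial metrics

Each 8-s learning trial yields nine scalars: a linear regression of the COM
trace gives the starting position (intercept at $t = 0$) and drift slope;
the detrended trace's single-sided amplitude spectrum (scaled so a sine of
amplitude $a$ reads $a$) is partitioned at 0.125-Hz resolution into
stimulus bins (1.0, 1.25 Hz), non-stimulus low-frequency bins (0.125,
0.250 Hz — the bins that dominate spontaneous sway) and the remaining
high-frequency bins, with powers that sum exactly to the full-spectrum
power; the feedback score is

$$\mathrm{fb} = \sum_{k=0.125}^{2\,\mathrm{Hz}} |y(k)| \times 100 +
|s| \times 1000,$$

flagged sway- or drift-dominated when one component exceeds 70% of the
score (strictly).  The summation starts at 0.125 Hz, the resolution of an
8-s window — a lower figure sometimes quoted for this score has no
corresponding bin.  Gain and phase at the two stimulus frequencies are
aggregated by amplitude-weighted averaging (weights: the stimulus
amplitudes); per-frequency values are available via `perFrequency = TRUE`.
The full-spectrum power is capped at 2 Hz for consistency with the score.

One caveat discovered while testing: a zero-mean oscillation is only free
of spurious regression slope when it is even about the window centre
(the integral of $t\sin(2\pi n t/T)$ over whole periods is $-T^2/2\pi n$),
so detrending identities are stated with cosine components.

## Bootstrap confidence bounds

Confidence bounds for cycle means, FRFs and coherence come from resampling
whole cycles with replacement (pool size preserved), recomputing the
statistic, sorting each scalar output across the 400 replicates and reading
the order statistics at `round(n(1±ci)/2)` — the 10th and 390th of 400 at
the 95% level.  Sorting is element-wise per frequency with no simultaneous
band correction, and the resampling unit is the cycle, not the subject.
`frfWithBootstrap()` exploits the row-wise nature of the per-cycle DFT to
precompute spectra once; a test asserts bit-identical bounds against the
generic engine re-running the estimators on every resample.

## The hierarchical trend model

Across the 75 learning trials each metric is modelled as
`metric ~ seq + (seq | subject)` with trial indices coded from 0: population
intercept $\beta_0$ and slope $\beta_1$, correlated subject-level
deviations $(b_{0i}, b_{1i})$, and residual noise.  Priors are weakly
informative — Normal(0, 10) on $\beta_0, \beta_1$, Half-Cauchy(0, 2) on the
two group-level standard deviations and (by symmetry, a choice this package
fixes) on the residual sd, and uniform on the intercept–slope correlation,
the one group-prior component left open by convention.  The posterior is
sampled with JAGS (4 chains × 4000 iterations including 2000 warmup by
default; reduced presets are used in tests), with all chains initialised at
the per-subject OLS solution — the group-level posterior is a funnel when
residual noise is small, and default initialisation strands the sampler far
from the mode.  A tiny ridge (1e-10) on the group covariance diagonal keeps
the precision matrix invertible in the noise-free limit.  Convergence is
diagnosed with split-$\hat R$; values above 1.05 raise a warning, never a
silent return.  A slope is called significant when its central 95% credible
interval excludes zero.  Note that strict shift-invariance of the slope
holds only within the support of the proper Normal(0, 10) intercept prior;
shifting all responses by much more than 10 units creates a genuine
prior–data conflict.

## The synthetic cohort and what it does (not) show

`learningCohortConfig()` fixes the study conditions: 19 subjects × 75
trials; the measured body lean drifting 3.3° → 2.4° and the proprioceptive
weight drifting so that stimulus-frequency sway power (∝ $w^2$) falls by
33%, both as exponential approaches with a 20-trial time constant;
between-subject dispersion (lean sd 0.4°, log-normal stiffness sd 0.08,
weight sd 0.03); constant torque noise, so the non-stimulus low-frequency
floor stays flat.  Because the learning stimulus has a nonzero mean tilt,
the generator back-computes the controller setpoint as
`lean − w·mean(u)`, so the configured lean curve is the ground truth for
the measured starting-position metric.  Each trial starts at its
quasi-static equilibrium (no artificial onset transient).

The generator emulates: stimulus-locked sway with a realistic gain/phase
curve, 1/f-like random sway, slow learning drifts with subject
heterogeneity, and marker/COP sensor noise.  It does not emulate:
amplitude-dependent sensory reweighting (unless enabled), intermittent or
nonlinear control, multi-link dynamics beyond the prescribed hip wobble,
fatigue, or any explicit prediction of the stimulus — so passing tests
validate the *analysis chain*, not those physiological hypotheses.

## Problem sizes and numerical conventions

Angles are degrees at every interface and radians only inside the
integrator; column names carry units (`tilt_deg`, `cop_x_m`).  All
randomness derives from per-stage seeds split from one master seed, and a
protocol run writes a manifest whose checksums are byte-identical across
reruns.  Test and validation runs use these problem sizes, chosen to probe
each property at the smallest scale at which it is meaningful: FRF oracle
checks on one 18-cycle trial; the coherence null at 17 cycles × 200
replications; bootstrap coverage on a 50-point Gaussian pool × 500
replications; trend-model coverage and false-positive rate at 8 subjects ×
15 trials × 200 replications with 2 × 1000 iterations; the end-to-end
signature on the full 19 × 75 cohort with 2 × 1500 iterations per trend
fit.  Degenerate inputs fail loudly: non-primitive tap sets report the
achieved period, non-integer cycle counts report the residual duration,
collinear calibration markers suggest more hip motion, single-cycle
coherence and single-subject trend fits are refused, and a diverging
simulation names the time of the fall.
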