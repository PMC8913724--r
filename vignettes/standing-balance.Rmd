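---
title: "Modelling quiet standing with vestibulospinal and proprioceptive feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling quiet standing with vestibulospinal and proprioceptive feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturesim)
```

## The control problem

Quiet human standing is the regulation of an unstable multi-segment
inverted pendulum by muscle activity, under substantial sensorimotor
delays and noisy sensing.  Two descending pathways dominate this task: the
reticulospinal tract sets a constant background *muscle tone*, and the
lateral vestibulospinal tract (VST) uses head-movement information from the
vestibular organs to excite extensor muscles and inhibit flexors, keeping
the body vertical.  `posturesim` implements a closed-loop model of this
system — a reduced sagittal-plane musculoskeletal plant plus a neural
controller with feedforward tone, delayed proprioceptive feedback, delayed
vestibular feedback, and calibrated Gaussian sensory noise — together with
the two-stage procedure that adjusts the controller's free parameters and
the sway-analysis stack used to characterize the resulting balance
behaviour.

## The plant

A plant is a serial chain of rigid segments pivoting about a fixed ankle,
with the feet represented only by a base-of-support (BOS) interval on the
ground.  The frame is x anterior, y up, z lateral; joint angles are
positive for extension (posterior rotation of the distal segment), so
extensor muscles have positive moment arms, flexors negative, and the
standing posture leans slightly anterior (negative ankle angle).  Two
built-in fixtures cover unit-scale and chain-scale behaviour:

* `one_link`: a 70 kg point mass 1 m above the ankle with one lumped
  extensor and one flexor group — the classic ankle-strategy pendulum.
* `four_link`: shank, thigh, trunk and head–neck segments (70 kg total,
  ~1.7 m stature analogue) with antagonist pairs at ankle, knee, hip and
  neck.  The head segment carries the vestibular sensor point (by default
  its centre of mass; the true vestibular-organ location within the head is
  not critical at this scale).

Muscle groups follow a deliberately minimal Hill-type law.  With
normalized length $\tilde L = L^{MT}/l_{opt}$ and normalized lengthening
rate $\tilde V = \dot L^{MT}/(v_{max} l_{opt})$:

$$F = a\, F_{max}\, f_L(\tilde L)\, f_V(\tilde V) + F_{pass}(\tilde L)$$

with a Gaussian force–length factor $f_L = \exp(-(\tilde L - 1)^2 / (2
\cdot 0.45^2))$, a clamped linear force–velocity factor $f_V =
\mathrm{clip}(1 + \tilde V,\, 0,\, 1.4)$ (zero at maximal shortening, an
eccentric plateau of 1.4 on stretch — the qualitative shape of the
standard Hill/Millard curves at minimal complexity), and an exponential
passive element engaged above optimal length ($0.02 F_{max} (e^{10(\tilde
L - 1)} - 1)$).  Force is tensile only.  Muscle geometry is linearized
with constant moment arms about the reference posture: $L^{MT} = l_{opt} -
\sum_j r_j (q_j - q_{ref,j})$; this is adequate for the few degrees of
sway the task involves.  Activation follows first-order dynamics
$\dot a = (u - a)/\tau$ with $\tau_{act} = 10$ ms when turning on and
$\tau_{deact} = 40$ ms when turning off, integrated exactly per step.

Rigid-body dynamics are formulated in absolute segment angles (mass
matrix, velocity-product terms, gravity levers precomputed at
construction) and integrated with fixed-step RK4 at `dt = 1` ms — the step
resolves the 10 ms activation time constant with margin, and a passive
chain conserves energy to better than $10^{-6}$ relative over 5 s (this is
a test in the suite).  The anterior–posterior centre of pressure follows
from the sagittal angular-momentum balance about the ankle,
$x_{COP} = (\dot L_{ankle} + g\sum_i m_i x_i)/F_y$, which coincides with
the net ankle muscle torque divided by the vertical ground reaction for a
massless foot; the test suite verifies the two derivations agree to
$10^{-9}$.

## The controller

Per control step (one per integrator step) the controller senses all
muscle lengths and lengthening velocities and an 18-component head state —
translational acceleration, angular acceleration, translational velocity,
angular velocity, position and angle, three world axes each, in that fixed
block order.  Sensed values receive receptor noise (below), pass through a
40 ms feedback delay line, and drive three output terms per muscle $i$:

* feedforward tone $u_{ff,i}$, a constant;
* proprioceptive feedback
  $u_{fb,prop,i} = K_{p,i}\,\frac{L_i(t-\tau_{fb}) - L_{i,0}}{L_{i,0}} +
  K_{d,i}\,\frac{\dot L_i(t-\tau_{fb}) - \dot L_{i,0}}{V_{i,max}}$;
* vestibular feedback $u_{fb,ves,i} = sig_i\, K_{ves} \cdot e_{ves}$, with
  $sig_i = +1$ for extensors and $-1$ for flexors — the excitatory /
  inhibitory asymmetry of the lateral VST.

The vestibular error $e_{ves}$ passes accelerations and velocities through
as raw signed values (they provide phase advance), takes absolute
deviations from the initial values for horizontal position and all angles,
and rectifies the vertical position: only a head *below* its reference
contributes, because the tract acts to hold the head up.  Setting the
vestibular gain vector identically to zero removes the pathway exactly and
reproduces a proprioception-only controller bit for bit.

The total command is clipped to $[0, 1]$ (activations are physical
fractions; raw components are kept for feedback-activity norms), delayed
by the 40 ms transmission delay, and fed to the activation dynamics.  The
slow branch of the loop therefore totals 120 ms: 40 (sensing) + 40
(transmission) + 40 (deactivation).  Both sensory modalities share the
same feedback delay; the delay lines are sampled at the integrator step
and hold the initial record for reads before t = 0 (the initial posture
equals the target posture, so startup feedback is near zero).

Gains are not free per muscle.  Muscles pool into functional groups that
share feedback gains (within-group consistency and bilateral symmetry);
two scalar knobs expand as $K_{p,i} = c_{p,i} k_p$, $K_{d,i} = c_{d,i}
k_d$ through a fixed 14-row coefficient table (`gain_coefficients()`, also
shipped as CSV), and six vestibular knobs $k_1..k_6$ each scale one
3-component block of the 18-vector with an overall factor 0.01.  Tone, by
contrast, may differ per muscle.

## Sensory noise

Each sensed channel is corrupted as $y = x + k_{noise}\,\mu\,X$, $X \sim
N(0,1)$, drawn independently per channel per control step, applied to the
receptor value before the delay line.  $\mu$ is calibrated per channel as
the time-average of $|x(t)|$ over one noise-free standing trial (floored
at $10^{-12}$ for identically zero channels, e.g. out-of-plane head
components), so a single dimensionless $k_{noise}$ spans channels of
different units; the default is $k_{noise} = 0.01$.  With $k_{noise} = 0$
the pipeline is bit-exactly deterministic and never touches the RNG; each
noisy trial takes an explicit integer seed and restores the caller's RNG
state.

## Two-stage parameter adjustment

**Stage 1 — tone candidates.**  Tone is delay-independent, so it is
computed under the no-delay, no-noise condition: for each knob combination
in a grid over the standard ranges ($k_p, k_d \in [1, 3]$; $k_1..k_6 \in
[10^{-4}, 10^{-2}]$, or zero when the vestibular channel is disabled), a
trial runs with zero tone; if the plant stands the full 5,000 ms, the tone
is the time-average of each muscle's activation over [3,000, 5,000] ms and
the target posture is updated to the time-average joint angles over the
same window (a single pass; iterating the two averages to convergence
changes little at this scale and is not done).  Candidates are summarized
by the whole-body tone norm $\lVert u_{ff}\rVert_2$, and candidates
closest to requested norm targets are selected (ties toward the smaller
norm; if gain tuning later fails for a selection, the next-closest
candidate is taken).  Default grid resolutions are 5 x 3 x 3 (`ci`
profile) or 5 x 5 x 3 (`full`) — a dense sweep like the original
whole-body protocol is deliberately out of desk-scale reach.

**Stage 2 — feedback gains.**  With tone and target posture frozen, the
knobs (8-dimensional with the vestibular channel, 2 without) are tuned by
CMA-ES in log10 space with projection onto the range box, minimizing

$$J = w_{fail} J_{fail} + w_{pos} J_{pos}, \qquad
J_{fail} = \frac{T_{simu} - T_{fail}}{T_{fail}}, \qquad
J_{pos} = \sum_j \int_0^{T_{fail}} |\theta_j(t) - \theta_j(0)|\,dt,$$

with $w_{fail} = 10{,}000$, $w_{pos} = 1$: any fall dominates, then
posture deviation discriminates.  A fall is the first instant the COM
height drops below threshold or the COM leaves the BOS; for reduced
fixtures the 0.7 m whole-body threshold is rescaled to 72% of standing COM
height ($0.7 \cdot h_0 / 0.96$), since 0.7 m is only meaningful for
full-body anthropometry.  A velocity guard ($|\dot q| > 50$ rad/s) flags
integrator blow-up as a fall, because the optimizer explores unstable
gains.  Evaluations run with the full delays and noise on a fixed
per-evaluation seed schedule, so CMA-ES ranks candidates on a consistent
stochastic objective.  CMA-ES itself is the standard
$(\mu/\mu_w, \lambda)$ strategy with rank-one and rank-$\mu$ covariance
updates and cumulative step-size adaptation, $\lambda = 4 + \lfloor 3 \ln
d\rfloor$, initial $\sigma = 0.3$ of the box range, 30 generations in the
`ci` profile (100 in `full`).

`fit_posture_controller()` wraps the whole pipeline into a single fitting
call returning a classed object with `coef()`, `simulate()`, `plot()`,
`residuals()` methods; `run_experiment()` repeats it over tone levels and
both conditions (vestibular channel present/absent) with ten seeded
replicate trials per fitted controller.

## Sway analysis

Trials are summarized by the mean absolute anterior–posterior COP velocity;
replicate sets by its mean and SD.  Power spectra use the classical
Lomb-Scargle periodogram (with the tau phase correction) because trial
series may be truncated or unevenly spaced in general; powers are
normalized to sum to 1 on a 100-point log-spaced grid over [0.1, 5] Hz.
Log–log slopes are fitted by ordinary least squares in two bands: $\beta_1$
over [0.1, 1] Hz (1 Hz inclusive — the edge assignment is a documented
convention, configurable) and $\beta_2$ over (1, 5] Hz.  The spectrum for a
condition is taken from the trial with the median objective J (lower median
for even counts, first among ties).  Conditions are compared per tone level
with Welch two-sample t-tests — the unequal-variance form is the safer
default at n = 10 — under a Bonferroni-corrected threshold $\alpha/n_{levels}$
(0.05/6 ≈ 0.0083 for six levels).  The correlation between tone norm and
COP-velocity SD uses Pearson's r.  `synth_powerlaw_trace()` generates
spectral-synthesis traces with known exponent to validate the slope
estimators; the suite requires mean recovered slopes within ±0.15 for
exponents 0, −1, −2.

## Fixture design and what the tests do (and do not) show

The gain ranges above are part of the study conditions, so the fixtures'
lumped muscle parameters (maximal forces, moment arms, optimal lengths)
were chosen once, at design time, such that a substantial portion of the
$[1,3]^2$ proprioceptive box stabilizes each fixture — the same property
the full-body model has in those ranges.  That makes individual $F_{max}$
values larger than single-muscle physiology (they lump bilateral synergist
groups, e.g. 20 kN for the one-link whole-body extensor).  The default
anterior lean places the COM a few centimetres ahead of the ankle, inside
the BOS `[-0.06, 0.18]` m, so gravity loads the extensors as in human
stance.

Because the reduced plants have 2–8 muscles rather than 94, tone norms are
O(0.01–0.1) rather than O(1–5); tone-norm targets are therefore free
parameters of `run_experiment()` (defaulting to candidate-norm quantiles)
rather than the whole-body values 1.5–4.5.  The synthetic fixtures emulate
the *structure* of the problem — instability, delays, antagonist muscle
control, vestibular sensing from a head segment — but not whole-body
anthropometric detail, muscle redundancy, or the co-contraction patterns a
94-muscle system can express.  Passing tests therefore validate the
controller's laws, the pipeline's mechanics and the direction of the
vestibular effect, not quantitative human sway magnitudes.

Numerical conventions worth knowing: trials start at the target posture
with activations equal to the tone; reference sensory values are taken at
that initial state; commands are clipped before the activation lag;
degenerate inputs (a fall at t = 0) yield a large sentinel objective; and
all times in configurations follow the ms conventions of the protocol
(5,000 ms trials, 40/40/10/40 ms delays) while trajectory time axes are in
seconds.

## Problem sizes

The shipped profiles keep every stage at desk scale: stage-1 sweeps of
15–75 combinations, CMA-ES budgets of 30 generations x ~10 evaluations,
ten replicate trials per condition, and 5,000-step trials.  These sizes
are the package's own defaults and are what the test suite and the
reproduction script exercise.

## Known limitations

Sagittal plane only; constant moment arms; no tendon elasticity,
short-range stiffness, or ground compliance; feet are not dynamic
segments; the medial vestibulospinal tract, vision, stretch reflexes,
intermittent control and cerebellar estimation are all outside the model's
scope.  Biarticular muscle groups are representable (a muscle may span
several joints and its extensor/flexor role sets the vestibular sign), but
the built-in fixtures use single-joint groups only.
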