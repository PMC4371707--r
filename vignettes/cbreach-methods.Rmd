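---
title: "Methods: cerebellar context-correction learning for reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cerebellar context-correction learning for reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The architecture in one paragraph

`cbreach` simulates a motor-learning architecture in which a cerebellar
module improves the reaching of an equilibrium-point (threshold) controller
by *predicting increases in error*. The central controller maps a 3D target
to equilibrium ("target") muscle lengths through inverse kinematics and
drives each of 11 Hill-type muscles with the positive part of a velocity
error. Whenever the reaching error starts to grow, "complex spikes" are
generated; each spike causes the module to store the sensorimotor *context*
from shortly before the error increase together with a *corrective* muscle
command. On later reaches, radial-basis-function recall replays those
corrections anticipatively as the trajectory re-enters a stored "error-prone
area". Four variants differ in where the spikes come from (visual distance
error vs. per-muscle proprioceptive rules) and in how corrections are built
(efference copies, single-muscle contractions, or a proprioceptive product
rule). An idealized point-mass model with a central force and impulsive
corrections is included to study why such corrections are stabilizing: they
drain angular momentum from the orbiting error dynamics.

## Arm model

The plant is a 4-DOF arm: a shoulder with three rotational degrees of
freedom (intrinsic ZXZ Euler angles $\alpha,\beta,\gamma$) and one elbow
flexion angle $\delta$. Rest pose is the arm hanging along $-z$ with the
shoulder at the origin ($x$ lateral, $y$ anterior, $z$ up). Segments are
cylinders; defaults $L_{arm}=0.30$ m, $L_{farm}=0.35$ m (the forearm
segment includes the hand), masses 2.1/1.65 kg, radii 4/3 cm. These
anthropometric values are typical of an adult human arm and give a maximum
reach of 0.65 m, covering all eight standard test targets (max distance
0.49 m). A small articulation inertia $\varepsilon = 5\times10^{-5}$
kg m$^2$ is added to the mass-matrix diagonal: the ZXZ chart is singular at
$\beta = 0$ (the rest pose), where $\alpha$ and $\gamma$ rotate about the
same axis, and $\varepsilon$ keeps the dynamics solvable there. The
conservation audit in the test suite therefore uses conical-pendulum-like
motion that stays away from that chart singularity.

Eleven composite muscles connect torso, upper arm and forearm:
flexor/extensor, abductor/adductor and two axial rotators at the shoulder,
biceps-like and triceps-like biarticulars, a brachialis-like monoarticular
elbow flexor, and two oblique stabilizers. The printed sources describe
this plant only topologically, so the attachment coordinates shipped in
`default_muscles()` (and `inst/extdata/arm_default.yaml`) are a documented
geometric idealization; all geometry tests are geometric, not anatomical.
Muscles at the elbow wrap over *bending lines*: a muscle's path goes
through the point of the bending segment that minimizes total length
whenever the straight path crosses the plane spanned by the segment and its
configured normal. The minimizing via point has a closed form (the mirror
construction of the convex 1-D problem), clamped to the segment; a
collinear via point degenerates to the straight path, so wrapped length is
always $\ge$ the Euclidean distance.

### Muscle law

The printed sources cite a Hill-type muscle used with equilibrium-point
controllers but give no equations, so the concrete law is a package design
decision, written to satisfy the properties the architecture needs:

* activation state: $\dot a = (\max(u,0) - a)/\tau_a$, $\tau_a = 20$ ms;
* active tension: $F_{max}\, a\, f_v(v)$ with $f_v$ a Hill hyperbola while
  shortening ($f_v(-v_{max}) = 0$) and a linear eccentric rise capped at
  1.5, continuous with slope $5/v_{max}$ at $v=0$; $v_{max}=0.6$ m/s;
* passive viscoelasticity: $[k_p (l - l_{rest}) + b_p v]^+$ with
  $k_p = 50$ N/m, $b_p = 20$ N s/m, engaged only beyond the rest length
  (rest lengths are the path lengths at the hanging pose).

Tension is therefore nonnegative, monotone in the stimulation, and
decreases with shortening speed. A "viscous term that grows with shortening
speed" would violate that force–velocity property, which is why the passive
damping is tied to the elastic term instead. Tensions map to generalized
torques by virtual work, $\tau = -J^\top f$ with $J = \partial l/\partial q$
evaluated by central differences.

### Integration

Rigid-body dynamics $M(q)\ddot q + c(q,\dot q) = \tau$ use the exact mass
matrix assembled from body Jacobians, Coriolis forces from numerically
differentiated Christoffel symbols ($\partial M/\partial q$ by central
differences, step $10^{-5}$), and gravity (default **off**, matching the
observation that the baseline behaves the same without gravity) from a
differentiated potential. The integrator is explicit midpoint (second
order) at a physics step of 0.5 ms with a 1 ms control step; muscle lengths
are linearized through $J$ within each control step. Energy on
conservative test problems is conserved to better than 0.1% per second at
a 0.1 ms audit step. When any joint speed exceeds `qd_max` (20 rad/s) the
state is clamped and the reach is *flagged unstable* but continues: runaway
oscillation ("flailing") is reportable behavior of the model, not a
simulation failure, and clamping keeps the 4 s integrated error comparable
across reaches.

## Central controller

Given a target, inverse kinematics produces the unique $\gamma = 0$ pose
(closed form; $\alpha$ uses `atan2(-x, y)`, which reduces to the arcsine
form where that form is defined and extends it; on the vertical axis
$\alpha := 0$). Muscle lengths at that pose are the equilibrium lengths
$\lambda$. Each millisecond the controller computes
$e_l = g_l(l - \lambda)$ and $e_v = g_v(v + e_l)$ with $g_l = 2,\ g_v = 1$
from proprioceptively delayed ($\tau_p = 25$ ms) lengths and velocities.
The muscle input is $[e_v]^+$ — the positive part is applied *before* the
output low-pass filter (first order, $\tau_f = 50$ ms), and a small
integral component $k_i \int (\text{filtered output})\,dt$, $k_i = 0.25$
s$^{-1}$, prevents the arm from settling in equilibria away from the
target. Neither $\tau_f$ nor $k_i$ is printed anywhere; both were
calibrated once against the baseline phenomenology (approach in roughly
1.5 s, residual non-periodic oscillation, instability for some targets)
and are exposed in the `controller:` configuration section.

With these defaults the bare controller reaches 7 of the 8 standard targets
to within 20% of the initial distance in 4 s and destabilizes on targets
whose geometry excites the weakly-actuated shoulder-spin direction — the
analogue of the instability the original study reports for one of its
targets (which target flails depends on the invented muscle geometry, so
the package does not claim target-level correspondence).

## Inferior olivary module

For the visual-error variants, $N = N_3 + N_7 = 20$ olivary cells carry
subthreshold oscillations at 3 and 7 Hz with phases evenly covering the
cycle. Each millisecond, cell $i$ spikes with probability

$$P^i_{CS}(t) = \frac{p\cos[\alpha(i)(t-\phi(i))] + 1}
{(1+e^{5-E})(1+e^{30-15[E']^+})}$$

clipped to $[0,1]$, with $p = 0.1$, subject to a 200 ms per-cell refractory
period. Two readings of the printed formula are possible; the default
treats the oscillation term as a multiplicative gate on the product of the
two sigmoids (the alternative parse, which adds the raw oscillation to the
gated term, is available as a configuration switch but always yields
$P \approx 1$). $E$ and $[E']^+$ enter in centimetres — the constants 5 and
30 are printed unitless, and at reach scale (tens of cm, tens of cm/s) the
cm reading places both thresholds inside the operating range; this is a
documented unit guess. Probabilities are *per millisecond*: a per-step
Bernoulli rate depends on the evaluation step, so the spike evaluation step
is fixed at 1 ms. Phases $\phi(i)$ are treated as offsets in seconds, as
written.

For the proprioceptive variants (models 2 and 3) a muscle emits a "complex
spike" when it is elongating, longer than its target length, and 200 ms
past its last spike; model 3 additionally requires the visual error to be
increasing.

## Cerebellar microcomplex

The context is a 28-vector: delayed visual error and derivative
($\tau_v = 150$ ms), delayed shoulder quaternion, quaternion rate, elbow
angle and rate ($\tau_p = 25$ ms), the 11 efferent commands, and the
desired pose (quaternion + elbow angle). Before any distance computation
each component is scaled (error $\times 10$, commands $\times 5$, rates and
quaternions $\times 1$, configurable): the components carry heterogeneous
units and an unscaled metric would be dominated by whichever unit happens
to be largest. The error components participate in the recall distance by
default (they are part of the module's input) but can be masked by setting
their scales to zero.

A spike at $t_{cs}$ is *handled* at the first time $t$ when the relevant
error derivative is no longer positive: if $t - t_{cs} \le 250$ ms a new
entry is stored, otherwise the spike is discarded (slow drifts whose
episodes outlast the window never store — visible on one standard target,
which spikes but stores nothing). The stored feature vector is the context
from $\tau_v - \tau_p + (t - t_{cs})/2$ before the spike — the delay
compensation that aligns the stored context with the state that *preceded*
the error increase. For the proprioceptive variants the same formula is
used with $\tau_v := \tau_p$ (their error pathway has no visual delay), so
the lookback is $(t - t_{cs})/2$.

Corrections per variant: **model 1** stores the time-average of the muscle
commands over $[t_{cs}, t]$ shifted back by $\tau_v - \tau_p$, times a gain;
**models 2/3** store a fixed-amplitude contraction of the spiking muscle;
**model 4** stores $w_i = \text{gain}\,[\langle l_i\rangle - \lambda_i]^+
\langle[\dot l_i]^+\rangle$ with averages over the same shifted window as
model 1's efference average ("a brief period before the error stopped
increasing").

Recall: $D(i) = \lVert f(i) - v \rVert^2$ on the scaled context,
$D_N = (M_F/\lVert D\rVert) D$, output $\sum_i w(i)e^{\gamma D_N(i)}$. The
printed kernel only decays for $\gamma < 0$, so the package validates
$\gamma < 0$. The $D_N$ normalization makes recall *relative*: an entry
contributes only when it is much closer to the current context than the
store as a whole, so corrections switch on sharply as a re-reach approaches
a stored area and switch between areas in sequence along the trajectory.
Because $M_F = 32$ multiplies the normalized distance, moderately negative
$\gamma$ already yields near-nearest-neighbour behaviour; the shipped
defaults ($\gamma_1 = -0.35$, $\gamma_4 = -0.5$, $\gamma_3 = -0.7$,
$\gamma_2 = -3$; gains 1.5, 250, 0.05, 0.002) were calibrated once so that
each variant expresses its qualitative behaviour, preserving the required
ordering: the per-muscle variants need smaller kernel radii (larger
$|\gamma|$) and much smaller amplitudes to stay stable, and the
visual-error constraint lets model 3 run hotter than model 2. New entries
fuse with their nearest neighbour (midpoint of features and of corrections)
when closer than 0.2 scaled units or when the store is full, so the store
never exceeds $M_F$ entries. The cerebellar output is added to the muscle
input after the controller's low-pass filter and clipped at zero with it.

## Experiment protocol

`run_experiment()` runs 8 successive reaches to each of the 8 standard
targets (stored as printed, in cm, in `inst/extdata/targets.csv`), one
fresh store per target, arm state reset between reaches, store carried
over. Resetting between reaches treats each 4 s episode as an independent
trial of the same reach, which is what a per-reach error metric assumes.
Performance is the time integral of hand–target distance over the 4 s
horizon; per-reach means across targets are normalized by the first reach
and reported with standard errors $SD/\sqrt{8}$. One seeded RNG stream
drives the olivary Bernoulli draws; with a fixed seed every log is
bit-reproducible. The baseline variant has no randomness at all.

## Idealized point-mass model

The hand becomes a point mass under a central force toward the target
(default linear spring, $k = m = 1$, closed elliptical orbits; an
inverse-square law is available), integrated by velocity Verlet at 0.1 ms,
which conserves angular momentum between impulses to near machine
precision. The ideal cerebellum is three numbers: a speed threshold
(0.05 m/s), a distance threshold (0.1 m), and a gain (2). An event starts
when the radial speed exceeds the speed threshold beyond the distance
threshold; the central force is integrated from onset until the largest
time at which (1) the radial speed still exceeds the threshold, (2) the
mass has rotated less than $\pi/2$ around the origin, and (3) the scaled
impulse would not reverse the radial velocity. The resulting impulse is
stored keyed on the onset state (position and velocity, velocity scaled by
$1/\omega$) and applied when the trajectory re-enters a ball of radius 0.02
around that state (0.5 s per-entry refractory, radial velocity positive,
impulse rescaled if it would reverse it). Because the impulse is the
integral of $-k\,r$ over a forward arc of less than $\pi/2$, its tangential
component opposes the motion and each application drains angular momentum;
runs terminate when the mass comes within the distance threshold
("reached") or when the radial-speed amplitude stays below the speed
threshold for a full period ("circular"). Circular orbits never trigger
corrections — the error never increases — which is the scheme's documented
blind spot. The monotonicity of $\lVert L\rVert$ at corrections is tested
with a $10^{-3}$ relative allowance: impulses are applied *near*, not *at*,
the stored state, and the finite generalization ball introduces exactly the
small angular mismatch that the idealized analysis flags as its caveat.

## What the simulations do and do not show

All data are self-generated: the simulations *are* the experiment. They
emulate closed-loop reaching with realistic delays, redundant actuation and
marginally-damped equilibrium-point control — the conditions under which
anticipatory corrections help. They do not emulate sensory noise,
muscle-model fidelity (no tendon dynamics, pennation or muscle mass),
anatomical muscle routing, shoulder translation, or a wrist; passing tests
show that the architecture behaves as described on this plant, not that it
reproduces human kinematic detail. Learning magnitudes depend on the
invented plant: targets whose baseline reach is smooth produce few error
episodes and learn little, so improvements are reported as across-target
means.

## Numerical choices and degenerate inputs

* Finite-difference steps: $10^{-6}$ (muscle Jacobian, gravity),
  $10^{-5}$ ($\partial M/\partial q$).
* IK clamps $\cos^{-1}$ arguments to $[-1, 1]$ against rounding at the
  reachable-annulus boundary; unreachable targets raise an error.
* Bending lines with coincident endpoints are configuration errors; a via
  point collinear with the attachments yields exactly the straight length.
* Delay lines return their initial sample until the delay has elapsed.
* An empty recall store returns a zero correction; $\lVert D\rVert = 0$
  yields full corrections ($D_N := 0$).
* Problem sizes used by the test suite and acceptance script: 8 targets
  $\times$ 8 reaches $\times$ 4 s per variant (1 ms control, 0.5 ms
  physics), 1000-target kinematic round-trips, a 60 s olivary refractory
  audit, and 20 seeded point-mass orbits up to 600 s at 0.1 ms.

## Known limitations

* The muscle geometry is idealized; moment arms, and therefore which
  targets destabilize the baseline, are properties of this package's arm,
  not of any subject.
* Eq.-level constants for the olivary gates assume the cm reading of the
  visual error; other unit choices would need re-tuned population
  parameters.
* The recall normalization couples every entry's weight to the whole
  store, so recall strength changes as the store grows — a property of the
  printed formulas, preserved deliberately.
* With per-millisecond Bernoulli spiking and the default gates, spike
  *counts* during an episode are limited mainly by the 200 ms refractory
  period; the subthreshold phases matter most near gate thresholds.
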