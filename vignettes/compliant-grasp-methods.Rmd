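---
title: "From surface EMG to a compliant grasp: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From surface EMG to a compliant grasp: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgrasp)
```

# Overview

`semgrasp` simulates, end to end, a control architecture in which a
prosthetic finger grasps objects *compliantly* using only the wearer's
muscle activity. The chain is:

1. multichannel surface EMG (synthetic here) is reduced to a normalized
   activation level;
2. a reduced-order Huxley cross-bridge muscle model converts activation
   into an estimated grasp force;
3. the Hill force–velocity relation converts the force history into an
   estimated muscle stiffness;
4. a fuzzy rule base maps the stiffness estimate (level and rate of
   change) to the stiffness parameter of an impedance controller;
5. the impedance controller drives a one-actuator linkage finger
   against a virtual elastic object, with a Lyapunov function logged
   to certify closed-loop stability.

The intent the wearer expresses through their muscles — squeeze softly
and slowly, or firmly and quickly — is thereby transferred to the
finger: soft, fragile objects receive a small desired force and a soft,
slow controller; rigid objects a large force and a stiff, fast one.

# The muscle model

## Bond-distribution dynamics

Cross-bridge theory describes the fraction `p(x, t)` of actin–myosin
bonds attached at normalized bond displacement `x`:

    dp/dt − v(t) ∂p/∂x = r(t) f(x) [1 − p] − g(x) p

where `r(t) ∈ [0, 1]` is neural activation, `f` and `g` are attachment
and detachment rate functions, and `v(t)` is the filament sliding
velocity. We adopt the classical piecewise-linear rates: `f(x) = f1·x`
on the power-stroke region `0 ≤ x ≤ 1` (zero elsewhere), `g(x) = g1·x`
for `x ≥ 0` and the fast constant `g2` for `x < 0`. Muscle force is
the scaled first moment `F = force_scale · ∫ x p dx`, and velocity is
closed through the Hill hyperbola

    v(F) = vb (F0 + Fa) / (Fa + F) − vb ,

so that `v(F0) = 0` and lighter loads shorten faster.

The activation itself comes from the filtered sEMG level `α(t)` through
the exponential shape nonlinearity
`r = (e^{γα} − 1) / (e^{γ} − 1)`, with `r = α` as the analytic `γ → 0`
limit. The default `γ = −3` makes `r` concave: low-effort contractions
are amplified, which matches the operating range of everyday grasping.

## Numerical treatment and model reduction

The PDE is discretized by Chebyshev collocation on `x ∈ [−1, 2]`
(64 points by default) with Clenshaw–Curtis quadrature for the force
functional; `solve_full_pde()` integrates the bilinear
(activation × state) dynamics with fixed-step RK4 and clips the state
to `[0, 1]` after each step. An explicit stability bound is checked up
front and a violation reports the largest admissible step.

For control use the model is reduced in two steps, mirroring the
spectral-plus-balanced-truncation route: the linear system frozen at a
nominal activation `r_nominal` and zero velocity is balanced (square
root method; the Lyapunov equations are solved through the
eigendecomposition of the diagonal reaction operator) and truncated to
3 states; the advection operator is projected onto the same basis,
giving

    da/dt = (A0 + v(t) A1) a + B r(t),      F = force_scale · C a .

Two numerical choices deserve comment:

* **Freezing the bilinear term.** The reaction term `r f p` is
  bilinear, but the reduced model must carry its activation dependence
  through the input matrix alone. Freezing at `r_nominal = 0.7`
  (mid-range of grasp efforts) bounds the steady-state force error of
  the linearization by about 3% across the whole activation range
  *provided detachment dominates attachment*. This motivates the
  default rate balance `f1/g1 = 0.1` (`f1 = 5`, `g1 = 50`,
  `g2 = 100 s⁻¹`): with attachment-dominated rates (as in the original
  1957 parameterization) the frozen-input linearization misstates
  sub-maximal force by tens of percent, while the detachment-dominated
  balance keeps the order-3 model within the 5% envelope that the test
  suite verifies against the full PDE on ramp-and-hold profiles. These
  are engineering defaults, not subject-identified constants; every
  rate is configurable.
* **Force calibration.** `force_scale` is calibrated per grid so the
  full-activation isometric force equals the Hill `F0` under the same
  quadrature used in simulation. Because the isometric bond
  distribution is constant on the power-stroke region, this makes
  terminal isometric forces exactly grid-invariant, which the grid
  convergence test exploits.

The isometric fixed point `p = r f / (r f + g)` is reached pointwise at
a rate `r f + g` that vanishes toward `x = 0`; verification runs
therefore integrate for ~10 s on the 64-point grid (whose slowest node
sits near `x = 0.02`).

# Stiffness estimation

Muscle stiffness is the force change per unit muscle shortening over a
sliding window `T` (default 0.1 s):

    K(t) = ΔF / ΔX ,   ΔX = vb ∫_{t−T}^{t} (F0 − F) / (Fa + F) dτ ,

with `ΔF = F(t) − F(t−T)`. Relaxation (`ΔF ≤ 0`) maps to `K = 0`
because the stiffness feeds a controller gain that must stay
non-negative; a window with no measurable shortening (force pinned at
`F0`) has undefined stiffness and raises an error. The normalized
estimate is `Ka = K / Kmax`, with the rate
`dKa = clamp((Ka(t) − Ka(t−T)) / T / 5 s⁻¹, 0, 1)`.

`Kmax` plays the role of the subject's maximum measured stiffness. It
is obtained by `calibrate_kmax()`: a brisk voluntary effort, modeled as
a 0.4 s ramp to `r = 0.9`, run through the same estimator. Two details
matter. An *instantaneous* step would concentrate the entire force rise
in one window and produce a maximum several orders of magnitude above
anything a voluntary contraction yields, crushing all everyday `Ka`
values to ~10⁻⁴; and driving the model all the way to `r = 1` parks
the force on the `F0` saturation where shortening vanishes and the
estimator degenerates. The 0.4 s / 0.9 calibration avoids both while
remaining a plausibly "maximal" effort.

# Fuzzy gain scheduling

`(Ka, dKa)` are mapped to the controller stiffness parameter `K̃d`
through a 5×5 rule base over the linguistic levels VS, SL, ME, RL, LE
with symmetric triangular membership functions (50% overlap, outer
sets saturating beyond their peaks, partition of unity everywhere).
The consequents are non-decreasing along both inputs: stiffer, faster
rising muscle activity always asks for an equal-or-stiffer controller.

**Inference scheme.** The classical Mamdani pipeline (min implication,
max aggregation, center-of-area defuzzification) is *not* monotone for
this rule table: measured violations reach ~1.6 on the 0–100 output
scale, an artifact of max-aggregation overlap and of consequents that
jump two levels between adjacent cells. Since monotonicity is the
property the schedule exists to provide, the default inference uses
product rule firing with center-average defuzzification (the weighted
mean of consequent-set centroids). With partition-of-unity inputs this
is exactly bilinear interpolation of the rule table, hence provably
monotone; the classical scheme remains available as
`infer_kd(..., method = "centroid")` for comparison.

**Universes.** The output universe is `[0, 100]`. The input universes
default to `[0, 0.08]` for `Ka` and `[0, 0.05]` for `dKa` — the spans
these estimates cover between the softest and firmest everyday grasp
in the demo suite. The choice is consequential: the low corner of the
rule table (VS/SL × VS/SL) is uniformly VS, so universes much wider
than the operating range would collapse the whole suite into one cell
and the schedule would stop discriminating. Inputs beyond a universe
saturate its LE set.

# Finger plant

The finger is a five-link planar chain driven by one actuated
coordinate `θ1`; a coupling map `θn(θ1)` (affine by default, with the
distal links rotating faster than the drive) stands in for the closed
linkage. All kinematics are evaluated as planar rotations in complex
arithmetic with first and second `θ1`-sensitivities carried
analytically, so the reduced Lagrangian quantities are closed form:

    M(θ1) = Σ In (dθn/dθ1)² + mn |d c̃n/dθ1|²
    C(θ1) = dM/dθ1 / 2
    G(θ1) = Σ mn g dỹn/dθ1
    M θ̈1 + C θ̇1² + G = τ1 − Jᵀ F − f .

The contact force enters the joint equation through `JᵀF` — with a 2×1
contact Jacobian this is the only dimensionally meaningful projection,
and it is used consistently in the plant and in the controller's
compensation term. The default geometry (links 10–40 mm, ~60 g total,
slender-rod inertias, millimeter centroid offsets) is a plausible
finger-scale parameter set; every quantity is configurable and the
coupling map accepts arbitrary differentiable functions, so a measured
four-bar closure can be substituted without touching the dynamics.
Friction is viscous plus smoothed Coulomb
(`f = 0.02 θ̇1 + 0.002 tanh(θ̇1/0.01)` N·m).

Correctness is guarded by oracles rather than by construction: the
Jacobian, `C`, and `G` are compared against central differences, and a
frictionless free swing started near the hanging equilibrium must
conserve total energy to 10⁻⁶ relative over 1 s at RK4 step 10⁻⁴ s.

# Impedance control and stability instrumentation

With error `e = θ1 − θ1d`, the command

    u = M Γ1 + Jᵀ F + f̃ + C θ̇1² + G,
    Γ1 = θ̈1d − Md⁻¹ [Bd ė + Kd e + (F − Fd)]

imposes the desired error dynamics `Md ë + Bd ė + Kd e = −(F − Fd)`
under perfect model compensation (the default for analysis runs; the
compensation terms can be detuned for robustness studies). Scheduling
sets `Fd = F_est` and `Kd = 0.3 K̃d`; the 0.3 gain maps the fuzzy
range onto `Kd ∈ [0, 30]` N·m/rad, large enough to shade the contact
response but small enough that the desired-force term, not the
stiffness term, dominates the contact equilibrium
`e* = Fd / (Kd + K_eff)` — which keeps the applied force ordered by
the wearer's intent. Damping defaults to the critical value
`Bd = sqrt(4 Md Kd)` (with a small floor), which suppresses ringing
and makes faster scheduling settle strictly faster.

Against a linear-spring object the contact force is `K_eff e` around
the equilibrium (`K_eff` the object stiffness projected to the joint
through the contact Jacobian frozen at the touch angle), and the
closed loop is the scalar LTI system

    ë + Bd/Md ė + (Kd + K_eff)/Md e = 0 .

Its Lyapunov pair

    V = ė²/2 + (Kd + K_eff)/Md · e²/2 ,    V̇ = −Bd/Md ė²

is non-negative / non-positive whenever `(Kd + K_eff)/Md > 0` and
`Bd/Md > 0`. `simulate_impedance_response()` integrates exactly this
system (RK4, default step 10⁻⁴ s) and samples `(V, V̇)` at 1 kHz; the
test suite checks the trajectory against the closed-form LTI solution
to 10⁻⁶ RMS and the sampled `V` for sample-to-sample monotonicity.
Note that the certificate concerns the *autonomous* error dynamics:
once gains are latched and the desired force is constant, `V` measured
about the contact equilibrium decays monotonically; while the
schedule is still moving the system is forced and no monotone `V` is
claimed.

# The closed-loop scenario engine

`run_grasp()` executes one grasp at 1 kHz (the control rate; plant,
muscle model and logs share the 1 ms step, and the control law is
evaluated at every integrator stage rather than held over the step —
a zero-order hold at this rate would visibly corrupt the
perfect-compensation cancellation that the analysis relies on):

* **Approach.** Before contact the drive applies a low constant torque
  (0.01 N·m, gravity compensated), closing the finger slowly.
* **Contact and latching.** The surface crossing angle is located
  geometrically; the first 1 kHz sample whose contact force exceeds
  0.05 N declares contact. At that instant the desired angle freezes
  at the contact angle, and the gains latch: `Fd` from the current
  force estimate, `K̃d` from the fuzzy schedule evaluated at the
  running peaks of `Ka` and `dKa` (the stiffness estimate is
  transient — it lives in the force rise — so its peak carries the
  expressed grip intent). Latching at contact reflects the
  adjust-on-contact control policy and makes the post-contact loop
  autonomous, so the logged Lyapunov certificate applies.
* **Contact model.** The object is a one-sided linear spring on the
  joint-space penetration with the Jacobian frozen at the touch angle,
  i.e. the linear contact law taken literally; this keeps the contact
  loop exactly LTI. The geometric normal-spring contact
  (`contact_force()`) is used to locate the surface.
* **Log.** 1 kHz rows with angle (degrees), contact force, commanded
  torque, proxy motor current/voltage (affine in torque and speed,
  for log compatibility only), the estimation chain (`F_est`, `Ka`,
  `dKa`, `K̃d`), the Lyapunov pair and the contact flag.

Scenario profiles plateau before contact (~1.26 s at the default
approach torque) so the latched `Fd` reflects the plateau effort.

# The synthetic sEMG generator

Each channel is zero-mean Gaussian noise band-limited to 20–95 Hz at
the 200 Hz armband rate, normalized to unit RMS and multiplied by a
piecewise-linear contraction envelope, plus an additive band-limited
noise floor (RMS 0.01). This reproduces the amplitude statistics that
the downstream envelope detector (full-wave rectification, zero-phase
2nd-order Butterworth low-pass at 2 Hz, division by the MVC level 0.8
≈ the rectified mean of a unit-RMS channel) actually uses: RMS
proportional to the envelope, hence `α ≈` envelope level. It does
*not* emulate motor-unit firing structure, electrode placement,
crosstalk, motion artifacts, or fatigue-related spectral compression —
so passing tests demonstrate correct signal processing and model
behavior under the assumed amplitude model, not robustness to real
recording pathologies. Generation is bit-reproducible per seed.

The four demo scenarios hold the study conditions fixed: envelope
plateaus 0.04 / 0.07 / 0.10 / 0.14 of MVC with rise times 0.45 / 0.35
/ 0.25 / 0.15 s (softer objects are gripped more gently and more
slowly), against object stiffnesses 300 / 600 / 1200 / 2400 N/m. Under
these conditions the estimated grasp forces land in the
few-newton range of published human measurements and the stiffness
estimates span roughly 1–8% of the calibrated maximum; the suite
asserts the *orderings* — estimated stiffness and applied force
strictly increase, settling time strictly decreases, scheduled
stiffness never decreases from the softest to the hardest object —
not the absolute values, which depend on subject-specific muscle
constants that are not public.

# Problem sizes and runtime

Defaults keep every analysis desk-scale: 64 collocation points
(32 where a coarser grid suffices for an oracle comparison), order-3
reduced models, 2–3 s simulations at 1 kHz, the full-PDE reference at
1 ms steps, and the scalar stability runs at 0.1 ms steps. The whole
test suite, including the four-object demo and three full-PDE
comparisons, completes in well under a minute on one core.

# Known limitations

* The reduced model's `A1` projection freezes the balanced basis at
  zero velocity; large sustained shortening rates would degrade it.
* The scheduling universes and `Kmax` calibration are tied to the
  grasp-effort range; a different muscle parameterization warrants
  re-deriving both (`calibrate_kmax()` automates the latter).
* The contact model is a frictionless normal spring without
  slip, rolling, or viscoelasticity; settling-time comparisons across
  objects assume this idealization.
* Steady-state force tracking has the usual impedance-control offset
  `F_ss = Fd K_eff / (Kd + K_eff)`; no integral action is included.
* One finger, planar, with an affine coupling surrogate for the
  closed chain; the optional adaptive-phase mode switch of the real
  mechanism is representable as a change of coupling map but is not
  exercised by the demo suite.
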