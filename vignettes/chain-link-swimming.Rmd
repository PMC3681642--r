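---
title: "Chain-link models of undulatory swimming: methods and design"
author: "swimchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain-link models of undulatory swimming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swimchain)
```

## The model

`swimchain` treats an undulatory swimmer — an eel, a larval zebrafish, a
robotic undulator — as a forced damped oscillation problem.  The body is a
planar chain of `N` rigid cylindrical links of total length `L` and radius
`r`.  Adjacent links are tied together at their common joint by stiff
penalty springs: rather than eliminating the joint constraint forces
exactly, a spring of stiffness `k_spring` (with a parallel damper acting on
the gap rate) pulls the two endpoints together whenever they try to
separate.  Each link obeys a planar Newton–Euler balance

* translational: link mass times acceleration = resistive drag + joint
  spring forces at the two ends,
* rotational: link inertia times angular acceleration = moments of the
  joint forces + the viscoelastic muscle moment + the distributed drag
  moment,

with free ends (the missing joint terms of links 1 and `N` are zero).
Muscles act through a preferred curvature `kappa0`: the joint moment is
`M_j = E Ic (kappa0_j - kappa_j) - delta * d(kappa_j)/dt`, so torque is
produced whenever the realized discrete curvature
`kappa_j = (theta_{j+1} - theta_j)/ell` deviates from the activation
program.  Swimming is actuated by a head-to-tail traveling wave of
preferred shape `h(x, t) = B sin(2*pi*(x/lambda - f t))` whose
second-derivative curvature is evaluated at the joints; the wavespeed is
`f*lambda` and the body swims opposite to the wave.

Two resistive drag laws cover the Reynolds-number range: a quadratic
cross-flow (Taylor) law for intermediate-to-high Re, with normal
coefficient `Cf` on the drag-coefficient plateau (0.9–1.1) and a laminar
skin-friction tangential term, and the linear anisotropic slender-body
(Lighthill) law for low Re with

    CN = 4*pi*mu / (log(2*Lambda/r) + 1/2),
    CT = 2*pi*mu / log(2*Lambda/r),      Lambda = 0.09 * lambda.

Anisotropy `CN > CT` is what makes undulation propulsive.

## Leading-order dynamics and the steady-velocity formula

Linearizing in the link inclinations, the transverse and rotational
equations become a linear spring–inertia–damper system driven by the
muscle program, while the axial equation is driven one-way by the source
term `(CN - CT) * v * theta`.  Averaging the axial equation over links and
one cycle gives the closed-form steady speed

    U = (CN - CT)/CT * <v * theta>,

the body- and cycle-average of transverse velocity times inclination.  Two
nulls follow immediately and are tested as properties: isotropic drag
(`CN = CT`) cannot swim, and kinematics with `v` and `theta` in quadrature
cannot swim.  `steady_velocity_estimate()` evaluates both the closed form
and the direct COM average on the same steady window (exactly one forcing
period, per the averaging convention) and they agree within 1% of the
wavespeed on leading-order runs.

A subtlety worth recording: the naive estimate obtained by assuming the
body exactly follows its preferred shape overpredicts `U` by roughly a
third.  The missing physics is whole-body recoil — the rigid translation
and rotation response that the free body superimposes on the prescribed
wave — which `integrate_chain()` captures and which reduces `<v*theta>`.

## Study conditions

Two canonical cases ship with the package:

* `validation_case()`: L = 20 cm, N = 40, r = 1 cm, E = 0.7 MPa, water, a
  2 Hz wave of amplitude 2.5 cm (or 3.5 cm), Taylor drag; wavespeed
  40 cm/s.  Used for the penalty-vs-constrained validation, the power
  ledger, and the frequency/stiffness sweeps.
* `zebrafish_case()`: L = 1 cm, N = 40, r = 0.05 cm, E = 0.7 MPa, water, a
  20 Hz wave, Lighthill drag; wavespeed 20 cm/s.  The wave amplitude is not
  part of the published parameter set; the package uses `B = 0.125 L`, the
  same amplitude-to-length ratio as the validation wave.  With it the
  leading-order and nonlinear models reach normalized speeds of about 0.092
  and 0.064.

Unprinted constants are chosen once, as follows, and are all exposed as
arguments:

* `k_spring` is calibrated, not guessed: `calibrate_k_spring()` doubles the
  stiffness until the maximum joint gap during a short probe run stays
  below `1e-3 * ell` — the requirement is exactly "the joints do not open".
* `zeta_joint = 1`: each penalty spring carries a parallel damper that
  critically damps the constraint-violation coordinate.  Physical motions
  keep the gap closed, so the damper does not act on them; it removes the
  undamped gap oscillations that the pure-spring penalty would otherwise
  ring at.
* `delta`, the Kelvin–Voigt tissue viscoelasticity, defaults to the value
  that places a 0.7 damping ratio at the shortest bending wavelength the
  chain can represent (`beta = pi/ell`).  Because curvature-rate damping
  scales as `beta^2`, the low deformation modes that carry the swimming
  motion keep damping ratios of order 1e-3 and their frequencies are
  unaffected; only unresolvable grid-scale ringing is suppressed.
* Activation programs ramp up smoothly over one period
  (`ramp_periods = 1`); an instantaneous switch-on excites every bending
  mode of the body at once.  The steady cycle is unchanged.

## Numerics

The equations are integrated with deSolve.  The default is adaptive
Dormand–Prince (`"ode45"`) with the step bounded by 1 ms, `rtol = 1e-6`,
`atol = 1e-9`.  The low-Reynolds zebrafish case is bending-stiff (the link
inertia is tiny relative to `E Ic`, putting grid-scale bending modes near
1e6 rad/s), so its runs use `method = "bdf"`: lsode restricted to order 2
— the A-stable orders, since the stiff modes are oscillatory and lightly
damped — with the analytic Jacobian assembled in compiled code.  Typical
problem sizes: 16 periods (0.8 s) at N = 40 for the zebrafish runs, 17
periods (8.5 s) for the power ledger (axial momentum settles with a ~5 s
time constant), 5 periods per grid point in the sweeps, six-point grids.

The constraint-elimination oracle integrates the exact kinematic-joint
dynamics in generalized coordinates (head point plus link angles) with the
joint forces projected out; it has no penalty stiffness and serves as the
ground truth that the penalty trajectories approach monotonically as
`k_spring` grows.

## Modal analysis

Differentiating the leading-order transverse/rotational equations once
more yields `M w'' + C w' + K w = F(t)` in the stacked velocity variables,
with diagonal `M`, symmetric `K` (penalty + elastic), and `C` collecting
transverse drag, rotational drag `CN ell^3/12`, viscoelasticity, and the
joint dampers.  `eigenmodes()` decomposes the first-order form;
underdamped modes are conjugate pairs counted once, sorted by natural
frequency `|Im(lambda)|/(2*pi)`.  In the stiff-joint limit the undamped
frequencies converge to the free-free Euler–Bernoulli beam values
(`f1 = (4.730/L)^2 sqrt(E Ic / (rho pi r^2)) / (2 pi)`, 235.5 Hz at the
zebrafish parameters), which is the package's independent check on the
assembly.  At the calibrated (finite) penalty stiffness the census at the
zebrafish parameters is 51 underdamped and 58 real modes with
`f1 ~ 228 Hz`; the corresponding published census (47 underdamped, first
frequencies 1435.01 and 3889.01 Hz) evidently reflects an unprinted
mass or stiffness convention — notably its frequency *ratio* 2.71 matches
the free-free beam ratio 2.76 within 2% while the absolute scale is about
6x the value implied by a neutrally buoyant uniform cylinder at the
printed geometry and modulus.  The package reports its own honestly
computed values.

Because the actuation frequency (20 Hz) sits far below the first natural
frequency, the forced response concentrates in the lowest few modes; this
is tested as >90% of response energy in the five lowest underdamped modes.
For nonlinear runs, where the damping matrix is state-dependent, the
kinematics are instead projected onto free-free beam eigenfunctions
(`beam_mode_projection()`, rigid components removed, modes limited to 8
before hyperbolic cancellation degrades the analytic forms).

## Power bookkeeping

Multiplying the rotational, transverse, and axial equations by their
velocities and cycle-averaging yields the power ledger: activation power
`E Ic kappa0 * d(rel angle)/dt` enters the rotational channel, the joint
springs hand it to the transverse and axial channels, and drag dissipates
it — overwhelmingly (>95% here) in the transverse direction, not the
axial one.  At steady state the three pair identities
(`P_muscle ~ -P_elastic_rot`, `P_elastic_trans ~ -P_drag_trans`,
`P_elastic_axial ~ -P_drag_axial`) hold within 2%.  `P_elastic_rot` is
defined as the entire non-muscle side of the rotational equation, so it
also contains the rotational-drag and viscoelastic losses (a few percent);
the package's energy-conservation test therefore checks the pair
identities rather than a three-term global sum that would only close if
those losses were exactly zero.

## Passive swimming

A rigid link forced by a transverse force and a phased torque has
closed-form sinusoidal steady responses; the time-averaged axial balance
gives `U` as a function of the force–torque phase, with an explicit null
phase.  The numerical sweep reproduces the analytic curve within 2% once
the forcing is ramped on — an abrupt start leaves the link with a
permanent mean-orientation offset that nothing restores.

For a link in a traveling transverse flow the drag is taken relative to
the link-averaged flow, and the flow exerts a moment through its first
moment along the link.  A clean result falls out of the uniform-rod
algebra: with the distributed-drag rotational damping `c_r = CN L^3 / 12`,
the drift cancels *identically* (`m c_r = I CN L` puts angle and relative
transverse velocity exactly in quadrature).  Any non-uniformity — taper in
mass or drag — breaks the degeneracy, so `c_r` is exposed and the shipped
demo uses half the uniform value.  A flexible chain in a short-wavelength
flow (`lambda_f = L/2`) needs no such asymmetry: it deforms, acquires
correlated `v` and `theta`, and swims passively with no muscle input, the
closed-form estimate again matching the simulated average within 2%.

The demo drag coefficients (`CN = 10`, `CT = 5` dyn s/cm^2) are the scale
of the quadratic cross-flow law linearized about the 10 cm/s flow
amplitude; with the actual water-viscosity slender-body coefficients the
20-cm rod is so inertia-dominated that transients outlast any reasonable
demonstration window.

## Gait optimization

The five-parameter gait family prescribes midline curvature
`kappa(s,t) = K(s)/L * sin(2*pi*(t/T - tau*s/L))` with `K(s)` the cubic
through control amplitudes at `s = 0, L/3, 2L/3, L`.  `objective_J()`
rebuilds the unit-speed midline at each phase, removes the rigid
components, and evaluates `J = -<v*theta>` from the prescribed kinematics
alone — no swimming simulation.  `optimize_gait()` runs bound-constrained
L-BFGS-B (deterministic; optional extra starts guard against local
maxima).

The default bounds (`K_i` in [0, 2.5], `tau` in [0.8, 2]) are a
domain-of-validity choice, made after observing that unconstrained
amplitude maximization drives tangent angles past a radian, where the
kinematic objective stops being a proxy for dynamic swimming speed and the
nonlinear replay actually slows down.  Within the bounds the relative
claims hold: the optimized gait has a higher `J` than the reference gait
`(1, 1.5, 2, 2.4; tau = 1)` and swims faster when replayed as preferred
curvature in the nonlinear model (0.31 vs 0.12 normalized at the
validation-case parameters).  `J` is invariant under time translation and
flips sign exactly under wave-direction reversal (`tau -> -tau`).

## What the tests do and do not show

All inputs here are synthetic by construction — the package's study
conditions are parameter sets, not data.  The generator (the traveling
wave, the gait family, the sinusoidal flow) emulates smooth periodic
actuation and flow; it does not emulate vortex wakes (the flow has no
memory), three-dimensional effects, tapered bodies, self-contact, or
sensory feedback.  Passing tests show internal consistency of the models
and agreement with the published reduced-order numbers, not fidelity to
any particular animal.

## Known limitations

* Resistive drag only; no added-mass/reactive forces and no wake memory.
* Planar motion, uniform circular cross-section.
* The published modal census/frequencies are not reproducible from the
  printed parameters (see above); the package reports its own.
* The Taylor tangential friction coefficient and several demo-scale
  constants are documented defaults, not published values.
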