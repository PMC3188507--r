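---
title: "Bistable activation waves in B-cell receptor signaling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistable activation waves in B-cell receptor signaling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrwave)
```

## The biological system and the model

B-cell activation begins with the aggregation of B-cell receptors (BCR) after
antigen binding. The receptors' ITAM motifs are phosphorylated by Src-family
kinases (SFK: Lyn, Fyn, Blk), and phosphorylated ITAMs in turn recruit and
activate more kinase — a positive feedback. Two nonlinearities accompany the
feedback: full receptor activation requires *double* ITAM phosphorylation,
and kinase dephosphorylation by a limited phosphatase pool follows
Michaelis–Menten kinetics. Together they make the receptor–kinase system
bistable: a resting (*inactive*) and a signaling (*active*) state coexist,
and a sufficiently strong local stimulus launches a traveling activation
front that converts the entire cell — an all-or-nothing switch triggered by
a cluster containing a tiny fraction of the receptors.

`bcrwave` implements this system in three tiers on the unit sphere (lengths
scaled by the cell radius `R*`, time by the receptor dephosphorylation rate
`gamma*`, kinase by its total density, receptors by their mean density):

* **well-mixed** (infinite diffusion): two ODEs,
  `dK/dt = eta a R (1-K) - b K/(1+K/H)`,
  `dR/dt = (K^2 + c0)(p - R) - R`,
  with `eta = 3/(1-r_n^3)` the surface-to-volume factor of the cytosolic
  shell outside the nucleus of radius `r_n`;
* **membrane** (kinase tethered to the membrane, the biologically favored
  case for SFK): the same kinetics with the axisymmetric Laplace–Beltrami
  diffusion `alpha^-2 (sin t)^-1 d/dt(sin t dK/dt)` added to the kinase
  equation and `a = 3/(1-r_n^3)`;
* **cytosol** (kinase free to diffuse): `K` obeys
  `dK/dt = alpha^-2 Lap K - b K/(1+K/H)` in the shell between nucleus and
  membrane, receptors live on the membrane, and the coupling is the
  nonlinear Robin boundary condition `alpha^-2 dK/dn = a R (1-K)` (flux
  proportional to active receptors and *inactive* kinase), with zero flux
  through the nuclear envelope.

The dimensionless diffusion parameter is `alpha = R* sqrt(gamma*/d*)`; the
model diffusion coefficient is `alpha^-2`, so large `alpha` means slow
diffusion. On a 6 um cell with `gamma* = 1/s`, `d* = 36, 4, 0.36, 0.04,
0.0013` um^2/s give `alpha = 1, 3, 10, 30, 167`.

Receptor clustering is static (ligand binding and the aggregation process
itself are outside the model's scope): a fraction `F` of all receptors sits
in a polar cap covering `1/i` of the membrane, giving local density
`(1-F) + F i` inside the cap and `(1-F)` outside, conserving the total
receptor number.

## Reconstructed kinetic forms

Two elements of the kinetics deserve an explicit statement because more than
one algebraic form is compatible with their verbal description, and the
package fixes them by validation against the quantitative anchors of the
system (the `b` operating band 6–25, the propagation-failure threshold near
19, the planar front-speed prefactor near 0.5, and the minimal membrane
cluster near 0.003):

* **Kinase dephosphorylation** is written `b K/(1 + K/H)`: `b` is the
  *pseudo-first-order* rate constant at low substrate and the rate saturates
  at `b H` when the phosphatase pool is busy (`K >> H`, with `H = 0.1`).
  The alternative normalization `b K/(K + H)` (maximum rate `b`) compresses
  the bistable window tenfold and puts every anchored `b` value outside it.
* **Spontaneous receptor activation** enters additively,
  `(K^2 + c0)(p - R)`: the kinase-driven double-phosphorylation channel
  `K^2` plus a basal channel `c0 = 0.01` (the activity of unphosphorylated
  kinase, ~100-fold weaker). Folding the basal activity into the per-event
  activity (`(K + c0(1-K))^2`) instead drops the lower fold of the bistable
  window by an order of magnitude and nearly triples the front-speed
  prefactor, contradicting both anchors.

With these forms and `eta a = 21.03` (`r_n = 0.95`) the bistable window is
`b` in `[7.0, 26.7]`, matching the stated operating band, and the measured
planar prefactor is `u0 = 0.48`.

## The b_q calibration

Throughout, `b` is fixed by the `q`-rule: the system must be bistable at the
reference receptor density and become monostable active exactly at a
`q = 1.5`-fold density. This makes the resting cell insensitive to modest
*uniform* receptor-level changes (a 1.4-fold increase relaxes back to the
inactive state) while a local `q`-fold density increase switches the cluster
locus on. Operationally `b_q` is the lower fold of the bistable window
evaluated at `p = q`: `calibrate_b_q()` bisects the root-count transition of
the steady-state equation.

For the membrane tier the bistable window coincides with the well-mixed one
(uniform states are spatially uniform), so the same `b_q` applies at every
`alpha`. For the cytosolic tier the uniform states are *radial profiles*:
kinase produced at the membrane decays towards the nucleus over the length
`1/(alpha sqrt(b))`, so the window shifts upward with `alpha`.
`calibrate_b_q_cytosol()` therefore applies the `q`-rule to the spherically
symmetric steady states, found by continuation in the membrane kinase level:
for each boundary value the interior Dirichlet problem is solved by Newton
iteration on a conservative radial grid, and the zeros of the Robin-condition
residual are counted. At `alpha = 10`, `r_n = 0.95` this gives
`b_q = 15.0` against the well-mixed 10.46; both keep the concentric resting
cell inactive at that geometry, and the package uses the well-mixed rule
where a single `alpha`-independent value is wanted and the radial rule where
the finite-`alpha` window matters (the displacement scenario below).

## Numerical methods

**Membrane / planar tier.** Method of lines on a nonuniform grid over
`[0, pi]`: conservative finite volumes with face metric `sin(theta)`
(pole-regular by construction: the polar control volumes close with zero
flux through the poles) or metric 1 for the planar variant. Receptor
clusters are resolved by geometric grid refinement (at least 25 nodes inside
the cap even for `1/i = 2e-6`; growth ratio 1.12 up to a far-field spacing
of at most `min(pi/400, 1/(3 alpha))`, i.e. a third of the front width).
Time integration is `deSolve::lsoda` with a banded Jacobian (the interleaved
`(K, R)` ordering gives bandwidth 2), `rtol = 1e-8`, `atol = 1e-10`. The
box invariants `0 <= K <= 1`, `0 <= R <= p(theta)` are checked at every
output time to 1e-5.

**Cytosolic tier.** Bilinear (Q1) finite elements on a mapped quadrilateral
meridian mesh in cylindrical coordinates, with the axisymmetric weight `rho`
in the weak form; one code path covers both the concentric shell and the
displaced nucleus (for each polar ray the radial coordinate is mapped
between the local nuclear surface and the membrane, so the thin gap always
keeps its `n_r` cells). The lumped mass matrix and a boundary mass on the
outer arc couple the receptor ODEs (living on boundary nodes) to the field.
Quadrature is exact enough that the assembled volume and surface agree with
the analytic shell values to 0.1% at the default resolution, and the
stiffness matrix annihilates constants to 1e-10 (discrete zero-flux).
Stepping is IMEX: diffusion, the linearized sink and the linearized Robin
flux are implicit (sparse Cholesky, numeric factor updated every step);
receptor kinetics are integrated exactly over the step for frozen boundary
kinase. The scheme is first-order in time; `dt = 0.05` resolves activation
times to a few tenths of a time unit, and the consistency test against the
well-mixed oracle uses `dt = 0.001` to reach the 1e-3 tolerance.

**Activation criterion.** A run counts as globally activated when the
spatial *minimum* of `K` crosses the midpoint between the two stable
well-mixed kinase levels, with linear interpolation between outputs. In the
cytosolic tier the minimum is taken over the outer-membrane trace: in the
active state the kinase level necessarily decays with depth into a thick
cytoplasm, so an interior minimum would never cross the midpoint even with
the whole membrane active. An R-based criterion can be emulated by passing a
custom threshold to `activation_time()`.

**Bisection drivers.** `critical_fraction_*` bisect geometrically in `F`
(relative tolerance 1e-2), `critical_b` linearly in `b` (absolute tolerance
0.1); both verify the bracket first and report failure sides. Horizons
default to several front transits (`max(300, 10 alpha)`; 800 for
`critical_b`, where near-threshold fronts are slow); a run that has not
swept the domain by the horizon counts as not activated, which biases
thresholds slightly conservatively — the printed tolerances absorb this.

## The straight-front critical b and its geometry

`critical_b(..., geometry = "straight")` treats the domain as a local patch
of membrane: the cluster occupies the length fraction `1/i` at one end and
the background density stays at the cell-wide mean (the aggregated receptors
are drawn from the whole cell, not the patch). With depletion switched on
(`deplete = TRUE`, the default for the spherical geometry where conservation
is global) the planar threshold at `alpha = 10` drops from 19.3 to 17.4 —
the two conventions bracket the physically plausible range, and the
spherical variant additionally carries the curvature penalty near the polar
cluster, which grows as diffusion gets faster (`alpha^-2 cot(theta)`), so
its threshold *increases* with `alpha`. Both variants are exposed; the
curvature-free, undepleted form is the validation default.

## The displaced-nucleus scenario

Displacing the nucleus thins the cytoplasm locally (gap `1 - r_n - shift`),
raising the local membrane-to-volume ratio, and can activate the cell with
*uniform* receptors. The driver needs a `b` inside a three-sided window:
above the finite-`alpha` inactive-existence fold (else the concentric cell
activates spontaneously), below the local fold of the thin gap (else nothing
nucleates), and below the propagation threshold of the *thickest* cytoplasm
(else the activity dome stays pinned at the gap). Under the reconstructed
kinetics the radial `q`-rule value sits above the third bound at
`r_n = 0.9`, `alpha = 10`, so the driver's default is
`b = 1.15 * radial_b_min(params)` — comfortably inside the window: the
concentric control stays inactive while the displaced cell activates fully,
starting at the thin-gap pole and spreading across the thick side.

## What the generators emulate, and what they do not

All inputs are parameter sets and geometry; there is no stochasticity
anywhere (identical configurations give bit-identical outputs). The cluster
model is a static, axisymmetric, sharp-edged cap: it emulates the *result*
of antigen-driven aggregation, not its kinetics, receptor diffusion, ligand
binding, downstream Syk signaling, or stochastic fluctuations of small
aggregates. Passing tests therefore validate the deterministic
reaction-diffusion mechanism — local monostability plus global bistability
plus front propagation — not the molecular noise regime in which very small
immunon-scale clusters (~10 receptors) live.

## Problem sizes and defaults

The shipped defaults are chosen so every result in the test-suite and the
reproduction script is grid- and horizon-converged at desk scale: membrane
grids of 400–900 nodes (refined caps), cytosolic meshes of ~2700 nodes
(301 x 9), `dt = 0.05`, bisection tolerances of 1e-2 (relative, in `F`) and
0.1 (absolute, in `b`). Doubling the membrane grid moves activation times by
under 1%; uniform mesh refinement moves the cytosolic activation time by
under 2%; extending the `critical_b` horizon from 800 to 1500 moves the
threshold by well under its tolerance.

## Known limitations

* The IMEX cytosolic stepper is first-order in time; very tight tolerance
  work should reduce `dt` (cost is linear).
* `alpha = 167` membrane runs need ~1700 nodes and several minutes; the
  suite validates the `alpha` scaling at 1–30 and the 167 case through the
  front-speed conversion instead.
* The exact printed configuration of the two propagation-threshold panels
  (straight vs curved, depleted vs undepleted background) is ambiguous in
  the source material; the package exposes both conventions rather than
  asserting one beyond the validated `alpha = 10` value.
* Non-axisymmetric clusters, deforming membranes and nuclear motion
  dynamics are out of scope (static displaced geometry only).

## A worked micro-example

```{r example, eval = FALSE}
prm <- membrane_params(alpha = 3, r_n = 0.95)
prm$b <- calibrate_b_q(prm, eta = 1)      # 10.461
tidy(bistability_range(prm, eta = 1))     # b_min 6.97, b_max 26.7
traj <- simulate_membrane(prm, receptor_distribution(F = 0.05, i = 1000),
                          t_end = 150)
glance(traj)                              # activated, T_A ~ 30
autoplot(traj)                            # the traveling front
```
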