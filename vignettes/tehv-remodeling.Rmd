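---
title: "Mechano-mediated remodeling of tissue-engineered heart valve leaflets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-mediated remodeling of tissue-engineered heart valve leaflets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tehvsim)
```

## The problem

Tissue-engineered heart valves (TEHVs) are implanted as acellular collagenous
matrices that host cells invade and remodel. Cell traction compacts the
matrix; compaction shortens the leaflets; shortened leaflets stop coapting
and the valve leaks. Whether a TEHV stays competent therefore depends on the
interplay between its *as-manufactured geometry*, the *hemodynamic load*
(2 kPa pulmonary or 10 kPa aortic diastolic pressure), and *cell-mediated
remodeling* of its collagen architecture. `tehvsim` implements a complete in
silico pipeline for this question: parametric half-leaflet geometry
generation for two design families, a fiber-level constitutive and
remodeling model evaluated at finite-element integration points, a
quasi-static geometrically nonlinear solver with inter-leaflet contact, and
the design metrics (regurgitant orifice area, regional stress peaks, fiber
order parameter, cost function) used to rank designs.

## The tissue model

The total Cauchy stress is the sum of three constituents,

$$\sigma = \sigma_{sf} + \sigma_{cf} + \sigma_{ecm},$$

with all fiber quantities carried on $N = 30$ equally spaced directions
$\gamma_i \in [0, \pi)$ in the leaflet plane, spanned by the local
circumferential ($\vec v_1$) and radial ($\vec v_2$) unit vectors.

**Stress fibers.** Actin (total fraction $\phi_a = 0.05$) partitions into
free monomer $\varphi_{mon}$ and polymerized fractions $\varphi_{sf}^i$ with
$\phi_a = \varphi_{mon} + \tfrac1N\sum_i \varphi_{sf}^i$ conserved exactly.
The per-fiber stress is
$\sigma_{sf}^i = \sigma_{max}\,(f_{\varepsilon,a}(\varepsilon^i) +
f_{\varepsilon,p}(\varepsilon^i))\,f_{\dot\varepsilon}(\dot\varepsilon^i)$
with $\sigma_{max} = 40$ kPa, the Green–Lagrange fiber strain
$\varepsilon^i$, and a strain-rate factor. The tensor contribution is
$\tfrac1N\sum_i \varphi_{sf}^i\sigma_{sf}^i\,\vec e_f^i\otimes\vec e_f^i$
with pushed-forward, renormalized directions. Polymerization follows
first-order kinetics whose mechano-regulated coefficient is
$k_0 + k_1\sigma_{max} f_{\varepsilon,a} f_{\dot\varepsilon}$; because the
valve loads and unloads every cycle (period 0.85 s), the fractions are not
integrated through every beat but relax exponentially (time constant
$\tau_{sf} = 5$ min) toward the analytic stationary fractions of the
cycle-averaged kinetics, solved jointly with actin conservation.

**Response functions.** The three stress-fiber factors and the
strain-dependent collagen degradation law are a *pluggable strategy*
(`sf_response_functions()`): every framework-level result in this package
holds for any admissible forms. The shipped defaults are chosen once, as
package defaults, to satisfy the constraints the model imposes on them:

* $f_{\varepsilon,a}(\varepsilon) = \exp(-(\varepsilon/\varepsilon_0)^2)$,
  $\varepsilon_0 = 0.12$ — bounded in $[0,1]$, maximal at the strain of peak
  contraction;
* $f_{\varepsilon,p}(\varepsilon) = (\max(\varepsilon,0)/\varepsilon_1)^2$,
  $\varepsilon_1 = 0.17$ — tension-only passive hardening (the source
  table prints a stress unit for $\varepsilon_1$; the strategy treats it as
  an opaque scale);
* $f_{\dot\varepsilon}(\dot\varepsilon) =
  1/(1 + (\kappa_v\dot\varepsilon)^2)$, $\kappa_v = 50$ s — bounded, even,
  decreasing in rate magnitude, so fast cyclic stretching suppresses both
  fiber stress and mechano-driven polymerization;
* collagen degradation rate $(2/\tau_{cf})/(1 + \exp(\varepsilon/
  \varepsilon_d))$ with $\varepsilon_d = 0.05$ — strictly decreasing in
  fiber strain, bounded by $2/\tau_{cf}$.

The strain-rate surrogate treats the cycle as a triangular wave between the
loaded and unloaded configurations:
$\dot\varepsilon^i = 2(\varepsilon^i_{loaded} - \varepsilon^i_{unloaded})/T$.

**Collagen.** Each direction carries a fraction $\varphi_{cf}^i$
(summing exactly to $\phi_{cf} = 0.5$) and a multiplicative growth stretch
$\lambda_{cf,g}^i$ so the elastic stretch is $\lambda_{cf,e}^i =
\lambda_f^i/\lambda_{cf,g}^i$. Fibers are tension-only exponential:
$\sigma_{cf}^i = k_1\lambda_e^2(e^{k_2(\lambda_e^2-1)}-1)$ for
$\lambda_e > 1$, with $k_1 = 33.01$ kPa, $k_2 = 11.74$. Cells compact
collagen toward the stress balance $\sigma_{cf}^i = \sigma_{sf}^i$ — the
preferred growth stretch solves this balance by safeguarded bisection
(bracket $[10^{-2}, \lambda_{cf}(1+10^{-6})]$, 100 halvings, residual below
$10^{-8}$ kPa) — and only where $\sigma_{cf}^i < \sigma_{sf}^i$; the growth
stretch relaxes with $\tau_\lambda = 1$ h. Turnover degrades each direction
at the strain-dependent rate ($\tau_{cf} = 12$ h scale) and redeposits the
degraded amount isotropically, conserving $\phi_{cf}$ to machine precision.
This is the mechanism behind circumferential alignment: circumferential
fibers are strained more, degrade less, and accumulate.

**Matrix.** The non-fibrous part is a compressible neo-Hookean solid,
$\sigma_{ecm} = \phi_{ecm}(\kappa\,\ln J/J\,I + (G/J)(B - J^{2/3}I))$ with
$\phi_{ecm} = 0.45$, $G = 1$ kPa, $\nu = 0.3$,
$\kappa = 2G(1+\nu)/(3(1-2\nu))$.

All remodeling relaxations are linear with piecewise-constant targets, so
they are integrated *exactly* (exponential updates; two half steps equal one
full step to machine precision). Turnover uses an explicit Euler step with
exact conservation. The internal unit system is mm/s/kPa (forces in mN);
parameters quoted in MPa or per Pa are converted once at construction.

## Geometry

Both design families generate a half-leaflet (symmetry plane $x = 0$,
valve axis $+z$, annulus near $z = 0$, one 120° sector centered on $+y$,
inter-leaflet contact planes $y = \tan 30°\,|x|$), with $R = 11.5$ mm and
$H = 14.3$ mm.

**Design 1** lofts connector curves between a cubic-Bézier attachment curve
(drawn in height/arc-length coordinates and wrapped around the valve
cylinder; shape factor $D_{1,1} \in \{0, 0.5, 1\}$ from narrow `N` to wide
`W` commissures) and a quadratic belly curve in the symmetry plane from the
annulus point $(-R, 0)$ to the leaflet tip, which crosses the valve axis by
0.125 mm and sits $\sin 17°\cdot(\pi R/3)$ below the commissure — the
17-degree free-edge rule. Belly curvature is parameterized by the sag of the
guiding point below the straight chord, levels $\{0, 2.5, 5\}$ mm
(`s`/`m`/`c`); the deepest level is the largest sag for which the default
grid builds without element inversion across all attachment levels and
thickness variants. Each connector ends with a 2 mm blend that turns it
perpendicular to the symmetry plane, so the mirrored full leaflet is
$C^1$-continuous there. A small tip extension (2.01 mm, matching the
Design-2 height increase 16.31 − 14.3 mm) is the increased-coaptation
variant.

**Design 2** samples the elliptic paraboloid
$x^2/D_{2,1}^2 + y^2/D_{2,2}^2 - z = 0$ ($D_{2,1}\in[2.8, 4.0]$
circumferential, $D_{2,2}\in[1.4,2.4]$ radial), rotates it by
$\tan^{-1}(R/2H)$ about the x-axis, displaces points that cross into
neighboring sectors onto the plane $y = \tan 30°\,|x|$ (the initial
coaptation area, held on the plane *exactly*; the fold into it is rounded on
the belly side only, over a 2 mm band, so closure is unaffected), and trims
every ray at the valve cylinder. The surface is meshed as a fan around the
leaflet apex with arc-length-uniform columns and a graded first ring.

Meshing details that matter numerically: the mid-surface is extruded into
8-node or 20-node bricks (default two layers; quadratic bricks are
subparametric — straight-edged — and use the 2×2×2 reduced rule standard
for quadratic bricks in soft tissue work); extrusion directors are the
surface normal field smoothed over a 1.5 mm physical scale (the
averaged-director treatment of folded shells) and projected into the
symmetry plane on that boundary; near the Design-2 apex the coaptation fold
tightens below the half-thickness, and the handful of near-zero-volume
offset slivers this produces are pruned as mesh cleanup. Default surface
sampling (14×14, two layers) gives 338 elements, matching the reference
budget of ~346.

## Mechanics

The solver is total-Lagrangian: internal forces use the first Piola stress
$P = J\sigma F^{-T}$, and the consistent (unsymmetric) tangent
$\partial P/\partial F$ is built by directed numerical perturbation of $F$,
vectorized across all integration points; sparse unsymmetric systems are
solved with `Matrix`. Pressure is a follower load on the arterial surface
with its (unsymmetric) load stiffness. Contact against the rigid
inter-leaflet planes is a nodal penalty with volume-lumped weights, default
stiffness $10^3 G\phi_{ecm}/t$, three regularizations that proved decisive
for robustness, and an optional augmented-Lagrange loop for tight
penetration tolerances:

* a *reference-gap allowance* — nodes of the extruded coaptation sheet that
  start at (or half a thickness inside) the plane are penalized only for
  moving further in, so the as-built valve is exactly in equilibrium;
* a *penetration-side cushion* — the normal traction grows quadratically
  over the first 0.02 mm of penetration, removing the active-set slope
  discontinuity that otherwise makes Newton chatter;
* Newton itself uses a trust-region cap (1 mm per iteration), backtracking
  only on invalid trial states (inversion, runaway exponential stress), and
  falls back to dynamic relaxation with kinetic damping plus a Newton
  polish through snap-through motions, with automatic load-increment
  bisection above that.

Equilibrium is declared at a relative residual of $10^{-6}$. The aortic
protocol ramps 2, 4, 6, 8, 10 kPa over the first five remodeling steps and
holds; pulmonary applies 2 kPa throughout.

**A known limitation, stated plainly.** The printed Design-2 construction
(vertex of the paraboloid at the valve axis) produces, in either axial
orientation, a closed shape whose free edge runs diagonally from commissure
to axis. Central prolapse of such a valve *slackens* rather than tensions
the free edge, and frictionless plane contact cannot resist in-plane
sliding of the coaptation, so the assembled Design-2 valves snap through at
diastolic pressures. The valve height $H$ barely enters the construction
(only through the tilt angle), which reinforces that the printed recipe is
under-determined. The geometry module therefore implements the construction
faithfully — every geometric property holds, including exact closure of all
nine grid variants at rest — while the remodeling study records Design-2
mechanical cells as structured non-convergence outcomes (the same outcome
class used for the thin-leaflet aortic cells). All mechanics-based design
comparisons in the test suite run on the Design-1 family, which is
mechanically well-posed and reproduces the expected directional findings.

## The remodeling loop

`run_remodeling()` staggers mechanics and biology: per step it (1) solves
the loaded (diastolic) and unloaded equilibria at frozen tissue state,
warm-started from the previous step; (2) evaluates per-point loaded and
unloaded fiber strains and the triangular-wave rate surrogate; (3) advances
stress fibers (analytic cyclic equilibrium + exponential relaxation),
growth stretches (stress balance + exponential relaxation) and turnover by
the remodeling step (default 0.5 h); (4) records ROA, belly/free-edge
lengths in both configurations, directional belly compaction, regional
stress peaks and both order parameters. Two stabilizations keep the
staggered coupling well behaved: the stress-fiber relaxation is
under-relaxed to an effective time constant of twice the remodeling step
(with $\tau_{sf} = 5$ min far below any step, the exact update would be a
raw fixed-point iteration of the stimulus–fraction map, which rings), and
the growth stretch carries a move limit of 0.01 per hour (the balance
target is evaluated at frozen strain, so unlimited relaxation overshoots
the self-consistent state). Neither device moves fixed points; the
staggered iterates still alternate mildly around the slow trajectory, so
trend readouts use two-step averages. It stops at equilibrium — relative
change of ROA and unloaded belly length below $10^{-3}$ over a trailing
24 h window, with ROA changes measured against max(mean ROA, 1 mm²) so
closed valves can equilibrate — or at the configured duration.

## Metrics

* **ROA** mirrors the half-leaflet, replicates it to three leaflets by 120°
  rotations, and integrates the star-shaped central orifice by angular ray
  casting from the valve axis ($\tfrac12 r_{gap}^2\,d\theta$, 1440 rays,
  snapping radius $10^{-4}$ mm). It is defined in the valve frame the mesh
  contract fixes (axis $z$, symmetry plane $x=0$), which is what makes it
  rotation-independent; deep slit-shaped gaps between separated coaptation
  lines are captured approximately (radially from the first covered point).
* **Profile lengths** integrate the symmetry-plane and free-edge curves
  with piecewise quadratics (second-order accurate on smooth arcs).
* **Directional compaction** projects per-point deformation gradients of
  the unloaded state on the reference circumferential/radial frames and
  averages logarithmic strains over the belly region. Regions (belly within
  35 % of the symmetry midline; commissure within 15 % and tip within 10 %
  of the leaflet span from their anchor points) are deterministic,
  configurable, and logged in the mesh.
* **Order parameter** $S = \sum_i\varphi^i\cos 2\gamma_i/\sum_i\varphi^i$:
  +1 circumferential, 0 isotropic, −1 radial.
* **Cost** per design: $C_P = ((T_P - P)/N_P)^2$ with batch-range
  normalizers and targets $T_{stress} = 0$, $T_{ROA} = 0$, aggregated as
  $C_{tot} = \sqrt{\sum w_p C_p / \sum w_p}$, computed per
  (design, condition) batch of converged cells.

## Problem sizes used by the test suite

The package's own verification runs at desk scale: material-point checks
use the full 30-direction model; solver verification uses one- and
18-element blocks; the remodeling comparisons use 36-element half-leaflets
(7×7 surface sampling, one layer, linear bricks), 4 h remodeling steps and
3 simulated days — the point in this model's dynamics where compaction,
its radial/circumferential anisotropy, the collagen order parameter and the
pulmonary/aortic contrast are all developed and stable in sign. The mesh
convergence check doubles 36 to 72 elements. These are the package's
standard verification sizes; production studies should use the default
338-element meshes, 0.5 h steps, and run to equilibrium (tens of simulated
days).

## What the synthetic conditions do and do not show

The generator-defined conditions reproduce the study set-up: isotropic
initial collagen (a circumferentially pre-aligned von-Mises-shaped initial
distribution is available via `prealign_kappa`), deliberately high
contractility (40 kPa, a conservative worst case for retraction), fixed
rigid attachment, three-fold symmetry, quasi-static diastole with the 0.85 s
period entering only through the rate surrogate. Passing tests show the
framework's internal consistency and the direction of its predictions;
they do not validate the response-function forms against the (unavailable)
supplementary closed forms, nor do the scaled meshes/durations claim the
magnitudes a full-resolution equilibrium run would give. No fluid dynamics,
no growth (mass addition), no inflammation or scaffold degradation.

## Worked example

```{r example, eval = FALSE}
mesh <- build_design1_leaflet(design1_params())  # 338 elements, 17 deg rule
free_edge_angle(mesh)
#> [1] 17

h <- run_remodeling(
  build_design1_leaflet(design1_params(), n_profile = 7L, n_span = 7L,
                        n_layers = 1L, order = 1L),
  prot = protocol("pulmonary", remodel_step = 4, max_duration = 3))
print(h)
tail(h$history[, c("time_h", "roa", "belly_length_unloaded",
                   "compaction_circ", "compaction_rad", "S_cf")], 1)
```
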