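---
title: "Methods: the coarse-grained viscoelastic cell model"
author: "cellflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coarse-grained viscoelastic cell model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`cellflow` simulates a eukaryotic cell suspended in flow as three coupled
coarse-grained components:

* two closed triangulated membranes (the outer cell membrane and the nucleus
  envelope), each carrying in-plane worm-like-chain (WLC) elasticity, bending
  resistance, global area and volume constraints, and pairwise membrane
  viscosity with matched thermal noise;
* a cytoskeleton of Kelvin-Voigt (KV) bonds — a spring and a viscous damper
  in parallel — connecting a clustered subset of outer-membrane particles to
  nucleus particles, plus an internal nucleus network of KV bonds linking
  most-distant nucleus particles;
* a dissipative particle dynamics (DPD) fluid in which all membrane
  particles are immersed, so cell motion is fully coupled to the flow.

The package provides two virtual instruments — micropipette aspiration and
an obstacle-channel device — and Theret half-space estimators that convert
aspiration traces into whole-cell elastic and viscous moduli.

# The force field

## DPD fluid

Every particle pair within the cutoff $r_c$ interacts through three forces:
a soft linear conservative repulsion $a_{ij}(1-r/r_c)\hat r$, a dissipative
force $-\gamma^D w^D(r)(\hat r\cdot v_{ij})\hat r$, and a random force
$\sigma w^R(r)\theta_{ij}\Delta t^{-1/2}\hat r$ with one standard-normal
draw $\theta_{ij}$ shared per pair per step so the pair force is exactly
antisymmetric.  The fluctuation-dissipation relations $\sigma^2=2\gamma^D
k_BT$ and $w^D=(w^R)^2$ are enforced at construction, with the generalized
weight $w^R(r)=(1-r/r_c)^s$, $s=0.75$.  Integration uses the modified
velocity-Verlet scheme with prediction factor $\lambda$ (default 0.5).

## Membranes

The in-plane shear energy is a sum of per-bond WLC terms
$\frac{k_BT\,l_{max}}{4p}\frac{3x^2-2x^3}{1-x}$, $x=l/l_{max}$, and a
per-triangle term $C_q/A_\alpha$ whose coefficient collects the
$x_0=l_0/l_{max}$ constants; because the energy is stated per current
triangle area, the implemented force includes the full gradient of the
$1/A_\alpha$ dependence.  Bending is $k_b[1-\cos(\theta-\theta_0)]$ over
edge-adjacent triangle pairs with a signed dihedral angle (convex outward
positive; $\theta_0 = 0$ by default, a per-configuration override is
exposed).  Global area and volume constraints are
$k_a k_BT(A-A_0)^2/2l_0^2A_0$ and $k_v k_BT(V-V_0)^2/2l_0^3V_0$.  All force
operators are exact negative gradients; the test suite verifies them
against central finite differences of the energies to a relative error
below $10^{-5}$.

Membrane viscosity acts pairwise on bonded particles,
$f^D=-\gamma^T v_{ij}-\gamma^C(v_{ij}\cdot\hat r)\hat r$ with
$\gamma^T=\gamma^C=\gamma$, paired with a random force built from the
traceless-symmetric projection of a per-bond Wiener matrix.  The printed
form of that force pair in the source literature dots the matrix into the
full separation vector; consistency with the $r$-independent dissipative
coefficients (and the equipartition test below) requires the unit vector,
which is what we implement.  An isolated membrane thermostated only by this
pair equilibrates to $k_BT$ within a few percent.

## Cytoskeleton and nucleus

Each KV bond carries the shared-strain law $\sigma_{tot} = k_s\,\epsilon +
k_v\,\dot\epsilon$ with $\epsilon=(l-l_0)/l_0$.  As a per-bond force we use
the strain-based tension $T=k_s(l-l_0)/l_0+k_v\dot l/l_0$, which makes the
bond response independent of its rest length and hence cell-size invariant;
an extension-based variant ($T=k_s(l-l_0)+k_v\dot l$) can be selected in
the configuration.  Single-bond creep under constant tension reproduces the
analytic solution $\epsilon(t)=(\sigma/k_s)(1-e^{-k_s t/k_v})$ to better
than 1%.

Bond placement: k-means clustering on vertex coordinates selects the
eligible particles (per cluster, the vertex nearest the centroid), spreading
anchors near-uniformly.  Topology `M1` wires each eligible outer vertex to
its nearest eligible nucleus vertex; `M2` (the default, with width $w=5$)
wires it to its $w$ closest nucleus vertices.  `M1` creates nearly straight
three-bond chains that span the cell through the nucleus network and
propagate aspiration stress to the far side of the cell (a concave
far-side artifact); the package exposes a chain-straightness diagnostic and
the tests verify that `M2` lowers it.  The number of eligible outer
vertices is `ceiling(rho * N_outer / w)` and the last one keeps fewer
partners when needed, so the bond count equals `round(rho * N_outer)`
exactly.  The nucleus network uses the same construction within one surface
with *most distant* partners (bonds span the nucleus interior), deduplicated
and topped up with next-most-distant partners until
`round(rho_nucl * N_nucl)` bonds exist.  The nucleus is five-fold stiffer:
`ks_nuc = 5 ks_cyt` is applied at build time, damper viscosities are
shared.  KV dampers carry no thermal noise term (only membrane bonds do);
the resulting slight temperature depression of membrane particles in dense
networks is visible in the `kbt_kin` diagnostic and does not affect the
mechanical measurements reported here.

# Parameters and units

Defaults (simulation units) for the membranes: persistence length
$p=0.00141$, membrane viscosity $\gamma=4$, area constraint $k_A=10{,}000$
(cell) / $5{,}000$ (nucleus), volume constraint $k_V=15{,}000$, maximum bond
length $l_{max}=3$ (cell) / $1.2$ (nucleus), equilibrium bond length
$l_0=0.5$, bending stiffness 65 (cell) / 250 (nucleus); nuclear-cytoplasmic
ratio 0.29, interpreted as a volume ratio (the nucleus mesh is rescaled
after meshing so the meshed volume ratio is exact; a diameter-ratio mode is
available).  Calibrated network parameters: $k_s=120$, $k_v=10$,
$\rho=0.8$ on both networks, topology `M2` with $w=5$, and
$k_s^{nucl}=600$ by the five-fold rule.

Two quantities the model needs are not fixed by those tables and are set
here as package defaults:

* **Thermal energy.** We use $k_BT=0.02$.  The choice matters because the
  WLC stiffness scales as $k_BT/p$: at substantially larger $k_BT$ the
  membrane dominates whole-cell elasticity and the Theret modulus becomes
  insensitive to $k_s$, contradicting the model's central design (the
  cytoskeleton is the main contributor to whole-cell mechanics, and the
  elastic modulus must respond strongly to $k_s$ and $\rho$).
  $k_BT=0.02$ places the defaults in that cytoskeleton-dominant regime.
* **Unit mapping.** `unit_map()` fixes micrometres, pascals and seconds per
  simulation unit (defaults 1 um, 6 Pa, $10^{-5}$ s).  These are nominal:
  desk-scale runs use them only to report physical numbers, and full-scale
  quantitative studies should calibrate pressure and time scales against a
  measured fluid viscosity and the cell's moduli.

DPD defaults: $r_c=1$, fluid density 3, $\gamma^D=4.5$, $s=0.75$,
$a_{ij}=25k_BT/r_c$ for a plain fluid, $\Delta t=0.01$ for fluid-only runs
and $0.005$ for runs containing a cell (stability of the stiffer membrane
and KV modes).

# Virtual micropipette

The pipette is an annular solid block: a mouth plane with a circular bore,
the bore cylinder, and (through the periodic wrap) a rear face that closes
the chamber.  Walls are frozen DPD particles at fluid density within one
cutoff of the surfaces plus analytic bounce-back reflection (position
mirrored, velocity negated).  The suction $\Delta P$ is applied as a body
force on fluid particles inside the tube, scaled by hydrostatic balance
$\Delta P = n f L$ over the forced section; the tube discharges through the
periodic boundary back into the chamber, producing a steady circulation.

Three instrument choices matter at desk scale and are deliberate:

* **A stiff instrument fluid.** A DPD fluid cannot sustain suction beyond
  its own background pressure (it cavitates).  The instrument therefore
  uses a large conservative coefficient ($a=25$ in force units, i.e.
  $1250\,k_BT/r_c$ at the default temperature), giving a background
  pressure around 23 that supports the applied pressure range.
* **Frictionless, non-adhesive walls for the cell.**  Membrane particles
  interact with the pipette through bounce-back only
  (`a_wall_membrane = 0` by default): the physical device walls are treated
  to be non-adhesive, and at coarse resolution discrete wall particles
  otherwise pin the aspirated tongue at the mouth lip.
* **Scaled geometry.**  The wall repulsion layer has thickness $\sim r_c$,
  which does not shrink with the cell; a paper-proportioned bore
  ($R_p\approx0.27R$) on a desk-scale cell would be plugged by it.  Scaled
  mode uses $R_p=0.7R$ and compressed hold/ramp times, with the cell
  starting seated at the mouth; `scaled = FALSE` restores the physical
  pipette radius and protocol timing through the unit map for full-scale
  runs.

Two measurement protocols are provided on top of the geometry above:

* **Fluid method** (default): the cell is immersed in the DPD fluid and the
  suction drives a genuine flow; this is the full physical instrument.
  At desk scale its readings are thermally noisy and, across engine seeds,
  chaotic trajectory divergence can exceed the parameter responses being
  measured.
* **Surface method**: the pressure difference is applied directly as a
  normal surface load on the membrane plug inside the bore (per-vertex
  force $\Delta P \cdot A_0/N_v$) with no explicit fluid; in aspiration the
  fluid's sole mechanical role is to transmit exactly this load.  Combined
  with quenched dynamics (`thermostat_scale = 0`: no random forces, pure
  overdamped relaxation through membrane viscosity and the bond dampers)
  and a quasi-static pressure staircase, the measurement becomes
  deterministic and roughly thirty times faster.  The parameter sweeps use
  this instrument; because it has no fluid it is also free of the
  cavitation ceiling, so creep measurements can use deeper suction that
  engages the cytoskeleton dampers measurably.

The staircase variant (`staircase = n`) replaces the linear ramp by $n$
constant-pressure plateaus; `theret_elastic_steps()` fits the Theret line
through time-averaged plateau positions, suppressing the noise of the
instantaneous maximum-extent statistic.

The trace records the aspiration length $L_p$ (maximum axial extent of cell
particles past the mouth plane) and the normalized length
$L_n=(L_p-L_0)/R_p$, where $L_0$ is the mean $L_p$ over the late part of a
reference hold at a small fraction of the maximum pressure (the protocol's
"minute pressure" reference, 30% of maximum in scaled mode).  In ramp mode
the pressure then rises linearly to the maximum; in creep mode it steps to
a constant value and holds.

# Rheology estimators

The elastic estimator fits a least-squares line to $\Delta P$ versus $L_n$
and reports $E = 3\Phi S/2\pi$ from the slope $S$, with the pipette wall
function $\Phi=2.1$ by default (reported in every estimate; the exact value
used by the original calibration is not documented, and 2.0-2.2 is the
accepted range).  The default fit window $L_n\in[0.2,1.0]$ is the
half-space model's linear regime; desk-scale traces of stiff cells live at
smaller $L_n$ and pass an explicit window.

The creep estimator fits $L_n(t)=L_\infty(1-a e^{-t/\tau})$, the
standard-linear-solid creep solution, and converts via $C=3\Phi\Delta
P/2\pi$: $k_1=C/L_\infty$, $k_2=a k_1/(1-a)$, and apparent viscosity
$\mu=\tau k_1k_2/(k_1+k_2)=\tau k_1 a$.  Self-inversion (generate with the
model, fit with the model) recovers parameters exactly without noise and
within two standard errors under 5% noise; the elastic estimate is
invariant to time rescaling while $\mu$ scales linearly with the clock, as
dimensional analysis requires.

# Obstacle channel

The device is a periodic channel bounded by two plates (bounce-back plus
frozen particles) containing rows of triangular prisms, apex upstream, with
configurable gap, base, row spacing and obstacle count; the physical
device (28 um height, 10 rows of 10 obstacles, 60 um row spacing, gaps
10/12/15 um) is reproduced by `channel_device_paper()` through the unit
map.  The driving body force is calibrated by secant iteration on cell-free
runs until the mean axial fluid velocity matches a target within 2%; in the
low-Reynolds regime the response is linear in the force, so convergence is
immediate.  The transit measurement reports the cell's axial
center-of-mass velocity, the transit time, and the relaxation time:
after each gap passage, the time until the asphericity (from the gyration
tensor of the cell particles) returns to within 5% of its pre-gap excursion
above baseline.  The 5% threshold is an implementation choice exposed as
`relax_frac`; the source experiments define relaxation only verbally as
recovery of the original shape.

# Problem sizes used by the tests

Desk-scale verification uses deliberately reduced problems so the whole
suite runs on one CPU in minutes: thermostat checks on 1,000-3,000 fluid
particles, cells of 4-5 simulation-unit diameter (a few hundred membrane
vertices, mesh edge about $l_0$), aspiration boxes of roughly 2,000-3,500
particles for 10-12k steps, and a two-row single-obstacle-per-row channel.
Parameter sweeps (elastic modulus versus $k_s$, $\rho$, persistence length;
viscosity versus $k_v$, $\gamma$) use three points spanning a factor of
about nine with a shared engine seed per sweep, which cancels most
common-mode noise.  What passes at this scale demonstrates the correctness
of the force field, thermostats, estimators and the directions of the
parameter responses; quantitative agreement with experimental moduli
(hundreds of Pa, tens of mPa s) requires full-resolution cells and the
physical protocol on cluster hardware, plus a calibrated unit map.

# Numerical notes and limitations

* Tie-breaks: nearest/farthest partner ties resolve to the lowest vertex
  index; k-means is seeded from the run seed and re-seeds itself (with a
  message) if a cluster empties.
* Degenerate inputs: overlapping DPD particles get a zero conservative
  force (soft potential) and a counted warning; zero-area triangles,
  overextended WLC bonds ($l\ge l_{max}$) and coincident KV endpoints are
  hard errors naming the element.
* A particle moving farther than $r_c$ in one step, or found deeper than
  $r_c$ inside a wall, aborts the run with a time-step diagnostic.
* Meshes with an exact vertex count are built by subdividing an icosahedron
  and splitting the longest edges in adjacency-disjoint batches, then
  smoothing tangentially; all closed-surface identities hold by
  construction, at the cost of mild edge-length dispersion.
* Size invariance of whole-cell elasticity is a design property of the
  constant bond density $\rho$ and the strain-based bond law, and the
  builder reproduces its premise exactly (bonds per outer particle equal
  across diameters).  At desk-scale resolution, however, the mesh edge
  $l_0$ is fixed while the cell shrinks, so the membrane's share of the
  measured modulus grows for small cells and strict size invariance of the
  Theret estimate is only recovered at full resolution.
* The generator does not model red-cell-like nonspherical rest shapes,
  cytoskeletal remodeling, bond rupture, or adhesion; the supplementary
  three-parameter (standard linear solid) bond law is an extension point,
  not implemented, as the two models were reported to behave similarly.
* Momentum is conserved exactly by all pair forces; global area/volume
  constraint forces conserve it through translation invariance.  Walls and
  body forces inject momentum by design.
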