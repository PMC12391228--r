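# cellflow

`cellflow` is an R package for simulating the mechanics of eukaryotic cells
in flow with a coarse-grained, particle-based model.  It is aimed at
cell-mechanics and microfluidics researchers who want a desk-scale,
fully-tested implementation of the model family used to study how membrane,
nucleus and cytoskeleton properties shape whole-cell rheology.

## The model

A cell is built from three components, all advanced by a dissipative
particle dynamics (DPD) integrator:

* **Membranes.** The outer membrane and the nucleus envelope are closed
  triangulated surfaces.  Each bond carries a worm-like-chain (WLC) energy
  `kBT l_max/(4p) (3x² − 2x³)/(1 − x)` with `x = l/l_max`; each triangle
  contributes a `C/A_α` expansion term; adjacent triangle pairs contribute
  bending energy `k_b [1 − cos(θ − θ₀)]`; and global constraints
  `k_A kBT (A − A₀)²/(2 l₀² A₀)` and `k_V kBT (V − V₀)²/(2 l₀³ V₀)` hold
  area and volume.  Membrane viscosity acts pairwise on bonds,
  `f^D = −γ^T v_ij − γ^C (v_ij·r̂) r̂` with `γ^T = γ^C = γ`, paired with a
  fluctuation–dissipation-consistent random force.
* **Cytoskeleton.** Kelvin–Voigt bonds (spring `k_s` and damper `k_v` in
  parallel, shared strain: `σ = k_s ε + k_v dε/dt`) connect k-means-selected
  outer-membrane particles to their `w` nearest nucleus particles (topology
  M2; the nearest-single-partner M1 variant is provided for comparison).
  Bond density `ρ` = bonds per outer-membrane particle makes mechanics
  independent of mesh resolution and cell size.  An internal nucleus network
  links most-distant nucleus particles with `k_s^nucl = 5 k_s` (the nucleus
  is five-fold stiffer) and the same `k_v`.
* **Fluid.** A DPD fluid (soft conservative repulsion, pairwise dissipative
  and random forces with `σ² = 2γ kBT`, `w^D = (w^R)²`,
  `w^R = (1 − r/r_c)^0.75`), integrated by the modified velocity-Verlet
  scheme, couples the cell to the flow.  Walls are frozen particles plus
  analytic bounce-back surfaces.

Two virtual instruments measure whole-cell rheology: micropipette
aspiration (pressure ramp for elasticity, constant-pressure creep for
viscosity) and a microfluidic obstacle channel (transit velocity and
post-constriction shape-relaxation time).  Theret half-space estimators
convert aspiration traces to moduli: `E = 3ΦS/(2π)` from the ramp slope
`S = d(ΔP)/d(L_n)`, and an apparent viscosity from the standard-linear-solid
creep fit `L_n(t) = L_∞(1 − a e^{−t/τ})`, `μ = τ k₁ a`.

See `vignettes/cellflow-methods.Rmd` for the full account of the force
field, parameters, instrument design and limitations.

## Worked example

Build a small cell with the calibrated parameters, aspirate it, and
estimate its elastic modulus:

```r
library(cellflow)

cell <- build_cell(diameter = 5, ks = 120, kv_damp = 10, seed = 1)
print(cell)
#> <cell_model> 5 um diameter, NC ratio 0.29 (volume)
#>   outer: 365 vertices; nucleus: 161 vertices
#>   cytoskeleton: 292 KV bonds (M2, rho = 0.8, ks = 120, kv = 10)
#>   nucleus network: 129 KV bonds (ks = 600 = 5 x 120)

tr  <- run_aspiration(cell, mode = "ramp", seed = 3)
est <- theret_elastic(tr, window = c(0.02, 2))
print(est)
```

The cell model print shows the mesh sizes, the exact bond count
`round(ρ N_outer) = round(0.8 × 365) = 292`, and the five-fold nucleus
stiffness rule (`600 = 5 × 120`).  The aspiration trace records the applied
pressure and the normalized aspiration length `L_n = (L_p − L_0)/R_p`; the
estimator reports the Theret elastic modulus (in Pa through the package's
nominal unit map) with its fit standard error and the wall function
`Φ = 2.1` used.  Desk-scale cells are deliberately small; quantitative
reproduction of experimental moduli needs full-resolution cells on cluster
hardware (see the vignette).

A command-line interface wrapping the same functions is installed at
`inst/cli/cellflow` (subcommands `build`, `aspirate`, `flow`, `analyze`,
`sweep`).

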