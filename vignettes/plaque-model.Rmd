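---
title: "A free-boundary model of early atherosclerotic plaque growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A free-boundary model of early atherosclerotic plaque growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atherosim)
```

## The model

`atherosim` simulates the earliest stage of atherosclerosis: lipoproteins
leaking through a lesioned endothelium into the arterial intima, their
oxidation by free radicals, and the resulting innate/adaptive immune cascade
that either builds a plaque or resolves it, depending on the blood levels of
LDL and HDL.

The state consists of fourteen transported concentrations/densities (all in
g cm^-3): LDL (`L`), HDL (`H`), oxidized LDL (`Lox`), free radicals (`r`),
macrophages (`M`), MCP-1 (`P`), T cells (`T`), IFN-gamma (`Ig`), smooth
muscle cells (`S`), IL-12 (`I12`), PDGF (`G`), MMP (`Q`), TIMP (`Qr`) and
foam cells (`F`), plus the ECM density `rho`, the tissue pressure `sigma`
and the common cell velocity `u`. Each species obeys an
advection-diffusion-reaction equation on the evolving 2-D intima domain;
cells are advected with `u`, chemicals only diffuse. The network is the
classical one: radicals oxidize LDL (and, more slowly, HDL); ox-LDL recruits
monocytes and is ingested by macrophages, which thereby become foam cells;
activated macrophages and foam cells secrete IL-12, which (with MHC-II
engagement) activates T cells; T cells secrete IFN-gamma, further activating
macrophages; SMCs enter from the media under MCP-1/PDGF chemotaxis and ECM
haptotaxis; MMP and TIMP bind each other and remodel/degrade the matrix.

Two closures couple the populations to the geometry. First, the total
density of cells plus matrix is constant,

  M + T + S + F + rho = 1 g cm^-3,

which the implementation makes *exact by construction*: `rho` is eliminated
(`close_state()` sets `rho := 1 - (M+T+S+F)`) instead of being integrated,
so the closure holds to machine precision at every accepted step. Second,
the intima behaves as a porous medium (Darcy's law): `u = -grad(sigma)`,
with the pressure solving

  -lap(sigma) = f + g  (+ a small correction for the common cell
  diffusivity),

where `f` sums the net cell production terms and `g` is the weighted ECM
turnover. On the lumen-facing free boundary the tissue is held together by
cell-cell adhesion, `sigma = gamma_adh * kappa` with `kappa` the boundary
curvature, and the boundary moves with the normal tissue velocity,
`V_n = -dsigma/dn`. The headline observable is the plaque weight
`W = integral of (M+T+S+F)` per unit vessel depth (the model is 2-D).

Boundary influxes are Robin (flux) conditions `dX/dn + b (X - X0) = 0`:
LDL, HDL, monocytes and T cells enter across the lumen boundary at their
blood values; SMCs enter across the media wall. The monocyte influx rate
rises with local ox-LDL and falls with local HDL; the SMC influx rate rises
with local MCP-1 and PDGF. Lateral boundaries of the channel geometry are
periodic.

## Reconstruction closures and their calibration

The original description of this model fixes the network topology, the rate
table, and the qualitative boundary dependencies, but several functional
forms are not recoverable (saturation/damping factors are described
verbally, and the chemotaxis magnitudes, the radical balance and the
ECM-source magnitudes do not survive as printed numbers). The package
therefore carries a small, explicitly labelled set of *reconstruction
closures* (group `"closure"` in `default_parameters(as_tibble = TRUE)`):

* `s_lip`, `s_cell` — permeability scales converting the tabulated influx
  rates (1/cm) into physical boundary mass-transfer velocities for
  lipoproteins and cells. `s_lip = 1e-3` makes intima lipid levels track
  blood levels with a ~10-day lag; `s_cell = 2.5e-4` places cell
  transmigration in the regime where influx competes with death rates, so
  that the chemoattractant enhancement of monocyte entry actually matters.
* `d_r` — a first-order radical quench (radicals are quenched on sub-second
  chemical timescales; without any quench the radical pool grows without
  bound because lipid oxidation consumes it only at ~1e-7/day). The
  standing radical level is `r0/d_r`.
* `a_M`, `K_MLox` — the monocyte-influx enhancement `1 + a_M * Lox/K_MLox`
  (kept linear so the LDL axis retains leverage at late times).
* `K_actLox` — half-saturation of the macrophage activation state
  `Lox/(K_actLox + Lox)` gating IL-12 secretion: resting monocytes in a
  lipid-free intima do not light the T-cell cascade.
* `H_ref`, `n_H` — the HDL anti-inflammatory Hill factor
  `1/(1 + (H/H_ref)^n_H)` damping monocyte influx, IL-12 production and
  T-cell activation.
* `delta_T` — a constant attenuation standing in for the implicit
  MHC-II/IL-10 factors in T-cell activation.
* `w_ecm` — weight of the ECM turnover term in the pressure source. At the
  tabulated MMP degradation constant the raw term would collapse the domain
  within days under any lipid condition, so it enters with a small weight.
* `gamma_adh` — the adhesion (surface-tension) coefficient. The boundary
  update is explicit, which is stable only for
  `dt < C h^3 / gamma_adh`; `gamma_adh = 1e-9` keeps the curvature
  condition a gentle regularizer at the mesh sizes used here.

These closures were calibrated *once*, against the reported endpoint
behaviour of the three recoverable lipid scenarios — (190, 40) mg/dL
doubling in 300 days, (130, 50) remaining small, (70, 60) nearly
disappearing — using the well-mixed (0-D) reduction of the model, and then
frozen. The same frozen defaults reproduce the scenario endpoints, the
monotone risk-map structure and the sensitivity sign pattern in the full
spatial simulator; no per-result tuning is done anywhere downstream.

## Numerics

Space is discretized with P1 (linear triangular) Galerkin finite elements on
structured mapped meshes. Both supported geometries are star-shaped graphs —
the channel cross-section `y in (0, g(x))` with a Gaussian bump on the free
boundary, and the annulus `f(theta) < r < R` — so mesh generation is a
mapped grid, and *remeshing after boundary motion is re-gridding*: topology,
node counts and the periodic pairing never change, element quality is
bounded by the boundary slope, and field transfer is per-column linear
interpolation (values the domain grew past are extended with the boundary
value). This replaces a general signed-distance remesher; it restricts the
free boundary to graph representations, which is exactly the regime the
model operates in (no plaque splitting or overhangs — these are out of scope
regardless).

Time stepping is backward Euler with the reaction terms split
semi-implicitly: each species' own linear decay (and linearized saturating
sinks) is implicit, cross-species couplings are explicit at the previous
step. The time term uses the lumped mass matrix, making the no-flux
diffusion step exactly conservative. Advection (Darcy drift for cells, plus
chemotaxis/haptotaxis drift for SMCs) is standard Galerkin without
stabilization; the Darcy and chemotactic velocities on the fixture meshes
give cell Peclet numbers well below 1. Negative nodal values after a
transport solve (undershoots near steep layers) are clipped to zero and the
clipped mass is accumulated in the state for inspection.

The pressure problem is solved with `sigma = gamma_adh * kappa` imposed on
the free boundary (curvature by a least-squares quadratic fit over a 5-node
stencil in the local tangent frame, second-order accurate; a circumcircle
construction serves as the test oracle), natural conditions on the media
wall and periodic lateral identification. The free boundary then moves by
the graph normal-motion law `dg/dt = V_n sqrt(1 + g'^2)` (explicit), with a
displacement cap of 20% of the local layer spacing — exceeding it rejects
the step and halves `dt` — and a single 1/4-1/2-1/4 smoothing pass along
the boundary that damps node-scale interface noise.

Linear systems are solved by sparse LU with one step of iterative
refinement and a normwise backward-error check (1e-8). Manufactured-solution
tests verify second-order spatial convergence of both the transport and the
pressure solvers; the conservation, maximum-principle and Robin-equilibrium
properties are tested separately.

Defaults: channel fixture 0.1 cm x 0.01 cm with a 0.005 cm x 0.015 cm
Gaussian bump (no canonical dimensions exist; these are package
fixture conventions), `h = 0.002` cm, `dt = 0.5` day, output every 5 days.
The initial state is foam-cell rich (M = 5e-5, T = 1e-5, S = 1e-4,
F = 3e-3 g cm^-3, chemicals zero), a documented convention for the "small
formed plaque".

## What the fixtures emulate — and what they do not

The channel fixture emulates a longitudinal section of intima with a small
incipient plaque; the annulus fixture a vessel cross-section. Real plaques
are three-dimensional, mechanically coupled to pulsatile flow and shear
stress, and contain debris, calcification and necrotic cores — none of
which are modelled. Passing the scenario tests therefore shows that the
*reconstructed network with the tabulated rates* reproduces the reported
lipid-dependent growth/regression behaviour at desk scale; it does not
validate the model against clinical imaging.

## Scale of the shipped computations

The package's own checks run the scenarios on meshes of a few hundred to
~1100 nodes (the channel at `h = 0.001`–`0.005`) — chosen as the resolution
at which the weight trajectories are mesh-stable to a few percent — with
the 5x3 risk grid and an n = 30 Latin hypercube screen at 100-day horizon
as the reduced analogues of the reference-resolution 121x21 map and the
n = 100 / 300-day screen. The full-resolution sweeps are a matter of computing budget, not of
code path: the same functions run them by changing `h`, the grids and `n`.

## Sensitivity analysis

`lhs_sample()` implements stratified Latin hypercube sampling over the 22
screened parameters (15 production/activation rates, 5 influx rates, and
the two blood lipid levels; ranges default to halving/doubling around the
baselines except where a tabulated range exists). `prcc()` computes partial
rank correlation coefficients by the standard construction: rank-transform,
regress each parameter's ranks and the output's ranks on all other
parameters' ranks, correlate the residuals; p-values use the t statistic
with `n - 2 - (k - 1)` degrees of freedom, reported raw (no multiplicity
correction). Failed simulations are dropped pairwise; a run with more than
10% failures is flagged invalid.

One caveat is worth stating plainly: under the density-elimination closure
the MMP term can only *reduce* the volumetric source of the pressure
equation, so the mechanistic chain by which MMP production (`lam_QS`)
promotes plaque weight is indirect here (matrix degradation frees volume
that the cell populations refill). The sign of PRCC(`lam_QS`) is an
emergent, not a structural, property of this reconstruction.

## Known limitations

* The reconstruction closures are calibrated to three scenario endpoints;
  other outputs (full weight trajectories, the 121x21 risk map) are
  reproduced qualitatively, not pixel-wise.
* Foam cells dominate the *initial* plaque but the late-time plaque mass is
  carried mostly by T cells and macrophages; reference composition data are not
  available, so this is unverifiable either way.
* Graph-represented boundaries exclude overhanging plaques; the channel
  moves the entire lumen-facing edge (not only the bump).
* No blood-flow shear stress, rupture mechanics, 3-D geometry, or
  triglyceride axis.

## A worked example

```{r example, eval = FALSE}
library(atherosim)

res <- run_scenario(190, 40, days = 300, config = list(h = 0.002))
glance(res)
autoplot(res)

rm5 <- risk_map(c(70, 100, 130, 160, 190), c(40, 50, 60), days = 100,
                config = list(h = 0.004))
autoplot(rm5)

sens <- run_sensitivity(n = 30, seed = 1, days = 100,
                        config = list(h = 0.005))
autoplot(sens)
```
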