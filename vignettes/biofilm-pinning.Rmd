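---
title: "Individual-based biofilm growth and the interface pinning transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-based biofilm growth and the interface pinning transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmpin)
```

# The model

`biofilmpin` simulates a bacterial biofilm growing on a flat substratum in a
flow-cell-like geometry, in two dimensions, and analyses the spatial
structure of the growing front. The model couples three ingredients:

1. **Agents.** Each bacterium is a disc with position $(x, z)$, radius $r$
   and biomass $m$, linked through a fictitious depth $d_{\mathrm{cell}}$ by
   $m = \rho_B \pi r^2 d_{\mathrm{cell}}$, where $\rho_B$ is the biomass
   density. A cell grows at the Monod rate
   $$\mu = \mu_{\max}\frac{S}{k_S + S},$$
   where $S$ is the nutrient concentration at its centre. When its radius
   reaches a stochastic per-cell division threshold, it splits into two
   daughters that conserve biomass exactly. Overlaps of the cells' zones of
   influence (radius times the shove factor $k_{\mathrm{shov}}$) are
   resolved by a randomised pairwise relaxation ("shoving").

2. **Nutrient.** The solute (oxygen in the default parameterisation) obeys a
   steady-state reaction-diffusion equation,
   $$\nabla\cdot(D\nabla S) = \frac{\mu_{\max} S}{k_S+S}\,\frac{\rho}{Y},$$
   solved anew for every growth update (separation of timescales). Nutrient
   arrives from above across a stagnant boundary layer of height $h_{bl}$;
   above the layer the concentration is pinned at $S_{\mathrm{bulk}}$;
   the substratum is a no-flux wall; the lateral direction is periodic; the
   diffusivity is reduced by a fixed factor inside the biofilm.

3. **Clipping.** To reach long times, cells that lie below both the lowest
   actively growing cell and the minimum of the interface (minus a safety
   margin) are removed periodically, and the removed slab height is folded
   into a `baseline_offset` so that *absolute* heights are preserved.

The default parameter set (see `bf_config()`) describes an oxygen-limited
*Pseudomonas aeruginosa* flow-cell biofilm: $S_{\mathrm{bulk}} =
6.6\times10^{-3}$ g/L, $Y = 0.64$, $\mu_{\max} = 0.29$ /h, $k_S =
8.12\times10^{-4}$ g/L, $D_S = 2.3\times10^{-4}$ m$^2$/day (0.8 inside the
biofilm), $h_{bl} = 80\ \mu$m, $\rho_B = 200$ g/L, $r_{\mathrm{div}} = 2\
\mu$m, $k_{\mathrm{shov}} = 1.15$, $L_y = 1032\ \mu$m, $N_0 = 300$.

# Spatial-structure analysis

All analysis operates on an 8 um grid in the absolute frame
($z_{\mathrm{abs}} = z + \texttt{baseline\_offset}$), so clipping cannot
alias heights.

* **Active layer.** A grid square is *active* when its biomass-weighted
  mean growth rate strictly exceeds $10^{-3}$ of the maximal attainable
  rate $\mu_{\max}S_{\mathrm{bulk}}/(k_S+S_{\mathrm{bulk}})$. The local
  active-layer thickness of a column is 8 um times its number of active
  squares — they need not be contiguous (a growing trough counts along
  with the crest above it). A column with no active square is a *gap*.
* **Multi-valued interface.** Interface squares contain biomass but have at
  least one empty 4-connected neighbour (lateral wrap; a virtual occupied
  row below the substratum prevents the contact line counting as
  interface). Because one lateral position can contribute several squares,
  overhangs are represented faithfully and $N_{\mathrm{int}} \ge D$.
* **Roughness.** $W = \langle (h - \langle h\rangle)^2\rangle^{1/2}$ over
  the interface-square centre heights (population convention).
* **Pinning.** An interface square is *pinned* if it is inactive and has
  not moved in 6 h (it appears at the same absolute position in the
  interface of the configuration one snapshot earlier);
  $f_P = N_P / N_{\mathrm{int}}$.

Trajectory statistics use a rolling-mean steady-state detector, a
Sokal-type windowed integrated autocorrelation time $\tau$, and
$\mathrm{SEM} = \sigma/\sqrt{n/\tau}$ for correlated series. Phases are
classified as **unpinned** ($f_P \equiv 0$ in steady state), **pinned** (a
pinning site that persists to the end of the run together with robustly
rising roughness), **transiently pinned** (episodic pinning that always
terminates, with a roughness steady state), or **transitional** otherwise.
The dimensionless transport-growth parameter
$$G_1^{-1/2} = \left(\frac{D_B Y (k_S+S_{\mathrm{bulk}})}{L_y^2\,\rho\,
\mu_{\max}}\right)^{1/2}$$
(and its $G_2$ variant with $S_{\mathrm{bulk}}$ in place of
$k_S+S_{\mathrm{bulk}}$) summarises where a parameter set sits relative to
the transition: large values mean transport-dominated, smooth growth.

# Numerical choices

* **Growth integrator.** Biomass is integrated exactly under the frozen
  field, $m \leftarrow m e^{\mu\,\Delta t}$, which removes first-order
  time-step bias and makes composition ($n$ steps of $\Delta t$ equal one
  step of $n\Delta t$) exactly testable. The default
  $\Delta t = 0.05/\mu_{\max}$ keeps the per-step biomass change at ~5%,
  so the frozen-field approximation's error in the step mass balance is
  below $\mu\Delta t/2 \approx 2.5\%$.
* **Nutrient solver.** Finite volumes with harmonic-mean face
  diffusivities; the Monod nonlinearity is handled by damped Picard
  iteration (relaxation 0.7) on the saturation factor; each linear system
  is an M-matrix solved by sparse Cholesky with the symbolic analysis
  cached across iterations. Convergence requires the nonlinear residual
  (scaled to concentration units by $a^2/D_S$) to fall below
  $10^{-6} S_{\mathrm{bulk}}$ in max norm. The converged field is
  non-negative and bounded by $S_{\mathrm{bulk}}$ without clamping
  (discrete maximum principle). Each step warm-starts from the previous
  field.
* **Boundary layer.** A morphological dilation of the biofilm voxel set by
  the Euclidean radius $h_{bl}$; voxels beyond it are bulk. The reduced
  diffusivity applies to biofilm voxels only.
* **Shoving.** Randomised Gauss-Seidel sweeps with a cell-list
  neighbourhood search; symmetric displacement of each violating pair;
  periodic in $x$, reflecting at the substratum. The default sweep cap is
  30: measured on mature states the residual plateaus by sweep ~10-20 at
  a small fraction of a radius, which is zone-of-influence softness — the
  shove factor 1.15 leaves ~0.5 um of slack before hard discs would
  touch — and further sweeps only cycle the jammed deep packing. An
  early-exit heuristic that stopped sweeping once the residual stalled
  was tried and rejected: reducing the per-step relaxation effort four-fold
  measurably smoothed the interface and suppressed pinning, i.e. the
  amount of mechanical relaxation per growth update is part of the
  physics, not just a tolerance.
* **Initial condition.** $N_0$ freshly divided cells (biomass uniform in
  40-60% of each cell's division mass) with stratified-jittered lateral
  positions proportional to cell diameter. A plain uniform draw of both
  radii and positions overfills the substratum at the default
  $N_0 = 300$, $L_y = 1032$ um and piles cells beyond $2 r_{\mathrm{div}}$;
  the freshly divided population is equally defensible biologically and
  seeds a genuine monolayer.
* **Steady-state detector.** Earliest index after which the rolling mean
  (window 10) of the remainder drifts by less than $1.5\times$ the mean
  rolling SD. The factor 1.5 is a calibration: the range of overlapping
  rolling means of pure white noise is itself close to one rolling SD, so
  an uncalibrated threshold rejects even stationary noise; 1.5 accepts iid
  series near their start while still rejecting linear drift.
* **Clipping details.** The clip line is the minimum of (lowest active
  cell, interface minimum, lowest empty analysis square) minus a 16 um
  margin (two analysis bins), snapped down to a bin boundary and kept
  below every retained cell body. The empty-square guard and bin snapping
  make all absolute-frame morphometrics *exactly* invariant under a clip;
  keeping the line below retained cell bodies prevents the frame shift
  from pushing anyone into the new no-flux floor.

# What the synthetic fixtures emulate

The fixture generators build biofilm states square-by-square from an
analytically prescribed occupancy-and-rate lattice, then fill each occupied
square with a dense lattice of radius-1 um cells. Ground-truth
morphometrics (interface set, roughness, thickness profile, pinned
fraction) are computed at generation time by an exhaustive neighbour scan
of that occupancy — independently of the vectorised analysis code under
test. Flat slabs, fingered profiles with mushroom overhangs, and
frame-to-frame sequences with prescribed pinned columns and drifting gaps
cover every analysis stage without running the simulator.

What they do *not* emulate: realistic packing disorder, biomass-weighted
rate mixtures within a square, or mechanically generated overhangs. A green
fixture test therefore establishes the correctness of the measurement
pipeline, not the realism of simulated morphologies; the simulation-level
acceptance runs cover the latter.

# Desk-scale behaviour and limitations

The full-scale regime the default parameterisation targets — very long
runs at $L_y = 1032$ um, up to ~$10^5$ cells — is expensive; at desk
scale the package works at reduced width (96-256 um) and a few times
$10^4$ cells.
Two systematic effects follow:

* $G_1^{-1/2} \propto 1/L_y$, so narrowing the domain moves every
  parameter set toward the smooth, transport-dominated side; parameter
  sets near the transition pin later and more sporadically than at full
  width. At width 256 um the transient-pinning reference set
  ($S_{\mathrm{bulk}} = 0.01$, $\mu_{\max} = 0.4$) is still in its initial
  roughening transient at 15,000 cells; pinning episodes first appear at
  ~20,000-25,000 cells, which is why the acceptance protocol runs until
  the roughness steady-state criterion fires (cap 45,000 cells).
* The pinned phase proper (permanent gaps, monotone roughness to arbitrary
  times) requires simultaneously thin active layers (low
  $S_{\mathrm{bulk}}$) and substantial total growth, whose product is
  fixed by the influx budget $D_S S_{\mathrm{bulk}} L_y / h_{bl}$; at desk
  scale such runs show the *onset* (monotonically rising W) rather than
  the asymptotic state.

Other limitations, inherited from the model class: no extracellular
matrix, no convective flow, no motility or detachment, two dimensions
only, and a deliberately crude overlap-relaxation mechanical model.
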