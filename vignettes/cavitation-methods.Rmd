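---
title: "Models and estimators for nanoscale cavitation in water and soft hydrogels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators for nanoscale cavitation in water and soft hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavitr)
```

## The problem

Soft gelatin hydrogels are standard brain-tissue simulants, and cavitation —
the nucleation, growth and collapse of vapour/void bubbles when the local
pressure drops below a threshold — is a leading candidate mechanism for
tissue damage under rapid loading. At the nanoscale this process can be
probed with molecular dynamics: a pre-existing bubble of a few nanometres is
carved into a periodic box of water (or of water threaded by a collagen-like
network), hydrostatic tension is imposed by expanding the box at a constant
volumetric strain rate, and the pressure, bubble geometry and transport
properties are read off the trajectory.

`cavitr` provides both halves of that analysis as reusable, tested code:

* **continuum bubble models** — the Laplace equilibrium threshold, a
  damped volume-pulsation model, the Rayleigh–Plesset (RP) equation, and the
  classical nucleation-time scaling of the threshold pressure;
* **trajectory estimators** — cavity detection and surface reconstruction,
  sphericity, virial global pressure, density excluding the cavity, threshold
  extraction, mean-square displacement and diffusion, and Green–Kubo shear
  viscosity;
* **synthetic generators** that emulate the statistical structure of the MD
  output with known ground truth, so every estimator can be validated without
  running MD.

## Continuum models

### Equilibrium threshold and the network decomposition

For a bubble of radius $R$ with negligible internal pressure, equilibrium
against the far field requires $P_{cav} = -2S/R$: tension, negative by our
sign convention. In a gel the same balance holds with the gel surface tension
$S_{gel}$, and the excess over the pure-liquid threshold is attributed to
the network, $P_{cav}|_{net} = P_{cav}|_{gel} - P_{cav}|_{liq}$
(`equilibrium_cavitation_pressure()`, `network_pressure()`).

The bundled media presets carry the measured continuum properties of the two
systems (SI units):

```{r media}
dplyr::bind_rows(medium_water(), medium_gel())
```

The preset initial radii (`preset_radius0()`) are the relaxed bubble radii of
the two systems, about 95 Å. The construction prescribes a 50 Å carve-out;
the relaxed radii that the presets use are the measured post-equilibration
values, and we keep both numbers distinct rather than reconciling them.

### Damped volume pulsation

Small-amplitude pulsation of a non-condensable bubble obeys
$m\ddot V + b\dot V + kV = 0$. The stiffness $k$ is proportional to the
internal gas pressure, which for a nanoscale void is negligible, so $k = 0$
is the default and $k$ is otherwise a user input (no proportionality constant
is available). Of the four damping channels only the viscous one survives at
constant temperature with no radiation and essentially no vapour:
$b = \eta/(\pi R^3)$. The model equation is written in the bubble *volume*,
so we adopt the volume-pulsation inertia $m = \rho/(4\pi R)$, the standard
(Strasberg) choice consistent dimensionally with $b$; the model source does
not state $m$ explicitly. With $k=0$ the solution is the exponential
relaxation $V(t) = C_1 e^{-bt/m} + C_2$ with constants fixed by $V(0)$ and
$\dot V(0)$; the relaxation rate is $b/m = 4\eta/(\rho R^2)$, about
$1.39\times10^{10}\,\mathrm{s^{-1}}$ for the water preset and twice that in
gel — the viscosity ratio is what damps the gel bubble faster. The
literature form of the damping parameter, $\delta = b/\sqrt{k/m}$, is not
the textbook dimensionless ratio $b/(2\sqrt{km})$; we report *both*
(`damping_ratio_delta`, `damping_ratio_std`) rather than guessing intent,
and suppress the natural frequency when $\delta^2 \ge 4$.

```{r oscillation}
glance(oscillation_parameters(medium_water(), preset_radius0("water")))
```

### Rayleigh–Plesset collapse

`solve_rp()` integrates
$R\ddot R + \tfrac32 \dot R^2 + \frac{4\eta}{\rho R}\dot R +
\frac{2\sigma}{\rho R} = -(P_{ext}-P_b)/\rho$
with `deSolve::lsodar` (adaptive, stiff-capable; relative tolerance $10^{-8}$,
absolute radius tolerance $10^{-12}$ m). The radial velocity diverges as
$R \to 0$, so integration stops by root detection when $R$ falls below a
configurable fraction of $R_0$ (default 1%); the remaining fall time scales
as $(R/R_0)^{5/2}$ and is negligible at that point. Three limits anchor the
solver:

* at $P_{ext} = P_b - 2\sigma/R_0$ the radius is stationary (the RHS
  vanishes identically, and the solver holds it to $10^{-3}$ over ten
  collapse scales);
* with $\eta = \sigma = 0$ and constant $\Delta P$ the collapse time matches
  the classical Rayleigh closed form
  $t_c = 0.914681\,R_0\sqrt{\rho/\Delta P}$ (`rayleigh_collapse_time()`,
  kept as an independent oracle) to better than 0.5%;
* collapse time grows monotonically with viscosity, which is why the gel
  preset always outlives the water preset under the same driving pressure —
  at these radii the collapse is viscosity-dominated, not
  surface-tension-dominated.

```{r rp}
glance(solve_rp(medium_water(), preset_radius0("water"),
                pressure_schedule(5e7), horizon = 1e-9))
glance(solve_rp(medium_gel(), preset_radius0("gel"),
                pressure_schedule(5e7), horizon = 1e-9))
```

### Nucleation-time scaling

Classical homogeneous-nucleation kinetics give
$P \propto [\ln(N k_B T t/h)]^{-1/2}$ for the critical tension at waiting
time $t$. `fisher_threshold_ratio()` evaluates the ratio between two waiting
times (surface tension cancels); across the 33 decades from an atomistic
vibration period ($10^{-15}$ s) to the age of the universe ($10^{18}$ s),
with $N = 6.022\times10^{23}$ and $T = 300$ K (CODATA $k_B$, $h$), the
threshold changes only by a factor `r round(fisher_threshold_ratio(1e-15, 1e18), 3)`
— the quantitative basis for treating strain-rate effects on homogeneous
nucleation as weak.

## Trajectory estimators

All trajectory work is in MD units: Å, ps, amu, per-atom stress in atm·Å³
(the stress-times-volume convention of LAMMPS dumps), pressures reported in
MPa with tension negative (1 atm = 0.101325 MPa).

### Virial pressure and per-atom volumes

`global_pressure()` implements
$P = (\sum P_{xx} + \sum P_{yy} + \sum P_{zz}) / (3\sum v_i)$ over the
per-atom stress and per-atom volumes, with optional species filtering (so
the pressure carried by the network alone, or by the water alone, can be
inspected). When a dump carries no volumes, `voronoi_volumes()` supplies
them from a voxelised periodic nearest-site tessellation: each voxel is
assigned to its nearest particle image and a particle's volume is its voxel
count times the voxel volume. The partition is exhaustive, so volumes sum to
the box volume *exactly*; individual cells converge to the true Voronoi
cells as the grid refines. Only the sum enters the pressure, so the default
1 Å grid is ample. Exact polyhedral Voronoi cells were judged out of
proportion for this role. Coincident particles are rejected as degenerate.

### Cavity detection and surface reconstruction

`detect_cavity()` replaces the interactive surface-mesh tool workflow with a
deterministic two-stage algorithm on a periodic voxel grid (default spacing
2 Å):

1. **Detection — probe occupancy.** Grid nodes farther than the probe
   radius (default 3 Å ≈ one water-molecule radius) from every particle are
   "deeply empty": a probe sphere fits there. These voxels are labelled into
   periodic-aware 6-connected components; components smaller than
   `min_volume` (default 200 Å³) are discarded as thermal density
   fluctuations — in a bulk bead fluid at ~1 g/cm³ the probe fits in about
   2% of space, in scattered pockets of a few voxels. The largest surviving
   component is the cavity; the others are counted (`n_secondary`), which is
   how the secondary nucleation events at high strain rate surface in the
   analysis.
2. **Measurement — equimolar density isosurface.** The probe-empty region
   systematically *under*-covers the void: erosion by a probe stops one
   interparticle gap short of the interface. For unbiased geometry the
   particles are binned onto the same grid and smoothed with a periodic
   Gaussian (width = probe radius), and the cavity is measured as the
   connected half-bulk-density region containing the core. For a sharp
   interface a symmetric kernel crosses half density exactly at the
   interface, so the measured volume is unbiased up to a curvature term of
   order $\sigma^2/R$ (≈ 0.2 Å at $R = 50$ Å); voids smaller than about two
   kernel widths are below the method's resolution and come out small.

`cavity_metrics()` triangulates the zero level set of the signed cavity
field by marching tetrahedra (Kuhn 6-tetrahedra cube decomposition; triangle
orientation fixed per-face toward the outside), then accumulates the
enclosed volume by the divergence theorem and the area from the triangle
cross products. From $V_c$ and $A_c$ it reports the sphericity index
$\Psi = \pi^{1/3}(6V_c)^{2/3}/A_c$ — 1 for a sphere (the minimum-area shape
at fixed volume), smaller for any deformation, which is how bubble–network
interaction shows up — and the volume-equivalent radius
$R = (3V_c/4\pi)^{1/3}$, which is also the default "bubble radius" series
(for non-spherical cavities a mesh-derived radius is ambiguous; the
equivalent radius is exactly consistent with the reported volume). On a
carved 50 Å spherical void at water density the reconstruction lands within
1% of the analytic volume at the default grid and within 5% at a grid twice
as coarse; the mesh sphericity of a voxel-sampled sphere is ~0.95 (surface
roughness from thermal jitter and sampling noise), so sphericity series
should be read comparatively, not as absolute shape factors.

```{r cavity}
fr <- make_fluid_with_cavity(box = c(120, 120, 120), cavity_radius = 50,
                             density = 1.02, seed = 1)
cav <- detect_cavity(fr)
cavity_metrics(cav)
```

### Growth pipeline, threshold and bookkeeping

`growth_analysis()` chains the per-frame estimators into aligned series of
pressure, radius, sphericity and density (excluding the cavity volume, so
the series tracks the state of the liquid rather than the trivial dilution
by the void). `threshold_pressure()` reads the cavitation threshold off a
pressure trace as the global minimum after a centred moving average
(default window 1 ps — raw nanoscale pressure fluctuates by tens of MPa, and
the source traces are clearly smoothed though no filter is stated); ties go
to the earliest time and minima at the trace ends are flagged as boundary
minima. `volume_strain_schedule()` encodes the imposed expansion: strain is
*linear* in time (constant volume expansion rate, matching how the
deformation is applied; exponential/true strain was considered and
rejected), so the standard rate $X = 6.7\times10^9\,\mathrm{s^{-1}}$ held
for 60 ps and $2X = 1.35\times10^{10}\,\mathrm{s^{-1}}$ held for 30 ps reach
the same final strain to within 1% (the published $2X$ is not exactly twice
$X$). `volume_decomposition()` closes the bookkeeping
$V_{system} = V_{water} + V_{network} + V_{bubble}$ with a 0.1% accounting
tolerance.

### Transport

`msd()` computes the mean-square displacement with *all* time origins per
lag via the FFT algorithm (O(n log n) per particle; an O(n²) brute-force
oracle guards it in the tests). Coordinates must be unwrapped; image-flag
columns are applied when present, and a frame-to-frame jump beyond half a
box edge without flags is an error rather than a silent corruption.
`diffusion_coefficient()` takes one sixth of the MSD slope (3D), fitted by
least squares over the central 20–80% of the lag range by default (early
lags are ballistic-contaminated, late lags origin-starved; no fit window is
stated in the source, so the window is configurable). A log–log exponent is
fitted alongside: α ≈ 1 marks diffusive motion, α ≈ 2 ballistic, and
`|α − 1| > 0.3` flags the estimate as non-diffusive.

`green_kubo_viscosity()` integrates the off-diagonal stress autocorrelation,
$\eta = \frac{V}{k_BT}\int_0^{t_c}\langle P_{ab}(0)P_{ab}(t)\rangle\,dt$,
averaged over the independent components and all time origins, by the
trapezoidal rule. The cutoff defaults to 10× the estimated autocorrelation
time (normalised autocorrelation integrated to its first zero crossing);
beyond that the integrand is noise. Standard errors come from ≥ 5
contiguous-block re-estimates, and the series must be at least 10× the
cutoff. Against an Ornstein–Uhlenbeck stress process with analytic viscosity
$Vs^2\tau/(k_BT)$ the estimator recovers truth within 15% at the test sizes.

## Synthetic data: what it emulates and what it does not

The generators produce monodisperse 18 amu beads (pseudo-water) rather than
3-site water molecules: every estimator in scope consumes positions, masses
and stress only, and beads keep the fixtures desk-scale. Placement is
uniform rejection sampling outside the carved cavity — not a lattice — to
avoid artificial crystalline degeneracies in the tessellation (lattice
fixtures are still used in tests where exact volumes are wanted). Frames of
a growth trajectory add small Gaussian jitter (σ = 0.3 Å) so surfaces are
rough like thermal interfaces, and particle identity is maintained by
carving a labelled subset, keeping MSD computable on the retained set.
Per-atom stress, when requested, is assigned isotropically to make the
virial pressure formula return the target exactly — an inversion oracle,
not a physical stress field.

Every generator is deterministic (same seed, same bytes), never disturbs
the caller's RNG stream, and records its parameters in a `ground_truth`
attribute sufficient to compute the expected estimator output analytically.
What the generators do *not* emulate: interatomic forces and realistic
pressure fluctuations, collagen fibril geometry, bound vs bulk water, or
the actual MD pressure traces. Passing tests therefore demonstrate that the
estimators are correct on data with the stated statistical structure, not
that the MD observations themselves are reproduced; the published MD
numbers (thresholds of −93/−101 MPa, threshold times of a few ps, measured
viscosities) enter only as inputs and qualitative ordering checks.

## Numerical choices and limitations

* Problem sizes in the tests and acceptance runs are desk-scale by design:
  boxes of 60–140 Å with $10^4$–$10^5$ beads, trajectories of ≤ 1000 frames,
  stress series of ≤ 6×10⁴ samples; all were chosen so the full suite runs
  in minutes on one CPU while leaving estimator errors comfortably inside
  the stated tolerances.
* Orthorhombic periodic boxes only; triclinic inputs are rejected with a
  clear error. All distances are minimum-image; cavity connectivity is
  periodic-aware, and the cavity field is re-centred by the periodic
  circular mean before meshing so the isosurface never touches the seam.
  A cavity must fit inside the box; per-frame analysis tracks only the
  largest cavity plus a count of the rest (no multi-cavity tracking across
  frames).
* The RP model here deliberately omits thermal, radiative and phase-change
  damping and any acoustic forcing, and holds $P_b$ and the material
  properties constant; deviations between measured and predicted collapse of
  a *non-spherical* bubble are expected and are part of what the
  measured-vs-predicted comparison (`analyze_collapse()`) is for.
* The voxelised tessellation gives exact volume conservation but per-cell
  volumes only to voxel resolution; the cavity method cannot resolve voids
  smaller than ~2 kernel widths; sphericity from voxel-sampled surfaces is
  depressed a few percent by roughness.
* CLI subcommands (`inst/cli/cavitr`) are thin wrappers over the exported
  functions; the package functions are the canonical interface.
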