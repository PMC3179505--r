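---
title: "Mapping ligand (un)binding with path collective variables and metadynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ligand (un)binding with path collective variables and metadynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmeta)
```

## The problem

Substrate binding and unbinding in a deep, buried pocket is a rare event:
the residence time in the bound basin is orders of magnitude longer than
anything plain dynamics can sample, and the transition involves many
coupled degrees of freedom (ligand translation and rotation, side-chain
gating, solvent exchange through the cavity). `pathmeta` implements the
enhanced-sampling protocol that handles this situation — steer the ligand
out once to obtain a coarse exit path, parameterize that path into a
frameset of reference configurations, and let metadynamics on the path
collective variables reconstruct the free-energy surface of the full
process — at a scale where every estimator can be checked against
brute-force or closed-form references.

All quantities are in kcal/mol, Angstrom, picoseconds, Kelvin and amu;
`kB_kcal * 300` is 0.5962 kcal/mol.

## Path collective variables

Given an ordered frameset of P reference configurations and the MSD metric
$D_i(\mathbf{R})$ — the mean squared deviation (A^2) between the current
configuration and frame $i$ after least-squares superposition over a
stable alignment cage — the two variables are

$$S(\mathbf{R}) = \frac{\sum_{i=1}^{P} i\, e^{-\lambda D_i}}{\sum_{i=1}^{P}
e^{-\lambda D_i}}, \qquad
Z(\mathbf{R}) = -\frac{1}{\lambda} \ln \sum_{i=1}^{P} e^{-\lambda D_i}.$$

$S$ runs from 1 (first frame) to P (last frame) and measures progression
along the path; $Z$ (A^2) measures distance from it. Design choices worth
stating explicitly:

* **Indexing.** $S$ is indexed 1..P rather than normalized to [0, 1], so a
  P-frame path puts its product basin near $S = P$ and basin positions can
  be read directly against frame numbers.
* **The $\lambda$ rule.** $\lambda$ is calibrated as
  $\ln(10)/\langle D_{\mathrm{adjacent}}\rangle$: a configuration one
  inter-frame spacing away from a frame contributes weight 0.1 to the
  sums. For a frameset with 1.1 A (RMSD) average spacing this gives
  $\lambda = 1.90$ A$^{-2}$, in the range used for protein-ligand paths.
  The rule treats the reported spacing as RMSD; the MSD entering the
  exponent is its square.
* **Selections.** The superposition uses a stable reference cage (for the
  toy pocket, restrained cage beads; for proteins, core backbone atoms),
  while the displacement is measured over the ligand heavy atoms only —
  flexible surroundings should not enter the metric.
* **Gradients.** $\partial S/\partial x$ and $\partial Z/\partial x$ are
  analytic with the optimal rotation and translation held fixed per
  evaluation. Because the alignment depends only on the cage atoms and
  gradients are taken (and bias forces applied) only on the displace
  atoms, this is exact for disjoint selections; the finite-difference
  consistency test guards it at 1e-4 relative error.
* **Numerics.** Both sums are evaluated in log-sum-exp form, so large
  $\lambda D$ never underflows; the naive-summation oracle test pins the
  agreement at 1e-10 where the naive form is representable.

**Frameset extraction.** Frames are selected from the steered trajectory
by a dynamic programme over a candidate grid (at most 500 frames; first
and last forced) minimizing $\sum (D_{\mathrm{adj}} - \tau)^2$. The target
spacing $\tau$ starts from the end-to-end MSD divided by $(P-1)^2$ — a
noise-free lower bound — and is refined to the achieved mean until
self-consistent. A cumulative arc-length target is deliberately avoided:
over a diffusive trajectory the summed frame-to-frame distance grows with
the number of frames considered and badly overestimates the real spacing.

## Steered dynamics

`run_smd()` drags the distance between the centres of mass of two
selections with a harmonic guide ($k$ = 20 kcal mol$^{-1}$ A$^{-2}$, speed
0.005 A/ps by default; the speed-extension arithmetic 7.5 A / 0.005 A/ps =
1500 ps is the standard schedule). The centre is held fixed during each
integration step and jumped between steps, and the work is charged
exactly at each jump as the restraint-energy difference at fixed
configuration — the discrete-protocol bookkeeping under which the
accumulated work obeys the nonequilibrium work theorem with no
velocity-dependent discretization bias (a naive force-times-velocity
trapezoid over a continuously moving centre undershoots by O(k v dt) and
shows up as an apparent second-law violation at fast pulls). Runs
equilibrate under the static restraint before pulling, since the work
bound presumes equilibrium initial conditions. Each realisation draws
fresh Maxwell-Boltzmann velocities from its seed; five realisations and
lowest-final-work selection (ties broken by force-profile total
variation, then run id) mirror common practice. The second-law bound and
the approach to the quasistatic limit at decreasing speed are both under
test against closed-form and histogram references, including a Jarzynski
cross-check that recovers the closed-form free energy at every speed.

## Metadynamics and FES reconstruction

Standard (non-well-tempered) metadynamics: every `stride` ps (default 1) a
Gaussian hill of height `deposition_rate * stride` (defaults 0.1 kcal/mol
per ps and hence 0.1 kcal/mol) and widths $\sigma_S$ = 0.15,
$\sigma_Z$ = 0.20 A$^2$ is deposited at the current (S, Z). The continuous
deposition the method idealizes is approximated by this discrete schedule;
stride is configurable and convergence is checked at more than one stride.
At convergence the accumulated bias mirrors the negative free energy, so
`reconstruct_fes()` returns $F = -V_{\mathrm{bias}}$ shifted to zero
minimum, as an exact hill sum on the analysis grid.

Engine details that matter:

* Bias **forces** during integration come from gradient grids (spacing
  $\sigma/10$, bilinear lookup) that every hill is splatted onto — the
  standard grid trick that keeps the cost independent of the hill count. A
  test bounds the grid force against the analytic hill-sum gradient at
  sub-percent level; `bias_value()`/`bias_gradient()` themselves are exact
  and carry the 1e-4 finite-difference contract.
* No walls are imposed on S beyond the frameset range: excursions simply
  show up as FES regions reported where sampled.
* The default stopping rule is the **recrossing event** — the return of S
  to the start region after first reaching the end region — with a step
  cap as safety. A recrossing marks the first moment the surface is usable,
  not the end of convergence: estimates here keep depositing past it when
  a converged surface (not a stopping time) is the goal, and average the
  min-shifted FES over several late checkpoints
  (`reconstruct_fes_averaged()`), the usual variance-reduction step.
* With `deposition_rate = 0` the run is plain Langevin dynamics recording
  (S, Z) — this is how the brute-force reference series are produced, and
  it is bit-identical to `run_langevin()` at the same seed.

Basins are found by steepest-descent watershed on the grid; basins
shallower than `min_depth` (default 1 kcal/mol — the customary isoline
spacing, below which a wrinkle is not a state) merge into their spill
neighbour. Barriers are minimax path values (lowest connecting saddle) via
a Dijkstra search with max-cell cost, validated against exhaustive
threshold-flood enumeration. Basin free-energy differences are
minimum-to-minimum.

## Toy systems and the Langevin integrator

The sampler is BAOAB-discretized Langevin dynamics (friction 5 ps$^{-1}$
and timestep 2 fs by default, 300 K); at zero friction it reduces to
velocity Verlet and conserves energy, which the NVE drift test checks.
BAOAB is chosen for its configurational accuracy at practical timesteps.
The integrator, steering and metadynamics loops are compiled (Rcpp), with
a self-contained RNG (xoshiro256++ uniforms, ziggurat normals) so
trajectories are bit-reproducible for a given integer seed.

Two toy systems carry the validation burden:

* `double_well_1d(barrier, separation)`: the quartic double well
  $V = b((2x/a)^2 - 1)^2$, embedded in 3D with a transverse harmonic tie
  (100 kcal mol$^{-1}$ A$^{-2}$). Its free energy along x is V itself, and
  Boltzmann well populations by quadrature are the reference for
  histogram and metadynamics estimates. A 15-frame frameset along x maps S
  affinely onto x, so the full path-CV metadynamics stack can be validated
  against the closed form.
* `build_toy_pocket()`: a funnel pocket emulating a buried binding cleft.
  A quasi-rigid ligand ring (stiff harmonic bonds, 200 kcal mol$^{-1}$
  A$^{-2}$; SHAKE-type constraints are out of scope) sits in an axial
  binding well of depth `pocket_depth` that decays over `channel_length`;
  its centre of mass is confined to a tube (radius 1.2 A) with axial caps,
  giving the unbound state a finite volume so the binding free energy is
  well defined. Purely repulsive (WCA, sigma 2.8 A) solvent beads live in
  a funnel — a 6 A cylinder in the bulk narrowing to 2 A inside the
  pocket — and cross a Gaussian gate bump at the mouth: height 0.5
  kcal/mol with a back-door (solvent can always reach the pocket bottom),
  4 kcal/mol without. The pocket interior attracts solvent weakly (1.5
  kcal/mol, a polar cavity), so the empty pocket hydrates while a bound
  ligand sterically dries it, and solvent competition for the cavity
  lowers the effective unbinding barrier — the solvent-exchange physics
  the back-door story is about. Reference cage beads restrained near the
  pocket bottom and mouth provide the alignment frame and the
  hydration-axis anchors. The binding well is deliberately narrow
  (half-width `channel_length`/12) so that barrier-crossing attempt
  frequencies stay high enough for brute-force reference runs at desk
  scale.

Defaults are chosen once as the study conditions: depth 6 kcal/mol (a
realistic substrate affinity, ~10 kT), 12 solvent beads, a 4-bead ligand,
back-door open. What the toy does **not** emulate: electrostatics,
explicit water structure, protein flexibility, or any conformational
gating — passing tests here validate the estimators, not force-field
realism.

## Hydration and geometry monitors

Water counts use the rational switching function
$(1 - (r/r_0)^n)/(1 - (r/r_0)^m)$ with $r_0$ = 3.5 A, $n$ = 6, $m$ = 16;
the removable singularity at $r = r_0$ is evaluated as its limit $n/m$
(0.375 at the defaults), and a perturbation oracle checks continuity.
`hydration_map()` probes the coordination at 11 points of a pocket axis
(10 slices) per frame and averages within S-bins of width 0.5, with Z
marginalized. The axis anchors are user-chosen stable points; the toy uses
the cage-bead centroids at the pocket bottom and mouth.

Monitors (`monitor_distance`, `monitor_dihedral`, `rmsd_rmsf`,
`cluster_single_linkage` at a 0.7 A cutoff, and the catalytic-competence
predicate) are deliberately plain implementations of textbook
definitions, each tested against an independent construction. The
competence cutoffs (hydride 4.5 A, hydrogen bonds 3.5 A) follow standard
structural practice and are configurable — they are a predicate
definition, not a fitted quantity.

## Problem sizes and numerical choices

Validation runs are sized for a single CPU: double-well metadynamics uses
1.5M steps (3 ns) per seed with hills every 1 ps; toy-pocket metadynamics
10M steps (20 ns); brute-force references use up to 2e8 steps (400 ns)
with (S, Z) recorded every 400 steps. Sampling runs on the toy pocket use
friction 2 ps$^{-1}$ — near the Kramers turnover for this system, where
barrier-crossing rates peak — while the default 5 ps$^{-1}$ remains the
protocol value; equilibrium free energies do not depend on the friction.
Free-energy comparisons between metadynamics and histogram references are
made on a common (S, Z) grid (0.5 x 0.5) over explicit bound/unbound
windows, with the metadynamics surface averaged over late checkpoints.
The compared statistic is the window Boltzmann free energy
(`fes_window_free_energy()`): minima of sparsely counted histogram cells
are biased low, while the pooled window weight is stable on both legs;
`basin_delta_g()` itself remains minimum-to-minimum, the convention used
when reading basins off a surface. Degenerate inputs (empty hill logs, flat surfaces, collinear
alignments, zero-displacement trajectories, coincident centres of mass)
are defined errors or documented conventions rather than silent results.

## Known limitations

* The toy pocket's bound basin is wide in S (the well bottom is flat over
  ~2 A), so "bound" and "unbound" are windows on the surface rather than
  single grid cells; analyses should use the window helpers rather than
  assume point basins.
* Histogram references need actual transitions; spontaneous round-trip
  times on the default pocket are ~10 ns, so reference values carry
  statistical error of one to a few tenths of kcal/mol at desk-scale run
  lengths.
* The FES is reported where sampled: regions never visited (or never
  biased) appear at the reference ceiling, and basin analysis should be
  windowed to the sampled region.
* Single-walker, constant-height metadynamics only; well-tempered and
  multiple-walker variants, reweighting, and alternative path metrics
  (curvilinear reparameterization, adaptive paths) are out of scope.
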