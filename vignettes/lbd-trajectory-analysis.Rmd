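---
title: "Methods: analysing ligand-binding-domain trajectories with lbdtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing ligand-binding-domain trajectories with lbdtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `lbdtraj`, the meaning
and defaults of every tunable parameter, the design of the synthetic
validation generator and the limits of what it can demonstrate, and the
numerical conventions the implementation commits to. Code chunks are shown
for orientation and are not evaluated here; the same computations are
exercised, with assertions, by the package's test suite.

## 1. The scientific model

Nuclear-receptor ligand-binding domains (LBDs) share a helical sandwich
fold whose C-terminal elements — helix 11, the connecting loop, and
helix 12 — act as a lid over the ligand pocket. An agonist stabilises the
closed lid (the surface that recruits coactivators); an antagonist keeps
the lid open or displaced. Resistance mutations in the androgen receptor
(T877A, W741C, F876L and their combinations) are understood to flip this
switch: the mutated pocket lets an antiandrogen such as hydroxyflutamide
stabilise the closed, agonist-like arrangement. The package analyses
molecular-dynamics output downstream of that hypothesis; it does not run
dynamics.

Two quantitative threads support the argument:

**Energetics.** The MM-GBSA single-trajectory bookkeeping is taken as
given: the enthalpy-like binding energy is the sum of four per-snapshot
component averages,

\[ \Delta E_{\mathrm{bind}} = \Delta E_{\mathrm{ele}}
   + \Delta E_{\mathrm{vdw}} + \Delta G_{\mathrm{polar}}
   + \Delta G_{\mathrm{nonpolar}}, \]

with the internal term identically zero because complex, receptor and
ligand snapshots come from the same trajectory. The free energy adds a
separately estimated entropy term, \(\Delta G_{\mathrm{bind}} =
\Delta E_{\mathrm{bind}} - T\Delta S\); `lbdtraj` consumes \(-T\Delta S\)
as an input scalar and never estimates it. `aggregate_binding()` averages
per-frame components column-wise first and applies the identities to the
means — equivalent to averaging totals, but it keeps every reported total
exactly consistent with its reported components. The nonpolar solvation
term uses the linear surface-area model \(\Delta G_{\mathrm{np}} =
\gamma \cdot \Delta\mathrm{SASA} + \beta\) with \(\gamma = 0.0072\)
kcal mol\(^{-1}\) Å\(^{-2}\), \(\beta = 0\) and a 1.4 Å water probe, the
standard GB/SA parameterisation. Pair energies use Coulomb's law with
\(k = 332.0636\) kcal Å mol\(^{-1}\) e\(^{-2}\) and a 12-6
Lennard-Jones form in the \(r_{\min}\) convention (per-atom
\(r_{\min}/2\) summed, \(\varepsilon\) combined geometrically), matching
common force-field tabulations.

`validate_energy_table()` exists because published component tables are
rounded to two decimals: it checks each row against the two identities and
flags residuals above a tolerance (default 0.015 kcal/mol, the largest
residual pure two-decimal rounding of four addends can produce plus
headroom). Flagged rows are reported, never corrected — the table is the
record; the flag is the finding.

**Geometry and conformation.** Hydrogen bonds use a strict geometric gate:
donor–acceptor heavy-atom distance < 3.5 Å **and** acceptor–H–donor angle
(vertex at the hydrogen) > 120°. Occupancy is the percentage of frames
satisfying both. Lid state is read from a distance-feature map: one
feature per lid C-alpha, its distance to the mass center of the rigid
core. Distances are invariant to global rigid motion, so no superposition
step can contaminate the features. Principal component analysis of the
feature covariance gives a low-dimensional map; a reference structure
(e.g. a crystallographic antagonist conformation) is projected into the
trajectory's own map and classified by convex-hull membership —
"antagonist-consistent" if inside the sampled cloud, "agonist-shifted" if
outside — with the Mahalanobis distance reported as a continuous margin.

## 2. Parameters, units, defaults

All coordinates are in Ångström, energies in kcal/mol, angles in degrees,
times in ps. Atom addressing is by `(residue_id, atom_name)` in the
author's residue numbering, e.g. `c(877, "OG1")`.

| Parameter | Default | Why |
|---|---|---|
| H-bond `max_distance` | 3.5 Å | conventional heavy-atom cutoff for moderate hydrogen bonds |
| H-bond `min_angle` | 120° | excludes incidental contacts with no donor–H–acceptor alignment |
| `window_last_frames` | `n_frames %/% 6` | tail window for equilibrated statistics; one-sixth of a production run is a common convergence window |
| SASA `probe` | 1.4 Å | water-molecule radius |
| SASA `n_sphere_points` | 960 | per-atom lattice giving sub-percent area error on isolated spheres (tested against the closed form) |
| Nonpolar `gamma`, `beta` | 0.0072, 0 | GB/SA surface-tension coefficient, kcal mol⁻¹ Å⁻² |
| `kclust` `cutoff` | 1.2 Å (pipeline) | backbone-RMSD radius separating thermal noise from state changes at C-alpha resolution |
| Coulomb constant | 332.0636 | kcal Å mol⁻¹ e⁻² |
| Lid / core selections | `resid 873-908 and name CA` / `resid 698-844` | helix-11–loop–helix-12 lid vs the rigid helical core in androgen-receptor numbering |

Pipeline configs are flat `key = value` text so that runs are
self-documenting and diffable; every numeric key is validated at parse
time and echoed into the run log.

## 3. The synthetic generator: what it models and what it cannot prove

`generate_topology()` / `generate_trajectory()` produce a 188-atom
C-alpha-resolution caricature of an LBD: 147 core C-alphas (residues
698–844) on a radius-10 Å spherical lattice, 36 lid C-alphas (residues
873–908) on fixed outward directions at radius `lid_closed_distance`
(12 Å) or `lid_open_distance` (20 Å) per frame, two acceptor sites (an
N705-like OD1 and a T877-like OG1) flanking the pocket, and a three-atom
ligand (`O4`, `H11`, `C11`, residue 999, resname `HF`) whose hydroxyl is
placed to donate to one site per frame: donor–acceptor distance
\(2.8 + 0.15\,\mathcal N(0,1)\) clamped to [2.5, 3.3] Å and an angular
tilt \(\min(25°, |\mathcal N(0, 8°)|)\), so generated bonds satisfy the
gate while the *site choice* (Bernoulli with `p_site_a`) is the recoverable
signal. Lid atoms get isotropic Gaussian noise (`noise_sd` 0.5 Å), core
atoms much less (`core_noise_sd` 0.1 Å — the core is rigid by
construction), and every frame is then hit with a random rigid rotation
(uniform quaternion) and a uniform translation in \([-20, 20]^3\) Å. The
rigid contamination is the point: any analysis that is supposed to be
superposition-correct or rigid-motion-invariant is tested against data
where ignoring that step would fail loudly.

Determinism: all random draws happen up front from a single seeded stream
in a fixed, documented order (states, site choices, core noise, site
noise, lid noise, bond distances, tilts, azimuths, quaternions, shifts),
so results are reproducible to the byte and adding consumers later cannot
silently reorder the stream. The true per-frame states and sites ride
along as attributes and can be exported (`write_ground_truth()`).

Realism limits — what a passing recovery test does *not* show:

- The two lid states are well separated (8 Å against 0.5 Å noise) and
  transitions are i.i.d. Bernoulli. Real trajectories have correlated
  dynamics, partial closures and intermediate states; recovery here shows
  the estimators are unbiased and rigid-motion-proof, not that they can
  resolve marginal or kinetically trapped states.
- Energy components are independent Gaussians around fixed means; passing
  the aggregation tests validates the bookkeeping, not any force field.
- The three-atom ligand has no internal degrees of freedom, so
  ligand-RMSD behaviour under induced fit is untested.
- The generator's hydrogen bonds are planted to pass the gate; occupancy
  recovery therefore tests counting and windowing, not the gate's
  discrimination on borderline geometry (that is covered separately by
  boundary-case unit tests).

Problem sizes used in the package's own validation (1000–5000 frames, 100
classification replicates) were chosen so that 3-sigma binomial bounds are
a few tenths of a percent to a few percent — tight enough that a logic
error cannot hide inside sampling noise on a single CPU in minutes.

## 4. Numerical conventions

These choices are deliberate and frozen; changing any of them changes
results at the reported precision.

- **Indexing** is 1-based throughout (R convention): frame 1 is the first
  frame, atom indices returned by `select()` are 1-based row numbers.
- **Superposition** uses the Kabsch algorithm: SVD of the 3×3
  cross-covariance with the reflection corrected via the sign of
  \(\det(UV^\top)\), guaranteeing a proper rotation. Collinear fit sets
  are rejected (second singular value test) rather than silently
  returning one of the degenerate optima. The transform convention is
  row-vector: `fitted = x %*% rotation + translation`.
- **RMSF** fits to frame 1 by default (`reference = "first"`); the
  `"mean"` option refits to the mean structure. `align = FALSE` skips the
  fit entirely — required when the ensemble has no global motion, because
  least-squares fitting to a noisy reference otherwise redistributes a
  small amount of apparent fluctuation between atoms.
- **PCA** uses the population covariance (1/N, `normalization =
  "population"`): the frames are treated as the full ensemble being
  summarised, not a sample from a larger one; `"sample"` (1/(N−1)) is
  available for comparison. Eigenvalues are clipped at zero (they are
  nonnegative in exact arithmetic). Eigenvector sign is fixed by making
  each vector's largest-magnitude coefficient positive, so reported score
  signs are reproducible across platforms and LAPACK builds.
- **Convex-hull classification** counts a point exactly on the hull
  boundary as inside (boundary-inclusive cross-product test): "inside the
  sampled region" includes its boundary. Degenerate clouds (collinear
  scores, singular covariance) are an error, not a silent verdict.
- **Strict inequalities** in the hydrogen-bond gate (< 3.5, > 120) mean a
  triple sitting exactly on a threshold fails. Occupancies are reported
  rounded to two decimals; mean distance/angle are averaged over the
  *satisfying* frames by default (`means_over = "satisfying"`), because
  the conventional tabulated geometry of a hydrogen bond describes the
  bond while formed; `means_over = "all"` is available.
- **Clustering** (`kclust`) is a leader pass (a frame outside `cutoff` of
  every centroid founds a new cluster at its own coordinates) followed by
  refinement sweeps (recompute centroids as member means, reassign each
  frame to the nearest centroid) until assignments are stable; empty
  clusters are dropped and clusters renumbered by first appearance. The
  representative is the member frame with minimum RMSD to the centroid;
  ties break to the lowest frame index. All distances are best-fit RMSDs
  (each frame is superposed onto the centroid over the clustering
  selection before measuring), so global rigid motion cannot create
  spurious clusters; the unit tests cover the tie and degenerate-cutoff
  behaviour explicitly.
- **Energy-table tolerance** 0.015 kcal/mol, as above, is the two-decimal
  rounding bound; tightening it to 0.005 also flags rows whose residual is
  exactly one rounding unit (0.01), which the tests demonstrate.
- **Trajectory text formats**: multi-model PDB coordinates carry three
  decimals (fixed-column format limit); the `xyz-frames` dialect carries
  six, and is the round-trip-exact interchange format at the package's
  working precision.

## 5. Decisions on underdetermined points

Several conventions were not fixed by the source material and had to be
chosen; they are recorded here so downstream users are not surprised.

- The ligand residue is named `HF` (hydroxyflutamide) with residue id 999
  and a `HETATM` record; selections default to `resname HF`.
- The reference structure is classified in the *trajectory's own* PC map
  (per-system projection), not in a map pooled across systems: the
  question is whether this system's sampling contains the reference
  conformation, and pooling would let a broad second system widen the
  hull of a narrow one.
- Trajectory readers take every frame (stride 1); subsampling, when
  wanted, is the caller's slice so that frame indices in reports always
  match the input file.
- `within R of <subquery>` uses strict `< R`, measures heavy atoms only,
  promotes whole residues, and excludes the subquery's own residues — the
  reading that matches "residues within R of the ligand" as used for
  binding-site definitions.
- The pipeline's synthetic default for the entropy scalar is 23.12
  kcal/mol, the wild-type-like value consistent with the default energy
  means, so a default run produces an internally consistent summary.

## 6. Known limitations

- No explicit-solvent, GB-polar, or entropy calculations: the polar
  solvation and \(-T\Delta S\) terms are inputs, because computing them
  requires force-field and normal-mode machinery outside this package's
  scope. Identities and decompositions are exact in whatever numbers they
  are given.
- PDB support covers fixed-column `ATOM`/`HETATM`/`MODEL` single-chain
  files — the interchange subset needed here — not the full format
  (altlocs, insertion codes, multi-chain complexes are rejected loudly).
- SASA is exact only in the lattice limit; with the default 960 points
  per atom the isolated-sphere error is below 0.5% (tested), adequate for
  the nonpolar term's 0.0072 kcal/mol/Å² scale but not for sub-Å²
  geometry work.
- The convex-hull classifier operates in the first two principal
  components; lid motions orthogonal to that plane are invisible to the
  verdict (the eigenvalue spectrum is reported so users can check how
  much variance the plane carries).
- `kclust` is a greedy leader algorithm: cluster count and membership can
  depend on frame order for marginal cutoffs. Determinism is guaranteed;
  optimality is not.
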