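---
title: "Auditing B-factors against known conformational heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing B-factors against known conformational heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bfaudit)
```

## The question the package answers

A Bragg experiment measures amplitudes of the *average* electron density
over all unit cells and all exposure time. Conformational heterogeneity —
static (site-to-site) or dynamic (in time) — enters the data only through
that average, and the standard refinement model compresses it into one
parameter per atom: an isotropic B-factor, or six anisotropic U components.
Both encode a single-site Gaussian. `bfaudit` quantifies what this
compression does when the underlying motion is *not* single-site Gaussian,
using crystals whose heterogeneity is synthetic and therefore exactly known.

The package is organised as a chain whose two endpoints can be compared
atom by atom: the generator records the true positional moments of every
atom while it samples, and the refinement engine estimates displacement
parameters from nothing but the averaged amplitudes, exactly as a
crystallographer would.

## Conventions

* Isotropic Debye–Waller convention: `B = (8π²/3)⟨|Δr|²⟩`, so `RMSF = 1 Å`
  corresponds to `B ≈ 26.32 Å²`. The anisotropic tensor is the Cartesian
  positional covariance `U = ⟨Δr Δrᵀ⟩` (Å²), with `B_eq = (8π²/3)·tr U` and
  `tr U = RMSF²`. These identities hold *by construction* in
  `compute_fluctuations()` and are asserted in the tests.
* Scattering-angle variable: `s = sinθ/λ = 1/(2d)` throughout. The
  Debye–Waller factor is `exp(-B s²)` (isotropic) or `exp(-2π² SᵀUS)` with
  `S` the Cartesian reciprocal vector, `|S| = 1/d`.
* Atomic form factors: the standard 4-Gaussian parameterisation
  `f(s) = Σ aᵢ exp(-bᵢ s²) + c` for H, C, N, O, P, S; `f(0)` reproduces the
  electron count to tabulation accuracy. A 5-Gaussian table would shift
  amplitudes of light elements by well under 0.1% and is not needed.
* Coordinates are fractional internally, wrapped to `[0, 1)` half-open;
  Cartesian Å appear at I/O boundaries and inside displacement sampling.
* Space groups P1 and C222₁ are supported, with C222₁'s eight operators
  (including the C-centring) stored explicitly from the standard tables.
  Systematic absences: `h + k` odd, and `(0,0,l)` with `l` odd.
* Reciprocal asymmetric unit: the lexicographically largest orbit member
  under the Laue group plus Friedel — for the orthorhombic class this is the
  unique all-non-negative representative; for P1, the hemisphere whose first
  non-zero index is positive.

## The synthetic-crystal generator

`build_template()` places a single chain — an idealised α-helix with
backbone N, CA, C, O and a CB–CG–CD side chain per residue, or any PDB file
— in the asymmetric unit. A restrained/mobile split is declared on the
chain: by default the N-terminal 60% of atoms are "restrained" and receive
only small harmonic jitter, which pins the lattice and suppresses rigid-body
contributions to B; the C-terminal 40% are mobile. The toy chain can be
padded with side-chain pseudo-atoms to match a stated total composition
(e.g. 373 atoms per chain for a united-atom villin headpiece model, giving
80,568 protein atoms in a 3×3×3 supercell of a Z = 8 cell).

`ensemble_spec()` attaches motion models to atom selections (each atom
covered at most once; uncovered mobile atoms stay put):

| kind | parameters | per-atom variance along the relevant axis |
|------|------------|--------------------------------------------|
| `harmonic_iso` | σ per axis (Å) | σ² |
| `harmonic_aniso` | 3×3 covariance (Å²) | as given |
| `bimodal_jump` | displacement d (Å), site probability p, local σ | p(1−p)\|d\|² + σ² |
| `rotamer_flip` | χ axis (two atoms), angle offsets (°), weights, local σ | two-point mixture over the rotation arc |
| `libration` | axis, angular σ (°) | ≈ r²σ²_rad at distance r from the axis |

Two design points matter scientifically. First, `bimodal_jump` and
`rotamer_flip` move their whole selection *coherently* (one Bernoulli or one
angle draw per conformer), emulating the rigid, correlated side-chain motion
that single-atom Gaussians cannot represent; `rotamer_flip` rotates the
subtree rigidly about the axis through the two named atoms, with the
template geometry defining the zero of the angle scale. Second, restrained
atoms default to σ = 0.058 Å/axis, i.e. RMSF ≈ 0.1 Å — the scale of a
tightly position-restrained crystal segment.

Sampling is site-resolved: in `iid_per_site` mode each of the `Z·n³` lattice
sites draws an independent conformer per snapshot (heterogeneity is then
both static and dynamic); in `shared` mode all sites are identical within a
snapshot. Each (snapshot, site) pair derives its own RNG substream from the
master seed by an integer hash, so results are bit-reproducible and
independent of evaluation order. Snapshots are stored without wrapping, so
mapping any monomer back to the reference frame (`ensemble_monomers`,
`map_to_reference`) is the exact inverse of its recorded generating operator
and lattice translation — **no least-squares superposition is ever
performed**, which is essential: fitting would silently absorb part of the
motion and corrupt the ground-truth B.

What the generator does *not* emulate: force-field energetics, solvent
(ordered or bulk), excluded volume between symmetry mates (conformers may
clash; the averaging phenomenon does not require sterics), correlations
*between* sites, and lattice defects. Passing tests therefore demonstrate
properties of averaging and refinement, not fidelity to any real crystal's
ensemble.

## Structure factors and averaging

For every snapshot the supercell's P1 structure factors are computed by
exact direct summation (`calc_sf_direct`); a density-grid FFT route
(`calc_sf_grid`, Gaussian splatting with per-atom truncation at 10⁻⁶ of
f(0)) is provided and agrees with the direct sum to better than 0.5% at a
0.3 Å grid — near-Nyquist grids alias the sharpest nitrogen form-factor
term, which is also why the pipeline adds a uniform +15 Å² to every atom
before density sampling and removes the corresponding `exp(-ΔB s²)` from the
averaged amplitudes afterwards (`shift_overall_b`; an exact inverse pair).

Averaging is *complex* (vector) averaging: `⟨F⟩ = (1/N) Σ F_k`. Over a
Gaussian ensemble this reproduces the Debye–Waller factor exactly
(`|⟨F⟩| = |F_static| e^{-8π²σ²s²}`), a property the tests verify by Monte
Carlo; over a multimodal ensemble it produces the interference terms (e.g.
`cos(π q·d)` for a two-site atom) that no single-site model can match.

`reduce_supercell()` keeps the supercell reflections on the unit-cell
lattice (indices divisible by the supercell factors — for identical cells
all others vanish by the lattice sum, and for disordered cells they carry
diffuse intensity that Bragg processing would not index), divides by the
number of cells so amplitudes are on the single-cell scale, and merges
symmetry equivalents of the target group by amplitude averaging after
aligning the operator phase shifts. The residual circular spread of aligned
phases is recorded; with finitely many sampled conformers the average is
only statistically symmetric, so weak reflections legitimately show spread
(a merge warning above 0.5 rad on reflections stronger than 2% of the
maximum). Merging equivalents quadruples the effective number of sampled
conformers per unique reflection.

## The refinement engine

`refine()` minimises the least-squares amplitude target

    Σ_work (|Fo| − k|Fc(B or U)|)²  [+ w_B Σ_bonded (B_i − B_j)²]

over the overall scale and per-atom displacement parameters, with atomic
positions held fixed. This is a deliberate simplification relative to
production maximum-likelihood refinement: the phenomenon under study —
a single-site Gaussian model confronted with multimodal truth — does not
depend on the statistical target, and a transparent engine makes every
gradient analytic and every result exactly reproducible. Consequences:
quantitative R factors are not comparable to any particular program's, and
no geometry, occupancy or position parameters exist. "Restrained" here means
only the optional B-similarity restraint over bonded pairs (1.8 Å cutoff).

Numerical choices: the scale k is profiled out analytically at every
evaluation (its gradient term vanishes at the optimum); optimisation is
bounded L-BFGS-B on `B ∈ [0.01, 999] Å²` (U bounds scaled accordingly) in
cycles of 40 iterations, stopping when the work-set R changes by < 10⁻⁵
(default 25 cycles); anisotropic refinement **starts from a converged
isotropic fit** — starting six components per atom from a flat overall B
can trap the quasi-Newton search in a poor basin, while the isotropic
optimum is reliably close; refined U tensors are projected back to positive
semidefinite (eigenvalues clamped at 10⁻⁴ Å²) and the number of projections
reported. Free reflections (default 5%, chosen uniformly by seed) never
enter the objective; R_free uses the work-set scale. On noise-free
self-consistent data the engine recovers per-atom B to < 0.2 Å² and R < 0.1%
from any start within bounds, and anisotropic mode never fits worse than
isotropic on identical data (nested models) — both are tested.

## The comparison layer

`compare_bfactors()` reports per-atom differences, the RMS deviation of the
two B profiles, the single largest difference Δmax, and an ordinary
least-squares regression of *refined on actual* B, optionally restricted to
a window (default 10–60 Å² — the range where one would still expect decent
agreement; below ~10 Å² agreement is trivially good, far above it the actual
values are dominated by a few extreme atoms). The regression is reported as
undefined when the actual-B variance is below 10⁻⁶ rather than propagating
NaN. `difference_map()` synthesises `(|Fo| − k|Fc|) e^{iφc}` maps (mean zero
by construction; the map variance satisfies Parseval against the coefficient
sums, which is tested), and `real_space_cc()` computes per-residue Pearson
correlations within 2 Å masks — a convention chosen to match how such maps
are usually displayed, not an optimised value.

## When does refinement underestimate heterogeneity?

The central design question was which conditions reproduce the
underestimation phenomenon, and the package's own experiments are
instructive:

* **Model at the dominant site** (a molecular-replacement solution from the
  starting/experimental structure), minority-population alternatives
  (p ≈ 0.3, or 70/30 rotamers): refinement locks onto the dominant
  conformation and reports essentially its local width. Actual B ≈ 19 Å²
  refines to ≈ 6 Å² in the shipped demo, for both isotropic and anisotropic
  B, while R stays near 8%. This is the regime the audit targets.
* **Model at the mean of a 50/50 two-site atom**: the low-resolution data
  pull B toward the full mixture variance while the sign-oscillating
  two-site interference pushes it higher still — the fit *over*estimates B.
  Underestimation is therefore not an automatic consequence of multimodality;
  it is tied to the model sitting in one well.

A related finding concerns resolution. Truncating the averaged data from
1.0 Å to 2.0 Å does **not** worsen the actual-vs-refined agreement under
this engine — it improves it slightly, robustly across heterogeneity
designs, restraint weights (0–50) and both refinement modes. The mechanism
is the same interference structure: the high-resolution data are what drive
the dominant-site lock, while the surviving low-resolution data carry the
full-variance envelope that a Gaussian *can* absorb, so the refined B drifts
toward the truth as resolution is lost. A worsening with lower resolution
evidently requires ingredients this engine deliberately omits (noise and
likelihood weighting, geometry-coupled positional refinement). The
resolution comparison is still shipped (`demo_resolution_config`, with
B-similarity restraints at w_B = 5, set a priori so the restraint is ~10% of
the data term at full resolution) because the direction of the effect is
itself a scientific result of the audit.

For the static-vs-dynamic contrast (`audit_static_vs_dynamic`), one
snapshot of 216 independently conformed sites is compared against many
snapshots. Since sites are i.i.d., both routes estimate the same ensemble;
the refined B profiles should agree within sampling error. The acceptance
threshold — RMS relative difference < 0.35 — was fixed a priori from the
sampling standard error of a variance estimate at 216 conformers
(√(2/216) ≈ 9.6% per atom, ~3.5 s.e. to allow for error correlation through
the refinement); the observed gap is well inside it, and shrinks by the
expected factor when the site count grows from 8 to 216.

## Problem sizes and reproducibility

The shipped demonstrations are sized for minutes on a single CPU: one unit
cell (8 sites, ≤ 280 atoms) at 1.5 Å with 200 snapshots for the
underestimation demo; 35 atoms, 1000 snapshots at 1.0 Å for Debye–Waller
recovery (σ = 0.2 Å/axis, recovered to ≈ 0.4%); a 3×3×3 supercell of a
2-residue chain (216 sites) at 1.8 Å for the static-disorder audit. The
full-scale configuration (3×3×3 supercell of 373-atom chains, 1.0 Å,
thousands of snapshots) is expressible in the same config schema but is a
long-running computation; the bookkeeping quantities for that composition
(atom counts, monomer pool, unique reflections, Matthews coefficient from
the shipped HP35 sequence) are computed exactly by `crystal_bookkeeping()`.

One caveat on exact integer reproducibility: the number of unique
reflections at a resolution boundary is sensitive to the third decimal of
the cell constants — for the reference cell, plausible roundings of the
printed cell move the 1.0 Å count by ±2 — so counts from differently
rounded cells can disagree by a reflection or two even when the enumeration
itself is exact (ours is pinned against a brute-force full-sphere oracle in
the tests).

Every stochastic step — sampling, free-set selection — derives from the
configuration seed; `run_pipeline()` twice with the same config is
bit-identical, and the YAML config round-trips to identical behaviour.

## Known limitations

* Orthorhombic cells and the P1/C222₁ pair only; no space-group inference.
* No solvent model of any kind; amplitudes correspond to protein-only cells.
* No positional, occupancy or geometry refinement; no TLS; no likelihood
  target. R factors are internally comparable only.
* Hydrogens are not modelled (templates are heavy-atom); occupancies are
  fixed at 1.
* The generator's motion models match summary scales (RMSF ranges,
  population ratios) of realistic side-chain disorder, not any specific
  protein's conformational distribution.
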