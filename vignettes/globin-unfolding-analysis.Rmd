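---
title: "Models and methods: globin unfolding trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: globin unfolding trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what its synthetic-data tests do and
do not demonstrate about real trajectories.

## The analysis problem

Thermal-unfolding simulations of holomyoglobin (a 153-residue, eight-helix
globin with a heme cofactor coordinated by His93) are summarised by a small
set of observables: per-residue secondary structure over time, the computed
CD ellipticity at 222 nm, Cα RMSD against the native structure, radius of
gyration, SASA, main-chain hydrogen-bond counts, the Fe–His93 distance that
signals heme loss, and cluster structure in the (RMSD, H-bond) plane that
reveals unfolding intermediates. `globinmelt` computes all of these from a
multi-model PDB export of the trajectory. Running the MD itself is out of
scope; so is any force-field energetics.

## Secondary structure: the Kabsch–Sander dialect

Hydrogen bonds between backbone amide (N–H) and carbonyl (C=O) groups are
scored with the classical electrostatic energy
\[
E = 27.888\left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} - \frac{1}{r_{OH}} -
\frac{1}{r_{CN}}\right)\ \text{kcal/mol},
\]
distances in Å, with a bond called at \(E < -0.5\). Amide hydrogens are
always re-placed geometrically (1.00 Å from N, opposite the preceding
carbonyl oxygen) regardless of whether the input file carries hydrogens:
this makes the assignment deterministic and independent of how the
trajectory was exported. Prolines and the N-terminal residue donate no
bonds. Near-coincident atoms (any of the four distances below 0.5 Å) take
the conventional clash energy −9.9.

Candidate pairs are restricted to sequence separation \(|i-j| \ge 2\) and
Cα–Cα distance ≤ 9.0 Å. The prefilter is verified loss-free in the test
suite by comparing against an exhaustive all-pairs search on every fixture;
at the −0.5 kcal/mol criterion a bond with Cα atoms further than 9 Å apart
is geometrically impossible. At most the two lowest-energy acceptors per
donor are kept.

Assignment follows the standard patterns: an n-turn at i is a bond from
CO(i) to NH(i+n) for n = 3, 4, 5; two consecutive n-turns make a minimal
helix (G/H/I); parallel and antiparallel bridges follow the Kabsch–Sander
four-bond patterns, with isolated bridges coded B and runs of two or more
consecutive bridges (ladders) coded E; T marks turn residues outside
helices; S marks bends, defined by the virtual Cα angle over (i−2, i, i+2)
exceeding 70°. Conflicts resolve by the priority H > E > B > G > I > T > S,
applied by layering the codes from low to high priority; ties inside one
class fall to the earlier-starting pattern simply because it is written
first. Two simplifications relative to full DSSP are deliberate: β-bulges
are not merged into ladders, and no π-helix chirality or bulge annotations
are produced. Both are irrelevant for a helix-dominated globin and would
only complicate the sheet bookkeeping of the late unfolding frames.

**Helical classes.** "Helical residue" counts default to codes {H, G, I};
a switch to {H} only is provided (`helix_classes` arguments). Total
helicity traces are what the default is meant to reproduce; strict-α
counting changes the absolute level by a few residues but not the decay
behaviour. Helix segments shorter than 4 residues (one α-turn) are
discarded by `helix_segments`: with truncation corrections k ≈ 2.6–3 such
stubs contribute nearly nothing to the CD signal, and counting them as
helices would distort the per-helix correction.

## The ellipticity model

Forward model, for helix segments of \(r_i\) residues \((i = 1..N_h)\):
\[
[\theta]_{222} = \frac{[\theta]_{helix}}{N_r}\sum_i \max(r_i - k,\, 0)
 \; + \; [\theta]_{RC}\,(1 - f_H), \qquad f_H = \frac{\sum_i r_i}{N_r}.
\]

Parameters, with defaults:

| parameter | meaning | default | units |
|---|---|---|---|
| \(N_r\) | residues in the protein | 153 | residues |
| \(N_h\) | number of helices | state-dependent (8 native) | — |
| \(k\) | helix-truncation correction | 2.57 (3.00 alternative) | residues |
| \([\theta]_{helix}\) | infinite-helix signal | −36,800 (Mb) / −39,500 (general) | deg·cm²·dmol⁻¹ |
| \([\theta]_{RC}\) | random-coil signal | +1000 | deg·cm²·dmol⁻¹ |

Design choices that were open:

* **Random-coil term.** The coil absorption is applied in proportion to the
  coil fraction, \([\theta]_{RC}(1-f_H)\). This is the reading under which
  the model reproduces the published helix-fraction table for the five
  myoglobin reference states exactly at two decimals, which is the
  package's anchor for the functional form.
* **Clamping.** In the forward direction segments with \(r_i \le k\)
  contribute zero helix signal (`max(r_i − k, 0)`). The inverse solves the
  *unclamped* linear relation for the total helical residue count R — the
  inversion assumes all helices longer than k, which holds for every
  reference state. Forward∘inverse is an exact identity (tested to 1e-9)
  whenever all segments exceed k.
* **Rounding.** Published fractions are reproduced with half-away-from-zero
  rounding at two decimals (`round_half_away`), and residue counts at the
  nearest integer. Base R's bankers' rounding differs on exact .5 cases.
  The reproduced residue row (121/96/87/63/29) matches the published
  122/97/88/63/27 within ±2; the published row's own rounding is not
  internally consistent with any single parameter column, so exactness is
  only claimed for the acid-intermediate entry (63).
* **+500 truncation.** Reported trajectory ellipticities are capped on the
  positive side at +500: as \(N_h \to 0\) the model loses meaning and the
  trace should saturate rather than chase the coil term. The cap applies
  only to time series (`trajectory_ellipticity`); scalar calls always
  return the raw value, which is also kept in the `theta222_raw` column.

## Trajectory metrics

Coordinates are Å internally (PDB-native); every user-facing distance is
converted once at the API boundary (nm, nm²), never per record. RMSD uses
the Kabsch SVD superposition with determinant correction so a reflection is
never applied; the test suite cross-checks it against an independent
quaternion-method implementation. The radius of gyration is mass-weighted
over protein atoms with heme excluded by default (both switchable), since
the reference values it is compared against are protein crystal-structure
values; atomic masses come from a small built-in table with a 12 Da
fallback for unknown elements (masses only weight centres of mass). SASA is
Shrake–Rupley with a deterministic golden-spiral lattice (960 points per
atom by default; doubling changes totals by well under 1%), radii N 1.55,
O 1.52, C 1.70, S 1.80 Å, probe 1.4 Å, hydrogens excluded. Contact maps
default to Cα distance < 8 Å at sequence separation ≥ 3 and are compared by
Jaccard percentage — the contact definition is conventional, not prescribed
by any experiment, and is configurable.

Heme loss is declared at the first frame where the Fe–His93
centre-of-mass distance reaches 1.28 nm, twice its native equilibrium value
of ~0.64 nm. Single-chain input is assumed throughout (myoglobin is
monomeric); multi-chain files are rejected rather than silently merged.

## Intermediate detection

Frames are clustered by k-means in the (Cα RMSD, main-chain H-bond count)
plane. Features are used **raw** (nm; counts) so centroids are directly
comparable to values quoted in raw units; standardization is available via
a flag but changes which compromise the clustering makes — raw units weight
the H-bond axis more heavily, which is the behaviour the reported centroids
imply. Lloyd iteration is delegated to `stats::kmeans(algorithm = "Lloyd")`;
initialization is seeded k-means++ (not provided by `stats`), with ten
restarts and the best inertia kept, making results deterministic given the
seed. Silhouettes use Euclidean distance via `cluster::silhouette`
(squared-Euclidean assignment + Euclidean silhouette is the common
pairing); singleton clusters score 0. k defaults to 3 — native-like,
intermediate, unfolded — with `silhouette_scan` over k = 2..6 for model
selection. Persistence is reported as contiguous time intervals in which
one cluster holds >50% of frames (after a width-5 modal smoothing), and
`plateau_detect` flags intervals whose moving least-squares slope stays
below a tolerance times the series' global range/duration — an explicit,
reproducible stand-in for by-eye plateau identification.

## The synthetic-data generator

Everything the pipeline consumes can be generated with known ground truth:

* **Backbones** are built by NeRF internal-coordinate placement with ideal
  bond lengths/angles (N–CA 1.458, CA–C 1.525, C–N 1.329 Å; 111.2°, 116.2°,
  121.7°; ω = 180°) and dihedrals (−57°, −47°) for helix and (−139°, 135°)
  for strand. The strand values are the classical antiparallel-sheet ideal;
  they were chosen over the flatter (−119°, 113°) parallel values because
  an isolated ideal strand should carry *no* backbone hydrogen bonds, and
  the parallel values sit close enough to the C7 contact geometry that the
  electrostatic energy of i→i−2 pairs hovers marginally below the −0.5
  criterion. Coil dihedrals are drawn uniformly from φ ∈ (−170°, −100°),
  ψ ∈ (120°, 180°) — a permitted extended/PPII-like region kept clear of
  that same marginal zone.
* **The native holo state** uses eight helical segments totalling 122
  intended residues (A–H-like layout, His at 93 on the F-like segment)
  joined by coil linkers, compacted by seeded pivot Monte Carlo (linker
  dihedral resampling, accepted when the radius of gyration shrinks and no
  Cα pair at separation ≥ 3 comes under 3.2 Å) until R_g ≤ 1.8 nm. The
  dihedral helix runs give up one terminal residue on alternating segments,
  so the assigned helical count comes out ≈ 118 of the 122 intended —
  matching the observation that assigned solution-state helicity (105–120
  residues, f_H 0.69–0.78) sits slightly below crystal values because helix
  ends fray. The heme is a 5-atom pseudo-group (Fe + 4 carbons, Fe mass
  55.85 Da) placed 0.64 nm from the residue-93 centre of mass; only the Fe
  position enters any computation. Residues are poly-alanine: sequence
  identity is irrelevant to every implemented computation.
* **Unfolding trajectories** keep
  \(N(t) = \text{residual} + (122-\text{residual})e^{-\lambda t}\) intended
  helical residues (rounded), removing residues from segment ends with the
  C- and F-like segments depleted at twice the rate of the others (those
  helices are the first lost in thermal unfolding). Removed residues are
  re-dihedralized to fresh seeded coil each frame, the chain is rebuilt,
  and Gaussian jitter (σ = 0.3 Å per coordinate) is added. The heme
  distance ramps linearly from 0.64 to 2.5 nm over 0.5 ns, anchored so the
  1.28 nm loss threshold is crossed exactly at the programmed departure
  time — making the detector's job honest (the crossing frame is defined by
  the schedule, not by the detector).
* **Defaults are the study conditions**: 153 residues, λ = 0.2 ns⁻¹,
  200 frames over 20 ns (dt = 100 ps), heme departure at 3.7 ns, residual
  helicity 10 residues, seed 42. The 20 ns window and the 3.7 ns departure
  mirror the slowest (sperm-whale-like) case of the thermal unfolding
  scenario the generator emulates; the residual of 10 residues reflects
  that assigned helicity does not reach exactly zero over such a window.

**What the generator does *not* emulate** — and hence what green tests do
not show about real data: no excluded volume or physics in the unfolding
frames (only the native state is compacted), no solvent, no β-sheet
formation from partially unfolded states, no refolding recurrences, and
jitter is isotropic Gaussian rather than thermal motion. Parameter-recovery
results (λ within 20%, heme-loss time within one frame, exact cluster
recovery on separated blob fixtures) validate the *analysis chain*, not the
realism of any force field.

## Numerical and scale choices

* Exponential decay fits (`fit_exponential_decay`) use `minpack.lm::nlsLM`
  with a fixed initializer (offset = series minimum, N0 = first value, λ
  from a log-linear comparison of the first and last thirds) and a
  Nelder–Mead fallback, so fits are deterministic given the data. Constant
  series return λ = 0 with a `degenerate` flag instead of failing.
* The test suite and examples use a 200-frame, 153-residue trajectory as
  the standard problem size — large enough for stable decay fits and
  three-phase clustering, small enough that the full suite (including the
  end-to-end pipeline test) runs in a few minutes on one CPU. The SASA
  column of `frame_metrics` is opt-in (`sasa_points`) because numerical
  SASA is the one per-frame cost that dominates everything else.
* Degenerate inputs fail loudly and early: multi-chain PDB input, insertion
  codes, coordinates exceeding the fixed-width PDB field, inversion of an
  ellipticity outside \([\,[\theta]_{helix}, [\theta]_{RC}\,]\), clustering
  of fewer distinct points than clusters, plateau windows longer than the
  series.

## Known limitations

* The hydrogen-bond dialect omits β-bulge merging; sheet content in late
  unfolding frames may be fragmented into more, shorter ladders than full
  DSSP would report.
* The ellipticity model treats all helices as α; 3₁₀ and π content is
  folded into the same per-segment truncation correction.
* The inverse model's residue counts are exact solutions of an idealized
  linear model; their agreement with published reference values is ±2
  residues, limited by the published table's own rounding.
* `read_pdb_models` ingests multi-model PDB only — no XTC/DCD/mmCIF — and
  assumes a single protein chain plus an optional HEM group.
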