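# globinmelt

Post-simulation analysis of thermal unfolding trajectories of holomyoglobin
and related globins.

When a 153-residue globin is unfolded in silico at high temperature, the
questions a structural biologist asks are always the same: how fast is helix
structure lost, when does the heme cofactor leave, what would the trajectory
look like in a CD spectrometer, and are there persistent intermediate states
between native and unfolded? This package answers all four from nothing more
than a multi-model PDB export of the trajectory:

* **Secondary structure** is assigned per residue and per frame with the
  Kabsch–Sander hydrogen-bond model: amide hydrogens are placed
  geometrically, the electrostatic bond energy
  `E = 27.888 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol is evaluated for
  all candidate donor–acceptor pairs, bonds are called at `E < −0.5`, and
  helices (H/G/I), strands and bridges (E/B), turns (T), bends (S) and coil
  (C) follow from the bond repetition patterns.
* **Ellipticity** links that assignment to the experimental observable. The
  mean residue ellipticity at 222 nm of a protein with helix segments of
  r_i residues (i = 1..N_h) is modelled as

  ```
  [θ]222 = ([θ]helix / N_r) · Σ_i max(r_i − k, 0)  +  [θ]RC · (1 − f_H)
  ```

  with f_H = Σ r_i / N_r, the helix-truncation correction k (≈ 2.57
  residues per helix), the infinite-helix signal [θ]helix (−36,800
  myoglobin-optimized or −39,500 general) and the random-coil absorption
  [θ]RC = +1000 deg·cm²·dmol⁻¹. The model is inverted exactly (linear in
  Σ r_i), so measured ellipticities of myoglobin states can be converted to
  helix fractions *with* the corrections for the number of helices actually
  present and for random-coil absorption — the two corrections that naive
  linear f_H estimates omit.
* **Trajectory metrics**: optimal-superposition Cα RMSD (Kabsch SVD, no
  reflections), 2D RMSD matrices, mass-weighted radius of gyration,
  Shrake–Rupley SASA on a deterministic sphere lattice, residue contact maps
  with Jaccard similarity, and the heme-loss criterion — the Fe–His93
  centre-of-mass distance (~0.64 nm when native) crossing 1.28 nm.
* **Intermediates**: k-means clustering of frames in the (RMSD, main-chain
  H-bond count) plane with silhouette validation and persistence/plateau
  reporting.
* **Synthetic data**: a fully seeded generator builds idealized globin
  backbones (NeRF internal-coordinate construction), compact native-like
  holo states, and unfolding trajectories with programmable exponential
  helix decay and heme-departure time — so every stage of the pipeline is
  testable against known ground truth without any deposited data.

## Worked example

Convert the native holomyoglobin ellipticity of −24,000 deg·cm²·dmol⁻¹ into
a helix fraction, assuming its eight helices:

```r
library(globinmelt)
invert_ellipticity(-24000, ellipticity_params(N_h = 8))
#> <ellipticity_result> theta222 = -24000.0 deg cm^2/dmol,
#>   f_H = 0.7922 (0.79 at 2 dp), R = 121.21 residues, N_h = 8
```

0.79 is the fraction of the 153 residues in helical conformation implied by
the measurement; 121 helical residues agrees with the 120–122 seen in
crystal structures. The full reference-state table:

```r
mb_state_helix_fractions()
#>                Holo, pH 7 Apo, pH 7 Apo, pH 6 ApoI, pH 4   I/U
#> f_H (-39500)         0.75      0.59      0.54       0.39  0.18
#> f_H (-36800)         0.79      0.63      0.57       0.41  0.19
#> helix residues     121.00     96.00     87.00      63.00 29.00
```

Note the acid intermediate (ApoI): −12,000 read with the correct four
helices gives f_H = 0.41 (63 residues), whereas assuming all eight helices
would give 0.45–0.47 — a 15% overestimate.

A synthetic native holo-globin and its analysis:

```r
g <- make_native_globin(seed = 1)
a <- assign_ss(g)
sum(a$codes %in% c("H", "G", "I"))      # 118 helical residues
nrow(helix_segments(a))                 # 8 helices
radius_of_gyration(g)                   # 1.79 nm
heme_his_distance(g)                    # 0.64 nm
segs <- helix_segments(a)
forward_ellipticity(segs$length, ellipticity_params(N_h = nrow(segs)))
#> theta222 = -23207.8 deg cm^2/dmol, f_H = 0.7712
```

An unfolding run with ground truth (λ = 0.2 ns⁻¹ helix decay over 20 ns,
heme departure at 3.7 ns):

```r
traj <- make_unfolding_trajectory()        # 200 frames, seed 42
ss <- ss_timeseries(traj)
fit_exponential_decay(frame_times(traj), ss$helix_count)
#> <decay_fit> N0 = 109.79, lambda = 0.1662 1/ns, offset = -5.59
detect_heme_loss(traj)
#> <heme_loss> lost at t = 3800 ps (threshold 1.28 nm)
cluster_trajectory(traj, k = 3, seed = 42)$phases
```

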