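---
title: "Measuring conformer-ensemble coverage in torsion space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring conformer-ensemble coverage in torsion space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confcover)
```

## The model

`confcover` treats a conformer of a cyclic molecule as the vector of its T
ring dihedral angles. Side-chain torsions are deliberately excluded: any
sampling algorithm can be expected to cover them, so ring torsions carry the
discriminating signal. Two modelling decisions follow from the circular
nature of dihedrals:

* **Embedding.** Angles are discontinuous at the −180°/+180° cut, so each
  torsion θ is mapped to (sin θ, cos θ). The embedding is injective on
  (−180°, 180°], continuous across the cut, and bounded in [−1, 1], giving a
  2T-dimensional feature space in which Euclidean geometry is meaningful for
  small angular differences.
* **Maps.** PCA with centering but *without* scaling (all features already
  share the [−1, 1] scale) gives a linear torsion map. The fitting set is an
  explicit argument: a typical analysis fits the map on the broadest
  available reference (e.g. all MD and simulated-annealing snapshots) and
  projects every other ensemble onto it, so all ensembles live in one
  comparable coordinate system. Molecules lacking some reference torsions
  are carried with masked columns; on projection their missing features are
  mean-imputed with the map center, contributing exactly zero after
  centering. Component signs are fixed by making each component's
  largest-magnitude loading positive, so maps are reproducible across
  backends and row orderings.

## Coverage metrics

**Cluster mixing.** k-means (stats::kmeans, Hartigan–Wong, 25 random starts,
1000 iterations by default, 500 requested clusters at production scale) on
the leading 8 latent components of the combined ensembles. A cluster is
*mixed* when it holds members of ≥ 2 origins. Within-cluster conformational
spread is summarized by the all-pairs circular torsion RMSD (computed in
radians, reported in degrees); the overall max is the max of cluster maxima
and the overall median the median of cluster medians, with singleton
clusters defined as RMSD 0 and excluded from the overall median. Clusters
above 2000 members are subsampled to bound the quadratic pair count.
Cluster identity is seed-dependent; only distribution-level statistics
(mixed fraction, RMSD summaries) should be interpreted.

**Variance curves.** For each dimensionality d, the trace and determinant of
the sample covariance of the leading d latent columns. The determinant
(generalized variance) collapses towards zero once near-collinear directions
enter — with sin/cos features this typically happens beyond 7–8 components —
which is itself diagnostic but limits its use as a headline number.

**Mahalanobis coverage.** The package's central metric. The more restricted
ensemble (by convention the conformer-generator output) is the *training*
set: its latent mean μ and covariance S over the leading d components define
a local model, and every conformer x of both ensembles receives
D_M(x) = sqrt((x − μ)ᵀ S⁻¹ (x − μ)). Max and median distances are reported
for d = 2…K. Because adding a component can only add non-negative squared
distance, curves are monotone non-decreasing in d for every fixed point;
scales at different d are not directly comparable, so curves should be read
within one plot. Rank-deficient S at high d is handled by a named
regularization policy: the default `"floor"` floors eigenvalues at
10⁻¹⁰·λ_max inside the inverse, `"pseudoinverse"` drops null directions,
and `"fail"` raises an error naming the offending d. The floor default
allows distances up to the full feature rank despite near-zero eigenvalues
while leaving well-conditioned cases bit-identical to the exact inverse.

**Dispersion test.** Per-conformer Euclidean distance to the own-group
centroid (the mean, in the leading 8 components), a one-way ANOVA F on those
distances, and a permutation p-value over random label permutations with the
add-one convention p = (b + 1)/(n_perm + 1). The convention guarantees
p ≥ 1/(n_perm + 1) — with the production default of 10000 permutations the
p-value cannot fall below ≈ 10⁻⁴. Pairwise group differences
ΔD = D_ref − D_generator come with Tukey HSD intervals computed on the
distance values. The implementation is plain base R; the test suite
cross-checks distances and F against vegan's betadisper (type = "centroid")
as an independent reference.

## Conformer descriptors

**IMHB.** Donors are N/O with an explicitly bonded hydrogen, acceptors N/O
other than the donor. A contact counts when H···A ∈ [1.5, 2.6] Å and the
geometric D–H···A angle is ≥ 110°. The published angle window extends to
220°, which is unreachable for a geometric angle on [0°, 180°]; the upper
bound is kept in the configuration for fidelity but is vacuous by default —
we found no operational interpretation that would not silently change the
window, so we deliberately did not guess one. Each hydrogen counts at most
once (nearest qualifying acceptor), avoiding double-counted bifurcated
contacts.

**3D-PSA.** Shrake–Rupley surface integration restricted to polar atoms
(N, O, and their bonded hydrogens; sulfur and charged-atom contributions are
excluded by default but configurable), with Bondi radii, a 1.4 Å probe and
a deterministic golden-spiral point lattice (960 points by default;
relative change under 1 % against 3840 points on a 50-atom fixture).
Absolute values are method-dependent — different radius sets or vendor
algorithms shift them — so only values computed with identical parameters
should be compared, and the 95 ± 17.7 / 145 ± 21.4 Å² report thresholds are
binning conventions, not measurements. Exactly duplicated atoms are
collapsed before integration so degenerate inputs cannot double-count
surface.

**Energy bins.** Within each run, relative energies are shifted so the run
minimum is zero (MD snapshot energies are only comparable after per-run
zeroing), then binned low (< 6), mid (6 ≤ E ≤ 10) and high (> 10 kcal/mol),
with conformers above 100 kcal/mol flagged discarded. Both boundary cases
land in the mid bin: 6.0 is excluded from "< 6" and 10.0 included by
"≤ 10".

## The synthetic generator, and what passing tests show

`sample_ensemble()` draws conformers from a mixture of torsional basins,
each basin a product of independent von Mises distributions (the minimal
circular analogue of a Gaussian well; sampling by the Best–Fisher rejection
method, validated against uniformity and concentration-limit oracles).
`make_overlap_pair()` builds the canonical experiment: a generator-like
training set from shared basins only, and an MD-like test set that also
samples extra basins, so the planted coverage gap is known exactly. Default
fixtures use 16 torsions, mirroring a 16-membered macrocycle ring, with a
12-torsion preset for the smaller-ring masked-torsion pathway; basin
concentrations around κ = 20 (angular sd ≈ 13°) emulate the torsional
spread of room-temperature snapshot ensembles. An optional energy model
(per-basin offset plus Gamma-distributed excess) exists purely to exercise
energy binning.

What the generator does *not* emulate: cross-torsion correlation within a
basin (torsions are independent given the basin, which keeps the ground
truth analytic), anharmonic basin shapes, kinetic connectivity, and
solvent- or charge-dependent basin weights. Passing tests therefore demonstrate that the metrics detect
*distributional* coverage gaps of the planted kind; they do not certify
completeness of any real ensemble — no rigorous completeness criterion
exists — nor reproduce numbers tied to proprietary MD data.

## Numerical choices and test scale

* Angles are stored on (−180°, 180°], wrapped on ingest (270° → −90°,
  −180° → +180°); a single convention avoids double counting the cut.
* Atom indices are 1-based everywhere (torsion definitions, bonds), the
  natural convention in R; SDF files are 1-based already.
* Dihedral signs follow the IUPAC convention and are verified against an
  independent two-plane-normal oracle and bio3d. The signed torsion is
  symmetric under full reversal of the atom quadruple — a property the test
  suite asserts.
* k-means uses Hartigan–Wong, the stats::kmeans default and the algorithm
  used in the original protocol. Restart count and iteration cap are the
  protocol defaults (25 / 1000).
* Acceptance-level simulations are sized for laptop-scale runs: coverage
  recovery uses 20 seeds × 250 + 250 conformers × 8 torsions, cluster
  calibration 5000 + 5000 conformers with k = 50, and the dispersion
  type-I-error study 1000 null replicates at 199 permutations. These sizes
  give the statistical resolution the assertions need (e.g. binomial error
  ≈ 0.7 % on a 5 % rejection rate at 1000 replicates).

## Known limitations

* SDF ingest supports V2000 multi-record files; V3000 records are rejected
  with a pointer to conversion tools. XYZ-series input infers bonds from
  covalent radii, which can mis-assign bonds in strained geometries.
* The Mahalanobis curves compare distances, not densities; two ensembles
  with equal support but different populations inside it are invisible to
  the max statistic and only partially visible to the median.
* The dispersion test detects differences in *spread*, not in location;
  combine it with the cluster and Mahalanobis views.
* PCA maps are strictly linear; strongly curved torsional manifolds can
  fold in projection. This is a deliberate scope choice, keeping loadings
  interpretable per torsion.
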