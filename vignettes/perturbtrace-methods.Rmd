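---
title: "Models and methods in perturbtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in perturbtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

perturbtrace analyzes imaging-based pooled CRISPR screens in which the
perturbation identity of each cell is read from a combinatorial
ternary FISH barcode and the phenotype is the 3D folding of a traced
chromosome plus nuclear morphology. This vignette explains the models
the package implements, the tunable parameters that matter, the
numerical choices behind the geometry code, what the synthetic
generator does and does not emulate, and the package's known
limitations.

## The barcode codec

A cell barcode is an ordered string of 10 ternary digits ("trits"),
giving a code space of $3^{10} = 59{,}049$; both the digit count and
the alphabet size are configuration, so longer designs work unchanged.
On the nucleic-acid side each (digit, value) combination is a 41-nt
segment (two 20-nt hybridization sequences around a one-nucleotide
spacer), segments are joined by single `C` spacers, and each
combination is served by one linear and one padlock probe — 60 probes
for the default design — with the three values of a digit assigned to
three distinct fluorescence channels. The packaged digit-segment
sequences are deterministic synthetic stand-ins with the correct
lengths and structure; the published segments live in a vendor-format
supplement and are not redistributed here.

**Trit calling.** Per imaging round the called value is the channel of
maximal intensity, with quality defined as the top-to-second intensity
ratio; digits below `min_ratio` (default 2.0, a deliberately simple
and conservative reduction) are left uncalled. Image-level spot
fitting, drift correction and segmentation are upstream of this
package.

**Decoding policy.** The published description names an
error-correcting decoder without printing its rule, so the package
states its own and treats it as a design choice: an exact, fully
called match to a good code is assigned; an exact match to a known bad
(multi-sgRNA) code is rejected outright, even if a one-trit correction
could reach a good code — ambiguity safety first; otherwise all good
codes within trit distance `max_correction` (default 1) are collected,
with uncalled digits matching for free, and the cell is assigned only
when exactly one candidate remains. Zero candidates and multiple
candidates are distinct rejection reasons, which the pipeline reports
per screen as its primary QC surface.

## Codebook construction

The sgRNA–barcode correspondence is recovered from two sequencing
libraries joined on their shared 20-nt UMI. Barcode reads cover the
code from the two ends; the two end-anchored partial codes are merged
only if they overlap and agree everywhere, otherwise the UMI is
dropped (a gap or a conflict is an assembly failure, not an error).
A code is *good* when exactly one sgRNA supports it with at least
`min_reads` UMI-distinct associations (default 2, which suppresses
singleton chimeric reads; the source description filters on read
quality without printing a count threshold, so this default is the
package's own) and *bad* when two or more sgRNAs do. Library QC
reports the sgRNA dropout rate `(designed - detected)/designed`; with
the screen-scale design of 420 sgRNAs and 412 detected this is the
familiar 1.9%.

The generator can also build codebooks with a guaranteed minimum
pairwise trit distance of 3, used to demonstrate perfect single-error
correction: codewords are the kernel of a $3 \times 10$ GF(3) check
matrix whose columns are pairwise linearly independent (a shortened
ternary Hamming code, 2,187 codewords).

## Chromatin-trace metrics

A trace is an ordered set of 27 3D positions (nm), one per TAD, with
missing targets allowed. All metrics use pair-level deletion: a pair
contributes only when both endpoints are observed, which is unbiased
for frequency ratios. Traces with under 60% of targets observed are
dropped from population statistics (configurable QC floor).

- *Distances*: Euclidean; 351 distinct inter-TAD pairs at 27 targets.
- *Contacts*: strict `d < 500` nm between nonadjacent targets (index
  separation ≥ 2); both the threshold and the adjacency rule are
  configuration. Long-range contacts are split A–A / A–B / B–B by the
  compartment labels and summarized per trace, matching displays that
  count traces; pooling pairs per perturbation is a documented
  alternative the package does not use.
- *Radius of gyration*: RMS distance of observed positions to their
  centroid.
- *Polarization index*: $\mathrm{PI} = \sqrt{(1 - V_s/V_a)(1 -
  V_s/V_b)}$ over the convex hulls of the A- and B-compartment
  positions and their intersection — 1 for disjoint hulls, 0 for
  coincident ones. The formula is not printed in the screen
  description itself; it is adopted from the chromatin-tracing
  literature the screen builds on. Scrambled-label controls permute
  compartment identities while preserving the A:B count.

**Geometry numerics.** No 3D computational-geometry dependency is
used. Hull facets are found by plane enumeration over point triples
(exact for the ≤ 27-point sets that occur here, including coplanar
facets, which are merged per plane and measured via a 2D hull), and
hull volumes follow from the facet-pyramid decomposition. The
intersection volume is counted on a single shared voxel grid (default
48 cells along the longest edge) so that discretization bias cancels
in the ratios $V_s/V_a$ and $V_s/V_b$; fewer than four observed
targets per compartment, or a degenerate (coplanar) hull, yields a
missing PI rather than a number.

## Screen statistics

Per sgRNA, against the pooled non-targeting controls:

- *Distance phenotypes* (adjacent-TAD, 26 pairs; overall inter-TAD,
  351 pairs): the effect size is the mean per-pair log2 fold change of
  median distances, matching the per-pair fold-change displays; pairs
  observed in fewer than 5 traces on either side are excluded. For
  inference the package deliberately does **not** run the classical
  signed-rank across the per-pair medians: those 26/351 paired
  differences share the same underlying traces and are therefore
  strongly positively correlated, and treating them as independent
  makes the signed-rank grossly anti-conservative — in all-null
  simulations about 17% of perturbation-phenotype tests cleared
  FDR < 0.1 that way. The default p value instead comes from a
  two-sided rank-sum on per-trace summaries (each trace's mean log2
  ratio to the control per-pair medians over the pair set): traces are
  the independent sampling units, so this test is calibrated, which
  the suite verifies by checking p-value uniformity under a split
  null. The pair-paired signed-rank remains available as
  `distance_test(method = "pair_signedrank")` as a display statistic,
  with this caveat attached.
- *Contact phenotypes*: two-sided rank-sum on per-trace frequencies;
  log2 ratio of group means with a pseudocount of $10^{-3}$ only when
  a mean is exactly zero. The exact rank-sum null is used for small
  untied groups, the normal approximation otherwise.
- *FDR*: Benjamini–Hochberg, one family per phenotype across
  perturbations (one family per volcano panel).
- *z score*: (perturbation mean − control mean) / control SD of the
  per-trace summary; this definition is the package's, since the
  corresponding published table does not print one.
- *Hit calling*: FDR < 0.1 plus an effect floor |log2fc| ≥ 0.15, both
  configurable. The floor is the package's stringency choice: at the
  trace counts of the bundled screens (hundreds per sgRNA) null log2fc
  values scatter with SD ≈ 0.05–0.1, so a floor must sit several null
  SDs up to do its job of excluding significance-without-effect; 0.15
  is about half the smallest effect the flagship design plants (a 20%
  distance change, |log2fc| = 0.32). Non-targeting controls are never
  listed as hits.
- *Correlation analyses*: Pearson r over upper-triangle pairs (351
  points for full matrices) with the two-sided t test and Fisher-z 95%
  intervals; the A/B score matrix averages the two TADs' compartment
  scores; short versus long range splits at 3 Mb of genomic midpoint
  separation; hit clustering uses average linkage on $1 - r$ with
  deterministic leaf order; cross-feature correlations are
  BH-corrected across feature pairs.

## Nuclear morphology

Intensity unevenness is the population coefficient of variation of
in-mask voxel intensities (population SD so the closed-form phantom
values are exact); it is invariant to positive rescaling. Sphericity
is $\Psi = \pi^{1/3} (6V)^{2/3} / A$ on the 3D mask — the package
computes genuinely in 3D and notes that a 2D projection proxy is the
untested alternative. Masks are resampled to isotropic voxels first
(nearest neighbor for masks, linear for intensities; the screen's
imaging used 108-nm pixels and 200-nm z steps). The surface area is
the coarea integral $\int \lVert \nabla (G_\sigma * M) \rVert\,dV$ of
a Gaussian-smoothed copy of the mask ($\sigma = 0.8$ voxels, mask
zero-padded so surfaces at the array edge are kept): voxel-face
counting systematically overestimates area and was rejected. The
estimator is rotation-invariant to well under 0.02 and accurate to a
few percent at the phantom sizes used; its one known bias is the
rounding of sharp convex edges, which leaves a digitized 40-voxel cube
about 4% above the closed-form $\Psi \approx 0.806$ — the tolerance
the tests state. Segmentation is upstream: the package consumes masks,
and multi-component masks are an error unless the caller vouches for
them.

## The polymer model

A minimal bead-spring chain at $k_BT = 1$: harmonic bonds (stiffness
50, rest length 1), hard-core excluded volume at 0.8, and a
square-well attraction of depth `K` within a cutoff radius —
the self-interaction energy of the screen's three-group experiment
(K = 1, 0.4, 0.1; 100 conformations each). Sampling is Metropolis
Monte Carlo with an even mix of single-bead displacements (half-width
0.25) and crankshaft rotations, started from a self-avoiding growth
conformation, in an Rcpp kernel driven by R's RNG so runs are
bit-reproducible from the seed.

The published experiment does not print its force field, chain length
or schedule, so these are the package's calibration: 100 beads, cutoff
1.4 and 8,000 sweeps per replicate, with the well depth ramped
linearly over the first half of the run. The cutoff was chosen by
scanning so that the three prescribed energies span the coil–globule
transition — with a wider well (e.g. 1.8) both K = 1 and K = 0.4 sit
deep in the globule phase and do not separate, and a hard quench at
K = 1 freezes rough, kinetically trapped surfaces; the gradual ramp
avoids necklace-state trapping at desk-scale sweep counts. All of
these are `sim_config()` fields. Incremental energies are rebased and
verified against a from-scratch recomputation, and acceptance rates
outside [0.1, 0.9] attach a non-equilibration warning to the
replicate.

The bounding envelope is the union of spheres (probe radius 1) around
the beads, voxelized at a step fine enough to resolve the probe
(≤ probe/3) and scored with the same sphericity code path as nuclei —
a convex hull cannot be multi-lobed, and multi-lobedness is precisely
the claim of interest. Weaker interaction yields lower median envelope
sphericity; the packaged experiment reproduces the monotone ordering
with pairwise rank-sum p < 0.01 at 100 replicates per energy.

## The synthetic screen generator

The generator emulates the screen's data products, not its optics:

- *Library*: non-targeting controls plus 2–3 sgRNAs per gene (the
  screen-scale default is 420 = 10 + 410 over 137 genes), each
  assigned a distinct barcode sampled without replacement; dropout and
  two-sgRNA code collisions can be planted.
- *Readouts*: the true channel per round draws a lognormal "on" signal
  and the others background; with probability `miscall_rate` (default
  0.02) the signal lands on a wrong channel, and with `lowconf_rate`
  (default 0.02) it is attenuated to near background so the digit goes
  uncalled.
- *Traces*: a Gaussian-chain baseline (per-axis step SD 280 nm, giving
  adjacent-TAD distances of a few hundred nanometres) with
  compartment-dependent structure — A and B targets pulled toward
  their compartment centroids and the two centroids separated by
  600 nm — so polarization and compartmental contacts are non-trivial;
  2–4 traces per cell as in G1-gated cells (cell-cycle gating itself
  is modeled as a pre-applied filter, not simulated); localization
  jitter SD 50 nm per axis; 9% random target dropout, the rate implied
  by the screen's own census of observed positions per trace.
  Perturbation effects act geometrically and exactly where possible:
  contracting a compartment's positions about its centroid scales its
  intra-compartment distances by exactly that factor, a global
  contraction scales everything, step scaling drives adjacent
  distances, and a centroid shift tunes A–B proximity.
- *Nuclei*: ellipsoid phantoms (semi-axes ≈ 3.0 × 2.7 × 2.2 µm with 5%
  per-cell jitter) on anisotropic voxels; a planted `sphericity_lobe`
  splits the phantom into two displaced lobes, and `cov_delta` scales
  the brightness of Gaussian condensate blobs painted into an
  otherwise near-uniform intensity field.

Everything is a pure function of (configuration, seed). What passing
tests on these data do **not** show: robustness to real image
artifacts (bleed-through, drift, mis-segmentation), to Hi-C-realistic
baseline conformations, to PCR bias or indel-bearing reads, or to
partial knockout penetrance — the generator draws every cell of an
sgRNA from the same effect.

## Problem sizes and defaults used by the bundled runs

The flagship integration run uses 60 sgRNAs (52 targeting + 8
non-targeting) × 120 cells with six planted effects (two global
compactors ×0.8, two decompactors ×1.25, one lobed-nucleus, one
condensate-free), about 21,000 traces in total, standing in for the
screen's 17,304 cells and 57,286 traces; the null-calibration run uses
twenty 12-sgRNA × 30-cell all-null screens; the polymer experiment
uses 100 conformations per energy. These sizes are the package's
choices for a single-workstation reproduction.

## Known limitations

- The decoding rule, the read-count threshold of the codebook, the
  z-score and effect-floor definitions, the polarization-index
  formula's provenance and the entire polymer force field are stated
  package choices where the source description is silent; all are
  parameterized.
- The coarea surface estimator under-measures sharp convex edges by a
  few percent (documented above); shapes of interest here — nuclei and
  envelopes — are smooth at the voxel scale.
- Gene-level aggregation across sgRNAs, Hi-C import and pathway
  enrichment are out of scope; analyses are per-sgRNA.
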