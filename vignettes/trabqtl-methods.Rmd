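---
title: "Methods: trabecular morphometry and consomic QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trabecular morphometry and consomic QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabqtl)
```

`trabqtl` chains three analysis stages: (1) six-parameter trabecular
morphometry of binary micro-CT volumes, (2) a consomic-panel screen against
the host strain with a nonadditivity index, and (3) block-partition QTL
mapping on subconsomic panels. This vignette documents the models, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## 1. Morphometry

All estimators act on a `voxel_volume`: a strictly binary 3D array
(foreground = bone) with an isotropic voxel size in µm. Anisotropic voxels
are rejected rather than resampled. The region of interest is an axial
slab `[ref + offset, ref + offset + width)` below a user-supplied reference
slice (the growth plate is *not* auto-detected); slice indices are 0-based
and intervals half-open. Structures truncated by the ROI boundary are
included with no edge correction — the standard convention for slab ROIs —
so thickness values at the slab faces are mildly boundary-inflated; choose
slabs whose faces fall mid-gap when that matters.

**BV/TV** is exact integer counting, so it is the one parameter with no
discretization error and is invariant under axis permutation.

**Tb.Th / Tb.Sp** use the sphere-fitting local thickness: the local
thickness at a point is the diameter of the largest inscribed sphere
containing that point, and Tb.Th is its volume-weighted mean over the bone
phase. We compute the exact Euclidean distance transform (a separable
lower-envelope algorithm in C++), then sweep candidate radii in descending
order, binned to half a voxel: at radius *r* the set of admissible sphere
centres is `{distance-to-background ≥ r}`, and every yet-unassigned voxel
within *r* of a centre receives thickness 2*r*. The half-voxel binning
bounds the bin error at one voxel of thickness, which is also the accuracy
the phantom suite enforces. Tb.Sp is *defined* as the same operator on the
complement, so the duality `tb_sp(v) = tb_th(complement_volume(v))` is an
identity in the code, not an approximation. A phase that fills the whole
box has no opposite phase to measure against; its thickness is then
box-limited and flagged with a warning.

**Tb.N** defaults to the direct 3D model `1/(Tb.Th + Tb.Sp)` — the modern
standard, and the one consistent with "number of plates crossed per unit
length" for parallel-plate geometry. The classical plate model
`BV/TV / Tb.Th` is available via `tb_n(..., model = "plate")`. The two
models agree for ideal plates and disagree for rods; we make no claim of
numerical identity with any proprietary implementation, only of
definitional fidelity checked on phantoms.

**Euler characteristic and Conn.D.** χ is the alternating cell count
V − E + F − C of the cubical complex of closed foreground voxels,
equivalent to local 2×2×2 configuration counting; this realizes the
26-connected-foreground / 6-connected-background convention, which must be
fixed for χ to be well defined. Components (β₀) and enclosed cavities
(β₂ = background components not touching the ROI boundary) come from
union-find labelling in C++, and the connectivity is β₁ = β₀ − χ + β₂,
giving Conn.D = β₁/TV. The implementation is checked against a brute-force
enumeration of vertices, edges, faces and cells on hundreds of random small
volumes, plus canonical topologies (balls, tori, multi-loop frames, hollow
shells).

**SMI.** The structure model index is `6·V·S′/S²` with `S′ = dS/dr` the
response of surface area to an infinitesimal outward dilation: 0 for ideal
plates, 3 for ideal cylinders, 4 for a sphere. Numerically we build the
signed Euclidean distance field (zero level midway between bone and marrow
voxel centres, unit gradient across the interface), smooth it with a
1-voxel Gaussian, and triangulate iso-surfaces by marching tetrahedra (six
tetrahedra per cell, linear interpolation). Two facts drive the remaining
choices. First, within about a voxel of the binary interface the sampled
distance field is quantization-limited: measured areas there are inflated
by lattice wrinkles and their *derivative* with respect to the level is
systematically biased. Second, SMI is invariant under uniform dilation for
exactly the geometries it is meant to distinguish (a dilated plate, rod or
ball keeps SMI 0, 3, 4). We therefore evaluate the index on the body
dilated by 3 voxels — `V` = volume enclosed by the dilated iso-surface,
`S′` a central difference with half-voxel steps — where the field is
clean. The smoothing sigma (1 voxel), dilation (3 voxels) and step (0.5
voxel) are exposed as arguments. The cost of the dilation is a mild
plate-ward blending when distinct structures sit closer than roughly twice
the dilation; at trabecular scale (separations of tens of voxels at usual
resolutions) this is negligible, but SMI values on volumes with gaps under
~8 voxels should be read with care. On phantoms the estimator lands within
0.2 of the three limits at feature sizes of 10 voxels and converges as the
voxel size shrinks.

## 2. Synthetic data as study conditions

The phantom generator renders plates, square-lattice rods, balls and a
plate/rod mixture with closed-form ground truth attached. Plates are
phase-shifted so they do not touch the volume faces, and rod/ball centres
are snapped to voxel centres so the discrete inscribed sphere matches the
analytic one; an oblique `tilt_deg` exists purely to stress
orientation-robustness of the estimators.

The consomic simulator fixes the study scale at 26 substitution strains
(autosomes with four split into centromeric/telomeric halves, plus X, Y and
mitochondrial lines) plus both parents, with 8 animals per strain — a
typical consomic-panel size; per-strain sample sizes are configurable.
Parameter means for the host (BV/TV 0.14, Tb.N 4.2 /mm, Conn.D 120 /mm³,
Tb.Sp 0.22 mm, SMI 1.8, Tb.Th 0.042 mm) and the donor (0.05, 2.6, 40,
0.38, 2.7, 0.042) are realistic 10-week proximal-tibia values with the
characteristic contrast: the donor is far more fragile on every parameter
except thickness, which barely differs. Epistasis is modelled as shrinkage
at the whole-genome genotype: each single-substitution strain expresses its
full per-chromosome effect, but the donor parent sits at its own fixed
mean, so the effects sum to `epistasis_coefficient` times the parental
difference (defaults 13.90 for BV/TV and 12.91 for Tb.N, with 22 of 26
strains carrying nonzero effects spread over 0.5–1.5× their mean and the
largest assigned to the Chr15 line; thickness moves only in the Chr14
line). No generative mechanism is claimed — this is the simplest model
with the documented signature that summed single-chromosome effects
massively exceed the parental difference. Noise is Gaussian and
independent across animals *and parameters*; real measurements are
correlated within an animal, so the simulated trait correlation matrix
reflects strain-level architecture only. Passing screens on these panels
therefore validates the inference machinery, not distributional realism of
real micro-CT measurements.

The subconsomic simulator defaults to eight strains whose donor segments
form a nested telomeric ladder on a 100 Mb chromosome with markers every
10 Mb, plus the host and the full-chromosome line: every adjacent pair in
the similarity order then differs in exactly one block, the cleanest
mapping configuration. Four QTL are planted by default (Tb.Th up near the
centromere; BV/TV up mid-chromosome; BV/TV and Tb.N down in two telomeric
blocks). Planted blocks must sit on the breakpoint grid or the generator
refuses, because effects attached to unrepresentable intervals could not
be mapped back faithfully.

Marker alleles are the primitive genotype representation. Donor intervals
are always *derived* from them with the midpoint breakpoint convention
(the breakpoint estimate halfway between flanking discordant markers; a
flagged alternative is deliberately not offered — outer-bound uncertainty
is visible directly in the marker table). Making alleles primitive is what
lets genotype TSVs round-trip exactly.

## 3. Panel screen

`dunnett_screen()` performs the many-to-one comparisons with the pooled
within-strain variance (df = N − k) and computes each family-wise adjusted
p from the equicorrelated multivariate-t distribution with the exact
correlation `sqrt(n_i n_j / ((n_i+n_0)(n_j+n_0)))`, integrated by
`mvtnorm`'s quasi-Monte-Carlo under a fixed seed, so unbalanced panels are
handled exactly rather than by a balanced approximation. Strains with zero
pooled variance get p = 1 and a `degenerate` flag. The per-strain Welch
p-value is reported alongside for reference, but note the guaranteed
monotonicity (adjusted ≥ unadjusted) holds against the pooled-variance
per-comparison test that underlies the statistic, not against Welch's
variant, whose standard error differs. The family-wise type-I error of the
screen is verified at 0.05 ± 0.02 over 2000 simulated null panels (seven
strains of four animals each — large enough to exercise the multivariate-t
tail, small enough to keep the suite fast).

The trait correlation matrix uses Spearman's rank correlation with
midranks, computed over all individual animals pooled (strain means via
`by = "strain_mean"`); pooling individuals is the default because the
screen's correlation structure is a property of the panel, not of strain
averages. Constant columns yield a missing correlation with a warning.

The nonadditivity index sums `(mean_s − mean_control)` over strains flagged
significant (parents excluded) and divides by the parental difference,
times 100. It is invariant under affine rescaling of the parameter and is
exactly 100% for perfectly additive architectures. Its sampling noise is
dominated by the control and donor means entering every term; with 8
animals per strain, run-to-run variation of one–two hundred percentage
points around a planted 1390% is expected.

## 4. Block mapping

The strain alignment minimizes the total symmetric-difference length (Mb)
between adjacent strains' donor-segment sets. The optimum is found exactly
by Held–Karp subset dynamic programming for panels up to 12 strains (ties
broken to the lexicographically first optimal order, so results are
deterministic), with the host parent anchored at one end and the
full-donor parent at the other, as such panels are conventionally drawn;
larger panels fall back to a nearest-neighbour heuristic with a warning.
An exhaustive permutation search is the test oracle.

Blocks are the atoms induced by all donor-interval endpoints, merged when
no strain distinguishes adjacent atoms, numbered from the centromeric end;
they tile the chromosome by construction. Adjacent pairs (plus any
explicitly requested extra pairs — panels are sometimes drawn with a
wrap-around comparison, and `extra_pairs` reproduces either convention)
are tested per parameter by two-sided Welch t-tests at the Bonferroni
threshold α divided by the *realized* number of pairs. Each significant
pair is mapped to the blocks where the two genotypes differ: exactly one
differing block localizes the QTL; several differing blocks produce one
flagged `ambiguous` call per candidate block rather than a silent drop.
When nested donor segments place one QTL-bearing block inside another
pair's differing region, calls are reported per comparison; no
cross-comparison effect subtraction is attempted. The donor-allele
direction is the sign of (donor-carrying neighbour mean − other neighbour
mean) for the differing block.

End-to-end recovery is validated on 200 simulated panels with four planted
single-block QTL of 10·SE magnitude and randomized blocks and signs: ≥95%
of runs must return exactly the planted blocks and directions at the
0.05/pairs threshold. With nine tested pairs and five null pairs per run,
the Bonferroni-controlled false-positive side alone caps expected exact
recovery near 97%, so the bound is tight but not fragile.

## 5. Pipeline, formats, determinism

Volumes travel as 8-bit binary multi-page TIFFs with a JSON sidecar
(voxel size, ground truth); phenotypes as CSV (strain, animal id, age,
six parameters) with validation errors that name the offending row;
genotypes as marker TSV with `B`/`M` alleles. `run_pipeline()` chains
simulation (when no inputs are given), morphometry (when volumes are
given), the screen and the block mapper, and stamps every report with the
seed and a configuration hash; reports carry no timestamps, so identical
configuration and seed give byte-identical files. All stochastic steps
(simulators, the multivariate-t integration) derive from explicit seeds.

## Known limitations

- Segmentation, BMD calibration and growth-plate detection are out of
  scope: inputs are already-binarized volumes with user-specified ROIs.
- SMI inherits the usual caveats of dilation-based estimators on
  concave/mixed structures, plus the 3-voxel dilation noted above.
- Local thickness is half-voxel binned; sub-voxel thickness gradations are
  not resolved.
- The simulators draw independent Gaussian noise per parameter and do not
  emulate within-animal trait correlation, age trends, litter effects, or
  body-size confounds.
- Conn.D on heavily speckled volumes counts noise loops like any
  Euler-based estimator; no despeckling is applied.
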