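---
title: "Methods: connectome analysis of a songbird basal ganglia circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome analysis of a songbird basal ganglia circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bgconnect` implements the quantitative analysis layer used on dense
electron-microscopy reconstructions of the songbird basal ganglia
nucleus Area X: quality-control filtering, skeleton morphometry,
cell-type connectivity matrices, a permutation null model for the
pallidal target selectivity of medium spiny neurons (MSNs), and
directed reciprocity statistics — together with a synthetic-connectome
generator that provides ground truth for validating every stage. This
vignette explains the models and the choices behind them.

## Data model and units

A connectome is a set of tibbles: cells (id, type, fragment flag),
synapses, organelles, skeleton nodes (SWC-style parent-linked forests),
soma surface vertices and per-cell spine counts, plus the dataset
geometry. All stored coordinates are in nanometres; every derived
length, area or volume is in micrometres (µm, µm², µm³), converted at
computation time and never in storage, so values are converted exactly
once. Synapse size is defined as the synaptic mesh area divided by two
(both faces of the cleft are part of the mesh); the halving is enforced
as an exact invariant at construction. Dangling identifiers are hard
errors: silently dropping unresolved rows is the dominant failure mode
of connectome tooling, so nothing is ever dropped implicitly.

Skeleton edges inherit a compartment only when both endpoints carry the
same label; edges spanning two labels count toward total length but
toward no single-compartment length. This convention is conservative,
affects only the handful of boundary edges per cell, and makes
path-length tests exact.

## Quality-control filters

Connectivity analyses use synapses with classifier probability ≥ 0.6
and size ≥ 0.1 µm², restricted to axo-dendritic and axo-somatic
geometries; axo-axonic rows are excluded from analysis but kept in the
raw table. Intrinsic neurons count as complete when they carry at least
one node of each compartment and at least 200 µm each of axonal and
dendritic path length; extrinsic axon fragments (HVC, LMAN, dopaminergic
classes) require 50 µm of total skeleton, with 0 and 200 µm provided as
sensitivity modes. Dendrite completeness additionally flags any cell
whose dendrite approaches within 7 µm of the dataset bounding box.

All thresholds are inclusive (`>=`): "a minimum of x" reads naturally
as inclusive, and fixing the convention makes boundary cases testable.
Exclusion audits attribute each row to the *first* failing criterion in
a documented order (probability, size, geometry, unknown label), so
audit counts plus retained count always equal the input count. Filters
are idempotent and monotone in their thresholds; both properties are
asserted by tests.

## Morphometry

Per-cell features are computed from the skeleton, the soma vertex
cloud, organelles and the synapse table:

- **Soma radius**: the median Euclidean distance from the soma vertices
  to their componentwise median coordinate. Robust to uneven sampling,
  and exactly translation- and rotation-invariant.
- **Median radii**: medians of stored node radii per compartment; an
  even count takes the mean of the two middle values (the standard
  convention, fixed here for testability).
- **Mitochondrial volume density**: organelles are mapped to the
  nearest skeleton node of their representative coordinate (exact ties
  to the lowest node id), whole-organelle to one compartment — an
  acknowledged approximation for organelles straddling the soma–axon
  boundary. Density is voxel count × voxel volume (default
  10 × 10 × 25 nm) per µm of compartment path length; the somatic
  variant divides by the estimated spherical soma volume instead.
- **Spine density and myelin fraction**: annotated spine count per µm
  of dendrite, and myelinated axonal path length (edges with both
  endpoints flagged) per total axonal length. Real pipelines derive
  both from surface models; here they are defined on the tabular inputs
  and documented as proxies.
- **Surface areas and volumes** come from truncated-cone (frustum)
  sections between consecutive nodes plus a spherical soma — a proxy
  for mesh surfaces, which are out of scope.

Undefined features (empty compartment, no vertices) are `NA`, never
zero, and rows containing them are dropped from embeddings with an
audit. The embedding standardises each feature to a z-score with the
population standard deviation and projects onto principal components;
the sign of each component is fixed so its largest-magnitude loading is
positive, removing the sign ambiguity of PCA. A constant feature is an
error naming the feature. The full feature vector spans 18 features
(lengths, surfaces, radii, soma size, cell volume, three mitochondrial
densities, vesicle-cloud density, three per-surface synaptic densities,
spine density, myelin fraction); a nonlinear (UMAP-style) embedding is
deliberately not provided — its coordinates are not stable across
library versions, nothing downstream consumes them, and the linear
projection separates the classes the thresholds target.

The three fast-spiking-like interneuron classes are assigned by four
thresholds: 0.025 µm³/µm axonal mitochondrial density, 0.11 µm axon
median radius, 11.5 µm soma radius, 0.025 /µm spine density. A class is
assigned only when the cell falls strictly on that class's side of all
four; equality or mixed sides leave the cell unassigned. The published
account gives the thresholds but not the sides, so the side table is a
package default (configurable): INT2 small-somaed and spiny; INT3
large, thick-axoned and mitochondria-rich; INT1 the remaining
consistent profile (large soma, thin axon, sparse spines). Note the
thresholds discriminate *within* the fast-spiking-like candidate pool:
MSNs (small and spiny) satisfy INT2's sides and large pallidal cells
can satisfy INT3's, so the classifier should be applied to candidate
interneurons, as in the worked example. The soma threshold is treated
as operating on the same scale as the median-distance soma size
feature; published soma sizes for these classes (~9–14 µm) straddle
11.5 µm on that scale, and the scale is configurable if a dataset's
estimate differs systematically.

## Connectivity matrices and routine statistics

Pair connections aggregate filtered synapses per ordered (pre, post)
pair with count, summed area and per-compartment breakdown; a
"multisynaptic" connection is one with at least two synapses. Type
matrices sum areas (and counts) over all cells of each ordered type
pair under three normalisations: global (entries sum to 1), output rows
(each nonzero row sums to 1) and input columns (each nonzero column
sums to 1), with denominators over the included type set only, so
removing a type and renormalising equals computing on the reduced set.
Compartment-targeting summaries report per-compartment *medians* of
per-cell percentages, which deliberately need not sum to 100.

Group comparisons follow the nonparametric convention: Kruskal–Wallis
omnibus, pairwise Wilcoxon rank-sum post hoc, significance at
p < 0.005; correlations are Spearman. These call the standard R
implementations; the package adds only the audit-friendly interfaces.

## The selectivity permutation null

The GP ratio of an MSN is GPi/(GPe + GPi) of summed synaptic area (or
synapse count; both weightings are provided and area is the default).
MSNs with no pallidal output are excluded with an audit count. The null
model asks: if MSN identities were irrelevant to target choice, how
selective would MSNs look? Each iteration permutes the presynaptic-id
column of the MSN→pallidum synapse table, leaving targets and sizes in
place. This conserves, exactly: the total synapse count and area, the
count and area received by every target cell, and each MSN's synapse
count. The per-iteration per-MSN ratios are histogrammed in 30 equal
bins on [0, 1] (left-closed bins, the last bin closed on both sides);
across 100 iterations the per-bin mean and 2.5/97.5 percentile band are
reported, together with the per-iteration fraction of MSNs with ratio
≥ 0.9. The percentile band makes no distributional assumption. Modal
bins break ties toward the bin nearer 0.5, so a boundary atom never
wins a tie against the central bump. One master seed drives the run;
iteration *i* permutes under derived seed `seed + i`, so any iteration
is reproducible in isolation. Shuffling operates on individual synapse
rows, not on aggregated connections: permuting connections would
destroy the per-target synapse-count margin that the null is defined to
preserve.

On enumerable inputs the Monte-Carlo null is checked against exhaustive
enumeration: the bundled `three_msn` toy has six synapses, hence 720
row permutations, and the test suite verifies that Monte-Carlo
selectivity fractions and mean ratios converge to the enumerated values
within Monte-Carlo error.

## The synthetic generator

The generator emulates the statistical structure the analyses assume,
and exports ground truth (true types, realised features, true GP
ratios) that no analysis function reads.

- **Pallidal synapse counts.** Per MSN, counts onto GPi and GPe are
  drawn from negative binomials fitted by method of moments to
  9.6 ± 7.2 and 3.54 ± 5.4 (the published per-MSN means ± SD); a
  Poisson is used when SD² ≤ mean, and an impossible pair errors. The
  published SDs exceed the means, ruling Poisson out for the defaults.
- **Two target-assignment modes.** `"marginal"` (default) draws the two
  counts independently, reproducing both printed marginal SDs. Because
  the GPe marginal then has a 36% atom at zero, a marginal-mode
  population is *itself* more selective than the permutation null — an
  intended property of the emulation, matching the direction of the
  published finding, but a confound when one wants to validate the null
  machinery. `"pooled"` mode keeps the same per-MSN totals and assigns
  each synapse's target type independently with the mean count share
  (0.73), making an unselective population exchangeable with the null:
  calibration tests (observed fraction inside the null band ~95% of the
  time) use this mode. Means are exact in both modes; pooled mode
  trades the GPe marginal SD (2.9 realised vs 5.4 configured) for
  exchangeability.
- **Synapse areas.** Lognormal per type pair (σ = 0.6, a typical
  synaptic-size spread). The GPe-side mean is 0.25 µm² and the GPi-side
  mean is solved in closed form so the *expected* aggregate GPi share
  of MSN→pallidum synaptic area equals the configured value (default
  0.75); GPi synapses therefore come out larger whenever the area share
  exceeds the count share, matching the published direction. At 8,000
  MSNs the realised share recovers the configured one to ±0.01 for
  shares 0.5–0.9.
- **Selective subpopulation.** `selective_fraction` forces that share
  of MSNs to send all pallidal synapses to GPi (ratio 1), providing a
  positive control whose observed selectivity must exceed the null
  band.
- **Skeletons** are parameterised trees: a soma ball with antipodal
  surface-vertex pairs (so the median-vertex centre, and hence the
  computed soma radius, is exact), plus axon and dendrite sticks folded
  into a 25 µm territory at 5 µm node spacing. A configurable fraction
  of MSNs is placed so the dendrite provably enters the 7 µm boundary
  margin (default 10%); all other cells stay provably clear of it.
  Realised (not target) lengths are recorded as ground truth.
- **Organelles and spines** are placed at compartment nodes with sizes
  rescaled so each cell's realised mitochondrial and vesicle densities
  match its drawn feature values up to integer voxel rounding;
  spine counts are rounded products of density and realised dendrite
  length. Interneuron features are drawn from Gaussian clusters whose
  default centres sit 3.3 SDs from the classification thresholds.
- **Fragments** get lognormal total lengths (median 10 µm), emulating
  the published fragment-length scale, and extrinsic projections
  (HVC/LMAN/DA onto MSNs and STNs) arrive at about one synapse per
  10 µm of fragment.
- **QC mode.** By default all probabilities are 1 and areas mostly
  clear the size filter: the default dataset emulates an
  already-filtered table. `qc_probability_mode = TRUE` draws a bimodal
  probability mixture, shrinks areas and injects non-axonal and unknown
  compartments so the filters have non-trivial work; filter tests use
  it.

Everything is deterministic under the seed, byte-for-byte.

### What the generator does not emulate

Real neuropil packing, mesh geometry, spatial synapse placement along
specific dendrites, and — importantly — the *joint* distribution of a
cell's GPi and GPe counts. The published data show 21% of MSNs
exclusively targeting GPi and ~73% targeting both, which no pair of
independent (or copula-coupled) negative-binomial marginals with the
printed moments can reproduce: those marginals force a 36% zero-GPe
fraction. One visible consequence: in the real data the permutation
null's GP-ratio histogram peaks near the aggregate area share (~0.75),
while under the synthetic marginals the single tallest bin is the
boundary bin at 1.0 (~10.6% of null mass, from MSNs with few pallidal
synapses that land entirely on GPi under shuffling), with the central
bump at 0.75–0.78 carrying ~9% per bin. The bump location is
reproduced; the modal *bin* is captured by the boundary atom. This is a
property of the published marginal moments, not a tunable of the
implementation, and we chose not to distort the documented count model
to force the modal bin inward.

## Problem sizes and runtime choices

Test and demonstration runs use 8,000 MSNs where a quantity's precision
matters (share recovery, count moments, the pooled null histogram),
2,000 MSNs for repeated calibration experiments (the coverage of a 95%
band does not depend on n), and populations of tens to hundreds for
exact oracle comparisons. Null runs use 100 iterations, matching the
published procedure; the toy enumeration uses 10,000 iterations against
all 720 exact permutations.

## Interfaces

The package is function-first: generation, filtering, morphometry,
matrices, the null and reciprocity are exported functions over tibbles,
composable with the pipe, with `tidy()`/`glance()` accessors and
`autoplot()` figures; `run_all()` orchestrates the full pipeline into a
report whose JSON serialisation embeds the complete configuration and
seed, and `bg_demo()` runs everything on a small synthetic dataset.
Shell-level entry points are intentionally not provided: the natural
unit of use is an R session or script against these functions, and
`scripts/acceptance.R` shows the scripted pattern.

## Known limitations

- Spine density and myelin fraction are tabular proxies (see above).
- Whole-organelle nearest-node mapping can misassign organelles that
  straddle compartment boundaries.
- Frustum surfaces underestimate true mesh surface area for highly
  non-cylindrical neurites.
- The INT side table and the soma-size scale are defaults that real
  datasets may need to reconfigure.
- The generator's marginal count model cannot match the published
  joint GPi/GPe count structure (see above); analyses of joint-count
  properties on synthetic data should use it with that caveat.
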