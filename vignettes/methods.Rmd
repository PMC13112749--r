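---
title: "Models and methods behind schickit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind schickit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(schickit)
```

`schickit` implements the downstream analysis stack for split-pool barcoded
single-cell Hi-C libraries: pair classification and per-cell QC, cell
calling, contact matrices and tracks, chromatin-state (melting/concretion)
detection, and cell phasing, together with a synthetic data generator that
plants ground truth for all of it. This vignette explains the models, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## The synthetic library

`toy_genome()` builds two small species — "alpha" (chrA1 20 Mb, chrA2
15 Mb, chrX 5 Mb, chrY 1 Mb, chrM 16 kb) and "beta" (chrB1 18 Mb, chrB2
12 Mb, chrBM 16 kb) — sized so 50-kb binning is meaningful on a desk. Cut
sites for a 4-bp cutter are drawn with exponential inter-arrival spacing
(mean 500 bp, the genome-wide statistics of a GATC digest) rather than by
scanning a literal sequence; `write_genome_fasta()` can emit a sequence
with the motif planted at exactly those sites (over an A/C/T background in
which the motif cannot occur by chance), so digestion round-trips exactly.

`simulate_cells()` draws, per barcode:

* **Cells and doublets.** Each slot becomes a cross-species doublet with
  probability `doublet_rate`; the two merged profiles keep their own
  species, state, and target counts. Background barcodes draw low lognormal
  counts (median 30 pairs) of unstructured contacts.
* **Categories.** Each pair is valid, `dangling_end`, `self_circle`,
  `religation`, or sub-mapq "dumped" by a multinomial draw. Defaults
  (0.5/0.2/0.1/0.1/0.1) put the valid-pair ratio near 50%, the efficiency
  scale of enrichment-based single-cell protocols; the magnitudes of
  artifact fractions in real libraries are otherwise free parameters.
  Dangling ends and self-circles sit exactly at fragment termini with
  inward/outward strands; religation pairs span adjacent fragments inward.
* **Valid contacts.** Cis separations follow a truncated power law
  `P(s) ~ s^-alpha` on `[1 kb, L]` (default `alpha = 1`); trans pairs pick
  two chromosomes weighted by copy-number x length. Ends are snapped
  0-300 bp inside their restriction fragment (sonication after ligation),
  and then nudged off same-fragment or adjacent-inward configurations so a
  planted-valid pair is classified valid — without this the classifier
  would be scored against label noise rather than its rule table.
* **Structure.** Intra-TAD and same-compartment contacts are favoured by
  bounded rejection-with-redraw (weights 4 and 3; a weight of 1 disables
  the structure, which the decay-slope checks use). TAD boundaries sit
  every 500 kb in both states; inside the designated melting region
  (chrA1:12-15 Mb) the concretion state carries boundaries every 250 kb
  and the melting state none — reduced insulation merging domains versus
  solidification into smaller domains. Compartments alternate in 2-Mb
  blocks; replication timing alternates early/late in 1-Mb blocks.
* **Phase.** Each cell's scalar phase in [0,1] tilts the probability that a
  cis anchor lands in an early domain (`0.5 + 0.6 * (0.5 - phase)`) and
  log-shifts the cis separations, moving contact mass between short and
  long range across the cycle.
* **Duplicates and false positives.** A `duplicate_rate` fraction of rows
  is re-emitted as copies of earlier rows of the same barcode; a
  `mito_fp_rate` fraction of valid pairs has one end relocated to chrM.

All randomness flows through one seed; the same configuration is
byte-identical across runs. What the generator does **not** emulate: read
sequences and sequencing errors (barcodes are fields, with an optional
mutation mode for demultiplexing tests), mappability and GC bias, polymer
physics or loop extrusion, copy-number variation, and inter-cell covariance
beyond the planted states. Passing tests therefore demonstrate correctness
of the computations under known truth, not robustness to every artefact of
real libraries.

## Classification and QC

Classification follows the HiC-Pro conventions: canonical mate order,
fragment assignment by binary search on the cut-site map, then the rule
table (trans valid; same fragment inward = dangling end, outward =
self-circle, equal strands dumped; adjacent inward = religation; otherwise
valid cis). `min_mapq` defaults to 10; mapq-dumped pairs are excluded from
the *reported* denominator while rule-table-dumped pairs stay in it. No
insert-size/fragment-end distance filter is applied by default; the
valid-pair ratio uses valid pairs *before* deduplication, the duplication
rate is the duplicated share of valid pairs, and cis/trans and the
mito-nuclear false-positive rate (pairs with exactly one end on chrM) use
unique valid pairs.

## Cell calling

Barcodes are ranked by unique valid pairs (ties broken lexicographically).
Knee finding works on the min-max-normalized (log10 rank, log10 count)
profile via the Kneedle difference curve `d = x + y - 1`. Our detector
departs from the classical arg-max of `d`: on curves whose called-cell
plateau spans a decade or more, the arg-max sits mid-plateau (log-rank
stretches the head) and misses the cliff by 10-20% of ranks. Instead a
knee candidate is a point whose difference curve falls by at least
`sensitivity x 0.02` within a 1%-of-curve lookahead window **and** whose
count drop is significant against Poisson shot noise
(`dlog10(count) x (c_hi c_lo)^(1/4) >= 5 x sensitivity` — integer-count
steps such as 2 to 1 at the background tail are never knees); among
candidates the knee is the steepest single step, i.e. the collapse point.
`knee2` on the full curve separates background; `knee1`, searched on the
sub-curve above `knee2` and restricted to its top half (a "doublet
boundary" below half the cells would be an edge artifact), separates
doublet-prone high-count barcodes. A featureless curve yields an explicit
no-knee result with everything labelled background.

Species assignment uses the inclusive 89% rule on unique valid pairs per
genome, symmetric in the two species; ties at the assignment threshold
never default to a species. The collision rate divides cross-species
doublets by all post-knee valid cells including the doublets themselves —
the defensible denominator when the printed fraction of an experiment
cannot be reconstructed from its counts.

## Matrices, decay, saturation, APA

Binning conserves mass (one upper-triangle increment per pair). ICE
balancing masks zero-coverage bins plus the lowest 2% of non-zero bins and
iterates `w <- w * mean(s)/s` on weighted row sums until their coefficient
of variation drops below `1e-5` (at most 200 iterations; non-convergence
returns the last weights flagged). Weights are normalized to mean 1 on
unmasked bins so an already-balanced matrix is a fixed point and scaling
all counts leaves the normalized balanced matrix unchanged.

Distance decay uses log10-spaced bins (8 per decade from 1 kb) and reports
both per-bin probability (summing to 1 per cell) and density
(probability / bin width), whose log-log slope estimates the decay
exponent. Downsampling is uniform without replacement and refuses requests
beyond the available depth. The saturation model `Y = Bmax X/(Kd + X)` is
fitted by constrained Levenberg-Marquardt least squares in linear space
(initialized at `Bmax = 2 max Y`, `Kd = median X`); log-space fitting is a
matter of taste we did not expose because the 2%-noise recovery already
sits well inside tolerance. Coverage counts contact *endpoints* (two per
pair) over non-mito bins — the denominator choice is documented rather
than canonical. APA averages `(2k+1)^2` balanced windows (defaults k = 10,
c = 3 at 25-kb resolution) and scores centre over the `c x c` corner at
maximal anchor distance.

## Insulation, boundaries, compartments

The insulation score is the multi-window diamond statistic: for windows of
200-750 kb in 50-kb steps, the mean balanced count in the `w x w` block
spanning each bin (anchor excluded), z-scored per chromosome per window and
averaged across windows. Full windows only — edge bins are masked, not
truncated — which keeps the statistic deterministic and testable against a
nested-loop oracle. Per-cell tracks skip ICE (single-cell matrices are too
sparse to balance stably); the per-chromosome z-score absorbs depth scale,
and state comparisons additionally downsample cells to equal unique valid
pairs. Boundaries are local minima with prominence at least `delta`
(default 0.01) on both sides, merged within 2 bins to the deeper minimum;
we use the prominence rule alone rather than a rank-sum significance test.

Compartment scores are the leading eigenvector (largest-magnitude
eigenvalue) of the Pearson correlation matrix of the
observed/expected-normalized cis matrix, computed per chromosome over
unmasked bins and unit-normalized. The eigenvector sign is arbitrary, so it
is oriented positively against a reference track: the simulator's planted
"A-ness"; for real data supply a proxy such as gene density.

## Melting and concretion states

Regions of interest are long (>= 300 kb) genes whose bin-length-weighted
majority of compartment-eigenvector bins is negative (B compartment),
aligned outward to the 50-kb grid. Cells are clustered on z-scaled
per-bin insulation scores in the region (per-bin mean imputation of missing
values), Ward linkage (`ward.D2` by default, `ward.D` available) on
Euclidean distance, tree cut at k = 2; the cluster with the lower median
raw score is the melting state, and an empty or singleton cluster flags the
result unstable.

The melting score pools **all** (cell, bin) scores per cluster — per-bin
medians are a visualization device, not the statistic — and computes the
one-sided Kolmogorov-Smirnov distance `D = sup_x [F_melt(x) - F_conc(x)]`,
fixed in the direction "melting shifted to lower insulation", with the
asymptotic p-value `p = exp(-2 D^2 m n/(m+n))` and significance at
`p < 1e-5`. Against a 10,000-draw permutation reference the asymptotic p is
accurate to well under 0.01 in the tail (p below ~0.1), and conservative by
up to ~0.05 mid-range; since the decision threshold sits at `1e-5`, the
tail is the regime that matters. `depth_guard()` flags cells under 250,000
unique valid pairs, below which state separation degrades; clustering
still proceeds, carrying the flag.

Desk-scale problem sizes: state tests run on a single 20-Mb autosome where
3,200 cis pairs per cell is the density equivalent of 500,000 pairs on a
3.1-Gb genome (and 645 the equivalent of 100,000); at the 500k-equivalent
the planted states separate with adjusted Rand index above 0.9, and the
separation degrades monotonically at the 100k-equivalent, mirroring the
loss of discernibility expected below a quarter-million contacts per cell.

## Phasing

Both phasing scores count contact endpoints (two per pair), pair- versus
endpoint-level counting being unspecified in the field's descriptions. The
repli-score is `(n_early + 1)/(n_late + 1)` with +1 pseudocounts keeping
scores finite; cells rank from early to late. The haploid score divides a
cell's sex-chromosome endpoint fraction by the XY-diploid expectation
`e_dip = (L_X + L_Y)/(2 L_auto + L_X + L_Y)`, so diploid cells sit near 1
while haploid-X cells sit near `(L_X/(L_auto + L_X))/e_dip` (about 1.58 on
the toy genome); the default haploid call threshold of 1.5 lies between the
two expectations and is configurable because sex-chromosome read-count
variation blurs the boundary, and the normalization itself is a declared
reconstruction rather than a canonical formula. Group contrasts of the
log2 trans/cis ratio use a two-sided Wilcoxon rank-sum test (exact for
small tie-free groups).

## Pipeline

`validate_config()` normalizes a YAML (or list) configuration — defaults
filled, `k`/`M` suffixes expanded, unknown keys rejected with the nearest
valid key named — and the resolved echo re-validates to itself.
`run_pipeline()` executes simulate, classify/QC, cell calling, matrices,
tracks, melting, and phasing in order, deriving each stage's seed from the
global one so identical configurations give byte-identical tabular outputs
and disabling a downstream stage never perturbs upstream results. If cell
calling retains no barcode (a featureless demo curve), downstream stages
fall back to all barcodes with a warning rather than halting.

## Known limitations

* The simulator's independence assumptions (per-pair category draws,
  per-cell independent profiles) understate the correlated artefacts of
  real libraries.
* Per-cell insulation on desk-scale depths is noisy; state recovery relies
  on the planted contrast being strong, as it is in the biological
  phenomenon but need not be in marginal regions.
* The haploid score assumes an XY reference; X0 or polyploid karyotypes
  need a different expectation.
* Knee finding assumes counts spanning the cells/background contrast; when
  cell and ambient count distributions overlap heavily, the no-knee result
  (with its warning) is the honest output.
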