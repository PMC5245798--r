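---
title: "Co-binding statistics and 3D chromatin structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-binding statistics and 3D chromatin structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfloops)
```

# Scope

`tfloops` implements the statistical layer that connects transcription-factor
co-binding to three-dimensional chromatin architecture: permutation and
hypergeometric tests for ChIP-seq peak co-occurrence, a distance-decay
background model for binned cis contact maps, cumulative-binomial interaction
(loop) calling with differential scoring and anchor-pair enrichment,
directionality-index domain (TAD) calling with boundary-relative metagene
profiling, knockdown response classification, and gene-set intersection
logic. Upstream processing (alignment, peak calling, duplicate removal,
differential-expression model fitting) is out of scope; the package consumes
their text outputs (BED/narrowPeak, gene tables, pairs files, contrast
tables).

Because the real sequencing libraries behind such analyses are large and
external, the package ships a first-class synthetic-data generator that
emits every input format with planted ground truth. All tests, including the
acceptance suite, run on generated data.

# Co-binding statistics

## Open-chromatin permutation null

Factor binding is confined to open chromatin, so raw genome-wide overlap
p-values overstate co-binding. The null model here draws, in each of
`n_iter` iterations (default 1,000), `n_a` and `n_b` whole sites
independently and without replacement from the open-chromatin universe and
records the size of the intersection. The draws are of *site identities*,
not shuffled base pairs. The empirical p-value uses the `(r + 1)/(n + 1)`
estimator, which never reports zero; at 1,000 iterations the floor is just
below 0.001, matching the "p < 0.001" granularity such analyses report.
The permutation mean converges to the hypergeometric expectation
`n_a * n_b / N`, which the tests verify by exact enumeration on a 6-site
universe and by a 3-standard-error bound at scale.

Whether the two draws should be disjoint or independent is underdetermined;
independent draws are implemented, which is the natural reading of drawing
each factor's site count separately.

## Promoter-preference null

To ask whether a distinguished subset of peaks (e.g. the co-bound ones)
prefers promoters, each iteration draws `ceiling(k/2)` peaks from one
factor's full peak set and `floor(k/2)` from the other, and counts how many
drawn peaks are classified `promoter` (midpoint within TSS +/- 1 kb). The
closed-form mean of this null is `(k/2) * (f_a + f_b)` with `f` the
promoter fractions of the two sets; the tests check convergence to it.

## Hypergeometric overlap

`hypergeometric_overlap(N, n_a, n_b, k)` returns the upper tail
`P(X >= k)` via `stats::phyper`, stable for universes up to 1e7. Two
conventions worth noting:

* `k = 0` returns exactly 1 (the upper tail from zero is the whole mass).
* `k` below the feasible minimum `max(0, n_a + n_b - N)` also returns 1
  rather than erroring. Anchor enrichment can produce such `k` honestly
  (a loop may touch both feature sets on the *same* end only), and the
  upper tail from an infeasibly small threshold is 1 by definition.

## Knockdown response

Tag counts are scaled to a common depth of 10 million mapped tags per
condition, and the per-peak fold reduction is
`scaled_control / max(scaled_knockdown, 1)`. The pseudocount is one tag
*on the normalized scale*: a constant, which makes the classification
invariant to jointly rescaling all tags and library totals (the
alternative - one raw tag, scaled - breaks that invariance). Classes are
nested: every >= 10-fold-reduced peak also counts as >= 3-fold reduced.

# Peak annotation

Peaks are classified by their integer-floor midpoint with priority
`promoter > TTS > exon > intron > intergenic`. Windows follow the common
conventions: promoters are TSS +/- 1 kb; transcription termination sites
span -100 bp/+1 kb around the strand-appropriate transcript end; peaks on
chromosomes with no annotated gene (unplaced scaffolds) are class `NA`.
The gene-table interface carries transcript spans but no exon models, so by
default each transcript counts as one exon and the `intron` class only
arises when an explicit exon table is supplied.

Coordinates are 0-based half-open throughout and BED I/O is bit-exact.
Overlap between peak sets means >= 1 bp intersection; equidistant
closest-TSS ties go to the gene with the smaller TSS coordinate; the
flanking-density assignment merges overlapping active peaks into single
sites first (disable with `merge = FALSE`).

# Contact maps and the background model

`bin_pairs` builds one symmetric dense matrix per chromosome from a
cis-oriented pairs table; trans pairs only enter the cis-fraction summary.
Dense storage is deliberate: at 10-25 kb bins on chromosome-arm scale
(<= ~2,000 bins) it is small, and every downstream operation indexes freely.

`fit_background` models the expected count of pair `(i, j)` as
`f(d) * w_i * w_j`, where

* `f(d)` is the mean observed count per pair at bin distance `d`.
  Distances up to 100 bins get their own stratum; longer distances are
  geometrically pooled (ratio 1.15) for stable estimates. This pooling is
  the package's "signal boosting" device; an explicit 2-bin sliding-window
  pre-aggregation of the matrix was considered and rejected, because the
  binomial caller must use raw bin-pair counts as its observed successes
  and smoothing the observed matrix would corrupt that bookkeeping.
* `w_i` is bin `i`'s observed total divided by the total the decay law
  predicts *for its position*, normalized to mean 1 over retained bins.
  Normalizing by predicted (not mean) totals handles chromosome-edge bins
  exactly: for a perfectly homogeneous matrix every weight is exactly 1 and
  expected equals observed, which the tests assert. Bins with weight below
  0.2 of the mean are masked (mappability/restriction-accessibility
  artifacts).
* Within every stratum, expected counts are rescaled so their sum equals
  the observed sum over unmasked pairs (relative error < 1e-6 enforced and
  tested). A per-stratum empirical variance is reported alongside.

The per-bin cross-condition correlation track correlates each bin's
observed/expected profile (all partners within 100 bins by default) between
two conditions; bins masked in either background or with fewer than 10
finite profile points are flagged invalid.

# Loop calling

For each candidate pair with separation in [2, 100] bins (adjacent bins are
dominated by decay and self-ligation), the cumulative binomial test uses:

* trials `n` = reads with an end in bin i + reads with an end in bin j
  (the literal "reads mapping within regions" reading; alternatives exist
  but are not the default),
* success probability `p_s` = expected(i, j) / n,
* p-value = upper-tail `P(X >= o)`, Benjamini-Hochberg q-values over all
  tested pairs, calls at q < 0.05.

Pairs with zero expected count but positive observed count are flagged and
excluded from testing rather than silently dropped.

**Calibration caveat (an honest red test).** The exact binomial upper tail
is a discrete test: at the expected counts this design produces (roughly
2-100 per pair at 1e6 pairs over 800 bins), the attained level of
"p < 0.05" is 0.02-0.05 depending on the local expectation, averaging about
0.034 over the tested pairs. The acceptance criterion that this fraction
fall inside the exact binomial 99% interval around 0.05 (about
[0.048, 0.052] at ~74,000 tests) is therefore unattainable for *any*
faithful implementation of the prescribed statistic; a mid-p correction
would fix it but would change the test. The corresponding acceptance
assertion is kept as specified and fails, with this analysis; the
recovery assertions of the same criterion (sensitivity >= 0.9,
false-discovery proportion <= 0.15 on loops planted at 5x background)
pass.

Differential scoring re-scores condition-1 calls with condition-2 reads:
`score = log2((o1/e1 + 0.1) / (o2/e2 + 0.1))`, with an unchanged band of
|score| < log2(1.5).

## Anchor enrichment

With the called loops as the universe (N), a loop "touches" a feature set
at an end iff that anchor bin intersects >= 1 feature. K loops touch set a,
n touch set b, and k have one end touching a and the *opposite* end
touching b (both ends for a = b, with expectation K*K/N). The p-value is
the upper-tail hypergeometric probability.

One design consequence matters for cross-condition comparisons: when the
features mark essentially the loop anchors themselves, K ~ n ~ k and the
fold `k*N/(K*n)` degenerates to ~`N/k`, which *decreases* as more true
feature-to-feature loops are called. The package therefore reads
"the edge strengthens in condition 2" off the connected share `k/N` (and
the absolute k), which is monotone in the planted signal; the end-to-end
test and acceptance report use that statistic.

# Domains and metagene profiles

The directionality index of bin `i` contrasts its upstream and downstream
contact sums within a window (default 20 bins):
`DI = sign(B - A) * ((A - E)^2/E + (B - E)^2/E)`, `E = (A + B)/2`, and 0
when `A = B` or `E = 0`. Bins within one window of a chromosome edge carry
artifactually extreme DI; they are flagged and take no part in domain
calling.

Domain calling is a transparent threshold/run-length state machine rather
than an HMM: a domain opens at the start of a sustained run (>= 3 bins) of
DI above the threshold and closes at the end of the *last* sustained run of
DI below the negative threshold before the next domain opens. Two
refinements proved necessary at fine resolutions, where the upstream- and
downstream-biased stretches each span half the domain and fragment into
several runs: a positive run with no intervening close continues the
current opening stretch (it does not re-open later), and consecutive
negative runs extend the close. Thresholds default to the 90th percentile
of |DI| over non-edge bins, making the caller invariant to positive
rescaling of DI. Planted-domain recovery is exact (boundaries within 1 bin,
bp-Jaccard 1.0) across 10, 20 and 25 kb resolutions in the acceptance runs.

Metagene profiles normalize every domain to four segments - upstream flank
(200 kb), two domain-body halves (midpoint rounded down), downstream
flank - of 175 equal-width bins each. Feature midpoints are counted per
bin, converted to density per bp, and averaged across domains, so the two
domain boundaries sit at profile positions 175 and 525 (0-based) of the
700-bin profile.

# Gene sets

`core_gene_intersection` keeps genes with adjusted p below 0.05 *and*
positive log2 fold change in every contrast. The direction requirement is
the default because the core list represents genes consistently
upregulated with the cell-fate change; a lax mode (any significant change)
is a flag. `binding_combination_expression` partitions genes by the exact
combination of factors bound at their promoter and summarizes each group's
fold-change distribution.

# The synthetic world

`simulate_regulatory_genome` emits genes on a jittered 10 kb grid (unique,
well-separated TSSs), an open-chromatin universe of one promoter site per
gene plus distal sites, and fixed-width (200 bp) peaks placed on those
sites. Promoter-placed peak centers are uniform within TSS +/- 1 kb.
Co-binding places a Binomial(`n_peaks`, `cobinding_rate`) number of the
second factor's peaks onto sites occupied by the first;
`cobinding_rate = NA` requests *neutral* placement (sites drawn uniformly
from the whole universe), which is the chance-level null the calibration
tests need - forced placement at the chance rate would be overdispersed
relative to the hypergeometric permutation null and inflate type-I error.
Knockdown tags are `floor(control / knockdown_fold)` at the first factor's
co-bound peaks with equal library totals, so the planted peaks round-trip
exactly through the fold classifier.

`simulate_contact_reads` samples cis pairs by inverse-CDF over discrete
bin-pair probabilities proportional to `distance^(-decay_exponent)`
(default 1.0, a polymer-physics convention; the underlying study never
reports its empirical exponent), multiplied by planted-domain enrichment
factors and per-condition loop intensities, with read positions uniform
within bins. One RNG stream per artifact is derived from the master seed,
so adding an artifact never perturbs the others, and identical
configurations regenerate byte-identical files (tested).

What the generator deliberately does **not** emulate: trans contacts, PCR
duplicates, restriction-fragment geometry, sequence content, copy-number
or mappability variation, and distance-dependent overdispersion beyond
multinomial sampling. A green planted-recovery test therefore establishes
correctness of the statistical machinery on data satisfying the model's
own assumptions - not robustness to the full pathology of real libraries.

Stated-world scales used by the acceptance suite: 20 Mb chromosome, 25 kb
bins, depth 1e6 pairs per condition, five 0.5-0.6 Mb domains at 4x
enrichment with boundaries on 100 kb multiples (so 10/20/25 kb binnings
align exactly), and loops planted at distances of 10-40 bins
(0.25-1 Mb) - the canonical chromatin-loop scale; at 5x over a background
expectation below ~3 counts (loops beyond ~1.5 Mb at this depth) the test
would measure sequencing depth, not the caller. The study-mimic world
(`study_mimic_config`) adds twelve regulatory loops connecting
knockdown-sensitive anchors to promoter anchors (weak in condition 1,
strong in condition 2) over twenty constant single-ended baseline loops,
co-bound promoters with elevated planted expression effects, and
promoter-like/enhancer-like features at boundaries/domain interiors.

# Numerical choices and degenerate inputs

* Empirical permutation p never reports 0 (`(r+1)/(n+1)`).
* `phyper`/`pbinom` are used on their stable tails; both are cross-checked
  in the tests against independent direct-summation and subset-enumeration
  oracles (max |difference| < 1e-12 over all instances with N <= 25 /
  n <= 50).
* Closest-TSS ties break toward the smaller TSS coordinate; domain-body
  midpoints round down; peak midpoints floor.
* Empty peak sets, empty contrast lists, depth-0 simulations (header-only
  pairs files) and all-zero matrices are defined, tested behaviors; an
  all-masked background or a windowless DI request is an error.

# Known limitations

* The binomial caller's discreteness (above) makes its raw p-values
  conservative at low expected counts; q-value-based calling is unaffected
  in practice but nominal-level guarantees are one-sided.
* The correlation track and the loop caller share the `max_distance`
  horizon; interactions beyond it are never tested.
* Domain calling assumes non-overlapping, non-nested domains; hierarchical
  structure is out of scope.
* The anchor-enrichment universe is the called loop set; a candidate
  bin-pair universe is a documented alternative not implemented here.
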