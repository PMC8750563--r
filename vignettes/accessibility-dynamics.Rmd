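---
title: "Methods: chromatin accessibility and expression dynamics of reversible EMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin accessibility and expression dynamics of reversible EMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtatac)
library(dplyr)
```

## The problem

Epithelial–mesenchymal transition (EMT) and its reversal (MET) reorganise the
chromatin landscape of carcinoma cells: the number and intensity of accessible
regions (ATAC-seq peaks) changes genome-wide across a treatment time course,
transcription-factor binding motifs such as AP-1, SMAD and CTCF gain or lose
representation in accessible sequence, and transcriptomic EMT state shifts in
concert. `emtatac` implements the quantitative core of such a time-course
analysis as tidy, tibble-first R functions: every statistic the pipeline
reports is computed by an exported, unit-tested function, and a seeded
synthetic-data generator plants known ground truth so the whole chain can be
validated end to end without any external download.

## Interval model and peak merging

Regions are plain tibbles (`chrom`, `start`, `end`, optional `name`/`score`)
with 0-based half-open coordinates, the BED convention. `merge_region_sets()`
unifies peaks across replicates or conditions when their centres lie within
`max_center_distance` (default 300 bp), taking the transitive closure of that
relation and spanning the union of each cluster. Because centres are points on
a line, the closure is exactly the chaining of consecutive sorted centres,
which makes the merge order-independent and idempotent — both are asserted as
properties in the test suite against a brute-force all-pairs oracle. Each
merged region records which input condition contributed, so condition-sharing
(Venn) counts come straight from `membership_counts()`.

Two reading choices were genuinely open and are fixed as follows: the merge
distance is centre-to-centre (the semantic of the tool family this mirrors),
and the merged interval is the union span of its members.

## Gaps and peak deserts

`gap_lengths()` measures `next start − previous end` between consecutive
same-chromosome peaks of a merged set; distances to chromosome ends are not
counted, so telomeric stretches never appear as gaps. A *peak desert*
(`count_peak_deserts()`) is a gap whose *effective* length — the gap length
minus the excluded-region bp (blacklist, assembly gaps, centromeres) falling
inside it — exceeds 1 Mb. Subtracting masked bp from the gap, rather than
splitting gaps at masked intervals, is the simpler of the two defensible
semantics and is the one implemented; with splitting, a desert interrupted by
a masked stretch could never reach the threshold even when its accessible
portion does. Gap statistics are computed per supplied peak set, so the caller
decides whether per-condition or cross-condition merged peaks are the unit.

## Score matrix, quantile normalisation, correlation

`build_score_matrix()` merges scored peak sets across conditions, recentres
every merged peak to a fixed 300-bp window, and fills the matrix with
`log2(score + 1)`. The log base is 2 so that differential scores read directly
as log2 fold changes; the +1 keeps zero scores at zero. A condition with no
peak in a row scores 0 rather than NA: the absence of a called peak is
informative, and it keeps quantile normalisation well defined over all rows.
When one condition contributes several peaks to a cluster, the maximum raw
score represents it.

`quantile_normalize()` delegates to the standard rank-mean procedure (ties
averaged), which forces identical value distributions across columns and is
idempotent; `correlation_matrix()` is plain Pearson over the normalised
columns. All merged bins enter the correlation by default — restricting to
bins scored in both conditions would discard exactly the rows where
conditions differ, which is the signal of interest; callers who want the
restricted version can filter the matrix tibble before calling.

## MPS/DPS accessibility change

For a pair of conditions with log-scale scores $a$ and $b$,
`classify_change()` reports the mean peak score $\mathrm{MPS} = (a+b)/2$ and
differential peak score $\mathrm{DPS} = a - b$. MPS below 3 is *low*
accessibility, above 5 *high*, otherwise *moderate*; $|\mathrm{DPS}| > 2$
marks a major change with its sign giving the direction. These thresholds are
the package defaults and surface as `pipeline_config()` parameters.

## Differential peaks

`differential_peaks()` flags regions with more target than background tags
under two simultaneous rules: a depth-independent fold filter and a
depth-dependent cumulative Poisson test. The background count is scaled to
the target depth, $\lambda = t_{bg} \cdot d_{t}/d_{bg}$ (zero backgrounds get
a 0.5 pseudocount so fold and tail probability stay defined), the fold is
$t_{t}/\lambda$, and the p-value is $P(X \ge t_{t})$ for
$X \sim \mathrm{Poisson}(\lambda)$, computed with `stats::ppois` and verified
against an explicit partial-sum oracle. Defaults: fold ≥ 4 and p < 10⁻⁴. A
region with zero target tags can never be flagged, and swapping target and
background yields a disjoint flagged set (tested as a property).

## Motif scanning and enrichment

A `pwm()` is a 4×L base-probability matrix with a background model
(uniform by default), a 0.001 pseudocount to keep log odds finite, and a
detection threshold defaulting to 80% of the maximum achievable summed
log2-odds score — a conventional operating point that admits roughly one
low-information mismatch in a sharp consensus. `scan_window()` scores every
offset on both strands; N or masked bases contribute 0 bits (background).
Strand symmetry is asserted property-style.

`extract_windows()` recentres peaks to fixed 50-bp windows (left-shifted by
1 bp when parity forces a choice) and drops windows that leave the chromosome
or touch the excluded mask. `motif_target_percentage()` is the percentage of
windows with at least one hit; `motif_enrichment_test()` compares hit counts
in target versus background windows with an upper-tail hypergeometric
probability — the classic known-motif statistic, with background windows
drawn from unmasked genome sequence. Reported motif sets keep only motifs
reaching p ≤ 10⁻¹² in at least one condition (so that a motif significant
after treatment still shows its baseline percentage), and
`percentage_change()` gives the signed percentage-point difference versus the
control condition. Because the "top differentially enriched" ranking could be
by significance or by effect size, the result table carries both `p_value`
and `percentage_change`; callers rank by either.

## Permutation overlap enrichment

`permutation_overlap_test()` asks whether the base-pair overlap between a
query and a reference region set exceeds chance. The null is built by
placing, for each permutation, one region per query region — preserving the
length multiset — uniformly over every valid start position in the genome,
where valid means the region fits inside a single unmasked span. Rather than
rejection-sampling against the mask, the implementation enumerates the valid
spans once and samples placements exactly (span chosen with probability
proportional to its number of valid starts, offset uniform); this is the same
target distribution with no failure mode, and the placement uniformity is
verified by a chi-square goodness-of-fit test plus an exhaustive-enumeration
oracle of the expected overlap on a toy genome. Shuffled regions are placed
independently and may overlap one another.

The empirical p-value is `max(1, #{null ≥ observed}) / n`, so with 1,000
permutations an observation exceeding every permuted overlap reports exactly
p = 0.001 — the floor of the test, not an exaggerated significance. Fold
enrichment is observed over null mean; `bonferroni()` adjusts across several
tests. The test is one-sided (enrichment), matching the question asked of
such data.

## EMT scoring (76GS-style)

`gs76_score()` scores each sample as a weighted sum of signature-gene
expression, the weight of each gene being its Pearson correlation with the
anchor gene (the CDH1 role) across samples; the anchor's own weight is 1 and
zero-variance non-anchor genes get weight 0. Scores are mean-centred, so the
global mean is zero by construction and positive scores read as epithelial.
Signed (not absolute) correlations are used, exactly as the weighting is
defined; genes missing from the expression table are dropped with a warning
and the coverage fraction is recorded. Pearson weights make the score
invariant to positive affine rescaling of any gene, which the tests assert.
At least 3 samples are required, or correlation weights are undefined.
The published 76-gene list itself is configuration data, not code;
`emt_signature()` ships a synthetic default (anchor + 37 epithelial + 38
mesenchymal genes) for simulation and testing, and accepts any user list.

`signature_summary()` gives per-sample mean z-scores for up/down gene sets
(constant genes contribute 0 rather than NaN), and
`hypergeometric_overlap()` tests gene-set overlaps against a stated universe
with the upper-tail hypergeometric probability, verified against complete
enumeration for small universes.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with ground truth
attached:

- `sim_genome()` masks a requested fraction of each chromosome with disjoint
  intervals (the blacklist/assembly-gap role); emitted fractions are within
  ±10% of the request.
- `sim_region_set()` places peak-like regions with truncated-normal lengths
  (minimum 50 bp, matching the motif-window width) uniformly over unmasked
  sequence. Emitted sets are mutually non-overlapping, as called peak sets
  are after replicate merging.
- `sim_condition_peaks()` builds multi-condition sets with a planted count of
  fully shared peaks and per-condition private peaks; each peak has an
  underlying log-normal accessibility score jittered per condition, so shared
  peaks correlate across conditions.
- `sim_nested_query()` plants an exact rounded fraction of query regions
  wholly inside reference regions (distinct hosts while available, so planted
  queries stay disjoint) and scatters the rest uniformly.
- `sim_tag_counts()` draws Poisson counts whose expected target:background
  ratio per region is the planted fold effect times the depth ratio — the
  same sampling family the differential test assumes.
- `sim_window_sequences()` plants the PWM consensus (either strand, random
  offset) in an exact rounded fraction of otherwise i.i.d. uniform DNA
  windows.
- `sim_expression()` moves epithelial-signature genes (including the anchor)
  linearly down, and mesenchymal genes up, along a per-sample EMT axis in
  [0, 1], adds Gaussian noise, and floors at a small positive value.

One pipeline seed fans out into independent child seeds per generator, so any
module can be regenerated alone; every generator is byte-reproducible under a
fixed seed.

What the generator does *not* emulate: read-level data (FASTQ), fragment-size
or Tn5 insertion bias, genomic sequence composition (windows are uniform
DNA, so background motif hit rates are lower than in GC-structured genomes),
peak-width/score dependence, and the correlation structure of real
transcriptomes beyond the planted EMT axis. Passing recovery tests therefore
demonstrates that the statistics are implemented correctly and are sensitive
at the planted effect sizes — not that real data of any particular depth
would yield the same operating characteristics.

## Problem sizes and tolerances

The default simulated study is two chromosomes (6 + 4 Mb) with 5% masked,
four conditions (untreated, short- and long-term treatment, withdrawal) of
120 shared + 40 private peaks each, tag depth 2×10⁵ with 8-fold effects
planted in 40 regions, 200 motif windows per condition with planted rates
17–30%, and expression along the axis (0, 0.5, 1, 0.15) with noise sd 0.5.
Tests use smaller instances of the same shapes (hundreds of regions,
99–10,000 permutations) chosen so the whole suite runs in a few minutes;
oracle comparisons are exact or at 10⁻¹⁰–10⁻¹² tolerance, stochastic
recovery checks use binomial bounds at fixed seeds.

## Known limitations

- The merge semantic is centre-distance chaining with union spans; very long
  peak chains can produce merged regions much wider than any member.
- Background motif windows are uniform-random sequence, not GC- or
  repeat-matched; enrichment p-values against real genomic backgrounds would
  be less extreme.
- The permutation null places regions independently (self-overlap allowed)
  and genome-wide; per-chromosome count-preserving or locally constrained
  shuffles are out of scope.
- Expression input is taken as already normalised; no quantification or
  dispersion-modelled differential testing is provided.
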