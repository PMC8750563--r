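# emtatac

Tidy R tools for analysing chromatin accessibility and expression dynamics
across a reversible epithelial–mesenchymal transition (EMT) time course.

ATAC-seq experiments that follow cells through EMT induction and withdrawal
produce per-condition peak sets, peak-score matrices, and matched expression
profiles. The questions asked of such data are stereotyped: how do peak sets
overlap across conditions, how do inter-peak gaps and megabase-scale "peak
deserts" change, how correlated are accessibility profiles after quantile
normalisation, which peaks change accessibility and near which genes, which
transcription-factor motifs gain or lose representation in accessible
sequence, whether accessible regions coincide with an independent mark more
than chance allows, and where each sample sits on the epithelial–mesenchymal
axis transcriptomically. `emtatac` implements each of these as a small,
composable, tibble-first function, plus a seeded synthetic-data generator
that plants known ground truth for end-to-end validation.

## The statistics at the core

- **Peak merging**: peaks whose centres lie within *d* = 300 bp are unified
  by transitive closure into union spans, with per-condition membership
  flags (Venn counts via `membership_counts()`).
- **Gap/desert statistics**: inter-peak gaps per chromosome; a *peak desert*
  is a gap whose length minus contained excluded-region bp exceeds 1 Mb.
- **Accessibility change**: per-peak mean peak score MPS = (a+b)/2 and
  differential peak score DPS = a − b on log2(score+1) scales; MPS < 3 low,
  > 5 high; |DPS| > 2 a major change.
- **Differential peaks**: flagged when target tags reach 4-fold over the
  depth-normalised background λ = t_bg·d_t/d_bg *and* the cumulative
  Poisson tail P(X ≥ t_t | λ) falls below 10⁻⁴.
- **Motif enrichment**: PWM log2-odds scanning of 50-bp peak-centred
  windows on both strands; per-condition target percentages, upper-tail
  hypergeometric enrichment against background windows (reported motifs
  reach p ≤ 10⁻¹²), and percentage-point change versus control.
- **Permutation overlap enrichment**: observed base-pair overlap between a
  query and reference set against a null of length-matched regions placed
  uniformly over the unmasked genome; empirical
  p = max(1, #{null ≥ obs})/n (floor 0.001 at n = 1000), fold = obs/mean,
  Bonferroni adjustment across tests.
- **EMT scoring**: a CDH1-anchored weighted sum — each signature gene is
  weighted by its Pearson correlation with the anchor across samples, scores
  are mean-centred (global mean exactly 0), positive = epithelial.

## Worked example

```r
library(emtatac)

genome <- sim_genome(c(chr1 = 6e6, chr2 = 4e6), excluded_fraction = 0.05, seed = 11)
peaks  <- sim_condition_peaks(genome, c("untreated", "tgfb"),
                              n_shared = 200, n_unique = 25, seed = 12)
sets <- lapply(peaks, \(p) p[, c("chrom", "start", "end", "score")])

membership_counts(merge_region_sets(sets))
#>   combination        n
#> 1 untreated,tgfb   200
#> 2 tgfb              25
#> 3 untreated         25
```

The planted sharing structure (200 common, 25 private peaks per condition)
is recovered exactly. Quantile-normalised accessibility profiles then
correlate, and per-peak changes classify:

```r
m <- quantile_normalize(build_score_matrix(sets))
round(correlation_matrix(m), 3)
#>           untreated  tgfb
#> untreated     1.000 0.235
#> tgfb          0.235 1.000

dplyr::count(classify_change(m$tgfb, m$untreated),
             accessibility_class, major_change)
#>   accessibility_class major_change     n
#> 1 high                FALSE           50
#> 2 low                 FALSE            9
#> 3 low                 TRUE            50
#> 4 moderate            FALSE          141
```

Shared peaks correlate strongly (r ≈ 0.95 row-wise); the modest global
correlation reflects the 50 condition-private peaks, which also surface as
the 50 major changes at low MPS (a peak absent in one condition scores 0
there). Overlap enrichment against an independent mark, with half the query
planted inside it:

```r
ref <- sim_region_set(genome, 80, length_mean = 1000, length_sd = 0, seed = 13)
q   <- sim_nested_query(ref, genome, n = 40, inside_fraction = 0.5,
                        query_length = 200, seed = 14)
permutation_overlap_test(q, ref, genome, n_permutations = 1000, seed = 15)
#> <overlap_enrichment>
#>   observed overlap: 4,000 bp
#>   null mean (sd):   64.56 (108.17) bp
#>   fold enrichment:  61.96
#>   empirical p:      0.001 (1000 permutations)
```

The 20 planted queries alone contribute 4,000 bp of overlap, ~62-fold the
length-matched random expectation, at the 1/1000 empirical floor. Finally,
EMT scoring of a simulated expression time course:

```r
sig  <- emt_signature()
expr <- sim_expression(sig, c(0, 0.5, 1, 0.15), noise_sd = 0.5, seed = 16)
names(expr) <- c("gene", "untreated", "tgfb_short", "tgfb_long", "withdrawn")
tidy(gs76_score(expr, sig))
#>   sample      score call
#> 1 untreated   246.  epithelial
#> 2 tgfb_short  -47.2 mesenchymal
#> 3 tgfb_long  -353.  mesenchymal
#> 4 withdrawn   154.  epithelial
```

Scores decrease along the planted EMT axis (0, 0.5, 1, 0.15), sum to zero
across samples, and the withdrawn sample returns toward the epithelial pole.

`run_simulate()` writes a complete fixture directory and `run_all()` executes
every stage on it; `inst/cli/emtatac` wraps both (plus a standalone `enrich`)
for shell use. All result objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` ggplot output.

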