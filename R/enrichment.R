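#' Shuffle a region set, preserving its length multiset
#'
#' Places one new region per query region, uniformly over every valid start
#' position in the genome: a placement is valid when the region fits inside a
#' single unmasked span (so shuffled regions never touch the excluded mask).
#' Placements are independent, so shuffled regions may overlap one another;
#' chromosome structure enters only through sizes and the mask.
#'
#' @param query Region tibble; the output has the same multiset of lengths.
#' @param genome A [genome_model()].
#' @return A sorted region tibble of shuffled placements.
#' @export
shuffle_length_matched <- function(query, genome) {
  query <- validate_regions(query, genome = NULL)
  if (nrow(query) == 0) return(query[, c("chrom", "start", "end")])
  sort_regions(sample_placements(genome, query$end - query$start))
}

# Summarise an observed overlap against a permutation null. Exported so the
# permutation machinery's arithmetic (fold enrichment, empirical p with its
# 1/N floor) can be applied to any observed/null pair.

#' Summarise observed base-pair overlap against a permutation null
#'
#' Computes the quantities reported by [permutation_overlap_test()]: fold
#' enrichment `observed / mean(null)` and the one-sided empirical p-value
#' `max(1, #{null >= observed}) / n`, which floors at `1/n` (0.001 for 1,000
#' permutations) when the observed overlap exceeds every permuted overlap.
#'
#' @param observed_bp Observed overlap in bp.
#' @param null_bp Numeric vector of permuted overlaps.
#' @return An object of class `overlap_enrichment`.
#' @export
summarize_overlap_null <- function(observed_bp, null_bp) {
  n <- length(null_bp)
  if (n < 1) abort("need at least one permutation")
  null_mean <- mean(null_bp)
  fold <- if (null_mean > 0) observed_bp / null_mean else {
    warn("null mean overlap is 0; fold enrichment reported as Inf")
    Inf
  }
  structure(
    list(
      observed_bp = observed_bp,
      null_mean_bp = null_mean,
      null_sd_bp = stats::sd(null_bp),
      fold_enrichment = fold,
      empirical_p = max(1, sum(null_bp >= observed_bp)) / n,
      n_permutations = n,
      null_bp = null_bp
    ),
    class = "overlap_enrichment"
  )
}

#' Permutation test for base-pair overlap enrichment
#'
#' Tests whether the observed base-pair overlap between a query and a
#' reference region set is larger than expected by chance, against a null
#' distribution built by repeatedly shuffling length-matched regions
#' throughout the (unmasked) genome and recording each permutation's overlap.
#' One-sided (enrichment only).
#'
#' @param query,reference Non-empty region tibbles.
#' @param genome A [genome_model()] defining the shuffle space.
#' @param n_permutations Number of shuffles (default 1000, giving an
#'   empirical p floor of 0.001).
#' @param seed Integer RNG seed.
#' @return An `overlap_enrichment` object with fields `observed_bp`,
#'   `null_mean_bp`, `null_sd_bp`, `fold_enrichment`, `empirical_p`,
#'   `n_permutations` and the raw `null_bp` vector. See [generics::tidy()]
#'   and [autoplot.overlap_enrichment()].
#' @examples
#' gm <- genome_model(c(chr1 = 1e5))
#' ref <- tibble::tibble(chrom = "chr1", start = 1000 * 0:9, end = 1000 * 0:9 + 500)
#' q <- tibble::tibble(chrom = "chr1", start = c(100, 1100), end = c(200, 1200))
#' permutation_overlap_test(q, ref, gm, n_permutations = 100, seed = 1)
#' @export
permutation_overlap_test <- function(query, reference, genome,
                                     n_permutations = 1000, seed = 1) {
  query <- validate_regions(query)
  reference <- validate_regions(reference)
  if (nrow(query) == 0 || nrow(reference) == 0) {
    abort("query and reference must be non-empty")
  }
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  observed <- basepair_overlap(query, reference)
  ref_idx <- build_overlap_index(reference)
  lengths <- query$end - query$start
  null_bp <- local_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      s <- sample_placements(genome, lengths)
      sum(overlap_with_index(ref_idx, s$chrom, s$start, s$end))
    }, numeric(1))
  })
  summarize_overlap_null(observed, null_bp)
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat("<overlap_enrichment>\n",
      "  observed overlap: ", format(x$observed_bp, big.mark = ","), " bp\n",
      "  null mean (sd):   ", format(round(x$null_mean_bp, 2), big.mark = ","),
      " (", format(round(x$null_sd_bp, 2), big.mark = ","), ") bp\n",
      "  fold enrichment:  ", format(round(x$fold_enrichment, 2)), "\n",
      "  empirical p:      ", format(x$empirical_p),
      " (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an overlap-enrichment result
#'
#' @param x An `overlap_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble of the result fields (without the raw null
#'   vector).
#' @export
tidy.overlap_enrichment <- function(x, ...) {
  tibble(
    observed_bp = x$observed_bp,
    null_mean_bp = x$null_mean_bp,
    null_sd_bp = x$null_sd_bp,
    fold_enrichment = x$fold_enrichment,
    empirical_p = x$empirical_p,
    adjusted_p = x$adjusted_p %||% NA_real_,
    n_permutations = x$n_permutations
  )
}

#' @rdname tidy.overlap_enrichment
#' @export
glance.overlap_enrichment <- tidy.overlap_enrichment

#' Bonferroni multiple-testing adjustment
#'
#' `adjusted_i = min(1, m * p_i)` for m p-values. Input p-values must lie in
#' (0, 1] (empirical p-values can never be 0).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p) {
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Apply a Bonferroni adjustment across several enrichment results
#'
#' @param results List of `overlap_enrichment` objects tested together.
#' @return The list with an `adjusted_p` field set on each element.
#' @export
adjust_enrichment_results <- function(results) {
  adj <- bonferroni(vapply(results, function(r) r$empirical_p, numeric(1)))
  purrr::map2(results, adj, function(r, a) { r$adjusted_p <- a; r })
}
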