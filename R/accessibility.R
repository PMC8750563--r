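#' Build a log-scale peak-score matrix across conditions
#'
#' Merges scored peak sets across conditions by centre distance, recentres
#' each merged peak to a fixed-width window (300-bp binning), and fills a
#' regions-by-conditions matrix with `log2(score + 1)` of the contributing
#' peak. A condition that has no peak in a merged region scores 0: absence of
#' a called peak is informative, not missing data, and it keeps quantile
#' normalisation well-defined.
#'
#' @param sets Named list of scored region tibbles (or one tibble with `set`
#'   and `score` columns); at least 2 conditions.
#' @param bin Window width in bp (default 300); also the merge distance.
#' @return A tibble with `region` (chrom:start-end of the recentred window),
#'   `chrom`, `start`, `end`, and one numeric column per condition.
#' @export
build_score_matrix <- function(sets, bin = 300) {
  if (is.data.frame(sets)) {
    labels <- unique(sets$set)
  } else {
    labels <- names(sets)
    for (s in sets) validate_regions(s, scored = TRUE)
  }
  if (length(labels) < 2) abort("need at least 2 conditions")
  merged <- merge_region_sets(sets, max_center_distance = bin)
  score_cols <- paste0("score_", labels)
  if (!all(score_cols %in% names(merged))) {
    abort("every input region must carry a score")
  }
  center <- floor((merged$start + merged$end) / 2)
  start <- pmax(0, center - bin %/% 2)
  end <- start + bin
  out <- tibble(
    region = paste0(merged$chrom, ":", start, "-", end),
    chrom = merged$chrom, start = start, end = end
  )
  for (i in seq_along(labels)) {
    v <- merged[[score_cols[i]]]
    out[[labels[i]]] <- log2(dplyr::coalesce(v, 0) + 1)
  }
  out
}

# Numeric condition columns of a score matrix tibble.
condition_cols <- function(m) {
  cand <- setdiff(names(m), c("region", "chrom", "start", "end"))
  cand[vapply(m[cand], is.numeric, logical(1))]
}

#' Quantile-normalise a peak-score matrix
#'
#' Forces every condition column to the same value distribution: the value at
#' rank r in each column becomes the mean of the rank-r values across the
#' original columns (ties share the mean of their ranks' values). Idempotent.
#'
#' @param m Score-matrix tibble from [build_score_matrix()], or any tibble
#'   whose numeric columns are the conditions.
#' @return The tibble with condition columns replaced by their
#'   quantile-normalised values.
#' @export
quantile_normalize <- function(m) {
  cols <- condition_cols(m)
  if (length(cols) < 2) abort("need at least 2 condition columns")
  x <- as.matrix(m[cols])
  if (!is.numeric(x)) abort("condition columns must be numeric")
  qn <- limma::normalizeQuantiles(x, ties = TRUE)
  for (i in seq_along(cols)) m[[cols[i]]] <- qn[, i]
  m
}

#' Pairwise Pearson correlation between conditions
#'
#' @param m (Typically quantile-normalised) score-matrix tibble.
#' @return A symmetric condition-by-condition correlation matrix with unit
#'   diagonal.
#' @export
correlation_matrix <- function(m) {
  cols <- condition_cols(m)
  x <- as.matrix(m[cols])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance condition column(s): ",
                 paste(cols[sds == 0], collapse = ", ")))
  }
  stats::cor(x, method = "pearson")
}

#' Classify per-peak accessibility change between two conditions
#'
#' For log-scale scores `a` and `b`, the mean peak score MPS = (a + b)/2
#' summarises overall accessibility and the differential peak score
#' DPS = a - b its change. MPS below 3 is "low" accessibility, above 5
#' "high", otherwise "moderate"; |DPS| > 2 marks a major change, signed by
#' its direction.
#'
#' @param score_a,score_b Log-scale peak scores (vectors of equal length).
#' @param mps_low,mps_high MPS class boundaries (defaults 3 and 5).
#' @param dps_major Major-change threshold on |DPS| (default 2).
#' @return A tibble with `mps`, `dps`, `accessibility_class`
#'   (low/moderate/high), `major_change` and `direction`
#'   (increase/decrease/none).
#' @examples
#' classify_change(c(4, 6.5, 1.0), c(4, 3.9, 3.5))
#' @export
classify_change <- function(score_a, score_b, mps_low = 3, mps_high = 5,
                            dps_major = 2) {
  mps <- (score_a + score_b) / 2
  dps <- score_a - score_b
  tibble(
    mps = mps,
    dps = dps,
    accessibility_class = dplyr::case_when(
      mps < mps_low ~ "low",
      mps > mps_high ~ "high",
      TRUE ~ "moderate"
    ),
    major_change = abs(dps) > dps_major,
    direction = dplyr::case_when(
      dps > dps_major ~ "increase",
      dps < -dps_major ~ "decrease",
      TRUE ~ "none"
    )
  )
}

#' Call differential peaks with a fold filter and cumulative Poisson test
#'
#' Background counts are scaled to the target sequencing depth
#' (`lambda = tags_background * depth_target / depth_background`; a zero
#' background gets a 0.5 pseudocount). A peak is flagged when its
#' depth-independent fold change `tags_target / lambda` reaches `min_fold`
#' and the depth-dependent upper-tail Poisson probability
#' `P(X >= tags_target | lambda)` falls below `max_p`.
#'
#' @param counts Tibble with `tags_target` and `tags_background` columns
#'   (e.g. from [sim_tag_counts()]); other columns pass through.
#' @param depth_target,depth_background Total tag counts per condition.
#' @param min_fold Minimum fold change (default 4).
#' @param max_p Cumulative Poisson p-value cutoff (default 1e-4).
#' @return The input with `lambda`, `fold`, `p_value` and logical
#'   `differential` appended.
#' @export
differential_peaks <- function(counts, depth_target = NULL,
                               depth_background = NULL,
                               min_fold = 4, max_p = 1e-4) {
  counts <- as_tibble(counts)
  if (!all(c("tags_target", "tags_background") %in% names(counts))) {
    abort("counts needs `tags_target` and `tags_background` columns")
  }
  tt <- counts$tags_target
  tb <- counts$tags_background
  if (any(tt < 0) || any(tb < 0)) abort("tag counts must be non-negative")
  if (any(tt != floor(tt)) || any(tb != floor(tb))) abort("tag counts must be integers")
  depth_target <- depth_target %||% sum(tt)
  depth_background <- depth_background %||% sum(tb)
  if (depth_target <= 0 || depth_background <= 0) abort("depths must be positive")
  lambda <- tb * depth_target / depth_background
  lambda[lambda == 0] <- 0.5
  fold <- tt / lambda
  p <- stats::ppois(tt - 1, lambda, lower.tail = FALSE)
  dplyr::mutate(counts, lambda = lambda, fold = fold, p_value = p,
                differential = fold >= min_fold & p < max_p)
}

#' Join differential peaks to nearest-TSS genes and expression fold change
#'
#' One row per differential peak: its nearest gene, signed TSS distance, and
#' the gene's expression ratio between the two samples (pseudocounted so
#' zero-expression genes stay defined). Genes present in the annotation but
#' absent from the expression table are kept with `missing_expression = TRUE`.
#'
#' @param diff_peaks Output of [differential_peaks()], typically filtered to
#'   `differential` rows (unfiltered input is filtered automatically when a
#'   `differential` column is present).
#' @param tss Tibble of TSS annotation (see [nearest_tss()]).
#' @param expr Expression tibble with a `gene` column and sample columns.
#' @param sample_a,sample_b Sample column names; the ratio is a over b.
#' @param pseudocount Added to both expression values; default 1.
#' @return A tibble with peak coordinates, `gene_id`, `tss_distance`,
#'   `expression_fc` and `missing_expression`.
#' @export
fc_vs_tss_table <- function(diff_peaks, tss, expr, sample_a, sample_b,
                            pseudocount = 1) {
  if ("differential" %in% names(diff_peaks)) {
    diff_peaks <- dplyr::filter(diff_peaks, .data$differential)
  }
  ann <- nearest_tss(diff_peaks, tss)
  fc <- expression_fold_change(expr, sample_a, sample_b, pseudocount = pseudocount)
  out <- dplyr::left_join(ann, fc[, c("gene", "fold_change")],
                          by = c(gene_id = "gene"))
  dplyr::mutate(dplyr::rename(out, expression_fc = "fold_change"),
                missing_expression = is.na(.data$expression_fc))
}
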