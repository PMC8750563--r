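#' Simulate a genome model with an excluded mask
#'
#' Builds a synthetic genome: the given chromosomes plus a random disjoint
#' mask of excluded intervals (emulating a blacklist / assembly-gap /
#' centromere set) covering approximately `excluded_fraction` of each
#' chromosome.
#'
#' @param chrom_sizes Named numeric vector or tibble (`chrom`, `size`) of
#'   chromosome lengths in bp.
#' @param excluded_fraction Fraction of each chromosome to mask, in `[0, 1)`.
#' @param seed Integer RNG seed; identical seeds give identical masks.
#' @param mask_length Mean length (bp) of one masked interval; intervals are
#'   drawn until the per-chromosome target fraction is reached.
#' @return A [genome_model()].
#' @examples
#' gm <- sim_genome(c(chr1 = 1e6), excluded_fraction = 0.1, seed = 1)
#' @export
sim_genome <- function(chrom_sizes, excluded_fraction = 0, seed = 1,
                       mask_length = NULL) {
  gm0 <- genome_model(chrom_sizes)
  if (excluded_fraction < 0 || excluded_fraction >= 1) {
    abort("excluded_fraction must be in [0, 1)")
  }
  if (excluded_fraction == 0) return(gm0)
  excluded <- local_seed(seed, {
    purrr::map2_dfr(gm0$chrom_sizes$chrom, gm0$chrom_sizes$size, function(cn, sz) {
      target <- excluded_fraction * sz
      mlen <- mask_length %||% max(1000, round(target / 20))
      starts <- numeric(0); ends <- numeric(0)
      covered <- 0
      attempts <- 0
      while (covered < target && attempts < 1e5) {
        attempts <- attempts + 1
        len <- min(max(100, round(stats::rnorm(1, mlen, mlen / 4))), sz)
        len <- min(len, target - covered + mlen * 0.25)
        len <- max(100, round(len))
        if (len >= sz) len <- floor(sz / 2)
        s <- floor(stats::runif(1, 0, sz - len))
        e <- s + len
        if (any(s < ends & e > starts)) next  # keep mask disjoint
        starts <- c(starts, s); ends <- c(ends, e)
        covered <- covered + len
      }
      tibble(chrom = cn, start = starts, end = ends)
    })
  })
  genome_model(gm0$chrom_sizes, excluded)
}

# Sample `n` interval placements uniformly over all valid start positions in
# the unmasked genome, one length per placement. Returns tibble
# (chrom, start, end). Lengths too long for every span raise an error.
sample_placements <- function(genome, lengths) {
  spans <- unmasked_spans(genome)
  out_chrom <- character(length(lengths))
  out_start <- numeric(length(lengths))
  span_len <- spans$end - spans$start
  for (g in split(seq_along(lengths), lengths)) {
    L <- lengths[g[1]]
    valid <- pmax(span_len - L + 1, 0)
    total <- sum(valid)
    if (total <= 0) {
      abort(paste0("no unmasked span can hold a region of length ", L))
    }
    pick <- sample.int(nrow(spans), length(g), replace = TRUE, prob = valid)
    off <- floor(stats::runif(length(g), 0, valid[pick]))
    out_chrom[g] <- spans$chrom[pick]
    out_start[g] <- spans$start[pick] + off
  }
  tibble(chrom = out_chrom, start = out_start, end = out_start + lengths)
}

#' Simulate a set of peak-like regions
#'
#' Region lengths are drawn from a normal distribution truncated below at
#' `min_length`; placements are uniform over the unmasked genome. Emitted
#' regions never intersect the excluded mask and never overlap one another
#' (called peak sets are non-overlapping after merging), and are sorted.
#'
#' @param genome A [genome_model()].
#' @param n_regions Number of regions to place.
#' @param length_mean,length_sd Region length distribution (bp).
#' @param seed Integer RNG seed.
#' @param min_length Lower truncation for region lengths; default 50 bp.
#' @param max_tries Bounded rejection attempts before giving up.
#' @return A sorted region tibble with a `name` column (`peak_1`, ...).
#' @export
sim_region_set <- function(genome, n_regions, length_mean = 500, length_sd = 150,
                           seed = 1, min_length = 50, max_tries = 200L) {
  if (n_regions < 0) abort("n_regions must be >= 0")
  if (length_mean <= 0) abort("length_mean must be positive")
  if (n_regions == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  local_seed(seed, {
    placed <- tibble(chrom = character(), start = numeric(), end = numeric())
    tries <- 0
    while (nrow(placed) < n_regions) {
      tries <- tries + 1
      if (tries > max_tries) {
        abort("genome too small or too masked to place the requested regions")
      }
      need <- n_regions - nrow(placed)
      lens <- pmax(min_length, round(stats::rnorm(need, length_mean, length_sd)))
      cand <- sample_placements(genome, lens)
      # drop candidates colliding with already placed regions or each other
      if (nrow(placed) > 0) {
        idx <- build_overlap_index(placed)
        keep <- overlap_with_index(idx, cand$chrom, cand$start, cand$end) == 0
        cand <- cand[keep, , drop = FALSE]
      }
      if (nrow(cand) > 1) {
        cand <- sort_regions(cand)
        self_ok <- c(TRUE, cand$start[-1] >= cand$end[-nrow(cand)] |
                       cand$chrom[-1] != cand$chrom[-nrow(cand)])
        cand <- cand[self_ok, , drop = FALSE]
      }
      placed <- dplyr::bind_rows(placed, cand)
    }
    placed <- sort_regions(placed[seq_len(n_regions), ])
    placed$name <- paste0("peak_", seq_len(nrow(placed)))
    placed
  })
}

#' Simulate a query set nested inside a reference at a known rate
#'
#' Plants a fraction of query regions wholly inside randomly chosen reference
#' regions; the remainder are placed uniformly over the unmasked genome. The
#' true containment labels are returned, giving ground truth for overlap
#' enrichment testing.
#'
#' @param reference Non-empty region tibble.
#' @param genome A [genome_model()] (sampling space for the non-nested part).
#' @param n Number of query regions.
#' @param inside_fraction Fraction (rounded to a count) planted inside the
#'   reference, in `[0, 1]`.
#' @param query_length Length of each query region (bp).
#' @param seed Integer RNG seed.
#' @return A region tibble with logical `inside` ground-truth labels, sorted.
#' @export
sim_nested_query <- function(reference, genome, n, inside_fraction = 0.5,
                             query_length = 200, seed = 1) {
  reference <- validate_regions(reference)
  if (nrow(reference) == 0) abort("reference must be non-empty")
  if (inside_fraction < 0 || inside_fraction > 1) {
    abort("inside_fraction must be in [0, 1]")
  }
  fits <- reference$end - reference$start >= query_length
  n_in <- round(inside_fraction * n)
  if (n_in > 0 && !any(fits)) {
    abort("no reference region is long enough to contain a query region")
  }
  local_seed(seed, {
    inside <- NULL
    if (n_in > 0) {
      ref <- reference[fits, , drop = FALSE]
      # prefer distinct host regions so planted queries stay disjoint and
      # total query bp equals the base-pair overlap with the reference
      pick <- sample.int(nrow(ref), n_in, replace = n_in > nrow(ref))
      slack <- ref$end[pick] - ref$start[pick] - query_length
      s <- ref$start[pick] + floor(stats::runif(n_in, 0, slack + 1))
      inside <- tibble(chrom = ref$chrom[pick], start = s,
                       end = s + query_length, inside = TRUE)
    }
    outside <- NULL
    if (n - n_in > 0) {
      outside <- sample_placements(genome, rep(query_length, n - n_in))
      outside$inside <- FALSE
    }
    q <- sort_regions(dplyr::bind_rows(inside, outside))
    q$name <- paste0("query_", seq_len(nrow(q)))
    q
  })
}

#' Simulate per-region tag counts with planted fold effects
#'
#' Counts are Poisson: each region receives an equal share of the background
#' depth, and the target-condition rate is that share scaled by the region's
#' fold effect and the depth ratio, so the expected target:background count
#' ratio per region is `fold_effect * depth_target / depth_background`.
#'
#' @param regions Region tibble.
#' @param depth_target,depth_background Total tag counts in each condition.
#' @param fold_effects Per-region multiplicative effect (recycled scalar or
#'   one value per region); 1 = no change.
#' @param seed Integer RNG seed.
#' @return The regions with `tags_target`, `tags_background` and the
#'   ground-truth `fold_effect` appended.
#' @export
sim_tag_counts <- function(regions, depth_target = 1e6, depth_background = 1e6,
                           fold_effects = 1, seed = 1) {
  regions <- validate_regions(regions)
  if (depth_target <= 0 || depth_background <= 0) abort("depths must be positive")
  n <- nrow(regions)
  fold_effects <- rep_len(fold_effects, n)
  if (any(fold_effects < 0)) abort("fold effects must be non-negative")
  local_seed(seed, {
    share <- 1 / n
    lam_bg <- depth_background * share
    lam_tg <- depth_target * share * fold_effects
    dplyr::mutate(regions,
                  tags_target = stats::rpois(n, lam_tg),
                  tags_background = stats::rpois(n, lam_bg),
                  fold_effect = fold_effects)
  })
}

#' Simulate fixed-width sequence windows with planted motif occurrences
#'
#' Generates `n_windows` i.i.d. uniform DNA windows and plants the PWM
#' consensus sequence at a random offset and strand in exactly
#' `round(plant_rate * n_windows)` of them. True plant labels are returned.
#'
#' @param n_windows Number of windows.
#' @param window_size Window length (bp), at least the motif length.
#' @param pwm A [pwm()] object whose consensus is planted.
#' @param plant_rate Fraction of windows carrying the consensus, in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A tibble with `name`, `sequence` and logical `planted` columns.
#' @export
sim_window_sequences <- function(n_windows, window_size, pwm, plant_rate = 0,
                                 seed = 1) {
  if (plant_rate < 0 || plant_rate > 1) abort("plant_rate must be in [0, 1]")
  motif <- pwm_consensus(pwm)
  L <- nchar(motif)
  if (window_size < L) abort("window_size must be >= motif length")
  n_plant <- round(plant_rate * n_windows)
  local_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n_windows), function(i) {
      paste(sample(bases, window_size, replace = TRUE), collapse = "")
    }, character(1))
    planted <- logical(n_windows)
    if (n_plant > 0) {
      which_plant <- sample.int(n_windows, n_plant)
      planted[which_plant] <- TRUE
      for (i in which_plant) {
        ins <- if (stats::runif(1) < 0.5) motif else revcomp(motif)
        off <- sample.int(window_size - L + 1, 1)
        substr(seqs[i], off, off + L - 1) <- ins
      }
    }
    tibble(name = paste0("window_", seq_len(n_windows)),
           sequence = seqs, planted = planted)
  })
}

#' Simulate an expression matrix along a planted EMT axis
#'
#' Epithelial-signature genes (positive direction, including the CDH1-role
#' anchor) decrease linearly as samples move from the epithelial end
#' (`emt_axis = 0`) to the mesenchymal end (`emt_axis = 1`); mesenchymal
#' genes increase; extra genes are pure noise. Values get additive Gaussian
#' noise and are floored at a small positive epsilon, keeping the matrix
#' strictly positive.
#'
#' @param signature An [emt_signature()]; genes with `direction = 1` behave
#'   epithelially, `-1` mesenchymally.
#' @param emt_axis Numeric vector in `[0, 1]`, one entry per sample (at
#'   least 3 samples, for correlation-based weighting downstream).
#' @param n_extra_genes Unrelated noise genes to append.
#' @param noise_sd Standard deviation of the additive expression noise.
#' @param seed Integer RNG seed.
#' @param base,span Baseline expression and signal amplitude shared by all
#'   signature genes.
#' @return A tibble with a `gene` column and one numeric column per sample
#'   (`sample_1`, ...).
#' @export
sim_expression <- function(signature, emt_axis, n_extra_genes = 0,
                           noise_sd = 0, seed = 1, base = 2, span = 8) {
  if (length(emt_axis) < 3) abort("need at least 3 samples")
  if (any(emt_axis < 0 | emt_axis > 1)) abort("emt_axis values must be in [0, 1]")
  genes <- signature$genes
  n_s <- length(emt_axis)
  local_seed(seed, {
    mu <- t(vapply(seq_len(nrow(genes)), function(i) {
      if (genes$direction[i] > 0) base + span * (1 - emt_axis)
      else base + span * emt_axis
    }, numeric(n_s)))
    extra <- matrix(base + span / 2, nrow = n_extra_genes, ncol = n_s)
    m <- rbind(mu, extra)
    m <- m + stats::rnorm(length(m), 0, noise_sd)
    m <- pmax(m, 0.01)
    out <- as_tibble(m, .name_repair = ~ paste0("sample_", seq_len(n_s)))
    dplyr::bind_cols(
      tibble(gene = c(genes$gene,
                      if (n_extra_genes > 0) paste0("noise_", seq_len(n_extra_genes)))),
      out
    )
  })
}

#' A synthetic CDH1-anchored EMT signature
#'
#' The published 76-gene scoring metric is configuration data, not code; this
#' constructor builds a signature of the same shape for simulation and
#' testing: an anchor gene in the CDH1 role plus epithelial (direction +1)
#' and mesenchymal (direction -1) members.
#'
#' @param genes Tibble with `gene` and `direction` (+1/-1) columns, or NULL
#'   for the default 76-gene synthetic signature (anchor + 37 epithelial +
#'   38 mesenchymal).
#' @param anchor Name of the anchor gene; must appear in `genes`.
#' @return An object of class `emt_signature`.
#' @export
emt_signature <- function(genes = NULL, anchor = "CDH1") {
  if (is.null(genes)) {
    genes <- tibble(
      gene = c("CDH1", sprintf("EPI%02d", 1:37), sprintf("MES%02d", 1:38)),
      direction = c(rep(1, 38), rep(-1, 38))
    )
  }
  genes <- as_tibble(genes)
  if (!all(c("gene", "direction") %in% names(genes))) {
    abort("signature genes need `gene` and `direction` columns")
  }
  if (!anchor %in% genes$gene) abort("anchor gene must be part of the signature")
  structure(list(genes = genes, anchor = anchor), class = "emt_signature")
}

#' @export
print.emt_signature <- function(x, ...) {
  cat("<emt_signature> ", nrow(x$genes), " genes, anchor ", x$anchor, "\n", sep = "")
  invisible(x)
}

#' Simulate multi-condition peak sets with controlled sharing
#'
#' Builds a pool of candidate peaks, marks `n_shared` of them present in all
#' conditions, and gives each condition `n_unique` private peaks, so
#' condition-membership (Venn) counts of the merged set are known in
#' advance. Each emitted peak carries a raw accessibility score drawn
#' log-normally around `score_meanlog`.
#'
#' @param genome A [genome_model()].
#' @param conditions Character vector of condition labels.
#' @param n_shared Peaks present in every condition.
#' @param n_unique Peaks private to each condition.
#' @param seed Integer RNG seed.
#' @param length_mean,length_sd Peak length distribution (bp).
#' @param score_meanlog,score_sdlog Log-normal parameters of each peak's
#'   underlying accessibility score.
#' @param condition_sdlog Per-condition log-scale jitter around a peak's
#'   underlying score; shared peaks therefore score similarly across
#'   conditions, which is what drives realistic cross-condition correlation.
#' @return A named list of scored region tibbles (one per condition) with a
#'   ground-truth `shared` column.
#' @export
sim_condition_peaks <- function(genome, conditions, n_shared = 100,
                                n_unique = 30, seed = 1,
                                length_mean = 500, length_sd = 150,
                                score_meanlog = 3, score_sdlog = 0.6,
                                condition_sdlog = 0.15) {
  k <- length(conditions)
  n_total <- n_shared + k * n_unique
  pool <- sim_region_set(genome, n_total, length_mean, length_sd, seed = seed)
  pool$base_meanlog <- local_seed(seed + 1, stats::rnorm(n_total, score_meanlog, score_sdlog))
  seeds <- child_seeds(seed + 2, k)
  shared <- pool[seq_len(n_shared), , drop = FALSE]
  out <- list()
  for (i in seq_len(k)) {
    lo <- n_shared + (i - 1) * n_unique + 1
    uniq <- pool[seq(lo, length.out = n_unique), , drop = FALSE]
    s <- dplyr::bind_rows(
      dplyr::mutate(shared, shared = TRUE),
      dplyr::mutate(uniq, shared = FALSE)
    )
    out[[conditions[i]]] <- local_seed(seeds[i], {
      sc <- round(exp(stats::rnorm(nrow(s), s$base_meanlog, condition_sdlog)), 2)
      sort_regions(dplyr::select(dplyr::mutate(s, score = sc), -"base_meanlog"))
    })
  }
  out
}

#' Simulate a TSS table
#'
#' Places one TSS per gene uniformly over the unmasked genome with a random
#' strand.
#'
#' @param genome A [genome_model()].
#' @param genes Character vector of gene ids (must be unique).
#' @param seed Integer RNG seed.
#' @return A tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
sim_tss <- function(genome, genes, seed = 1) {
  if (anyDuplicated(genes)) abort("gene ids must be unique")
  local_seed(seed, {
    pos <- sample_placements(genome, rep(1, length(genes)))
    tibble(gene_id = genes, chrom = pos$chrom, tss = pos$start,
           strand = sample(c("+", "-"), length(genes), replace = TRUE))
  })
}
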