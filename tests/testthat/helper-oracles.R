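# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs. These deliberately share no code with
# the functions they validate.

# Transitive closure of the centre-distance relation by repeated pairwise
# union over an explicit distance matrix.
oracle_merge <- function(sets, d) {
  combined <- dplyr::bind_rows(lapply(sets, tibble::as_tibble), .id = "set")
  n <- nrow(combined)
  center <- (combined$start + combined$end) / 2
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (combined$chrom[i] == combined$chrom[j] &&
          abs(center[i] - center[j]) <= d && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(split(seq_len(n), comp), function(idx) {
    tibble::tibble(
      chrom = combined$chrom[idx[1]],
      start = min(combined$start[idx]),
      end = max(combined$end[idx]),
      members = list(sort(unique(combined$set[idx])))
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# Base-pair overlap by explicit per-position set intersection.
oracle_overlap_bp <- function(a, b) {
  pos <- function(r) {
    unlist(lapply(seq_len(nrow(r)), function(i) {
      paste0(r$chrom[i], ":", seq(r$start[i], r$end[i] - 1))
    }))
  }
  length(intersect(unique(pos(a)), unique(pos(b))))
}

# Nearest TSS by exhaustive all-pairs scan.
oracle_nearest_tss <- function(regions, tss) {
  center <- floor((regions$start + regions$end) / 2)
  out_gene <- character(nrow(regions))
  out_dist <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    tt <- tss[tss$chrom == regions$chrom[i], ]
    if (nrow(tt) == 0) { out_gene[i] <- NA; out_dist[i] <- NA; next }
    d <- abs(center[i] - tt$tss)
    cand <- tt[d == min(d), ]
    cand <- cand[order(cand$gene_id), ][1, ]
    out_gene[i] <- cand$gene_id
    raw <- center[i] - cand$tss
    out_dist[i] <- if (cand$strand == "-") -raw else raw
  }
  tibble::tibble(gene_id = out_gene, tss_distance = out_dist)
}

# Upper-tail hypergeometric by complete enumeration of draws.
oracle_hyper_enum <- function(overlap, size_a, size_b, universe_size) {
  draws <- utils::combn(universe_size, size_b)
  hits <- colSums(draws <= size_a)  # treat 1..size_a as set A
  mean(hits >= overlap)
}

# Upper-tail Poisson probability by explicit partial summation.
oracle_poisson_tail <- function(k, lambda) {
  kk <- seq(k, max(k + 50, ceiling(lambda + 40 * sqrt(lambda + 1))))
  sum(exp(-lambda + kk * log(lambda) - lfactorial(kk)))
}

# Textbook Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exhaustive log2-odds PWM scoring of every offset on one strand.
oracle_scan_scores <- function(mat, background, sequence) {
  L <- ncol(mat)
  bases <- strsplit(sequence, "")[[1]]
  vapply(seq_len(nchar(sequence) - L + 1), function(off) {
    sum(vapply(seq_len(L), function(j) {
      b <- bases[off + j - 1]
      if (!b %in% rownames(mat)) return(0)
      log2(mat[b, j] / background[match(b, c("A", "C", "G", "T"))])
    }, numeric(1)))
  }, numeric(1))
}

# Exact expected overlap of one shuffled region with a reference by
# enumerating every valid placement on a fully unmasked toy genome.
oracle_expected_overlap <- function(chrom_len, region_len, ref_start, ref_end) {
  starts <- 0:(chrom_len - region_len)
  mean(vapply(starts, function(s) {
    max(0, min(s + region_len, ref_end) - max(s, ref_start))
  }, numeric(1)))
}
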