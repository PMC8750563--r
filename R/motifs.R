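#' Position weight matrix for motif scanning
#'
#' A PWM is a 4-by-L matrix of base probabilities (rows A, C, G, T; columns
#' sum to 1) plus a background model and a log-odds detection threshold.
#' Matching is by summed log2 odds `log2(p_base / bg_base)` over all offsets
#' and both strands.
#'
#' @param matrix 4-by-L numeric matrix (or count matrix; columns are
#'   normalised) with rows in A, C, G, T order.
#' @param name Motif name.
#' @param background Background base probabilities; default uniform.
#' @param threshold Log-odds detection threshold; default `threshold_frac`
#'   of the maximum achievable score.
#' @param threshold_frac Fraction of the maximum score used when `threshold`
#'   is NULL; default 0.8.
#' @param pseudocount Added to matrix probabilities before normalisation to
#'   keep log odds finite; default 0.001.
#' @return An object of class `pwm`.
#' @examples
#' m <- matrix(c(0.97, 0.01, 0.01, 0.01), 4, 6)  # poly-A motif
#' p <- pwm(m, name = "polyA")
#' scan_window(p, "TTTAAAAAATT")
#' @export
pwm <- function(matrix, name = "motif", background = rep(0.25, 4),
                threshold = NULL, threshold_frac = 0.8, pseudocount = 1e-3) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) abort("PWM needs 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4) abort("PWM needs length >= 4")
  if (any(matrix < 0)) abort("PWM entries must be non-negative")
  matrix <- matrix + pseudocount
  matrix <- sweep(matrix, 2, colSums(matrix), "/")
  rownames(matrix) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  logodds <- log2(matrix / background)
  max_score <- sum(apply(logodds, 2, max))
  structure(
    list(name = name, matrix = matrix, background = background,
         logodds = logodds, max_score = max_score,
         threshold = threshold %||% (threshold_frac * max_score)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, ": length ", ncol(x$matrix),
      ", consensus ", pwm_consensus(x),
      ", threshold ", round(x$threshold, 2), "/", round(x$max_score, 2),
      " bits\n", sep = "")
  invisible(x)
}

#' @rdname pwm
#' @param x A `pwm` object.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$matrix)[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Read PWMs from a JASPAR-style plain-text file
#'
#' Accepts the common JASPAR layouts: a `>name` header followed by four rows
#' of counts, either bare numbers or `A [ 1 2 3 ]` bracketed rows.
#'
#' @param path File path.
#' @inheritParams pwm
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4),
                        threshold_frac = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0) abort("no '>' motif headers found")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4) abort(paste0("motif ", name, ": expected 4 matrix rows"))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[|\\]$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(paste0("motif ", name, ": ragged matrix rows"))
    }
    out[[name]] <- pwm(do.call(rbind, rows), name = name,
                       background = background, threshold_frac = threshold_frac)
  }
  out
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else (N, masked) NA.
encode_dna <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  v
}

# Best log2-odds score of `pwm` over all offsets of one encoded strand.
# NA positions (N / masked bases) contribute 0 (background score).
best_score_encoded <- function(logodds, enc) {
  L <- ncol(logodds)
  n <- length(enc)
  if (n < L) return(-Inf)
  best <- -Inf
  for (off in 0:(n - L)) {
    idx <- enc[(off + 1):(off + L)]
    sc <- logodds[cbind(idx, seq_len(L))]
    sc[is.na(idx)] <- 0
    s <- sum(sc)
    if (s > best) best <- s
  }
  best
}

#' Scan a sequence window for a motif hit
#'
#' Scores every offset on both strands by summed log2 odds against the PWM
#' background; a hit is any score at or above the PWM's threshold. N (or any
#' non-ACGT) positions score as background (0 bits). Strand-symmetric:
#' a sequence and its reverse complement give identical results.
#'
#' @param pwm A [pwm()] object.
#' @param sequence A single DNA string at least as long as the motif.
#' @return A list with `hit` (logical) and `best_score` (best log2 odds over
#'   offsets and strands).
#' @export
scan_window <- function(pwm, sequence) {
  if (!nzchar(sequence)) abort("empty sequence")
  if (nchar(sequence) < ncol(pwm$matrix)) {
    abort("sequence shorter than the motif")
  }
  fwd <- best_score_encoded(pwm$logodds, encode_dna(sequence))
  rev <- best_score_encoded(pwm$logodds, encode_dna(revcomp(sequence)))
  best <- max(fwd, rev)
  list(hit = best >= pwm$threshold, best_score = best)
}

#' Extract fixed-width windows centred on peak centres
#'
#' One window per peak, of length exactly `size`, centred on the peak centre
#' (shifted left by 1 bp when parities force a choice). Windows running past
#' a chromosome boundary, or intersecting the excluded mask, are dropped;
#' the number dropped is reported as an attribute.
#'
#' @param regions Region tibble.
#' @param size Window width in bp (default 50, the motif-scan width).
#' @param genome Optional [genome_model()]; enables boundary and mask
#'   filtering.
#' @return A region tibble of windows, with attribute `n_dropped`.
#' @export
extract_windows <- function(regions, size = 50, genome = NULL) {
  regions <- validate_regions(regions)
  if (size <= 0) abort("window size must be positive")
  center <- floor((regions$start + regions$end) / 2)
  start <- center - size %/% 2
  w <- tibble(chrom = regions$chrom, start = start, end = start + size)
  keep <- w$start >= 0
  if (!is.null(genome)) {
    sizes <- stats::setNames(genome$chrom_sizes$size, genome$chrom_sizes$chrom)
    keep <- keep & w$end <= sizes[w$chrom]
    idx <- build_overlap_index(genome$excluded)
    keep <- keep & overlap_with_index(idx, w$chrom, w$start, w$end) == 0
  }
  out <- w[which(keep), , drop = FALSE]
  attr(out, "n_dropped") <- nrow(w) - nrow(out)
  out
}

#' Percentage of windows containing a motif hit
#'
#' @param windows Tibble with a `sequence` column (e.g. from
#'   [sim_window_sequences()] or [read_fasta()]).
#' @param pwm A [pwm()] object.
#' @return Percentage in `[0, 100]` of windows with at least one hit.
#' @export
motif_target_percentage <- function(windows, pwm) {
  if (nrow(windows) == 0) abort("no windows supplied")
  hits <- vapply(windows$sequence, function(s) scan_window(pwm, s)$hit, logical(1))
  100 * sum(hits) / length(hits)
}

#' Hypergeometric motif-enrichment test
#'
#' Upper-tail hypergeometric probability of seeing at least `target_hits`
#' hit windows among the target draws, given the combined target+background
#' window universe and its total hit count: the classic known-motif
#' enrichment statistic for window sets.
#'
#' @param target_hits,target_total Hit and total window counts in the target
#'   set.
#' @param background_hits,background_total Hit and total window counts in
#'   the background set.
#' @return The p-value `P(X >= target_hits)`.
#' @export
motif_enrichment_test <- function(target_hits, target_total,
                                  background_hits, background_total) {
  if (any(c(target_hits, target_total, background_hits, background_total) < 0)) {
    abort("counts must be non-negative")
  }
  if (target_hits > target_total || background_hits > background_total) {
    abort("hits cannot exceed totals")
  }
  K <- target_hits + background_hits
  N <- target_total + background_total
  stats::phyper(target_hits - 1, K, N - K, target_total, lower.tail = FALSE)
}

#' Motif percentage change relative to a control condition
#'
#' @param condition_pct,control_pct Target percentages in `[0, 100]`.
#' @return Signed percentage-point difference, condition minus control.
#' @examples
#' percentage_change(18.9, 17.1)  # AP-1-style shift: +1.8 points
#' @export
percentage_change <- function(condition_pct, control_pct) {
  if (any(c(condition_pct, control_pct) < 0 | c(condition_pct, control_pct) > 100)) {
    abort("percentages must lie in [0, 100]")
  }
  condition_pct - control_pct
}

#' Per-condition motif enrichment table
#'
#' Scans one set of windows per condition against each PWM, computes the
#' target percentage, the hypergeometric enrichment p against a shared
#' background window set, the percentage change versus a control condition,
#' and applies the significance filter (motifs with p above `max_p` in every
#' condition are dropped from the reported set).
#'
#' @param condition_windows Named list of window tibbles (with `sequence`),
#'   one per condition.
#' @param background_windows Background window tibble.
#' @param pwms List of [pwm()] objects.
#' @param control Name of the control condition for percentage change;
#'   default the first.
#' @param max_p Significance cutoff; motifs whose minimum p across
#'   conditions exceeds it are discarded (default 1e-12).
#' @return A tibble with one row per motif and condition: `motif`,
#'   `condition`, `target_pct`, `background_pct`, `p_value`,
#'   `percentage_change`.
#' @export
motif_enrichment_table <- function(condition_windows, background_windows, pwms,
                                   control = names(condition_windows)[1],
                                   max_p = 1e-12) {
  if (is.null(names(condition_windows))) abort("condition_windows must be named")
  rows <- purrr::map_dfr(pwms, function(p) {
    bg_hits <- sum(vapply(background_windows$sequence,
                          function(s) scan_window(p, s)$hit, logical(1)))
    bg_total <- nrow(background_windows)
    purrr::imap_dfr(condition_windows, function(w, cond) {
      hits <- sum(vapply(w$sequence, function(s) scan_window(p, s)$hit, logical(1)))
      tibble(
        motif = p$name, condition = cond,
        target_pct = 100 * hits / nrow(w),
        background_pct = 100 * bg_hits / bg_total,
        p_value = motif_enrichment_test(hits, nrow(w), bg_hits, bg_total)
      )
    })
  })
  rows <- rows |>
    dplyr::group_by(.data$motif) |>
    dplyr::mutate(percentage_change = percentage_change(
      .data$target_pct, .data$target_pct[.data$condition == control][1]
    )) |>
    dplyr::filter(min(.data$p_value) <= max_p) |>
    dplyr::ungroup()
  rows
}

#' Read and write FASTA sequence sets
#'
#' @param path File path.
#' @return `read_fasta()` returns a tibble with `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = names(x), sequence = unname(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs Tibble with `name` and `sequence` columns.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(seqs$sequence, seqs$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
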