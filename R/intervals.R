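#' Read a BED file into a region tibble
#'
#' Coordinates are 0-based half-open, as in the BED standard. Three to six
#' columns are understood (`chrom`, `start`, `end`, `name`, `score`,
#' `strand`); extra columns are dropped.
#'
#' @param path Path to a tab-separated BED file.
#' @param genome Optional [genome_model()] used to validate chromosome names
#'   and bounds.
#' @return A sorted tibble with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(fields))
  if (ncol < 3) abort("BED requires at least 3 tab-separated columns")
  col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  if (anyNA(start) || anyNA(end)) abort("non-numeric BED coordinates")
  out <- tibble(chrom = col(1), start = start, end = end)
  if (ncol >= 4) out$name <- col(4)
  if (ncol >= 5) {
    score <- suppressWarnings(as.numeric(col(5)))
    if (anyNA(score)) abort("non-numeric BED score column")
    out$score <- score
  }
  if (ncol >= 6) out$strand <- col(6)
  sort_regions(validate_regions(out, genome = genome))
}

#' Write a region tibble to a BED file
#'
#' Emits BED3/BED5/BED6 depending on which of `name`, `score`, `strand` are
#' present; `write_bed()` then `read_bed()` round-trips `chrom`, `start`,
#' `end`, `name` and `score` exactly.
#'
#' @param regions Region tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- sort_regions(validate_regions(regions))
  n <- nrow(regions)
  cols <- list(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE))
  want_score <- !is.null(regions[["score"]]) || !is.null(regions[["strand"]])
  if (!is.null(regions[["name"]]) || want_score) {
    cols <- c(cols, list(regions[["name"]] %||% rep(".", n)))
  }
  if (want_score) {
    cols <- c(cols, list(format(regions[["score"]] %||% rep(0, n),
                                scientific = FALSE, trim = TRUE)))
  }
  if (!is.null(regions[["strand"]])) cols <- c(cols, list(regions[["strand"]]))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Merge peak sets by centre distance
#'
#' Unifies peaks whose centres lie within `max_center_distance` of one another
#' (transitive closure, the `mergePeaks -d` semantic): each merged region
#' spans the union of its members and records which input condition(s)
#' contributed, so membership combinations can be counted directly
#' (Venn-style condition sharing).
#'
#' @param sets Either a single region tibble with a `set` column naming the
#'   condition each peak came from, or a named list of region tibbles (names
#'   become condition labels).
#' @param max_center_distance Maximum centre-to-centre distance (bp) for two
#'   peaks to be unified. Default 300.
#' @return A sorted tibble with `chrom`, `start`, `end`, one logical
#'   membership column per input condition, and, when every input peak is
#'   scored, one `score_<condition>` column holding the maximum contributing
#'   raw score (NA where the condition is absent).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = c(100, 450), end = c(200, 500))
#' b <- tibble::tibble(chrom = "chr1", start = 180, end = 260)
#' merge_region_sets(list(A = a, B = b))
#' @export
merge_region_sets <- function(sets, max_center_distance = 300) {
  if (max_center_distance < 0) abort("max_center_distance must be >= 0")
  if (is.data.frame(sets)) {
    if (!"set" %in% names(sets)) abort("region tibble input needs a `set` column")
    combined <- as_tibble(sets)
    labels <- unique(combined$set)
  } else {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      names(sets) <- paste0("set", seq_along(sets))
    }
    labels <- names(sets)
    combined <- dplyr::bind_rows(lapply(sets, as_tibble), .id = "set")
  }
  combined <- validate_regions(combined)
  has_scores <- "score" %in% names(combined) && !anyNA(combined$score)
  if (nrow(combined) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    for (l in labels) out[[l]] <- logical()
    return(out)
  }
  combined <- combined |>
    dplyr::mutate(center = (.data$start + .data$end) / 2) |>
    dplyr::arrange(.data$chrom, .data$center, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    # centres are 1-D, so the transitive closure of the pairwise distance
    # relation is exactly chaining consecutive sorted centres
    dplyr::mutate(cluster = cumsum(c(1, diff(.data$center) > max_center_distance))) |>
    dplyr::ungroup()
  merged <- combined |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     members = list(unique(.data$set)), .groups = "drop")
  for (l in labels) {
    merged[[l]] <- purrr::map_lgl(merged$members, ~ l %in% .x)
  }
  if (has_scores) {
    sc <- combined |>
      dplyr::group_by(.data$chrom, .data$cluster, .data$set) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "set", values_from = "score",
                         names_prefix = "score_")
    merged <- dplyr::left_join(merged, sc, by = c("chrom", "cluster"))
  }
  merged |>
    dplyr::select(-"cluster", -"members") |>
    sort_regions()
}

#' Count condition-membership combinations of a merged peak set
#'
#' @param merged Output of [merge_region_sets()].
#' @param labels Membership columns to tabulate; default all logical columns.
#' @return A tibble with one row per observed membership combination
#'   (`combination`, comma-separated condition labels) and its peak count `n`.
#' @export
membership_counts <- function(merged, labels = NULL) {
  if (is.null(labels)) {
    labels <- names(merged)[vapply(merged, is.logical, logical(1))]
  }
  if (length(labels) == 0) abort("no logical membership columns found")
  combo <- apply(as.matrix(merged[labels]), 1, function(r) {
    paste(labels[r], collapse = ",")
  })
  dplyr::count(tibble(combination = combo), .data$combination, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Inter-peak gap lengths
#'
#' Gaps are measured between consecutive peaks on the same chromosome
#' (`next start - previous end`); distances to chromosome ends are not
#' counted. The input must be a merged (non-overlapping) set.
#'
#' @param regions Merged region tibble.
#' @return A tibble with one row per gap: `chrom`, `gap_start`, `gap_end`,
#'   `gap_length`. Summarise with e.g. `median(gap_lengths(x)$gap_length)`.
#' @export
gap_lengths <- function(regions) {
  regions <- sort_regions(validate_regions(regions))
  by_chrom <- split(regions, regions$chrom)
  purrr::map_dfr(by_chrom, function(d) {
    if (nrow(d) < 2) {
      return(tibble(chrom = character(), gap_start = numeric(),
                    gap_end = numeric(), gap_length = numeric()))
    }
    gs <- d$end[-nrow(d)]
    ge <- d$start[-1]
    if (any(ge < gs)) abort("regions overlap; merge before computing gaps")
    tibble(chrom = d$chrom[1], gap_start = gs, gap_end = ge, gap_length = ge - gs)
  })
}

#' Count peak deserts
#'
#' A peak desert is an inter-peak gap whose effective length — gap length
#' minus the bp of excluded sequence (blacklist, assembly gaps, centromeres)
#' falling inside the gap — exceeds `min_gap`.
#'
#' @param regions Merged region tibble.
#' @param genome A [genome_model()] supplying the excluded regions.
#' @param min_gap Desert threshold in bp; default 1 Mb.
#' @return Integer count of deserts.
#' @export
count_peak_deserts <- function(regions, genome, min_gap = 1e6) {
  gaps <- gap_lengths(regions)
  if (nrow(gaps) == 0) return(0L)
  idx <- build_overlap_index(genome$excluded)
  excl_bp <- overlap_with_index(idx, gaps$chrom, gaps$gap_start, gaps$gap_end)
  sum(gaps$gap_length - excl_bp > min_gap)
}

#' Annotate peaks with the nearest transcription start site
#'
#' Distance is `peak centre - TSS position`, with the sign flipped for minus
#' strand genes so that positive always means downstream of the TSS. The
#' nearest TSS is chosen by absolute distance; exact ties go to the
#' lexicographically smallest `gene_id`.
#'
#' @param regions Region tibble.
#' @param tss A tibble with columns `gene_id`, `chrom`, `tss` (bp) and
#'   `strand` (`+`/`-`).
#' @return The input regions with `gene_id` and signed `tss_distance` columns
#'   appended (NA for peaks on chromosomes without any TSS).
#' @export
nearest_tss <- function(regions, tss) {
  regions <- validate_regions(regions)
  tss <- as_tibble(tss)
  if (nrow(tss) == 0) abort("TSS table is empty")
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(tss))) {
    abort("TSS table needs columns gene_id, chrom, tss, strand")
  }
  tss <- dplyr::arrange(tss, .data$tss, .data$gene_id)
  tss_by_chrom <- split(tss, tss$chrom)
  center <- floor((regions$start + regions$end) / 2)
  gene <- rep(NA_character_, nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  for (cn in unique(regions$chrom)) {
    tt <- tss_by_chrom[[cn]]
    sel <- which(regions$chrom == cn)
    if (is.null(tt)) next
    for (i in sel) {
      d_abs <- abs(center[i] - tt$tss)
      best <- which(d_abs == min(d_abs))
      k <- best[order(tt$gene_id[best])[1]]
      gene[i] <- tt$gene_id[k]
      raw <- center[i] - tt$tss[k]
      dist[i] <- if (tt$strand[k] == "-") -raw else raw
    }
  }
  if (anyNA(gene) && nrow(regions) > 0) {
    warn("some peaks lie on chromosomes without any TSS; returned NA")
  }
  dplyr::mutate(regions, gene_id = gene, tss_distance = dist)
}

#' Total base-pair overlap between two region sets
#'
#' Both sets are collapsed to disjoint intervals first, so the result is the
#' size (bp) of the intersection of their genomic footprints; symmetric in
#' its arguments.
#'
#' @param a,b Region tibbles.
#' @return Total overlapping bp as a double.
#' @export
basepair_overlap <- function(a, b) {
  a <- validate_regions(a)
  b <- validate_regions(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ga <- GenomicRanges::reduce(regions_to_granges(a))
  gb <- GenomicRanges::reduce(regions_to_granges(b))
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(ga, gb, ignore.strand = TRUE))))
}
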