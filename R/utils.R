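#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive independent child seeds from one parent seed, staying inside the
# 32-bit integer range expected by set.seed().
child_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Validate a region table
#'
#' Checks the tidy region representation used throughout the package: one row
#' per genomic region with 0-based half-open coordinates.
#'
#' @param regions A data frame with columns `chrom`, `start`, `end` and
#'   optionally `name` and `score`.
#' @param scored Require a non-missing, non-negative `score` column.
#' @param genome Optional [genome_model()]; when supplied, chromosome names
#'   and bounds are checked.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_regions <- function(regions, scored = FALSE, genome = NULL) {
  regions <- as_tibble(regions)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(regions))
  if (length(missing_cols) > 0) {
    abort(paste0("region table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(regions) > 0) {
    if (!is.numeric(regions$start) || !is.numeric(regions$end)) {
      abort("region coordinates must be numeric")
    }
    if (any(regions$start != floor(regions$start)) || any(regions$end != floor(regions$end))) {
      abort("region coordinates must be integers")
    }
    if (any(regions$start < 0)) abort("region start coordinates must be >= 0")
    if (any(regions$start >= regions$end)) {
      abort("every region must satisfy start < end (0-based half-open)")
    }
  }
  if (scored) {
    if (!"score" %in% names(regions) || anyNA(regions$score)) {
      abort("region table must carry a complete `score` column")
    }
    if (nrow(regions) > 0 && any(regions$score < 0)) abort("scores must be non-negative")
  }
  if (!is.null(genome) && nrow(regions) > 0) {
    sizes <- stats::setNames(genome$chrom_sizes$size, genome$chrom_sizes$chrom)
    unknown <- setdiff(unique(regions$chrom), names(sizes))
    if (length(unknown) > 0) {
      abort(paste0("unknown chromosome(s): ", paste(unknown, collapse = ", ")))
    }
    if (any(regions$end > sizes[regions$chrom])) {
      abort("region extends past its chromosome end")
    }
  }
  regions
}

# Sort by (chrom, start, end); chromosome order is lexicographic.
sort_regions <- function(regions) {
  dplyr::arrange(regions, .data$chrom, .data$start, .data$end)
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

granges_to_regions <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Collapse overlapping/adjacent-inclusive regions to a disjoint sorted set.
reduce_regions <- function(regions) {
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  sort_regions(granges_to_regions(GenomicRanges::reduce(regions_to_granges(regions))))
}

# Cumulative-coverage index over a disjoint sorted region set, for fast
# point/interval overlap queries without building GRanges in inner loops.
build_overlap_index <- function(regions) {
  regions <- reduce_regions(regions)
  split(regions, regions$chrom) |>
    lapply(function(d) {
      w <- d$end - d$start
      list(start = d$start, end = d$end, cum = cumsum(as.numeric(w)), w = as.numeric(w))
    })
}

# Total covered bp strictly below coordinate x (vectorised over x).
.covered_below <- function(idx_chrom, x) {
  j <- findInterval(x, idx_chrom$start)
  out <- numeric(length(x))
  hit <- j > 0
  if (any(hit)) {
    jj <- j[hit]
    out[hit] <- idx_chrom$cum[jj] - idx_chrom$w[jj] +
      pmin(idx_chrom$w[jj], pmax(0, x[hit] - idx_chrom$start[jj]))
  }
  out
}

# Overlap in bp between intervals [start, end) on `chrom` and the indexed set.
overlap_with_index <- function(index, chrom, start, end) {
  out <- numeric(length(start))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    idx <- index[[cn]]
    if (is.null(idx)) next
    out[sel] <- .covered_below(idx, end[sel]) - .covered_below(idx, start[sel])
  }
  out
}
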