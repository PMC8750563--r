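#' Genome model: chromosome sizes plus excluded regions
#'
#' Bundles the chromosome-size table with a set of excluded regions
#' (ENCODE-style blacklist, assembly gaps, centromeres). The model defines the
#' valid sampling space for region simulation, length-matched shuffling and
#' peak-desert accounting.
#'
#' @param chrom_sizes A data frame with columns `chrom` and `size` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param excluded Optional region table of excluded intervals; defaults to
#'   none. Regions are validated against chromosome bounds and collapsed to a
#'   disjoint sorted set.
#' @return An object of class `genome_model`: a list with tibbles
#'   `chrom_sizes` and `excluded`.
#' @examples
#' gm <- genome_model(c(chr1 = 1e6, chr2 = 5e5))
#' genome_size(gm)
#' @export
genome_model <- function(chrom_sizes, excluded = NULL) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes), size = unname(chrom_sizes))
  }
  chrom_sizes <- as_tibble(chrom_sizes)
  if (nrow(chrom_sizes) == 0) abort("genome model needs at least one chromosome")
  if (!all(c("chrom", "size") %in% names(chrom_sizes))) {
    abort("chrom_sizes needs columns `chrom` and `size`")
  }
  if (any(chrom_sizes$size <= 0)) abort("chromosome sizes must be positive")
  if (anyDuplicated(chrom_sizes$chrom)) abort("duplicated chromosome names")
  chrom_sizes$size <- as.numeric(chrom_sizes$size)
  if (is.null(excluded)) {
    excluded <- tibble(chrom = character(), start = integer(), end = integer())
  }
  gm <- structure(
    list(chrom_sizes = chrom_sizes, excluded = excluded),
    class = "genome_model"
  )
  gm$excluded <- reduce_regions(validate_regions(excluded, genome = gm))
  gm
}

#' @export
print.genome_model <- function(x, ...) {
  cat(
    "<genome_model> ", nrow(x$chrom_sizes), " chromosome(s), ",
    format(genome_size(x), big.mark = ","), " bp; ",
    nrow(x$excluded), " excluded region(s) (",
    format(sum(x$excluded$end - x$excluded$start), big.mark = ","), " bp)\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname genome_model
#' @param genome A `genome_model`.
#' @export
genome_size <- function(genome) sum(genome$chrom_sizes$size)

#' Read and write two-column chrom.sizes files
#'
#' @param path Path to a tab-separated file with chromosome name and length.
#' @return `read_chrom_sizes()` returns a tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  as_tibble(d)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Tibble with `chrom` and `size` columns.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(chrom_sizes[, c("chrom", "size")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Maximal unmasked spans per chromosome: the complement of the excluded set
# within chromosome bounds. Returns a tibble (chrom, start, end).
unmasked_spans <- function(genome) {
  excl <- split(genome$excluded, genome$excluded$chrom)
  purrr::map2_dfr(genome$chrom_sizes$chrom, genome$chrom_sizes$size, function(cn, sz) {
    e <- excl[[cn]]
    if (is.null(e) || nrow(e) == 0) {
      return(tibble(chrom = cn, start = 0, end = sz))
    }
    starts <- c(0, e$end)
    ends <- c(e$start, sz)
    keep <- starts < ends
    tibble(chrom = cn, start = starts[keep], end = ends[keep])
  })
}
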