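# Small in-code fixtures shared across test files.

toy_genome <- function(sizes = c(chr1 = 1e6), excluded = NULL) {
  genome_model(sizes, excluded)
}

regions_tbl <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = chrom, start = start, end = end, ...)
}

toy_tss <- function() {
  tibble::tibble(
    gene_id = c("GENEA", "GENEB", "GENEC"),
    chrom = c("chr1", "chr1", "chr2"),
    tss = c(10000, 50000, 20000),
    strand = c("+", "-", "+")
  )
}
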