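#' CDH1-anchored weighted EMT score (76GS-style)
#'
#' Scores each sample as a weighted sum of signature-gene expression, where
#' each gene's weight is its Pearson correlation with the anchor gene
#' (CDH1 role) across samples and the anchor's own weight is 1. Scores are
#' mean-centred across samples, so the global mean is zero; positive scores
#' read as epithelial, negative as mesenchymal.
#'
#' @param expr Expression tibble: `gene` column plus one numeric column per
#'   sample (at least 3 samples).
#' @param signature An [emt_signature()]; scoring uses the intersection of
#'   its genes with `expr` (a warning reports missing genes).
#' @return An object of class `emt_score` holding a per-sample tibble
#'   (`sample`, `score`, `call`), the gene weights, and the signature
#'   coverage fraction.
#' @examples
#' sig <- emt_signature()
#' expr <- sim_expression(sig, emt_axis = c(0, 0.5, 1), seed = 1)
#' gs76_score(expr, sig)
#' @export
gs76_score <- function(expr, signature) {
  expr <- as_tibble(expr)
  if (!"gene" %in% names(expr)) abort("expression table needs a `gene` column")
  samples <- setdiff(names(expr), "gene")
  samples <- samples[vapply(expr[samples], is.numeric, logical(1))]
  if (length(samples) < 3) abort("need at least 3 samples for correlation weights")
  if (any(vapply(expr[samples], function(x) any(x < 0), logical(1)))) {
    abort("expression values must be non-negative")
  }
  anchor <- signature$anchor
  if (!anchor %in% expr$gene) abort(paste0("anchor gene ", anchor, " absent from expression"))
  found <- intersect(signature$genes$gene, expr$gene)
  if (length(found) < 2) abort("fewer than 2 signature genes found in expression")
  if (length(found) < nrow(signature$genes)) {
    warn(paste0(nrow(signature$genes) - length(found),
                " signature gene(s) missing from expression; scoring the intersection"))
  }
  x <- as.matrix(expr[match(found, expr$gene), samples])
  rownames(x) <- found
  a <- x[anchor, ]
  if (stats::sd(a) == 0) abort("anchor gene has zero variance across samples")
  w <- apply(x, 1, function(g) {
    if (stats::sd(g) == 0) 0 else stats::cor(g, a)
  })
  w[anchor] <- 1
  raw <- as.numeric(crossprod(x, w))
  score <- raw - mean(raw)
  structure(
    list(
      scores = tibble(sample = samples, score = score,
                      call = ifelse(score >= 0, "epithelial", "mesenchymal")),
      weights = tibble(gene = found, weight = unname(w)),
      coverage = length(found) / nrow(signature$genes),
      anchor = anchor
    ),
    class = "emt_score"
  )
}

#' @export
print.emt_score <- function(x, ...) {
  cat("<emt_score> anchor ", x$anchor, ", signature coverage ",
      round(100 * x$coverage, 1), "%\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' Tidy an EMT score result
#'
#' @param x An `emt_score` object.
#' @param ... Unused.
#' @return `tidy()`: the per-sample tibble (`sample`, `score`, `call`);
#'   `glance()`: a one-row tibble with sample count, signature coverage and
#'   the anchor gene.
#' @export
tidy.emt_score <- function(x, ...) x$scores

#' @rdname tidy.emt_score
#' @export
glance.emt_score <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), coverage = x$coverage, anchor = x$anchor)
}

#' Per-sample mean z-score summaries for gene signatures
#'
#' Each gene is z-scored across samples (constant genes contribute 0); each
#' sample's summary for a gene set is the mean z over the set's genes found
#' in the expression table. Typical use: core EMT-Up and EMT-Down signatures.
#'
#' @param expr Expression tibble (`gene` plus sample columns).
#' @param up_genes,down_genes Character vectors of gene ids.
#' @return A list with `summary` (tibble: `sample`, `up`, `down`) and
#'   `z` (per-gene z-score tibble for heatmap rendering, with a `set`
#'   column).
#' @export
signature_summary <- function(expr, up_genes, down_genes) {
  expr <- as_tibble(expr)
  samples <- setdiff(names(expr), "gene")
  zscore <- function(genes, label) {
    found <- intersect(genes, expr$gene)
    if (length(found) == 0) abort(paste0("no ", label, " genes found in expression"))
    x <- as.matrix(expr[match(found, expr$gene), samples])
    z <- t(apply(x, 1, function(g) {
      s <- stats::sd(g)
      if (s == 0) rep(0, length(g)) else (g - mean(g)) / s
    }))
    dimnames(z) <- list(found, samples)
    z
  }
  zu <- zscore(up_genes, "up")
  zd <- zscore(down_genes, "down")
  z_tbl <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(gene = rownames(zu), set = "up"), as_tibble(zu)),
    dplyr::bind_cols(tibble(gene = rownames(zd), set = "down"), as_tibble(zd))
  )
  list(
    summary = tibble(sample = samples, up = unname(colMeans(zu)),
                     down = unname(colMeans(zd))),
    z = z_tbl
  )
}

#' Per-gene expression fold change between two samples
#'
#' The fold change is simply the ratio of the two samples' expression
#' values, pseudocounted so zeros stay defined:
#' `(x_a + eps) / (x_b + eps)`.
#'
#' @param expr Expression tibble (`gene` plus sample columns).
#' @param sample_a,sample_b Sample column names (ratio is a over b).
#' @param pseudocount Epsilon added to both values; default 1.
#' @return A tibble with `gene` and `fold_change`.
#' @export
expression_fold_change <- function(expr, sample_a, sample_b, pseudocount = 1) {
  expr <- as_tibble(expr)
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(expr)) abort(paste0("unknown sample: ", s))
  }
  tibble(
    gene = expr$gene,
    fold_change = (expr[[sample_a]] + pseudocount) / (expr[[sample_b]] + pseudocount)
  )
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric probability of the observed overlap between two
#' gene sets drawn from a common universe: `P(X >= |a intersect b|)` for
#' `X ~ Hypergeometric(N = |universe|, K = |a|, n = |b|)`.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return A tibble with `overlap`, `size_a`, `size_b`, `universe_size` and
#'   `p_value`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  K <- length(set_a); n <- length(set_b); N <- length(universe)
  tibble(
    overlap = k, size_a = K, size_b = n, universe_size = N,
    p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  )
}

#' Read and write gene-by-sample expression tables
#'
#' Plain TSV with gene ids in the first column and one column per sample.
#'
#' @param path File path.
#' @return `read_expression()` returns a tibble with a `gene` column.
#' @export
read_expression <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  names(d)[1] <- "gene"
  as_tibble(d)
}

#' @rdname read_expression
#' @param expr Expression tibble.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
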