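#' Pipeline configuration
#'
#' Collects every tunable threshold of the accessibility/expression pipeline,
#' with the analysis defaults baked in: 300-bp merge distance and score bins,
#' 50-bp motif windows, 1-Mb desert threshold, MPS class bounds 3/5, major
#' DPS change at |2|, differential peaks at 4-fold with Poisson p < 1e-4,
#' 1,000 permutations, motif significance cutoff 1e-12. Unknown keys are
#' rejected.
#'
#' @param ... Named overrides of the defaults listed above, plus the
#'   simulation block (`chrom_sizes`, `excluded_fraction`, `conditions`,
#'   `n_shared`, `n_unique`, `n_tss`, `fold_effect`, `n_fold_regions`,
#'   `depth`, `motif_plant_rates`, `n_windows`, `emt_axis`, `noise_sd`).
#' @param file Optional YAML file of overrides (applied before `...`).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(
    seed = 1,
    merge_distance = 300,
    score_bin = 300,
    window_size = 50,
    desert_min_gap = 1e6,
    mps_low = 3,
    mps_high = 5,
    dps_major = 2,
    diff_min_fold = 4,
    diff_max_p = 1e-4,
    n_permutations = 1000,
    motif_max_p = 1e-12,
    # simulation block
    chrom_sizes = c(chr1 = 6e6, chr2 = 4e6),
    excluded_fraction = 0.05,
    conditions = c("untreated", "tgfb_short", "tgfb_long", "withdrawn"),
    n_shared = 120,
    n_unique = 40,
    n_tss = 150,
    fold_effect = 8,
    n_fold_regions = 40,
    depth = 2e5,
    motif_plant_rates = c(untreated = 0.17, tgfb_short = 0.30,
                          tgfb_long = 0.28, withdrawn = 0.18),
    n_windows = 200,
    emt_axis = c(untreated = 0, tgfb_short = 0.5, tgfb_long = 1, withdrawn = 0.15),
    noise_sd = 0.5
  )
  overrides <- list(...)
  if (!is.null(file)) overrides <- c(yaml::read_yaml(file), overrides)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Generate the full synthetic fixture for the pipeline
#'
#' Writes every input the pipeline consumes, with ground truth: chrom.sizes
#' and exclusion mask, per-condition scored peak BEDs, tag counts with
#' planted fold effects, per-condition motif windows (FASTA) plus background
#' windows, an expression table along a planted EMT axis, a TSS table, and a
#' JSON manifest with ground-truth labels and file checksums. Fully
#' reproducible from the config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(config$seed, 8)
  genome <- sim_genome(config$chrom_sizes, config$excluded_fraction, seed = seeds[1])
  write_chrom_sizes(genome$chrom_sizes, file.path(out_dir, "genome.chrom.sizes"))
  write_bed(genome$excluded, file.path(out_dir, "excluded.bed"))

  peaks <- sim_condition_peaks(genome, config$conditions,
                               n_shared = config$n_shared,
                               n_unique = config$n_unique, seed = seeds[2])
  for (cond in names(peaks)) {
    write_bed(peaks[[cond]], file.path(out_dir, paste0("peaks_", cond, ".bed")))
  }

  sig <- emt_signature()
  axis <- config$emt_axis[config$conditions]
  expr <- sim_expression(sig, axis, n_extra_genes = 40,
                         noise_sd = config$noise_sd, seed = seeds[6])
  names(expr) <- c("gene", config$conditions)
  write_expression(expr, file.path(out_dir, "expression.tsv"))
  utils::write.table(sig$genes, file.path(out_dir, "signature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # TSS ids reuse the expression gene names (plus fillers) so differential
  # peaks annotate to genes with measurable expression fold changes
  gene_ids <- expr$gene
  if (config$n_tss > length(gene_ids)) {
    gene_ids <- c(gene_ids,
                  sprintf("GENE%04d", seq_len(config$n_tss - length(gene_ids))))
  }
  tss <- sim_tss(genome, gene_ids, seed = seeds[3])
  utils::write.table(tss, file.path(out_dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  base_peaks <- peaks[[1]][, c("chrom", "start", "end", "name")]
  fold_effects <- rep(1, nrow(base_peaks))
  planted <- seq_len(min(config$n_fold_regions, nrow(base_peaks)))
  fold_effects[planted] <- config$fold_effect
  counts <- sim_tag_counts(base_peaks, depth_target = config$depth,
                           depth_background = config$depth,
                           fold_effects = fold_effects, seed = seeds[4])
  utils::write.table(counts, file.path(out_dir, "tag_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  motif <- default_test_pwm()
  window_seeds <- child_seeds(seeds[5], length(config$conditions) + 1)
  for (i in seq_along(config$conditions)) {
    cond <- config$conditions[i]
    w <- sim_window_sequences(config$n_windows, config$window_size, motif,
                              plant_rate = config$motif_plant_rates[[cond]],
                              seed = window_seeds[i])
    write_fasta(w[, c("name", "sequence")],
                file.path(out_dir, paste0("windows_", cond, ".fa")))
    utils::write.table(w[, c("name", "planted")],
                       file.path(out_dir, paste0("windows_", cond, ".truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bg <- sim_window_sequences(config$n_windows * 2, config$window_size, motif,
                             plant_rate = 0,
                             seed = window_seeds[length(window_seeds)])
  write_fasta(bg[, c("name", "sequence")], file.path(out_dir, "windows_background.fa"))
  writeLines(jaspar_lines(motif), file.path(out_dir, "motif.jaspar"))

  reference <- sim_region_set(genome, 60, length_mean = 1000, length_sd = 200,
                              seed = seeds[7])
  query <- sim_nested_query(reference, genome, n = 40, inside_fraction = 0.6,
                            query_length = 200, seed = seeds[8])
  write_bed(reference, file.path(out_dir, "reference_marks.bed"))
  write_bed(query[, c("chrom", "start", "end", "name")],
            file.path(out_dir, "query_regions.bed"))

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    conditions = as.list(config$conditions),
    emt_axis = as.list(axis),
    ground_truth = list(
      fold_effect_regions = base_peaks$name[planted],
      fold_effect = config$fold_effect,
      motif_plant_rates = as.list(config$motif_plant_rates),
      query_inside_fraction = 0.6,
      query_inside = query$name[query$inside]
    ),
    checksums = as.list(stats::setNames(tools::md5sum(files), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# A short palindromic-free test motif with a sharp consensus.
default_test_pwm <- function() {
  consensus <- "ACGTGACC"
  m <- matrix(0.02, 4, nchar(consensus),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], rownames(m))
  m[cbind(idx, seq_len(ncol(m)))] <- 0.94
  pwm(m, name = "TESTMOTIF")
}

jaspar_lines <- function(p) {
  counts <- round(p$matrix * 100)
  c(paste0(">", p$name),
    vapply(seq_len(4), function(i) {
      paste0(rownames(p$matrix)[i], " [ ", paste(counts[i, ], collapse = " "), " ]")
    }, character(1)))
}

#' Run the full analysis pipeline on a fixture directory
#'
#' Executes every stage on the files produced by [run_simulate()] (or
#' equivalently structured user data): peak merging with membership counts,
#' gap/desert statistics, score matrix with quantile normalisation and
#' correlation, MPS/DPS classification per condition pair, differential
#' peaks joined to TSS distance and expression fold change, motif
#' enrichment percentages and changes, permutation overlap enrichment, and
#' the EMT score. Tables are written as TSV (and the enrichment result as
#' JSON) under `out_dir`.
#'
#' @param fixture_dir Directory holding the pipeline inputs.
#' @param config A [pipeline_config()]; thresholds and the seed come from
#'   here.
#' @param out_dir Output directory; default `file.path(fixture_dir, "results")`.
#' @return A named list with every stage's result.
#' @export
run_all <- function(fixture_dir, config = pipeline_config(),
                    out_dir = file.path(fixture_dir, "results")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(fixture_dir, ...)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  genome <- stage("genome", {
    genome_model(read_chrom_sizes(fp("genome.chrom.sizes")),
                 read_bed(fp("excluded.bed")))
  })
  peaks <- stage("peaks", {
    conds <- config$conditions
    stats::setNames(lapply(conds, function(cond) {
      read_bed(fp(paste0("peaks_", cond, ".bed")))
    }), conds)
  })

  merged <- stage("merge", merge_region_sets(peaks, config$merge_distance))
  venn <- membership_counts(merged, labels = config$conditions)

  gaps <- stage("gaps", {
    purrr::map_dfr(peaks, function(p) gap_lengths(p), .id = "condition")
  })
  gap_medians <- gaps |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(median_gap = stats::median(.data$gap_length), .groups = "drop")
  deserts <- stage("deserts", {
    tibble(condition = config$conditions,
           deserts = vapply(peaks, function(p) {
             as.integer(count_peak_deserts(p, genome, config$desert_min_gap))
           }, integer(1)))
  })

  matrix_qn <- stage("matrix", {
    quantile_normalize(build_score_matrix(peaks, bin = config$score_bin))
  })
  cors <- stage("correlation", correlation_matrix(matrix_qn))

  control <- config$conditions[1]
  mpsdps <- stage("mpsdps", {
    purrr::map_dfr(setdiff(config$conditions, control), function(cond) {
      dplyr::bind_cols(
        tibble(pair = paste0(cond, "_vs_", control), region = matrix_qn$region),
        classify_change(matrix_qn[[cond]], matrix_qn[[control]],
                        mps_low = config$mps_low, mps_high = config$mps_high,
                        dps_major = config$dps_major)
      )
    })
  })

  tss <- as_tibble(utils::read.table(fp("tss.tsv"), header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE))
  counts <- as_tibble(utils::read.table(fp("tag_counts.tsv"), header = TRUE,
                                        sep = "\t", stringsAsFactors = FALSE))
  expr <- read_expression(fp("expression.tsv"))
  diff <- stage("diffpeaks", {
    differential_peaks(counts, depth_target = config$depth,
                       depth_background = config$depth,
                       min_fold = config$diff_min_fold,
                       max_p = config$diff_max_p)
  })
  fc_tss <- stage("fc_vs_tss", {
    fc_vs_tss_table(diff, tss, expr,
                    sample_a = config$conditions[2], sample_b = control)
  })

  pwms <- read_jaspar(fp("motif.jaspar"))
  windows <- stats::setNames(lapply(config$conditions, function(cond) {
    read_fasta(fp(paste0("windows_", cond, ".fa")))
  }), config$conditions)
  bg <- read_fasta(fp("windows_background.fa"))
  motifs <- stage("motifs", {
    motif_enrichment_table(windows, bg, pwms, control = control,
                           max_p = config$motif_max_p)
  })

  enrich <- stage("enrich", {
    permutation_overlap_test(read_bed(fp("query_regions.bed")),
                             read_bed(fp("reference_marks.bed")),
                             genome, n_permutations = config$n_permutations,
                             seed = config$seed)
  })

  sig_genes <- as_tibble(utils::read.table(fp("signature.tsv"), header = TRUE,
                                           sep = "\t", stringsAsFactors = FALSE))
  emt <- stage("emtscore", gs76_score(expr, emt_signature(sig_genes)))

  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(venn, "membership_counts.tsv")
  wt(gaps, "gap_lengths.tsv")
  wt(gap_medians, "gap_medians.tsv")
  wt(deserts, "peak_deserts.tsv")
  wt(matrix_qn, "score_matrix_qn.tsv")
  utils::write.table(cors, file.path(out_dir, "correlation.tsv"), sep = "\t",
                     quote = FALSE)
  wt(mpsdps, "mps_dps.tsv")
  wt(diff, "differential_peaks.tsv")
  wt(fc_tss, "fc_vs_tss.tsv")
  wt(motifs, "motif_enrichment.tsv")
  jsonlite::write_json(tidy(enrich), file.path(out_dir, "overlap_enrichment.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  wt(tidy(emt), "emt_scores.tsv")

  list(
    merged_peaks = merged, membership_counts = venn,
    gap_lengths = gaps, gap_medians = gap_medians, peak_deserts = deserts,
    score_matrix = matrix_qn, correlation = cors, mps_dps = mpsdps,
    differential_peaks = diff, fc_vs_tss = fc_tss,
    motif_enrichment = motifs, overlap_enrichment = enrich, emt_score = emt
  )
}
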