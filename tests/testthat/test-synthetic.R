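test_that("simulated genomes mask the requested fraction and are reproducible", {
  gm0 <- sim_genome(c(chr1 = 1e6), excluded_fraction = 0, seed = 1)
  expect_equal(nrow(gm0$excluded), 0)
  gm <- sim_genome(c(chr1 = 5e6), excluded_fraction = 0.2, seed = 7)
  frac <- sum(gm$excluded$end - gm$excluded$start) / 5e6
  expect_gte(frac, 0.18)
  expect_lte(frac, 0.22)
  # mask is disjoint and in bounds
  expect_true(all(gm$excluded$start[-1] >= gm$excluded$end[-nrow(gm$excluded)]))
  expect_true(all(gm$excluded$end <= 5e6))
  gm2 <- sim_genome(c(chr1 = 5e6), excluded_fraction = 0.2, seed = 7)
  expect_identical(gm$excluded, gm2$excluded)
  expect_error(sim_genome(c(chr1 = 1e6), excluded_fraction = 1), "\\[0, 1\\)")
  expect_error(genome_model(tibble::tibble(chrom = character(), size = numeric())),
               "at least one chromosome")
})

test_that("simulated region sets respect the mask, the count and the seed", {
  gm <- sim_genome(c(chr1 = 2e6, chr2 = 1e6), excluded_fraction = 0.3, seed = 11)
  expect_equal(nrow(sim_region_set(gm, 0, seed = 1)), 0)
  rs <- sim_region_set(gm, 100, seed = 3)
  expect_equal(nrow(rs), 100)
  expect_equal(basepair_overlap(rs, gm$excluded), 0)
  expect_identical(rs, sim_region_set(gm, 100, seed = 3))
  # sorted and mutually non-overlapping
  g <- gap_lengths(rs)
  expect_true(all(g$gap_length >= 0))
  # an over-masked genome cannot host the request
  tiny <- genome_model(c(chr1 = 2000), regions_tbl("chr1", 0, 1900))
  expect_error(sim_region_set(tiny, 50, length_mean = 500, seed = 1),
               "too small|no unmasked span")
})

test_that("nested queries land inside the reference at exactly the planted rate", {
  gm <- toy_genome(c(chr1 = 1e7))
  ref <- sim_region_set(gm, 100, length_mean = 1000, length_sd = 0, seed = 5)
  q_all <- sim_nested_query(ref, gm, n = 50, inside_fraction = 1,
                            query_length = 200, seed = 17)
  expect_equal(basepair_overlap(q_all, ref), 50 * 200)
  q_half <- sim_nested_query(ref, gm, n = 50, inside_fraction = 0.5,
                             query_length = 200, seed = 17)
  expect_equal(sum(q_half$inside), 25)
  # containment labels are truthful
  idx <- emtatac:::build_overlap_index(ref)
  ov <- emtatac:::overlap_with_index(idx, q_half$chrom, q_half$start, q_half$end)
  expect_true(all(ov[q_half$inside] == 200))
  expect_error(sim_nested_query(ref, gm, n = 10, inside_fraction = 2), "\\[0, 1\\]")
  short_ref <- regions_tbl("chr1", 0, 50)
  expect_error(sim_nested_query(short_ref, gm, n = 5, inside_fraction = 1,
                                query_length = 200, seed = 1), "long enough")
})

test_that("fully random queries overlap the reference at about its coverage fraction", {
  gm <- toy_genome(c(chr1 = 1e7))
  ref <- sim_region_set(gm, 50, length_mean = 1000, length_sd = 0, seed = 2)
  cover <- sum(ref$end - ref$start) / 1e7  # 0.5% of the genome
  q <- sim_nested_query(ref, gm, n = 400, inside_fraction = 0, query_length = 100, seed = 9)
  frac <- basepair_overlap(q, ref) / sum(q$end - q$start)
  sd3 <- 3 * sqrt(cover * (1 - cover) / 400)
  expect_lt(abs(frac - cover), sd3 + 0.01)
})

test_that("tag counts follow the planted fold model and are reproducible", {
  gm <- toy_genome()
  rs <- sim_region_set(gm, 200, seed = 4)
  tc <- sim_tag_counts(rs, depth_target = 2e5, depth_background = 2e5,
                       fold_effects = 1, seed = 6)
  expect_identical(tc, sim_tag_counts(rs, 2e5, 2e5, 1, seed = 6))
  ratio <- mean(tc$tags_target / tc$tags_background)
  expect_lt(abs(ratio - 1), 0.1)
  # an 8-fold region with expected background count 50
  one <- regions_tbl("chr1", 0, 500)
  r8 <- sim_tag_counts(one, depth_target = 50, depth_background = 50,
                       fold_effects = 8, seed = 3)
  expect_gte(r8$tags_target / r8$tags_background, 6)
  expect_lte(r8$tags_target / r8$tags_background, 10)
  expect_error(sim_tag_counts(one, 1e5, 1e5, fold_effects = -1), "non-negative")
})

test_that("window simulation plants the consensus at the exact rounded count", {
  p <- emtatac:::default_test_pwm()
  w0 <- sim_window_sequences(50, 50, p, plant_rate = 0, seed = 1)
  expect_false(any(w0$planted))
  w <- sim_window_sequences(100, 50, p, plant_rate = 0.17, seed = 2)
  expect_equal(sum(w$planted), 17)
  expect_true(all(nchar(w$sequence) == 50))
  # every planted window scores at or above the detection threshold
  hits <- vapply(w$sequence[w$planted], function(s) scan_window(p, s)$hit, logical(1))
  expect_true(all(hits))
  expect_identical(w, sim_window_sequences(100, 50, p, plant_rate = 0.17, seed = 2))
  expect_error(sim_window_sequences(10, 4, p, plant_rate = 0.5), ">= motif length")
  expect_error(sim_window_sequences(10, 50, p, plant_rate = 1.5), "\\[0, 1\\]")
})

test_that("simulated expression encodes the EMT axis and stays positive", {
  sig <- emt_signature()
  expect_error(sim_expression(sig, c(0, 1)), "at least 3")
  e0 <- sim_expression(sig, c(0, 0.5, 1), noise_sd = 0, seed = 1)
  anchor <- as.numeric(e0[e0$gene == "CDH1", -1])
  expect_true(all(diff(anchor) < 0))  # anchor decreases along the axis
  mes <- as.numeric(e0[e0$gene == "MES01", -1])
  expect_true(all(diff(mes) > 0))
  expect_true(all(as.matrix(e0[, -1]) > 0))
  en <- sim_expression(sig, c(0, 0.5, 1), n_extra_genes = 5, noise_sd = 1, seed = 3)
  expect_identical(en, sim_expression(sig, c(0, 0.5, 1), n_extra_genes = 5,
                                      noise_sd = 1, seed = 3))
  expect_true(all(as.matrix(en[, -1]) > 0))
})

test_that("condition peak sets share exactly the planted common peaks", {
  gm <- toy_genome(c(chr1 = 5e6))
  sets <- sim_condition_peaks(gm, c("a", "b", "c"), n_shared = 30, n_unique = 10, seed = 8)
  expect_named(sets, c("a", "b", "c"))
  for (s in sets) {
    expect_equal(sum(s$shared), 30)
    expect_equal(nrow(s), 40)
    expect_true(all(s$score > 0))
  }
  merged <- merge_region_sets(lapply(sets, function(s) s[, c("chrom", "start", "end", "score")]))
  counts <- membership_counts(merged, labels = c("a", "b", "c"))
  expect_equal(counts$n[counts$combination == "a,b,c"], 30)
})
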