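test_that("the score matrix recentres merged peaks and log-transforms scores", {
  a <- regions_tbl("chr1", 100, 200, score = 7)
  b <- regions_tbl("chr1", 5000, 5400, score = 15)
  m <- build_score_matrix(list(A = a, B = b), bin = 300)
  expect_equal(nrow(m), 2)
  expect_true(all(m$end - m$start == 300))
  # raw score 7 -> log2(8) = 3; condition absent from a row -> 0
  row_a <- m[m$start == 0, ]  # centre 150, clipped window [0, 300)
  expect_equal(row_a$A, 3)
  expect_equal(row_a$B, 0)
  # identical inputs give identical columns
  m2 <- build_score_matrix(list(A = a, B = a))
  expect_equal(m2$A, m2$B)
  expect_error(build_score_matrix(list(A = a[, 1:3], B = b)), "score")
  expect_error(build_score_matrix(list(A = a)), "at least 2")
})

test_that("quantile normalisation equalises column distributions by rank means", {
  m <- tibble::tibble(region = c("r1", "r2", "r3"), A = c(1, 2, 3), B = c(6, 4, 5))
  qn <- quantile_normalize(m)
  expect_equal(qn$A, c(2.5, 3.5, 4.5))
  expect_equal(qn$B, c(4.5, 2.5, 3.5))
  # identical columns are a fixed point; result multisets are identical
  same <- tibble::tibble(A = c(2, 7, 1), B = c(2, 7, 1))
  expect_equal(quantile_normalize(same), same)
  withr::with_seed(1, {
    big <- tibble::tibble(A = rexp(50), B = rexp(50), C = rexp(50))
  })
  qbig <- quantile_normalize(big)
  expect_equal(sort(qbig$A), sort(qbig$B))
  expect_equal(sort(qbig$B), sort(qbig$C))
  # idempotence
  expect_equal(quantile_normalize(qbig), qbig)
})

test_that("condition correlations match a textbook Pearson formula", {
  withr::with_seed(3, {
    m <- tibble::tibble(A = rnorm(10), B = rnorm(10), C = rnorm(10))
  })
  cm <- correlation_matrix(m)
  expect_equal(diag(cm), c(A = 1, B = 1, C = 1))
  expect_equal(cm, t(cm))
  expect_true(all(cm >= -1 & cm <= 1))
  expect_equal(cm["A", "B"], oracle_pearson(m$A, m$B), tolerance = 1e-12)
  expect_equal(cm["A", "C"], oracle_pearson(m$A, m$C), tolerance = 1e-12)
  neg <- tibble::tibble(A = c(1, 2, 3), B = c(-1, -2, -3))
  expect_equal(correlation_matrix(neg)["A", "B"], -1)
  expect_error(correlation_matrix(tibble::tibble(A = c(1, 1, 1), B = 1:3)),
               "zero-variance")
})

test_that("MPS/DPS classification applies the low/high and major-change thresholds", {
  r <- classify_change(c(4, 6.5, 1.0), c(4, 3.9, 3.5))
  expect_equal(r$mps, c(4, 5.2, 2.25))
  expect_equal(r$dps, c(0, 2.6, -2.5))
  expect_equal(r$accessibility_class, c("moderate", "high", "low"))
  expect_equal(r$major_change, c(FALSE, TRUE, TRUE))
  expect_equal(r$direction, c("none", "increase", "decrease"))
  # antisymmetry of DPS, symmetry of MPS
  fwd <- classify_change(c(1, 5, 2.2), c(4, 0.5, 2.2))
  bwd <- classify_change(c(4, 0.5, 2.2), c(1, 5, 2.2))
  expect_equal(fwd$dps, -bwd$dps)
  expect_equal(fwd$mps, bwd$mps)
})

test_that("differential peaks need both the 4-fold filter and the Poisson tail", {
  counts <- tibble::tibble(tags_target = c(40, 12, 0, 5),
                           tags_background = c(5, 4, 10, 0))
  d <- differential_peaks(counts, depth_target = 100, depth_background = 100)
  # target 40 vs lambda 5: fold 8, p below 1e-4
  expect_true(d$differential[1])
  expect_equal(d$p_value[1], oracle_poisson_tail(40, 5), tolerance = 1e-12)
  # fold 3 fails the filter regardless of p
  expect_false(d$differential[2])
  expect_equal(d$fold[2], 3)
  # zero target tags can never be flagged
  expect_false(d$differential[3])
  # zero background gets the 0.5 pseudocount
  expect_equal(d$lambda[4], 0.5)
  expect_equal(d$fold[4], 10)
  expect_error(differential_peaks(tibble::tibble(tags_target = -1, tags_background = 1)),
               "non-negative")
})

test_that("no region is differential in both directions", {
  gm <- toy_genome()
  rs <- sim_region_set(gm, 150, seed = 2)
  fold <- withr::with_seed(5, sample(c(1, 1, 1, 8), 150, replace = TRUE))
  tc <- sim_tag_counts(rs, 1e5, 1e5, fold_effects = fold, seed = 12)
  fwd <- differential_peaks(tc, 1e5, 1e5)
  swapped <- dplyr::rename(tc, tags_target = "tags_background",
                           tags_background = "tags_target")
  bwd <- differential_peaks(swapped, 1e5, 1e5)
  expect_equal(sum(fwd$differential & bwd$differential), 0)
})

test_that("planted 8-fold effects are recovered with high sensitivity and specificity", {
  gm <- toy_genome(c(chr1 = 5e6))
  rs <- sim_region_set(gm, 400, seed = 21)
  fold <- rep(1, 400)
  fold[1:100] <- 8
  tc <- sim_tag_counts(rs, depth_target = 2e4, depth_background = 2e4,
                       fold_effects = fold, seed = 22)
  d <- differential_peaks(tc, depth_target = 2e4, depth_background = 2e4)
  sens <- mean(d$differential[d$fold_effect == 8])
  fpr <- mean(d$differential[d$fold_effect == 1])
  expect_gte(sens, 0.95)
  expect_lte(fpr, 0.01)
})

test_that("differential peaks join to nearest genes and expression ratios", {
  tss <- tibble::tibble(gene_id = c("G1", "G2", "G3"),
                        chrom = "chr1", tss = c(1000, 6000, 20000),
                        strand = c("+", "+", "-"))
  expr <- tibble::tibble(gene = c("G1", "G2"), s1 = c(9, 3), s2 = c(4, 3))
  peaks <- regions_tbl("chr1", c(900, 5800, 19500, 30000, 40000),
                       c(1100, 6200, 20500, 30200, 40200),
                       tags_target = c(40L, 50L, 60L, 8L, 80L),
                       tags_background = c(5L, 5L, 5L, 5L, 5L),
                       differential = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  out <- fc_vs_tss_table(peaks, tss, expr, "s1", "s2")
  expect_equal(nrow(out), 4)  # the non-differential peak is dropped
  # hand-joined oracle: nearest genes and pseudocounted ratios
  expect_equal(out$gene_id[1:3], c("G1", "G2", "G3"))
  expect_equal(out$expression_fc[out$gene_id == "G1"], (9 + 1) / (4 + 1))
  expect_equal(out$expression_fc[out$gene_id == "G2"], 1)
  expect_true(all(out$missing_expression[out$gene_id == "G3"]))
  # identical samples give unit ratios everywhere
  same <- fc_vs_tss_table(peaks, tss, dplyr::mutate(expr, s2 = s1), "s1", "s2")
  expect_true(all(same$expression_fc[!same$missing_expression] == 1))
  # a peak centred on its gene's TSS joins to that gene at distance 0
  centred <- regions_tbl("chr1", 900, 1100, tags_target = 40L,
                         tags_background = 5L, differential = TRUE)
  got <- fc_vs_tss_table(centred, tss, expr, "s1", "s2")
  expect_equal(got$gene_id, "G1")
  expect_equal(got$tss_distance, 0)
})
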