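test_that("BED writing then reading is the identity on coordinates, names and scores", {
  rs <- regions_tbl("chr1", c(100, 900, 5000), c(350, 1300, 5600),
                    name = c("a", "b", "c"), score = c(1.5, 7, 0))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs, path)
  back <- read_bed(path)
  expect_equal(back[, c("chrom", "start", "end", "name", "score")],
               rs[, c("chrom", "start", "end", "name", "score")])
})

test_that("malformed BED input is rejected and empty files give empty sets", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t50", path)
  expect_error(read_bed(path), "start < end")
  writeLines("chr1\tx\t50", path)
  expect_error(read_bed(path), "non-numeric")
  writeLines(character(0), path)
  expect_equal(nrow(read_bed(path)), 0)
  expect_error(read_bed(withr::local_tempfile()), "no such file")
})

test_that("reading against a genome model validates chromosome names", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrUn\t10\t50", path)
  expect_error(read_bed(path, genome = toy_genome()), "unknown chromosome")
})

test_that("merging chains peaks whose centres lie within the distance", {
  a <- regions_tbl("chr1", c(100, 450), c(200, 500))
  b <- regions_tbl("chr1", 180, 260)
  m <- merge_region_sets(list(A = a, B = b), max_center_distance = 300)
  # centres 150, 475, 220: gaps 70 and 255, both within 300 -> one region
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100)
  expect_equal(m$end, 500)
  expect_true(m$A && m$B)
})

test_that("merging a set with itself is idempotent and an empty partner leaves it unchanged", {
  a <- regions_tbl("chr1", c(100, 2000), c(200, 2500))
  m <- merge_region_sets(list(A = a, B = a))
  expect_equal(m[, c("chrom", "start", "end")], a)
  expect_true(all(m$A) && all(m$B))
  empty <- regions_tbl(character(), integer(), integer())
  m2 <- merge_region_sets(list(A = a, B = empty))
  expect_equal(m2[, c("chrom", "start", "end")], a)
  expect_true(all(m2$A))
  expect_false(any(m2$B))
  expect_error(merge_region_sets(list(A = a), max_center_distance = -1), ">= 0")
})

test_that("merge agrees with a brute-force transitive-closure oracle and ignores input order", {
  for (seed in 1:5) {
    sets <- withr::with_seed(seed, {
      lapply(1:3, function(i) {
        n <- sample(3:12, 1)
        start <- sort(sample.int(5000, n))
        regions_tbl(sample(c("chr1", "chr2"), n, replace = TRUE),
                    start, start + sample(50:400, n, replace = TRUE))
      })
    })
    names(sets) <- c("A", "B", "C")
    got <- merge_region_sets(sets, max_center_distance = 300)
    want <- oracle_merge(sets, 300)
    expect_equal(got[, c("chrom", "start", "end")],
                 want[, c("chrom", "start", "end")])
    got_members <- lapply(seq_len(nrow(got)), function(i) {
      sort(c("A", "B", "C")[c(got$A[i], got$B[i], got$C[i])])
    })
    expect_equal(got_members, want$members)
    # order of input sets must not change the merged intervals
    rev_got <- merge_region_sets(rev(sets), max_center_distance = 300)
    expect_equal(rev_got[, c("chrom", "start", "end")],
                 got[, c("chrom", "start", "end")])
  }
})

test_that("membership combinations are counted per merged region", {
  sets <- list(A = regions_tbl("chr1", c(0, 5000), c(100, 5100)),
               B = regions_tbl("chr1", 30, 130))
  counts <- membership_counts(merge_region_sets(sets))
  expect_equal(counts$n[counts$combination == "A,B"], 1)
  expect_equal(counts$n[counts$combination == "A"], 1)
})

test_that("gap lengths enumerate consecutive same-chromosome gaps only", {
  rs <- regions_tbl("chr1", c(0, 300, 1000), c(100, 400, 1100))
  g <- gap_lengths(rs)
  expect_equal(g$gap_length, c(200, 600))
  expect_equal(median(g$gap_length), 400)
  # book-ended peaks produce a zero-length gap
  expect_equal(gap_lengths(regions_tbl("chr1", c(0, 100), c(100, 200)))$gap_length, 0)
  # single peak per chromosome contributes nothing
  expect_equal(nrow(gap_lengths(regions_tbl(c("chr1", "chr2"), c(0, 0), c(10, 10)))), 0)
  expect_error(gap_lengths(regions_tbl("chr1", c(0, 50), c(100, 150))), "overlap")
})

test_that("peak deserts subtract excluded bp from gaps before thresholding", {
  gm <- toy_genome(c(chr1 = 5e6))
  peaks <- regions_tbl("chr1", c(0, 3500000), c(1000, 3501000))
  expect_equal(count_peak_deserts(peaks, gm), 1)  # effective gap 3,499,000
  gm2 <- toy_genome(c(chr1 = 5e6), regions_tbl("chr1", 200000, 3400000))
  expect_equal(count_peak_deserts(peaks, gm2), 0)  # effective gap 299,000
  dense <- regions_tbl("chr1", seq(0, 4.5e6, by = 5e5), seq(0, 4.5e6, by = 5e5) + 1000)
  expect_equal(count_peak_deserts(dense, gm), 0)
})

test_that("nearest TSS uses signed centre distance with the strand flip", {
  tss <- toy_tss()
  # peak centred exactly on GENEA's TSS
  r0 <- nearest_tss(regions_tbl("chr1", 9000, 11000), tss)
  expect_equal(r0$tss_distance, 0)  # centre 10000 falls on the TSS
  r1 <- nearest_tss(regions_tbl("chr1", 11200, 11800), tss)
  expect_equal(r1$gene_id, "GENEA")
  expect_equal(r1$tss_distance, 1500)
  # same peak centre against the minus-strand gene flips the sign
  r2 <- nearest_tss(regions_tbl("chr1", 51200, 51800), tss)
  expect_equal(r2$gene_id, "GENEB")
  expect_equal(r2$tss_distance, -1500)
  expect_error(nearest_tss(regions_tbl("chr1", 0, 10), tss[0, ]), "empty")
})

test_that("nearest TSS matches an exhaustive all-pairs oracle, ties broken by gene id", {
  withr::with_seed(42, {
    tss <- tibble::tibble(
      gene_id = sprintf("G%03d", sample(200)),
      chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
      tss = sample.int(1e5, 200, replace = TRUE),
      strand = sample(c("+", "-"), 200, replace = TRUE)
    )
    start <- sample.int(1e5, 300)
    peaks <- regions_tbl(sample(c("chr1", "chr2"), 300, replace = TRUE),
                         start, start + sample(50:500, 300, replace = TRUE))
  })
  got <- nearest_tss(peaks, tss)
  want <- oracle_nearest_tss(peaks, tss)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$tss_distance, want$tss_distance)
})

test_that("base-pair overlap is symmetric, self-identical and matches enumeration", {
  a <- regions_tbl("chr1", c(0, 200), c(100, 300))
  b <- regions_tbl("chr1", 50, 150)
  expect_equal(basepair_overlap(a, b), 50)
  expect_equal(basepair_overlap(b, a), 50)
  expect_equal(basepair_overlap(a, a), 200)
  expect_equal(basepair_overlap(a, regions_tbl("chr2", 0, 100)), 0)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- regions_tbl(sample(c("chr1", "chr2"), 8, TRUE),
                       s <- sample.int(2000, 8), s + sample(10:200, 8, TRUE))
      y <- regions_tbl(sample(c("chr1", "chr2"), 8, TRUE),
                       s2 <- sample.int(2000, 8), s2 + sample(10:200, 8, TRUE))
    })
    expect_equal(basepair_overlap(x, y), oracle_overlap_bp(x, y))
    expect_equal(basepair_overlap(x, y), basepair_overlap(y, x))
  }
})

test_that("the internal overlap index agrees with the exported GRanges route", {
  withr::with_seed(7, {
    ref <- regions_tbl("chr1", s <- sort(sample.int(5000, 12)), s + sample(20:150, 12, TRUE))
    q <- regions_tbl("chr1", s2 <- sample.int(5000, 30), s2 + sample(10:100, 30, TRUE))
  })
  idx <- emtatac:::build_overlap_index(ref)
  per_region <- emtatac:::overlap_with_index(idx, q$chrom, q$start, q$end)
  total_vs_reduced <- sum(vapply(seq_len(nrow(q)), function(i) {
    basepair_overlap(q[i, ], ref)
  }, numeric(1)))
  expect_equal(sum(per_region), total_vs_reduced)
})
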