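test_that("find_cpg_sites scans forward-strand CG dinucleotides", {
  idx <- find_cpg_sites(c(chr1 = "ACGTCG"))
  expect_equal(idx$pos, c(1L, 4L))
  expect_equal(nrow(find_cpg_sites(c(chr1 = "AAAA"))), 0L)
  expect_equal(find_cpg_sites(c(chr1 = "CGCGCG"))$pos, c(0L, 2L, 4L))
  # case-insensitive; N and invalid characters never match
  expect_equal(find_cpg_sites(c(chr1 = "acgtCg"))$pos, c(1L, 4L))
  expect_equal(nrow(find_cpg_sites(c(chr1 = "CNGCNG"))), 0L)
  expect_equal(nrow(find_cpg_sites(c(chr1 = ""))), 0L)
  # multiple chromosomes
  idx2 <- find_cpg_sites(c(chrA = "CGA", chrB = "TTCG"))
  expect_equal(idx2$chrom, c("chrA", "chrB"))
  expect_equal(idx2$pos, c(0L, 2L))
})

test_that("find_cpg_sites removes blacklisted sites", {
  bl <- data.frame(chrom = "chr1", start = 4L, end = 6L)
  idx <- find_cpg_sites(c(chr1 = "ACGTCG"), blacklist = bl)
  expect_equal(idx$pos, 1L)
  # 1-bp overlap of the dinucleotide with the interval suffices
  bl2 <- data.frame(chrom = "chr1", start = 5L, end = 6L)
  expect_equal(find_cpg_sites(c(chr1 = "ACGTCG"), blacklist = bl2)$pos, 1L)
})

test_that("find_cpg_sites reads the bundled FASTA", {
  idx <- find_cpg_sites(toy_path("toy_ref.fa"))
  expect_equal(idx$pos, c(100L, 130L, 160L, 190L, 220L))
  expect_equal(unique(idx$chrom), "chr1")
})

test_that("segment_regions chains sites within the linking distance", {
  mk <- function(pos) cpg_index("chr1", pos)
  expect_equal(segment_regions(mk(c(100, 150, 900)), 100)$region_id,
               c(0L, 0L, 1L))
  expect_equal(segment_regions(mk(10), 100)$region_id, 0L)
  expect_equal(segment_regions(mk(c(0, 101, 202)), 100)$region_id,
               c(0L, 1L, 2L))
  # chromosome boundaries always break regions
  idx <- segment_regions(cpg_index(c("c1", "c1", "c2"), c(0, 10, 12)), 50)
  expect_equal(idx$region_id, c(0L, 0L, 1L))
})

test_that("cpg_index rejects unsorted or duplicated positions", {
  expect_error(cpg_index("chr1", c(5, 5)), "strictly increasing")
})

test_that("build_coverage_matrix reproduces the worked 6-read layout", {
  idx <- segment_regions(read_cpg_table(toy_path("toy_sites.tsv")), 70)
  reads <- read_bed(toy_path("toy_reads.bed"))
  cms <- build_coverage_matrix(reads, idx)
  expect_length(cms, 1L)
  cm <- cms[[1]]
  expect_equal(cm$n, 6L)
  expect_equal(cm$k, c(1L, 1L, 1L, 3L, 3L, 5L))
  expect_equal(cm$l, c(1L, 2L, 3L, 4L, 5L, 5L))
  expect_equal(attr(cms, "discarded"), 0L)
  ref <- fig1_cm()
  expect_equal(dense_coverage(cm), dense_coverage(ref))
})

test_that("reads covering no CpG site are discarded and tallied", {
  idx <- segment_regions(cpg_index("chr1", c(100L, 400L)), 50)
  reads <- data.frame(chrom = "chr1", start = c(200L, 95L),
                      end = c(250L, 103L))
  cms <- build_coverage_matrix(reads, idx)
  expect_length(cms, 1L)
  expect_equal(attr(cms, "discarded"), 1L)
  expect_equal(cms[[1]]$n, 1L)
  expect_equal(cms[[1]]$k, 1L)
  expect_equal(cms[[1]]$l, 1L)
})

test_that("a read straddling two regions is a hard error", {
  idx <- segment_regions(cpg_index("chr1", c(100L, 200L)), 50)
  reads <- data.frame(chrom = "chr1", start = 90L, end = 210L)
  expect_error(build_coverage_matrix(reads, idx), "link_dist")
})

test_that("min_overlap = 2 requires the full dinucleotide inside the read", {
  idx <- segment_regions(cpg_index("chr1", 100L), 50)
  graze <- data.frame(chrom = "chr1", start = 101L, end = 140L)  # G only
  expect_equal(build_coverage_matrix(graze, idx)[[1]]$n, 1L)
  cms2 <- build_coverage_matrix(graze, idx, min_overlap = 2L)
  expect_length(cms2, 0L)
  expect_equal(attr(cms2, "discarded"), 1L)
})

test_that("coverage construction conserves reads and ignores input order", {
  set.seed(71)
  idx <- segment_regions(cpg_index("chr1", sort(sample.int(5000, 40))), 60)
  reads <- data.frame(chrom = "chr1",
                      start = sample.int(5200, 300, replace = TRUE))
  reads$end <- reads$start + 50L
  cms <- build_coverage_matrix(reads, idx)
  retained <- sum(vapply(cms, function(cm) cm$n, integer(1)))
  expect_equal(retained + attr(cms, "discarded"), nrow(reads))

  perm <- sample.int(nrow(reads))
  cms2 <- build_coverage_matrix(reads[perm, ], idx)
  expect_equal(attr(cms2, "discarded"), attr(cms, "discarded"))
  span_key <- function(cms) sort(unlist(lapply(cms, function(cm)
    sprintf("%d:%d-%d", cm$region_id, cm$k, cm$l))))
  expect_equal(span_key(cms2), span_key(cms))
})

test_that("coverage TSV dump round-trips exactly", {
  set.seed(5)
  idx <- segment_regions(cpg_index("chr1", sort(sample.int(2000, 15))), 60)
  reads <- data.frame(chrom = "chr1",
                      start = sample.int(2100, 60, replace = TRUE))
  reads$end <- reads$start + 45L
  cms <- build_coverage_matrix(reads, idx)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_tsv(cms, path)
  back <- read_coverage_tsv(path)
  expect_equal(length(back), length(cms))
  for (i in seq_along(cms)) {
    expect_equal(back[[i]]$positions, cms[[i]]$positions)
    expect_equal(back[[i]]$k, cms[[i]]$k)
    expect_equal(back[[i]]$l, cms[[i]]$l)
    expect_equal(back[[i]]$region_id, cms[[i]]$region_id)
  }
})

test_that("read_sam converts mapped SAM records to 0-based intervals", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    "r1\t0\tchr1\t96\t60\t7M\t*\t0\t0\tACGTACG\tIIIIIII",
    "r2\t16\tchr1\t156\t60\t40M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)  # r3 unmapped, dropped
  reads <- read_sam(sam, sample = "A")
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$start, c(95L, 155L))  # SAM POS is 1-based
  expect_equal(reads$end, c(102L, 195L))
  expect_equal(reads$strand, c("+", "-"))
  expect_equal(unique(reads$sample), "A")
})

test_that("mre_site_counts anchors reads at cut-site CpGs", {
  idx <- cpg_index("chr1", c(100L, 300L))
  at_site <- data.frame(chrom = "chr1", start = 100L, end = 150L)
  expect_equal(as.integer(mre_site_counts(at_site, idx)), c(1L, 0L))
  # read anchoring no CpG is discarded
  off <- data.frame(chrom = "chr1", start = 210L, end = 260L)
  cnt <- mre_site_counts(off, idx)
  expect_equal(as.integer(cnt), c(0L, 0L))
  expect_equal(attr(cnt, "discarded"), 1L)
  # additivity
  two <- data.frame(chrom = "chr1", start = c(100L, 100L),
                    end = c(150L, 150L))
  expect_equal(as.integer(mre_site_counts(two, idx)), c(2L, 0L))
  # motif-derived shift: HpaII-style cut one base 5' of the CG
  shifted <- data.frame(chrom = "chr1", start = 99L, end = 149L)
  expect_equal(as.integer(mre_site_counts(shifted, idx)), c(1L, 0L))
  # minus-strand reads anchor at their 5' end = interval end
  minus <- data.frame(chrom = "chr1", start = 252L, end = 302L,
                      name = "r", score = 0L, strand = "-")
  expect_equal(as.integer(mre_site_counts(minus, idx)), c(0L, 1L))
})
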