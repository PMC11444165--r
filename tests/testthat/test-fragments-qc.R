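simple_fs <- function(df, sizes = c(chrom1 = 100000L)) {
  fragment_set(df, sizes)
}

test_that("call_peaks_simple finds coverage plateaus", {
  fs <- simple_fs(data.frame(chrom = "chrom1", start = c(100, 100, 100),
                             end = c(200, 200, 200),
                             barcode = c("a", "b", "c"), count = 1L))
  pk <- call_peaks_simple(fs, min_coverage = 2L, min_width = 50L)$all
  expect_equal(length(pk), 1L)
  expect_equal(GenomicRanges::start(pk) - 1L, 100)
  expect_equal(GenomicRanges::end(pk), 200)

  ## coverage never reaches threshold -> empty set
  fs2 <- simple_fs(data.frame(chrom = "chrom1", start = 100, end = 200,
                              barcode = "a", count = 1L))
  expect_equal(length(call_peaks_simple(fs2, min_coverage = 2L)$all), 0L)

  ## two plateaus separated by a zero-coverage gap -> two peaks
  fs3 <- simple_fs(data.frame(
    chrom = "chrom1", start = c(100, 100, 5000, 5000),
    end = c(300, 300, 5400, 5400),
    barcode = c("a", "b", "a", "b"), count = 1L))
  pk3 <- call_peaks_simple(fs3, min_coverage = 2L, min_width = 50L)$all
  expect_equal(length(pk3), 2L)
})

test_that("merge_peak_sets merges overlaps but not book-ended intervals", {
  a <- peak_set("chrom1", 100, 200)
  b <- peak_set("chrom1", 150, 300)
  m <- merge_peak_sets(list(a, b))
  expect_equal(length(m), 1L)
  expect_identical(names(m), "chrom1:100-300")

  ## half-open book-ends share zero bp
  b2 <- peak_set("chrom1", 200, 300)
  m2 <- merge_peak_sets(list(a, b2))
  expect_equal(length(m2), 2L)

  ## single input -> identity
  m3 <- merge_peak_sets(list(a))
  expect_identical(names(m3), names(a))
})

test_that("compute_cell_qc applies the strict QC gate", {
  ## cell with 2,000 fragments, 240 in peaks -> frip 0.12, pass
  peaks <- peak_set("chrom1", 0, 10000)
  n <- 2000
  df <- data.frame(chrom = "chrom1",
                   start = c(seq_len(240) * 40L,
                             20000L + seq_len(n - 240) * 40L),
                   barcode = "cellA", count = 1L)
  df$end <- df$start + 30L
  qc <- compute_cell_qc(simple_fs(df), peaks)
  expect_equal(qc$unique_reads, 2000L)
  expect_equal(qc$frip, 0.12)
  expect_true(qc$pass)

  ## exactly 1,500 fragments fails the strict > 1,500 rule even at frip 0.5
  df2 <- data.frame(chrom = "chrom1",
                    start = c(seq_len(750) * 10L, 20000L + seq_len(750) * 40L),
                    barcode = "cellB", count = 1L)
  df2$end <- df2$start + 8L
  qc2 <- compute_cell_qc(simple_fs(df2), peaks)
  expect_equal(qc2$unique_reads, 1500L)
  expect_equal(qc2$frip, 0.5)
  expect_false(qc2$pass)

  ## all fragments inside peaks -> frip 1
  df3 <- data.frame(chrom = "chrom1", start = seq_len(50) * 100L,
                    barcode = "cellC", count = 1L)
  df3$end <- df3$start + 50L
  qc3 <- compute_cell_qc(simple_fs(df3), peaks)
  expect_equal(qc3$frip, 1.0)
})

test_that("FRiP is invariant to fragment order and duplicates collapse", {
  b <- small_bundle()
  fr <- b$fragments$fragments
  perm <- fr[sample.int(nrow(fr))]
  qc1 <- compute_cell_qc(b$fragments, b$peaks_true)
  qc2 <- compute_cell_qc(fragment_set(perm, b$fragments$chrom_sizes),
                         b$peaks_true)
  expect_equal(qc1, qc2)
})

test_that("binary matrix matches overlap semantics and is idempotent", {
  peaks <- peak_set("chrom1", c(100, 1000), c(200, 1500))
  df <- data.frame(chrom = "chrom1",
                   start = c(120, 110, 130, 2000),
                   end = c(130, 125, 140, 2100),
                   barcode = c("a", "a", "a", "b"), count = 1L)
  df <- rbind(df, data.frame(chrom = "chrom1", start = 1990, end = 2050,
                             barcode = "a", count = 1L))
  fs <- simple_fs(df)
  qc <- compute_cell_qc(fs, peaks, min_reads = 0L, min_frip = -1)
  cm <- build_binary_matrix(fs, peaks, qc)
  ## two fragments in the same peak -> still 1
  expect_equal(as.numeric(cm$binary["chrom1:100-200", "a"]), 1)
  expect_equal(as.numeric(cm$counts["chrom1:100-200", "a"]), 3)
  expect_equal(as.numeric(cm$binary["chrom1:1000-1500", "a"]), 0)
  ## QC-passing cell absent from fragments -> error
  qc_bad <- rbind(qc, data.table::data.table(barcode = "ghost",
                                             unique_reads = 10L, frip = 1,
                                             pass = TRUE))
  expect_error(build_binary_matrix(fs, peaks, qc_bad), "absent")
})

test_that("binary matrix equals the brute-force overlap oracle", {
  set.seed(42)
  for (rep in 1:3) {
    n_pk <- 50L; n_cells <- 60L
    starts <- sort(sample.int(50000L, n_pk)) * 10L
    pk <- peak_set("chromZ", starts, starts + sample(50:200, n_pk, TRUE))
    bcs <- sprintf("c%03d", seq_len(n_cells))
    fr <- data.table::data.table(
      chrom = "chromZ",
      start = sample.int(600000L, 800L),
      barcode = sample(bcs, 800L, TRUE), count = 1L)
    fr[, end := start + sample(30:400, .N, TRUE)]
    fs <- fragment_set(fr, c(chromZ = 2e6))
    qc <- compute_cell_qc(fs, pk, min_reads = 0L, min_frip = -1)
    cm <- build_binary_matrix(fs, pk, qc)
    oracle <- overlap_oracle_matrix(unique(fr, by = c("chrom", "start", "end", "barcode")),
                                    enhancermap:::peaks_bed(pk), qc$barcode)
    expect_identical(unname(as.matrix(cm$binary)), unname(oracle * 1))
    ## column sums = distinct peaks hit per cell
    expect_equal(unname(Matrix::colSums(cm$binary)), unname(colSums(oracle)))
  }
})

test_that("QC truth on a synthetic bundle is recovered exactly", {
  b <- small_bundle()
  qc <- compute_cell_qc(b$fragments, b$peaks_true)
  expect_setequal(filter_cells(qc), b$truth$qc$barcode[b$truth$qc$pass])
})

test_that("cell matrix round-trips through MatrixMarket files", {
  cm <- small_matrix()
  dir <- withr::local_tempdir()
  write_cell_matrix(cm, dir)
  cm2 <- read_cell_matrix(dir)
  expect_equal(unname(as.matrix(cm$binary)), unname(as.matrix(cm2$binary)))
  expect_identical(colnames(cm$binary), colnames(cm2$binary))
  expect_identical(names(cm$peaks), names(cm2$peaks))
})
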