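test_that("identical config and seed give byte-identical bundles", {
  cfg <- small_config(seed = 3)
  b1 <- generate_dataset(cfg)
  b2 <- generate_dataset(cfg)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
})

test_that("generator respects basic bundle invariants", {
  b <- small_bundle()
  fr <- b$fragments$fragments
  expect_true(all(fr$barcode %in% b$cell_metadata$barcode))
  expect_true(all(fr$start >= 0))
  expect_true(all(fr$end <= b$fragments$chrom_sizes[fr$chrom]))
  expect_true(all(fr$start < fr$end))
  ## fragments sorted after load
  expect_false(is.unsorted(order(fr$chrom, fr$start)[seq_len(0)]))
  ## truth identifiers exist in the bundle
  expect_true(all(unlist(b$truth$marker_peaks) %in% names(b$peaks_true)))
  expect_true(all(unlist(lapply(b$truth$modules, `[[`, "peaks")) %in%
                    names(b$peaks_true)))
  expect_true(all(names(b$truth$cell_clusters) %in% b$cell_metadata$barcode))
  ## config infeasibility is caught
  expect_error(synth_config(n_peaks = 10L, marker_peaks_per_cluster = 40L),
               "infeasible")
})

test_that("per-cell depth matches the configured mean within 5%", {
  cfg <- synth_config(n_chromosomes = 4L, chrom_length_bp = 8e6,
                      n_peaks = 800L, n_genes = 50L,
                      cells_per_cluster = 100L, depth_mean = 3000,
                      frac_low_quality_cells = 0,
                      marker_peaks_per_cluster = 20L,
                      stage_diff_peaks_per_cluster = 4L,
                      n_coaccess_modules = 2L, module_span_bp = 3e5,
                      seed = 9)
  b <- generate_dataset(cfg)
  depth <- b$fragments$fragments[, .N, by = barcode]$N
  expect_gte(length(depth), 500L)
  expect_lt(abs(mean(depth) / 3000 - 1), 0.05)
})

test_that("marker_effect = 1 yields equal marker detection in and out of cluster", {
  cfg <- small_config(seed = 13, marker_effect = 1,
                      stage_diff_peaks_per_cluster = 0L,
                      frac_low_quality_cells = 0)
  b <- generate_dataset(cfg)
  qc <- compute_cell_qc(b$fragments, b$peaks_true)
  cm <- build_binary_matrix(b$fragments, b$peaks_true, qc, b$cell_metadata)
  lab <- truth_labels(b, cm)
  X <- cm$binary
  for (cl in names(b$truth$marker_peaks)) {
    idx <- which(lab == cl)
    mk <- b$truth$marker_peaks[[cl]]
    ## per-cell marker detection fractions: cells are the independent unit
    ## (peak detections within a cell share its depth)
    cell_f <- Matrix::colMeans(X[mk, , drop = FALSE])
    f_in <- mean(cell_f[idx]); f_out <- mean(cell_f[-idx])
    se <- sqrt(var(cell_f[idx]) / length(idx) +
                 var(cell_f[-idx]) / (ncol(X) - length(idx)))
    expect_lt(abs(f_in - f_out), 3 * se + 1e-12)
  }
})

test_that("planted SNP enrichment matches the configured fold over seeds", {
  ratios <- vapply(1:20, function(s) {
    cfg <- synth_config(n_chromosomes = 4L, chrom_length_bp = 8e6,
                        n_peaks = 800L, n_genes = 20L,
                        cells_per_cluster = 2L, depth_mean = 100,
                        marker_peaks_per_cluster = 30L,
                        stage_diff_peaks_per_cluster = 0L,
                        n_coaccess_modules = 2L, module_span_bp = 3e5,
                        snps_per_trait = 400L, snp_enrichment_fold = 5,
                        seed = 400 + s)
    b <- generate_dataset(cfg)
    tr <- b$truth$planted_traits[[1]]
    mk <- b$peaks_true[b$truth$marker_peaks[[tr$cluster]]]
    snps <- b$snps[b$snps$trait == tr$trait]
    gr <- GenomicRanges::GRanges(snps$chrom,
                                 IRanges::IRanges(snps$pos + 1L, snps$pos + 1L))
    x <- sum(GenomicRanges::countOverlaps(gr, mk) > 0)
    l_mk <- sum(IRanges::width(mk))
    l_all <- sum(IRanges::width(b$peaks_true))
    (x / l_mk) / (nrow(snps) / l_all)
  }, numeric(1))
  expect_gte(mean(ratios), 3)
  expect_lte(mean(ratios), 7)
})

test_that("write_bundle round-trips losslessly and handles empty bundles", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  rb <- read_bundle(dir)
  expect_equal(rb$fragments$fragments[, .(chrom, start, end, barcode, count)],
               enhancermap:::copy_sorted_fragments(b$fragments))
  expect_identical(names(rb$peaks_true), names(b$peaks_true))
  expect_equal(as.data.frame(rb$genes), as.data.frame(b$genes))
  expect_equal(rb$snps[order(snp_id)], b$snps[order(snp_id)])
  expect_identical(sort(rb$tftg_db$tf), sort(b$tftg_db$tf))
  expect_identical(unname(as.matrix(rb$motif_annotation)),
                   unname(as.matrix(b$motif_annotation[
                     sort(rownames(b$motif_annotation)), ])))
  ## format definition: one fragment -> one BED-like line
  line1 <- readLines(file.path(dir, "fragments.tsv"), n = 2L)[2L]
  f1 <- b$fragments$fragments[order(chrom, start, end, barcode)][1]
  expect_identical(line1, paste(f1$chrom, f1$start, f1$end, f1$barcode,
                                f1$count, sep = "\t"))
  ## empty bundle: valid files with headers
  b0 <- b
  b0$fragments <- fragment_set(
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               barcode = character(0), count = integer(0)),
    b$fragments$chrom_sizes)
  b0$cell_metadata <- b$cell_metadata[0]
  dir0 <- withr::local_tempdir()
  write_bundle(b0, dir0)
  expect_identical(readLines(file.path(dir0, "fragments.tsv")),
                   "chrom\tstart\tend\tbarcode\tcount")
  rb0 <- read_bundle(dir0)
  expect_equal(nrow(rb0$fragments$fragments), 0L)
})

test_that("simulate_labeled_embedding plants the requested stage shift", {
  sim <- simulate_labeled_embedding(n_clusters = 4, cells_per_cluster = 500,
                                    shift = list(C4 = c(0.2, 0.8)), seed = 2)
  p1 <- tapply(sim$stage == "P1", sim$cluster, mean)
  expect_lt(abs(p1[["C4"]] - 0.2), 0.06)
  expect_lt(max(abs(p1[c("C1", "C2", "C3")] - 0.5)), 0.08)
  sim2 <- simulate_labeled_embedding(n_clusters = 4, cells_per_cluster = 500,
                                     shift = list(C4 = c(0.2, 0.8)), seed = 2)
  expect_identical(sim, sim2)
})
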