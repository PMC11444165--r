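#' Minimal coverage-threshold peak calling on pooled fragments
#'
#' For each sample group, pools the group's fragments and reports the maximal
#' intervals where fragment coverage is at least `min_coverage` and interval
#' width is at least `min_width`. This is a deliberately simple caller used
#' to make the multi-sample merge path executable on synthetic aggregates;
#' it does not replace a published peak caller on real data.
#'
#' @param fragments A [fragment_set()].
#' @param sample_groups Named vector mapping barcode to group, or NULL for a
#'   single pooled group.
#' @param min_coverage Minimum pooled fragment coverage.
#' @param min_width Minimum peak width (bp).
#' @return Named list of peak `GRanges`, one per group.
#' @export
call_peaks_simple <- function(fragments, sample_groups = NULL,
                              min_coverage = 2L, min_width = 100L) {
  fr <- fragments$fragments
  if (is.null(sample_groups)) {
    groups <- setNames(rep("all", length(unique(fr$barcode))),
                       unique(fr$barcode))
  } else groups <- sample_groups
  miss <- setdiff(unique(fr$barcode), names(groups))
  if (length(miss)) stop2("sample_groups does not cover all barcodes")
  out <- list()
  for (g in unique(groups)) {
    sub <- fr[fr$barcode %in% names(groups)[groups == g]]
    if (!nrow(sub)) {
      warning("empty group '", g, "': empty peak set")
      out[[g]] <- peak_set(character(0), integer(0), integer(0))
      next
    }
    per_chrom <- lapply(split(sub, sub$chrom), function(s) {
      cov <- IRanges::coverage(IRanges::IRanges(s$start + 1L, s$end))
      sl <- IRanges::slice(cov, lower = min_coverage, rangesOnly = TRUE)
      sl[IRanges::width(sl) >= min_width]
    })
    chs <- rep(names(per_chrom), vapply(per_chrom, length, integer(1)))
    ir <- unlist(IRanges::IRangesList(per_chrom), use.names = FALSE)
    out[[g]] <- peak_set(chs, IRanges::start(ir) - 1L, IRanges::end(ir))
  }
  out
}

#' Per-cell quality control metrics
#'
#' Computes per barcode the number of unique (deduplicated) fragments and
#' FRiP, the fraction of those fragments overlapping (>= 1 bp) any peak in
#' the merged universe, and flags cells passing the stringent gate
#' `unique_reads > min_reads` and `frip > min_frip` (both strict).
#'
#' @param fragments A [fragment_set()].
#' @param peaks Merged peak `GRanges`.
#' @param min_reads Unique-fragment threshold (strict >). Default 1500.
#' @param min_frip FRiP threshold (strict >). Default 0.10.
#' @return data.table with columns barcode, unique_reads, frip, pass.
#' @export
compute_cell_qc <- function(fragments, peaks, min_reads = 1500L,
                            min_frip = 0.10) {
  fr <- unique(fragments$fragments, by = c("chrom", "start", "end", "barcode"))
  if (!nrow(fr))
    return(data.table(barcode = character(0), unique_reads = integer(0),
                      frip = numeric(0), pass = logical(0)))
  gr <- GenomicRanges::GRanges(fr$chrom,
                               IRanges::IRanges(fr$start + 1L, fr$end))
  in_peak <- rep(FALSE, nrow(fr))
  hits <- GenomicRanges::findOverlaps(gr, peaks, minoverlap = 1L)
  in_peak[unique(S4Vectors::queryHits(hits))] <- TRUE
  fr2 <- data.table(barcode = fr$barcode, in_peak = in_peak)
  qc <- fr2[, .(unique_reads = .N, frip = mean(in_peak)), by = barcode]
  qc[, pass := unique_reads > min_reads & frip > min_frip]
  setorder(qc, barcode)
  qc[]
}

#' Barcodes passing the QC gate
#'
#' @param qc Output of [compute_cell_qc()].
#' @return Character vector of passing barcodes.
#' @export
filter_cells <- function(qc) qc$barcode[qc$pass]

#' Binary peak-by-cell detection matrix
#'
#' Entry (p, c) is 1 iff QC-passing cell c has at least one fragment
#' overlapping (>= 1 bp) peak p. A parallel fragment-count layer records how
#' many fragments of the cell fall in the peak.
#'
#' @param fragments A [fragment_set()].
#' @param peaks Merged peak `GRanges` (the universe the QC used).
#' @param qc Output of [compute_cell_qc()] on the same universe.
#' @param metadata Optional cell metadata table keyed by `barcode`.
#' @return A list of class `cell_matrix` with sparse `binary` and `counts`
#'   (peaks x cells), `peaks`, and `metadata` for retained cells.
#' @export
build_binary_matrix <- function(fragments, peaks, qc, metadata = NULL) {
  keep <- filter_cells(qc)
  fr <- unique(fragments$fragments, by = c("chrom", "start", "end", "barcode"))
  missing <- setdiff(keep, unique(fr$barcode))
  if (length(missing))
    stop2("QC-passing cells absent from fragments: ",
          paste(head(missing, 3L), collapse = ", "))
  fr <- fr[fr$barcode %in% keep]
  gr <- GenomicRanges::GRanges(fr$chrom,
                               IRanges::IRanges(fr$start + 1L, fr$end))
  hits <- GenomicRanges::findOverlaps(gr, peaks, minoverlap = 1L)
  pi <- S4Vectors::subjectHits(hits)
  ci <- match(fr$barcode[S4Vectors::queryHits(hits)], keep)
  counts <- sparseMatrix(i = pi, j = ci, x = 1,
                         dims = c(length(peaks), length(keep)),
                         dimnames = list(names(peaks), keep))
  binary <- counts
  binary@x <- rep(1, length(binary@x))
  md <- if (!is.null(metadata)) {
    md <- as.data.table(metadata)
    md[match(keep, md$barcode)]
  } else data.table(barcode = keep)
  structure(list(binary = binary, counts = counts, peaks = peaks,
                 metadata = md),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix:", nrow(x$binary), "peaks x", ncol(x$binary), "cells;",
      sprintf("%.1f%% nonzero\n",
              100 * length(x$binary@x) / prod(dim(x$binary))))
  invisible(x)
}

#' Write a cell matrix to MatrixMarket + TSV sidecars
#'
#' @param cm A `cell_matrix`.
#' @param directory Output directory.
#' @return Invisibly, the directory.
#' @export
write_cell_matrix <- function(cm, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  Matrix::writeMM(cm$binary, file.path(directory, "binary.mtx"))
  Matrix::writeMM(cm$counts, file.path(directory, "counts.mtx"))
  fwrite(peaks_bed(cm$peaks), file.path(directory, "peaks.tsv"), sep = "\t")
  fwrite(cm$metadata, file.path(directory, "barcodes.tsv"), sep = "\t")
  invisible(directory)
}

#' Read a cell matrix written by [write_cell_matrix()]
#'
#' @param directory Directory with binary.mtx, counts.mtx, peaks.tsv,
#'   barcodes.tsv.
#' @return A `cell_matrix`.
#' @export
read_cell_matrix <- function(directory) {
  binary <- as(Matrix::readMM(file.path(directory, "binary.mtx")),
               "CsparseMatrix") * 1
  counts <- as(Matrix::readMM(file.path(directory, "counts.mtx")),
               "CsparseMatrix") * 1
  pk <- fread(file.path(directory, "peaks.tsv"))
  peaks <- peak_set(pk$chrom, pk$start, pk$end, sort_peaks = FALSE)
  md <- fread(file.path(directory, "barcodes.tsv"),
              colClasses = list(character = "barcode"))
  dimnames(binary) <- dimnames(counts) <- list(names(peaks), md$barcode)
  structure(list(binary = binary, counts = counts, peaks = peaks,
                 metadata = md), class = "cell_matrix")
}
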