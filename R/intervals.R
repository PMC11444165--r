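#' Fragment sets and peak sets
#'
#' A `fragment_set` holds per-cell deduplicated genomic fragments in 0-based
#' half-open (BED) coordinates together with chromosome sizes. A peak set is
#' represented as a [GenomicRanges::GRanges] whose names are stable peak ids
#' of the form `chrom:start-end` (0-based half-open in the id string).
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`,
#'   `barcode`, `count` (0-based half-open coordinates).
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, chrom_sizes) {
  fr <- as.data.table(fragments)
  need <- c("chrom", "start", "end", "barcode")
  if (!all(need %in% names(fr)))
    stop2("fragments need columns: ", paste(need, collapse = ", "))
  if (!"count" %in% names(fr)) fr[, count := 1L]
  fr[, chrom := as.character(chrom)]
  if (nrow(fr)) {
    if (any(fr$start < 0L) || any(fr$end <= fr$start))
      stop2("invalid fragment coordinates: need 0 <= start < end")
    if (is.null(names(chrom_sizes)) || !all(fr$chrom %in% names(chrom_sizes)))
      stop2("all fragment chromosomes must appear in chrom_sizes")
    too_big <- fr$end > chrom_sizes[fr$chrom]
    if (any(too_big)) stop2("fragment end beyond chromosome size")
  }
  setorder(fr, chrom, start, end, barcode)
  structure(list(fragments = fr[],
                 chrom_sizes = chrom_sizes),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", nrow(x$fragments), "fragments,",
      length(unique(x$fragments$barcode)), "barcodes,",
      length(x$chrom_sizes), "chromosomes\n")
  invisible(x)
}

## GRanges view of a fragment set (1-based closed, as GRanges convention)
fragments_granges <- function(fs) {
  fr <- fs$fragments
  GenomicRanges::GRanges(
    seqnames = fr$chrom,
    ranges = IRanges::IRanges(start = fr$start + 1L, end = fr$end))
}

#' Build a peak set from 0-based half-open intervals
#'
#' @param chrom,start,end Vectors describing peak intervals (BED convention).
#' @param sort_peaks Sort by (chrom, start)? Default TRUE.
#' @return A `GRanges` with names and metadata column `peak_id`.
#' @export
peak_set <- function(chrom, start, end, sort_peaks = TRUE) {
  stopifnot(length(start) == length(end))
  chrom <- rep_len(as.character(chrom), length(start))
  if (length(start) && any(end <= start)) stop2("peaks need start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  if (sort_peaks && length(gr)) gr <- GenomicRanges::sort(gr)
  ids <- if (length(gr))
    peak_id_string(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr))
  else character(0)
  names(gr) <- ids
  S4Vectors::mcols(gr)$peak_id <- ids
  gr
}

## data.frame (BED, 0-based half-open) view of a peak GRanges
peaks_bed <- function(peaks) {
  data.table(chrom = as.character(GenomicRanges::seqnames(peaks)),
             start = GenomicRanges::start(peaks) - 1L,
             end = GenomicRanges::end(peaks),
             peak_id = names(peaks))
}

#' Merge peak sets into a single non-overlapping universe
#'
#' Overlapping (>= 1 bp) intervals are merged; book-ended intervals (zero
#' overlap under half-open coordinates) are kept separate. Peak ids are
#' regenerated as `chrom:start-end`.
#'
#' @param sets A list of peak `GRanges` (or a single `GRanges`).
#' @return A merged peak `GRanges`.
#' @export
merge_peak_sets <- function(sets) {
  if (is(sets, "GRanges")) sets <- list(sets)
  if (!length(sets)) stop2("need at least one peak set")
  all_gr <- suppressWarnings(do.call(c, unname(lapply(sets, function(g) {
    unname(GenomicRanges::granges(g))
  }))))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(all_gr),
                                  min.gapwidth = 0L)
  peak_set(as.character(GenomicRanges::seqnames(merged)),
           GenomicRanges::start(merged) - 1L,
           GenomicRanges::end(merged),
           sort_peaks = TRUE)
}

#' Gene models
#'
#' @param gene_id Character gene identifiers.
#' @param chrom,start,end 0-based half-open gene body coordinates.
#' @param strand `"+"` or `"-"` (required).
#' @return data.table of class `gene_model` with one row per gene.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand) {
  if (any(!strand %in% c("+", "-"))) stop2("strand must be '+' or '-'")
  if (any(end <= start)) stop2("genes need start < end")
  g <- data.table(gene_id = as.character(gene_id),
                  chrom = as.character(chrom),
                  start = as.integer(start), end = as.integer(end),
                  strand = as.character(strand))
  setattr(g, "class", c("gene_model", class(g)))
  g[]
}
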