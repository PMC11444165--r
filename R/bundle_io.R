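#' Write a synthetic bundle to plain-text files
#'
#' Emits the external formats the pipeline readers consume: a BED-like
#' fragments TSV sorted by (chrom, start), peaks BED, genes BED6, SNPs as
#' BED4 plus SNP id, motif annotation and TF-target TSVs, cell metadata TSV,
#' chromosome sizes TSV, and the ground truth as JSON. All coordinates are
#' 0-based half-open.
#'
#' @param bundle A `synthetic_bundle`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(is(bundle, "synthetic_bundle"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory))
      stop2("cannot create directory: ", directory)
  }
  path <- function(f) file.path(directory, f)
  fr <- copy_sorted_fragments(bundle$fragments)
  fwrite(fr, path("fragments.tsv"), sep = "\t")
  fwrite(data.table(chrom = names(bundle$fragments$chrom_sizes),
                    size = as.integer(bundle$fragments$chrom_sizes)),
         path("chrom_sizes.tsv"), sep = "\t")
  fwrite(peaks_bed(bundle$peaks_true), path("peaks.bed"), sep = "\t")
  g <- bundle$genes
  fwrite(data.table(chrom = g$chrom, start = g$start, end = g$end,
                    name = g$gene_id, score = 0L, strand = g$strand),
         path("genes.bed"), sep = "\t")
  s <- bundle$snps
  fwrite(data.table(chrom = s$chrom, start = s$pos, end = s$pos + 1L,
                    trait = s$trait, snp_id = s$snp_id),
         path("snps.bed"), sep = "\t")
  ma <- as(bundle$motif_annotation, "TsparseMatrix")
  mtab <- data.table(motif = rownames(ma)[ma@i + 1L],
                     peak_id = colnames(ma)[ma@j + 1L])
  setorder(mtab, motif, peak_id)
  fwrite(mtab, path("motif_annotation.tsv"), sep = "\t")
  fwrite(bundle$tftg_db, path("tftg.tsv"), sep = "\t")
  fwrite(bundle$cell_metadata, path("cell_metadata.tsv"), sep = "\t")
  sets <- rbindlist(lapply(names(bundle$gene_sets), function(s)
    data.table(set = s, gene = bundle$gene_sets[[s]])),
    use.names = TRUE, fill = TRUE)
  if (!nrow(sets)) sets <- data.table(set = character(0), gene = character(0))
  fwrite(sets, path("gene_sets.tsv"), sep = "\t")
  truth <- bundle$truth
  truth$qc <- as.data.frame(truth$qc)
  truth$stage_diff_peaks <- lapply(truth$stage_diff_peaks, as.data.frame)
  jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c("fragments.tsv", "chrom_sizes.tsv", "peaks.bed", "genes.bed",
             "snps.bed", "motif_annotation.tsv", "tftg.tsv",
             "cell_metadata.tsv", "gene_sets.tsv", "truth.json")
  invisible(setNames(vapply(files, path, character(1)), files))
}

copy_sorted_fragments <- function(fs) {
  fr <- data.table::copy(fs$fragments)
  setorder(fr, chrom, start, end, barcode)
  fr[, .(chrom, start, end, barcode, count)]
}

#' Read a fragments TSV into a fragment set
#'
#' @param path Fragments TSV (columns chrom, start, end, barcode, count;
#'   0-based half-open).
#' @param chrom_sizes Named integer vector, or path to a two-column
#'   chrom/size TSV.
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    cs <- fread(chrom_sizes)
    chrom_sizes <- setNames(as.integer(cs[[2L]]), as.character(cs[[1L]]))
  }
  fr <- fread(path, colClasses = list(character = "chrom"))
  fragment_set(fr, chrom_sizes)
}

#' Read a peaks BED file
#'
#' @param path BED3(+name) file, 0-based half-open.
#' @return Peak `GRanges`.
#' @export
read_peaks <- function(path) {
  b <- fread(path)
  peak_set(b[[1L]], b[[2L]], b[[3L]])
}

#' Read gene models from a BED6 file
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return A [gene_model()].
#' @export
read_genes <- function(path) {
  b <- fread(path)
  if (ncol(b) < 6L) stop2("genes BED must have 6 columns (strand required)")
  gene_model(b[[4L]], b[[1L]], b[[2L]], b[[3L]], b[[6L]])
}

#' Read a SNP catalog from a BED4+id file
#'
#' @param path TSV with columns chrom, start, end, trait, snp_id
#'   (0-based positions; end = start + 1).
#' @return data.table with columns snp_id, trait, chrom, pos.
#' @export
read_snps <- function(path) {
  b <- fread(path, colClasses = list(character = 1L))
  data.table(snp_id = as.character(b[[5L]]), trait = as.character(b[[4L]]),
             chrom = as.character(b[[1L]]), pos = as.integer(b[[2L]]))
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param directory Directory produced by [write_bundle()].
#' @return A list with the same data slots as a `synthetic_bundle`
#'   (truth parsed from JSON; motif annotation as a sparse matrix).
#' @export
read_bundle <- function(directory) {
  path <- function(f) file.path(directory, f)
  fs <- read_fragments(path("fragments.tsv"), path("chrom_sizes.tsv"))
  peaks <- read_peaks(path("peaks.bed"))
  genes <- read_genes(path("genes.bed"))
  snps <- read_snps(path("snps.bed"))
  ma <- fread(path("motif_annotation.tsv"))
  motifs <- sort(unique(ma$motif))
  if (nrow(ma)) {
    pk <- names(peaks)
    motif_annotation <- sparseMatrix(
      i = match(ma$motif, motifs), j = match(ma$peak_id, pk), x = 1,
      dims = c(length(motifs), length(pk)),
      dimnames = list(motifs, pk))
  } else motif_annotation <- NULL
  sets_tab <- fread(path("gene_sets.tsv"))
  gene_sets <- if (nrow(sets_tab))
    split(sets_tab$gene, sets_tab$set) else list()
  list(fragments = fs, peaks_true = peaks, genes = genes, snps = snps,
       motif_annotation = motif_annotation,
       tftg_db = fread(path("tftg.tsv")),
       cell_metadata = fread(path("cell_metadata.tsv"),
                             colClasses = list(character = "barcode")),
       gene_sets = gene_sets,
       truth = jsonlite::read_json(path("truth.json"), simplifyVector = TRUE))
}
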