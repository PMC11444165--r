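#' Restrict a SNP catalog to the assayable peak universe
#'
#' Keeps SNPs whose (0-based) position falls inside any universe peak under
#' half-open interval semantics: a SNP at position `end` of a peak
#' `[start, end)` is outside it.
#'
#' @param snps data.table with columns snp_id, trait, chrom, pos.
#' @param universe Merged peak `GRanges`.
#' @return The retained rows of `snps`.
#' @export
snps_in_universe <- function(snps, universe) {
  if (!nrow(snps)) return(snps)
  gr <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(snps$pos + 1L, snps$pos + 1L))
  hits <- GenomicRanges::findOverlaps(gr, universe)
  snps[sort(unique(S4Vectors::queryHits(hits)))]
}

#' Binomial enrichment of trait SNPs in cluster-specific enhancers
#'
#' For each (cluster, trait) pair, the expected hit fraction `p0` is the
#' total merged length of the cluster's marker peaks divided by the total
#' universe length; the observed count `x` is the number of the trait's
#' (universe-filtered) SNPs inside the cluster's marker peaks. The p-value
#' is the exact upper binomial tail `P(X >= x)`, `X ~ Binomial(n_trait,
#' p0)`, with Benjamini-Hochberg correction across the full cluster x trait
#' grid.
#'
#' @param snps Universe-filtered SNP catalog (see [snps_in_universe()]).
#' @param markers A `marker_peak_table`, or a named list mapping cluster to
#'   peak-id vectors.
#' @param universe Merged peak `GRanges` (carrying the marker peak ids).
#' @return data.table with columns cluster, trait, n_trait, x, p0, fold, p,
#'   p_adj.
#' @export
binomial_enrichment <- function(snps, markers, universe) {
  marker_sets <- if (is(markers, "marker_peak_table") ||
                     is.data.frame(markers)) {
    split(markers$peak_id, markers$cluster)
  } else markers
  if (!length(marker_sets)) stop2("no marker peaks provided")
  total_len <- sum(IRanges::width(GenomicRanges::reduce(universe)))
  rows <- list()
  for (cl in names(marker_sets)) {
    ids <- marker_sets[[cl]]
    if (!length(ids)) stop2("cluster ", cl, " has no retained marker peaks")
    mk <- universe[intersect(ids, names(universe))]
    p0 <- sum(IRanges::width(GenomicRanges::reduce(mk))) / total_len
    for (tr in unique(snps$trait)) {
      sub <- snps[snps$trait == tr]
      n_trait <- nrow(sub)
      if (n_trait == 0L) next
      gr <- GenomicRanges::GRanges(sub$chrom,
                                   IRanges::IRanges(sub$pos + 1L, sub$pos + 1L))
      x <- length(unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr, mk))))
      p <- pbinom(x - 1L, n_trait, p0, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.table(
        cluster = cl, trait = tr, n_trait = n_trait, x = x, p0 = p0,
        fold = (x / n_trait) / p0, p = p)
    }
  }
  res <- rbindlist(rows)
  res[, p_adj := p.adjust(p, method = "BH")]
  res[]
}
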