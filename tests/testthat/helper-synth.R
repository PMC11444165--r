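## shared fixtures: built once per test run and cached in this environment
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## a small, fast bundle for module-level tests
small_config <- function(seed = 7, ...) {
  ## depth-to-peak ratio kept close to the default conditions so detection
  ## probabilities stay in the same regime
  defaults <- list(n_chromosomes = 4L, chrom_length_bp = 8e6,
                   n_peaks = 2000L, n_genes = 80L, cells_per_cluster = 80L,
                   depth_mean = 2500, marker_peaks_per_cluster = 60L,
                   stage_diff_peaks_per_cluster = 6L,
                   n_coaccess_modules = 4L, module_span_bp = 1e5,
                   seed = seed)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(synth_config, defaults)
}

small_bundle <- function() {
  cached("small_bundle", generate_dataset(small_config()))
}

small_matrix <- function() {
  cached("small_matrix", {
    b <- small_bundle()
    qc <- compute_cell_qc(b$fragments, b$peaks_true)
    build_binary_matrix(b$fragments, b$peaks_true, qc, b$cell_metadata)
  })
}

## the full default-condition bundle used by the acceptance checks
default_bundle <- function() {
  cached("default_bundle", generate_dataset(synth_config(seed = 101L)))
}

default_matrix <- function() {
  cached("default_matrix", {
    b <- default_bundle()
    qc <- compute_cell_qc(b$fragments, b$peaks_true)
    build_binary_matrix(b$fragments, b$peaks_true, qc, b$cell_metadata)
  })
}

truth_labels <- function(b, cm) {
  setNames(as.character(b$truth$cell_clusters[colnames(cm$binary)]),
           colnames(cm$binary))
}

## brute-force O(F*P) interval overlap oracle on BED coordinates
overlap_oracle_matrix <- function(frag_dt, peaks_bed_dt, barcodes) {
  M <- matrix(0L, nrow(peaks_bed_dt), length(barcodes),
              dimnames = list(peaks_bed_dt$peak_id, barcodes))
  for (fi in seq_len(nrow(frag_dt))) {
    f <- frag_dt[fi]
    for (pi in seq_len(nrow(peaks_bed_dt))) {
      p <- peaks_bed_dt[pi]
      if (f$chrom == p$chrom && f$start < p$end && f$end > p$start)
        M[pi, f$barcode] <- 1L
    }
  }
  M
}

## embedding object from a plain coordinate matrix
as_embedding <- function(coords) {
  structure(list(coords = coords, d = ncol(coords), var_share = NULL,
                 dropped_first = FALSE), class = "embedding")
}
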