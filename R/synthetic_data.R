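#' Configuration for the synthetic single-cell enhancer dataset
#'
#' Defines the study conditions the generator emulates: a compact genome with
#' a non-overlapping enhancer peak universe, clusters of cells with marker
#' peaks, overdispersed per-cell fragment depth around the deep-coverage
#' average of ~7,290 unique fragments, per-cell FRiP variation with a planted
#' low-quality subset, per-cluster motif programs, trait-associated SNP
#' enrichments, distance-bounded co-accessible peak modules driven by a
#' per-cell latent state, stage-shifted cluster abundances, and stage-
#' differential marker peaks.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome (bp).
#' @param n_genes Number of gene models.
#' @param n_peaks Number of true enhancer peaks.
#' @param n_clusters Number of planted cell clusters.
#' @param cells_per_cluster Cells per cluster.
#' @param n_samples Number of aggregation groups ("bulk samples").
#' @param depth_mean,depth_dispersion Mean and negative-binomial size of the
#'   per-cell unique fragment count.
#' @param frip_range Length-2 numeric: per-cell target fraction of fragments
#'   in peaks for good cells (uniform draw).
#' @param frac_low_quality_cells Fraction of cells planted to fail QC.
#' @param marker_peaks_per_cluster Marker peaks per cluster.
#' @param marker_effect In-cluster vs out-of-cluster fragment-rate ratio for
#'   marker peaks (1 = null).
#' @param n_motifs Number of motifs in the motif-by-peak annotation.
#' @param planted_motif_per_cluster Integer vector mapping cluster index to
#'   the motif planted on its marker peaks (default: motif i for cluster i).
#' @param n_traits Number of GWAS traits.
#' @param snps_per_trait SNPs per trait.
#' @param snp_enrichment_fold Density fold by which planted trait SNPs favour
#'   their target cluster's marker peaks.
#' @param n_coaccess_modules Number of co-accessible peak modules (first half
#'   active in all clusters, second half private to one cluster).
#' @param module_span_bp Maximum genomic span of one module (bp).
#' @param condition_shift Named list mapping cluster label to c(P1, P10)
#'   stage fractions (must sum to 1). Default: last two clusters shifted
#'   80/20 towards P1 and P10 respectively, others balanced.
#' @param stage_diff_peaks_per_cluster Number of marker peaks per cluster
#'   whose in-cluster boost applies in one stage only.
#' @param seed Integer seed; the bundle is a deterministic function of the
#'   full configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_chromosomes = 8L,
                         chrom_length_bp = 50e6,
                         n_genes = 300L,
                         n_peaks = 6000L,
                         n_clusters = 6L,
                         cells_per_cluster = 200L,
                         n_samples = 24L,
                         depth_mean = 7290,
                         depth_dispersion = 8,
                         frip_range = c(0.2, 0.5),
                         frac_low_quality_cells = 0.1,
                         marker_peaks_per_cluster = 120L,
                         marker_effect = 5,
                         n_motifs = 50L,
                         planted_motif_per_cluster = NULL,
                         n_traits = 6L,
                         snps_per_trait = 200L,
                         snp_enrichment_fold = 5,
                         n_coaccess_modules = 6L,
                         module_span_bp = 250000L,
                         condition_shift = NULL,
                         stage_diff_peaks_per_cluster = 15L,
                         seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks),
              n_clusters = as.integer(n_clusters),
              cells_per_cluster = as.integer(cells_per_cluster),
              n_samples = as.integer(n_samples),
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              frip_range = frip_range,
              frac_low_quality_cells = frac_low_quality_cells,
              marker_peaks_per_cluster = as.integer(marker_peaks_per_cluster),
              marker_effect = marker_effect,
              n_motifs = as.integer(n_motifs),
              planted_motif_per_cluster = planted_motif_per_cluster,
              n_traits = as.integer(n_traits),
              snps_per_trait = as.integer(snps_per_trait),
              snp_enrichment_fold = snp_enrichment_fold,
              n_coaccess_modules = as.integer(n_coaccess_modules),
              module_span_bp = as.numeric(module_span_bp),
              condition_shift = condition_shift,
              stage_diff_peaks_per_cluster = as.integer(stage_diff_peaks_per_cluster),
              seed = as.integer(seed))
  counts <- c("n_chromosomes", "n_genes", "n_peaks", "n_clusters",
              "cells_per_cluster", "n_samples", "n_motifs", "n_traits",
              "snps_per_trait", "n_coaccess_modules")
  for (f in counts) if (cfg[[f]] < 1L) stop2(f, " must be >= 1")
  if (cfg$marker_peaks_per_cluster < 1L) stop2("need >= 1 marker peak per cluster")
  fr <- cfg$frac_low_quality_cells
  if (fr < 0 || fr > 1) stop2("frac_low_quality_cells must be in [0,1]")
  if (length(cfg$frip_range) != 2L || any(cfg$frip_range < 0) ||
      any(cfg$frip_range > 1) || diff(cfg$frip_range) < 0)
    stop2("frip_range must be an increasing pair in [0,1]")
  if (cfg$n_clusters * cfg$marker_peaks_per_cluster +
      4L * cfg$n_coaccess_modules > cfg$n_peaks)
    stop2("config infeasible: more marker/module peaks than peaks")
  if (cfg$stage_diff_peaks_per_cluster > cfg$marker_peaks_per_cluster)
    stop2("stage_diff_peaks_per_cluster cannot exceed marker_peaks_per_cluster")
  labels <- paste0("C", seq_len(cfg$n_clusters))
  if (is.null(cfg$condition_shift)) {
    cs <- rep(list(c(P1 = 0.5, P10 = 0.5)), cfg$n_clusters)
    names(cs) <- labels
    if (cfg$n_clusters >= 2L) {
      cs[[labels[cfg$n_clusters - 1L]]] <- c(P1 = 0.8, P10 = 0.2)
      cs[[labels[cfg$n_clusters]]] <- c(P1 = 0.2, P10 = 0.8)
    }
    cfg$condition_shift <- cs
  }
  ok <- vapply(cfg$condition_shift, function(p)
    length(p) == 2L && all(p >= 0) && abs(sum(p) - 1) < 1e-8, logical(1))
  if (!all(ok)) stop2("condition_shift fractions must be pairs summing to 1")
  if (is.null(cfg$planted_motif_per_cluster)) {
    if (cfg$n_motifs < cfg$n_clusters)
      stop2("n_motifs must be >= n_clusters for default planted motifs")
    cfg$planted_motif_per_cluster <- seq_len(cfg$n_clusters)
  }
  cfg$cluster_labels <- labels
  class(cfg) <- "synth_config"
  cfg
}

## internal fixed generator constants (documented in the methods vignette)
.synth_const <- list(
  peak_width = c(300L, 700L),
  frag_len = c(50L, 500L),
  program_marker_weight = 0.5,   # markers near program genes: common peaks
  loose_marker_weight = 0.1,     # remaining markers: rare outside cluster
  module_on_weight = 3.0,
  module_off_weight = 0.02,
  module_size = 4L,
  stage_diff_extra = 1.6,        # extra favoured-stage factor on marker_effect

  markers_per_program_gene = 4L,
  n_program_genes = 10L,
  motif_density = 0.05,
  bg_weight_shape = 0.5,
  low_frip_range = c(0.01, 0.05),
  good_depth_floor = 1601L,
  low_depth_range = c(200L, 1400L))

## greedy allocation of runs of `len` consecutive free slots on one chromosome
.take_runs <- function(free, chrom_of, n_runs, len) {
  starts <- integer(0)
  cand <- which(free)
  cand <- cand[sample.int(length(cand))]
  for (s in cand) {
    if (length(starts) >= n_runs) break
    idx <- s:(s + len - 1L)
    if (max(idx) > length(free)) next
    if (!all(free[idx])) next
    if (length(unique(chrom_of[idx])) != 1L) next
    free[idx] <- FALSE
    starts <- c(starts, s)
  }
  if (length(starts) < n_runs)
    stop2("could not place ", n_runs, " slot runs of length ", len,
          "; increase n_peaks or genome size")
  list(starts = sort(starts), free = free)
}

#' Generate a synthetic single-cell enhancer dataset with planted truth
#'
#' Draws per-cell fragments with negative-binomial depth; a cell's in-peak
#' fragments are distributed over the peak universe with multinomial weights
#' that encode cluster marker boosts, stage-restricted boosts, and per-cell
#' latent on/off co-accessibility modules; the remainder falls uniformly on
#' the genomic background. Trait SNPs are placed over the peak universe with
#' target-cluster marker peaks upweighted by `snp_enrichment_fold`. The
#' result is byte-identical for identical configurations.
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_bundle` with elements `fragments`
#'   ([fragment_set()]), `peaks_true` (peak `GRanges`), `genes`
#'   ([gene_model()]), `snps`, `motif_annotation` (sparse motif-by-peak
#'   matrix), `tftg_db`, `cell_metadata`, `gene_sets`, `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(is(config, "synth_config"))
  local_seed(config$seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(cfg) {
  k <- .synth_const
  labels <- cfg$cluster_labels
  K <- cfg$n_clusters

  ## ---- genome and slot grid -------------------------------------------
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_sizes <- setNames(rep(as.integer(cfg$chrom_length_bp),
                              cfg$n_chromosomes), chroms)
  slots_per_chrom <- rep(cfg$n_peaks %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_peaks %% cfg$n_chromosomes
  if (extra) slots_per_chrom[seq_len(extra)] <- slots_per_chrom[seq_len(extra)] + 1L
  slot_chrom <- rep(chroms, slots_per_chrom)
  slot_w <- floor(cfg$chrom_length_bp / slots_per_chrom)
  names(slot_w) <- chroms
  if (any(slot_w < k$peak_width[2] + 100))
    stop2("genome too small for n_peaks non-overlapping peaks")
  slot_pos0 <- unlist(lapply(seq_along(chroms), function(i)
    (seq_len(slots_per_chrom[i]) - 1L) * slot_w[i]), use.names = FALSE)

  ## peaks: one per slot, random offset and width within its slot
  widths <- sample(k$peak_width[1]:k$peak_width[2], cfg$n_peaks, replace = TRUE)
  max_off <- slot_w[slot_chrom] - widths - 1L
  starts <- slot_pos0 + floor(runif(cfg$n_peaks) * max_off)
  peaks <- peak_set(slot_chrom, starts, starts + widths, sort_peaks = FALSE)
  peak_ids <- names(peaks)
  peak_start0 <- starts
  peak_end0 <- starts + widths

  ## ---- structured slot allocation -------------------------------------
  free <- rep(TRUE, cfg$n_peaks)
  mod_size <- k$module_size
  span_needed <- function(len) {
    (len - 1L) * max(slot_w) + k$peak_width[2]
  }
  if (span_needed(mod_size) > cfg$module_span_bp)
    stop2("module_span_bp too small for the peak slot spacing; increase ",
          "module_span_bp or n_peaks")
  alloc <- .take_runs(free, slot_chrom, cfg$n_coaccess_modules, mod_size)
  free <- alloc$free
  module_peaks <- lapply(alloc$starts, function(s) s:(s + mod_size - 1L))
  names(module_peaks) <- paste0("module", seq_len(cfg$n_coaccess_modules))
  n_global_mod <- ceiling(cfg$n_coaccess_modules / 2)
  module_home <- c(rep(NA_character_, n_global_mod),
                   labels[((seq_len(cfg$n_coaccess_modules - n_global_mod) - 1L) %% K) + 1L])

  mpg <- k$markers_per_program_gene
  n_prog <- min(k$n_program_genes, cfg$marker_peaks_per_cluster %/% mpg)
  n_loose <- cfg$marker_peaks_per_cluster - n_prog * mpg
  marker_peaks <- vector("list", K)
  loose_markers <- vector("list", K)
  program_runs <- vector("list", K)
  names(marker_peaks) <- names(program_runs) <- labels
  for (i in seq_len(K)) {
    runs <- if (n_prog > 0) {
      a <- .take_runs(free, slot_chrom, n_prog, mpg); free <- a$free
      a$starts
    } else integer(0)
    program_runs[[i]] <- runs
    mk <- unlist(lapply(runs, function(s) s:(s + mpg - 1L)), use.names = FALSE)
    loose <- integer(0)
    if (n_loose > 0) {
      a <- .take_runs(free, slot_chrom, n_loose, 1L); free <- a$free
      loose <- a$starts
    }
    loose_markers[[i]] <- loose
    marker_peaks[[i]] <- sort(c(mk, loose))
  }

  ## stage-differential markers, drawn from the loose markers so the
  ## program-gene signal is stage-stable; direction alternating P1/P10
  stage_diff <- lapply(seq_len(K), function(i) {
    n_sd <- cfg$stage_diff_peaks_per_cluster
    pool <- if (length(loose_markers[[i]]) >= n_sd)
      loose_markers[[i]] else marker_peaks[[i]]
    if (n_sd == 0L) return(data.table(peak = integer(0), stage = character(0)))
    pk <- pool[seq_len(n_sd)]
    data.table(peak = pk,
               stage = rep_len(c("P1", "P10"), n_sd))
  })
  names(stage_diff) <- labels

  ## ---- base peak weights ----------------------------------------------
  base_w <- rgamma(cfg$n_peaks, shape = k$bg_weight_shape, rate = 1)
  prog_idx <- unlist(lapply(seq_len(K), function(i)
    setdiff(marker_peaks[[i]], loose_markers[[i]])), use.names = FALSE)
  base_w[prog_idx] <- k$program_marker_weight
  base_w[unlist(loose_markers, use.names = FALSE)] <- k$loose_marker_weight
  all_module_idx <- unlist(module_peaks, use.names = FALSE)
  base_w[all_module_idx] <- k$module_off_weight

  ## ---- genes ------------------------------------------------------------
  prog_genes <- vector("list", K)
  gene_rows <- list()
  gid <- 0L
  for (i in seq_len(K)) {
    ids <- character(0)
    for (s in program_runs[[i]]) {
      gid <- gid + 1L
      idx <- s:(s + mpg - 1L)
      gstart <- max(0L, min(peak_start0[idx]) - sample(0:5000, 1L))
      gend <- min(chrom_sizes[slot_chrom[s]],
                  max(peak_end0[idx]) + sample(0:5000, 1L))
      id <- sprintf("gene%04d", gid)
      gene_rows[[gid]] <- data.table(gene_id = id, chrom = slot_chrom[s],
                                     start = gstart, end = gend,
                                     strand = sample(c("+", "-"), 1L))
      ids <- c(ids, id)
    }
    prog_genes[[i]] <- ids
  }
  names(prog_genes) <- labels
  n_rand_genes <- max(0L, cfg$n_genes - gid)
  for (j in seq_len(n_rand_genes)) {
    gid <- gid + 1L
    ch <- sample(chroms, 1L)
    len <- sample(5000:60000, 1L)
    st <- sample.int(as.integer(chrom_sizes[ch]) - len - 1L, 1L)
    gene_rows[[gid]] <- data.table(gene_id = sprintf("gene%04d", gid),
                                   chrom = ch, start = st, end = st + len,
                                   strand = sample(c("+", "-"), 1L))
  }
  gtab <- rbindlist(gene_rows)
  genes <- gene_model(gtab$gene_id, gtab$chrom, gtab$start, gtab$end,
                      gtab$strand)
  gene_sets <- prog_genes
  names(gene_sets) <- paste0("program_", labels)

  ## ---- cells and metadata ----------------------------------------------
  n_cells <- K * cfg$cells_per_cluster
  barcodes <- sprintf("cell%05d", seq_len(n_cells))
  cell_cluster <- rep(labels, each = cfg$cells_per_cluster)
  p1_frac <- vapply(cfg$condition_shift[cell_cluster], `[`, numeric(1), 1L)
  stage <- ifelse(runif(n_cells) < p1_frac, "P1", "P10")
  condition <- sample(c("MI", "sham"), n_cells, replace = TRUE)
  day <- sample(c(3L, 7L), n_cells, replace = TRUE)
  n_reps <- max(1L, round(cfg$n_samples / 8))
  replicate <- sample(seq_len(n_reps), n_cells, replace = TRUE)
  zone <- ifelse(condition == "MI",
                 sample(c("IZ", "BZ", "RZ"), n_cells, replace = TRUE), "none")
  sample_id <- paste(stage, condition, paste0("D", day),
                     paste0("R", replicate), sep = "_")
  metadata <- data.table(barcode = barcodes, stage = stage,
                         condition = condition, day = day, zone = zone,
                         replicate = replicate, sample_id = sample_id)

  n_low <- floor(cfg$frac_low_quality_cells * n_cells)
  low_idx <- sample.int(n_cells, n_low)
  low_type <- rep("", n_cells)
  if (n_low) low_type[low_idx] <- rep_len(c("lowdepth", "lowfrip"), n_low)
  depth <- rnbinom(n_cells, mu = cfg$depth_mean, size = cfg$depth_dispersion)
  depth <- pmax(depth, k$good_depth_floor)
  depth[low_type == "lowdepth"] <-
    sample(k$low_depth_range[1]:k$low_depth_range[2],
           sum(low_type == "lowdepth"), replace = TRUE)
  frip_t <- runif(n_cells, cfg$frip_range[1], cfg$frip_range[2])
  frip_t[low_type == "lowfrip"] <-
    runif(sum(low_type == "lowfrip"), k$low_frip_range[1], k$low_frip_range[2])

  ## ---- fragments ---------------------------------------------------------
  marker_w_of <- lapply(seq_len(K), function(i) {
    sd_tab <- stage_diff[[i]]
    list(always = setdiff(marker_peaks[[i]], sd_tab$peak),
         p1 = sd_tab$peak[sd_tab$stage == "P1"],
         p10 = sd_tab$peak[sd_tab$stage == "P10"])
  })
  names(marker_w_of) <- labels
  chrom_cum <- cumsum(as.numeric(chrom_sizes))
  frag_list <- vector("list", n_cells)
  flen_min <- k$frag_len[1]; flen_span <- k$frag_len[2] - k$frag_len[1]
  for (c_i in seq_len(n_cells)) {
    cl <- cell_cluster[c_i]
    w <- base_w
    mw <- marker_w_of[[cl]]
    w[mw$always] <- w[mw$always] * cfg$marker_effect
    fav <- if (stage[c_i] == "P1") mw$p1 else mw$p10
    w[fav] <- w[fav] * cfg$marker_effect * k$stage_diff_extra
    ## latent module states
    for (m in seq_len(cfg$n_coaccess_modules)) {
      home <- module_home[m]
      on <- if (is.na(home) || home == cl) runif(1) < 0.5 else FALSE
      if (on) w[module_peaks[[m]]] <- k$module_on_weight
    }
    n_in <- rbinom(1L, depth[c_i], frip_t[c_i])
    n_bg <- depth[c_i] - n_in
    cnt <- rmultinom(1L, n_in, w)[, 1L]
    hit <- which(cnt > 0L)
    pk_idx <- rep(hit, cnt[hit])
    fs <- peak_start0[pk_idx] +
      floor(runif(length(pk_idx)) * (peak_end0[pk_idx] - peak_start0[pk_idx]))
    ## background: uniform over concatenated genome
    gpos <- runif(n_bg) * chrom_cum[length(chrom_cum)]
    bg_ch <- findInterval(gpos, c(0, chrom_cum), rightmost.closed = TRUE)
    bg_start <- floor(gpos - c(0, chrom_cum)[bg_ch])
    ch_all <- c(slot_chrom[pk_idx], chroms[bg_ch])
    st_all <- c(fs, bg_start)
    len_all <- flen_min + floor(runif(length(st_all)) * (flen_span + 1L))
    en_all <- pmin(st_all + len_all, chrom_sizes[ch_all])
    frag_list[[c_i]] <- data.table(
      chrom = ch_all, start = as.integer(st_all), end = as.integer(en_all),
      barcode = barcodes[c_i],
      in_peak = c(rep(TRUE, length(pk_idx)), rep(FALSE, n_bg)))
  }
  frags <- rbindlist(frag_list)
  ## background fragments can still overlap peaks; flag them for truth FRiP
  bg <- frags[in_peak == FALSE]
  if (nrow(bg)) {
    bg_gr <- GenomicRanges::GRanges(bg$chrom,
                                    IRanges::IRanges(bg$start + 1L, bg$end))
    hit_bg <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(bg_gr, peaks, minoverlap = 1L)))
    bg_flag <- rep(FALSE, nrow(bg)); bg_flag[hit_bg] <- TRUE
    frags[in_peak == FALSE, in_peak := bg_flag]
  }
  frags <- unique(frags, by = c("chrom", "start", "end", "barcode"))
  qc_truth <- frags[, .(unique_reads = .N, frip = mean(in_peak)),
                    by = barcode]
  qc_truth[, pass := unique_reads > 1500L & frip > 0.10]
  frags[, count := 1L]
  fs_obj <- fragment_set(frags[, .(chrom, start, end, barcode, count)],
                         chrom_sizes)

  ## ---- SNPs --------------------------------------------------------------
  trait_pool <- c("CAD", "Hypertension", "HeartFailure",
                  "AtrialFibrillation", "Stroke", "LDL")
  traits <- if (cfg$n_traits <= length(trait_pool))
    trait_pool[seq_len(cfg$n_traits)] else
      c(trait_pool, paste0("Trait", seq_len(cfg$n_traits - length(trait_pool))))
  n_planted <- min(3L, cfg$n_traits, K)
  planted_trait_cluster <- setNames(labels[seq_len(n_planted)],
                                    traits[seq_len(n_planted)])
  pw <- as.numeric(peak_end0 - peak_start0)
  snp_rows <- list()
  for (ti in seq_along(traits)) {
    wgt <- pw
    tgt <- planted_trait_cluster[traits[ti]]
    if (!is.na(tgt) && ti <= n_planted) {
      mk <- marker_peaks[[tgt]]
      wgt[mk] <- wgt[mk] * cfg$snp_enrichment_fold
    }
    pk <- sample.int(cfg$n_peaks, cfg$snps_per_trait, replace = TRUE,
                     prob = wgt)
    pos <- peak_start0[pk] +
      floor(runif(cfg$snps_per_trait) * (peak_end0[pk] - peak_start0[pk]))
    snp_rows[[ti]] <- data.table(
      snp_id = sprintf("rs%s%04d", ti, seq_len(cfg$snps_per_trait)),
      trait = traits[ti], chrom = slot_chrom[pk], pos = as.integer(pos))
  }
  snps <- rbindlist(snp_rows)

  ## ---- motif annotation ---------------------------------------------------
  motif_ids <- sprintf("TF%02d", seq_len(cfg$n_motifs))
  mi <- list(); mj <- list()
  planted_motif <- setNames(motif_ids[cfg$planted_motif_per_cluster], labels)
  for (m in seq_len(cfg$n_motifs)) {
    hits <- which(runif(cfg$n_peaks) < k$motif_density)
    cl <- which(cfg$planted_motif_per_cluster == m)
    if (length(cl)) hits <- union(hits, unlist(marker_peaks[cl]))
    if (!length(hits)) hits <- sample.int(cfg$n_peaks, 1L)
    mi[[m]] <- rep(m, length(hits)); mj[[m]] <- hits
  }
  motif_annotation <- sparseMatrix(
    i = unlist(mi), j = unlist(mj), x = 1,
    dims = c(cfg$n_motifs, cfg$n_peaks),
    dimnames = list(motif_ids, peak_ids))

  ## ---- TF -> target-gene database -----------------------------------------
  all_gene_ids <- genes$gene_id
  tftg_rows <- list()
  for (i in seq_len(K)) {
    tg <- unique(c(prog_genes[[i]],
                   sample(all_gene_ids, min(5L, length(all_gene_ids)))))
    tftg_rows[[i]] <- data.table(tf = planted_motif[labels[i]], target = tg)
  }
  decoys <- setdiff(motif_ids, planted_motif)
  for (d in head(decoys, 10L)) {
    tftg_rows[[length(tftg_rows) + 1L]] <-
      data.table(tf = d, target = sample(all_gene_ids,
                                         min(10L, length(all_gene_ids))))
  }
  tftg_db <- unique(rbindlist(tftg_rows))

  ## ---- truth ---------------------------------------------------------------
  fate <- if (K >= 2L) {
    list(cluster_a = labels[K - 1L], cluster_b = labels[K],
         a_biased = prog_genes[[K - 1L]], b_biased = prog_genes[[K]])
  } else NULL
  truth <- list(
    cell_clusters = setNames(cell_cluster, barcodes),
    marker_peaks = lapply(marker_peaks, function(i) peak_ids[i]),
    program_genes = prog_genes,
    planted_traits = lapply(seq_len(n_planted), function(i)
      list(trait = traits[i], cluster = labels[i],
           fold = cfg$snp_enrichment_fold)),
    modules = lapply(seq_along(module_peaks), function(m)
      list(peaks = peak_ids[module_peaks[[m]]], home = module_home[m])),
    planted_motif = as.list(planted_motif),
    condition_shift = cfg$condition_shift,
    stage_diff_peaks = lapply(stage_diff, function(d)
      data.table(peak_id = peak_ids[d$peak], stage = d$stage)),
    fate = fate,
    qc = qc_truth[])
  names(truth$modules) <- names(module_peaks)

  structure(list(fragments = fs_obj,
                 peaks_true = peaks,
                 genes = genes,
                 snps = snps,
                 motif_annotation = motif_annotation,
                 tftg_db = tftg_db,
                 cell_metadata = metadata,
                 gene_sets = gene_sets,
                 truth = truth,
                 config = cfg),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", nrow(x$cell_metadata), "cells,",
      length(x$peaks_true), "peaks,", nrow(x$genes), "genes,",
      nrow(x$snps), "SNPs\n")
  invisible(x)
}

#' Simulate a labelled low-dimensional embedding with planted abundance shifts
#'
#' A lightweight generator for benchmarking neighbourhood differential
#' abundance: Gaussian cluster blobs in `d` dimensions with per-cluster stage
#' fractions and balanced replicates.
#'
#' @param n_clusters Number of blobs.
#' @param cells_per_cluster Cells per blob.
#' @param d Embedding dimensionality.
#' @param shift Named list mapping cluster label to c(P1, P10) fractions;
#'   unlisted clusters are balanced.
#' @param n_replicates Replicates per stage.
#' @param sep Blob centre separation in units of the within-blob SD.
#' @param seed Integer seed.
#' @return List with `embedding` (matrix), `cluster`, `stage`, `replicate`.
#' @export
simulate_labeled_embedding <- function(n_clusters = 6L, cells_per_cluster = 100L,
                                       d = 5L, shift = list(),
                                       n_replicates = 2L, sep = 8,
                                       seed = 1L) {
  local_seed(seed, {
    labels <- paste0("C", seq_len(n_clusters))
    n <- n_clusters * cells_per_cluster
    centers <- matrix(stats::rnorm(n_clusters * d, sd = sep), n_clusters, d)
    cl <- rep(labels, each = cells_per_cluster)
    emb <- centers[rep(seq_len(n_clusters), each = cells_per_cluster), ] +
      matrix(stats::rnorm(n * d), n, d)
    rownames(emb) <- sprintf("cell%05d", seq_len(n))
    p1 <- vapply(cl, function(x)
      if (!is.null(shift[[x]])) shift[[x]][1] else 0.5, numeric(1))
    stage <- ifelse(runif(n) < p1, "P1", "P10")
    repl <- sample(seq_len(n_replicates), n, replace = TRUE)
    list(embedding = emb, cluster = cl, stage = stage, replicate = repl)
  })
}
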