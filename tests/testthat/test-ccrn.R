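## deterministic metacell fixture: two module peaks driven by a shared
## latent plus independent peaks, all on one chromosome within the window
latent_metacells <- function(m = 60, n_extra = 4, q_on = 0.95, q_off = 0.02,
                             k_agg = 10, n_ballast = 60, seed = 8) {
  set.seed(seed)
  starts <- (seq_len(n_extra + 2) - 1L) * 60000L + 1000L
  chroms <- c(rep("chr1", n_extra + 2), rep("chr2", n_ballast))
  all_starts <- c(starts, (seq_len(n_ballast) - 1L) * 60000L + 1000L)
  peaks <- peak_set(chroms, all_starts, all_starts + 500L,
                    sort_peaks = FALSE)
  counts <- matrix(0, length(peaks), m)
  rownames(counts) <- names(peaks)
  for (j in seq_len(m)) {
    z <- runif(k_agg) < 0.5
    q <- ifelse(z, q_on, q_off)
    counts[1, j] <- sum(runif(k_agg) < q)
    counts[2, j] <- sum(runif(k_agg) < q)
    for (e in seq_len(n_extra))
      counts[2 + e, j] <- rbinom(1, k_agg, 0.4)
    ## ballast peaks on another chromosome keep meta-cell totals stable,
    ## as the genome-wide universe does in real data
    counts[(n_extra + 3):nrow(counts), j] <-
      rbinom(n_ballast, k_agg, 0.4)
  }
  structure(list(counts = counts,
                 members = rep(list(character(k_agg)), m),
                 peaks = peaks, subset = "all"),
            class = "metacell_matrix")
}

test_that("meta-cell aggregation conserves totals and respects clusters", {
  b <- small_bundle()
  cm <- small_matrix()
  emb <- tfidf_lsi(cm, d = 15)
  ## 100 cells at k_agg 50 -> 2 meta-cells of 50
  sub <- colnames(cm$binary)[1:100]
  meta2 <- aggregate_metacells(cm, emb, k_agg = 50L, cells = sub)
  expect_equal(ncol(meta2$counts), 2L)
  expect_equal(sort(lengths(meta2$members)), c(50L, 50L))
  expect_equal(sum(meta2$counts), sum(cm$binary[, sub]))
  ## each cell in at most one meta-cell
  expect_false(any(duplicated(unlist(meta2$members))))
  ## meta-cells are cluster-coherent on the default planted structure
  bd <- default_bundle()
  cmd <- default_matrix()
  embd <- tfidf_lsi(cmd, d = 20)
  labd <- truth_labels(bd, cmd)
  meta <- aggregate_metacells(cmd, embd, k_agg = 20L)
  purity <- vapply(meta$members, function(mm) {
    max(table(labd[mm])) / length(mm)
  }, numeric(1))
  expect_gte(mean(purity), 0.9)
  ## subset smaller than k_agg: one meta-cell with warning
  expect_warning(m1 <- aggregate_metacells(cm, emb, k_agg = 50L,
                                           cells = sub[1:10]), "single")
  expect_equal(ncol(m1$counts), 1L)
})

test_that("co-accessibility scores separate shared-latent from independent peaks", {
  meta <- latent_metacells()
  ed <- coaccessibility_scores(meta, window_bp = 500000, min_metacells = 10)
  key <- paste(ed$peak_i, ed$peak_j)
  pair12 <- ed[key == paste(names(meta$peaks)[1], names(meta$peaks)[2])]
  expect_gte(pair12$score, 0.5)
  null_scores <- ed$score[!(ed$peak_i == names(meta$peaks)[1] &
                              ed$peak_j == names(meta$peaks)[2])]
  expect_lt(median(abs(null_scores)), 0.1)
  ## pairs beyond the distance bound are never emitted
  expect_true(all(ed$distance <= 500000))
  far <- peak_set("chr1", c(0, 600001), c(500, 600501))
  meta_far <- meta
  meta_far$peaks <- far
  meta_far$counts <- meta$counts[1:2, ]
  rownames(meta_far$counts) <- names(far)
  ed_far <- coaccessibility_scores(meta_far, window_bp = 500000)
  expect_equal(nrow(ed_far), 0L)
  ## symmetric, canonical order, no self-edges
  expect_true(all(ed$peak_i < ed$peak_j | ed$peak_i != ed$peak_j))
  expect_false(any(ed$peak_i == ed$peak_j))
})

test_that("build_ccrns forms transitive components above the threshold", {
  edges <- data.table::data.table(
    peak_i = c("chr1:100-200", "chr1:300-400", "chr1:700-800"),
    peak_j = c("chr1:300-400", "chr1:500-600", "chr1:900-950"),
    distance = c(200, 200, 200), score = c(0.5, 0.3, 0.05))
  peaks <- peak_set("chr1", c(100, 300, 500, 700, 900),
                    c(200, 400, 600, 800, 950))
  g <- build_ccrns(edges, peaks, threshold = 0.1)
  expect_equal(length(g$networks), 1L)
  expect_setequal(g$networks[[1]],
                  c("chr1:100-200", "chr1:300-400", "chr1:500-600"))
  ## all edges below threshold -> no networks
  g0 <- build_ccrns(edges[score < 0.1], peaks, threshold = 0.1)
  expect_equal(length(g0$networks), 0L)
})

test_that("network specificity is driven by peak-set Jaccard overlap", {
  mk_graph <- function(peaksets) {
    structure(list(networks = peaksets,
                   edges = data.table::data.table()), class = "ccrn_graph")
  }
  shared_net <- c("p1", "p2", "p3")
  g1 <- mk_graph(list(N1 = shared_net, N2 = c("p7", "p8")))
  g2 <- mk_graph(list(N1 = shared_net))
  spec <- ccrn_specificity(list(A = g1, B = g2))
  got <- setNames(spec$specific, paste(spec$cluster, spec$network))
  expect_false(got[["A N1"]])   # identical network in two clusters: shared
  expect_true(got[["A N2"]])    # disjoint peak set: specific
  expect_false(got[["B N1"]])
})

test_that("gene-level CCRN counts match a brute-force window scan", {
  peaks <- peak_set("chr1", c(100000, 180000, 900000), c(100500, 180500, 900500))
  genes <- gene_model(c("g1", "g2"), "chr1", c(150000L, 700000L),
                      c(160000L, 710000L), c("+", "+"))
  graph <- structure(list(networks = list(
    CCRN_1 = names(peaks)[1], CCRN_2 = names(peaks)[2],
    CCRN_3 = names(peaks)[3]), edges = data.table::data.table()),
    class = "ccrn_graph")
  counts <- gene_ccrn_counts(graph, genes, peaks, c(chr1 = 2e6))
  got <- setNames(counts$n_networks, counts$gene_id)
  ## g1 window [100000,190000) covers peaks of networks 1 and 2
  expect_equal(unname(got["g1"]), 2L)
  expect_equal(unname(got["g2"]), 0L)
})

test_that("shuffled meta-cell columns yield essentially no networks", {
  meta <- latent_metacells(m = 80, n_extra = 6)
  set.seed(9)
  shuf <- meta
  shuf$counts <- t(apply(meta$counts, 1L, sample))
  colnames(shuf$counts) <- colnames(meta$counts)
  g <- build_ccrns(coaccessibility_scores(shuf, min_metacells = 10),
                   meta$peaks)
  expect_lte(length(g$networks), 0L + ceiling(0.05 * 1))
})
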