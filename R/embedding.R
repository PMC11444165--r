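#' TF-IDF normalisation and latent semantic indexing of a binary matrix
#'
#' Standard LSI for binary chromatin matrices: per-cell term-frequency
#' scaling, per-peak inverse document frequency
#' `log(1 + n_cells / detection_count)`, `log1p` scaling of the product
#' (times 1e4), and a truncated SVD. The first component is dropped when its
#' absolute correlation with per-cell detection depth exceeds
#' `depth_cor_max`, as it then captures depth rather than cell state.
#'
#' @param cm A `cell_matrix` (or a sparse binary peaks x cells matrix).
#' @param d Number of components to return (>= 2).
#' @param depth_cor_max Depth-correlation threshold for dropping the first
#'   component. Default 0.9.
#' @return A list of class `embedding`: `coords` (cells x d), `var_share`,
#'   `d`, `dropped_first`.
#' @export
tfidf_lsi <- function(cm, d = 30L, depth_cor_max = 0.9) {
  X <- if (is(cm, "cell_matrix")) cm$binary else cm
  if (!nrow(X) || !ncol(X)) stop2("matrix is empty")
  if (d >= min(dim(X))) stop2("d must be smaller than both matrix dimensions")
  if (d < 2L) stop2("d must be >= 2")
  det_count <- rowSums(X > 0)
  keep <- det_count > 0
  Xk <- X[keep, , drop = FALSE]
  depth <- colSums(Xk)
  if (any(depth == 0)) stop2("cells with zero detected peaks present")
  tf <- Xk %*% Diagonal(x = 1 / depth)
  idf <- log(1 + ncol(Xk) / det_count[keep])
  L <- as.matrix(Diagonal(x = idf) %*% tf)
  L <- log1p(L * 1e4)
  ## SVD via the cell-space Gram matrix (cheaper when peaks >> cells)
  G <- crossprod(L)
  eig <- eigen(G, symmetric = TRUE)
  nd <- d + 1L
  ev <- pmax(eig$values[seq_len(nd)], 0)
  sv <- sqrt(ev)
  V <- eig$vectors[, seq_len(nd), drop = FALSE]
  ## deterministic sign: largest-magnitude loading positive
  for (j in seq_len(nd)) {
    mj <- which.max(abs(V[, j]))
    if (V[mj, j] < 0) V[, j] <- -V[, j]
  }
  coords_full <- sweep(V, 2L, sv, "*")
  var_share_full <- ev / sum(pmax(eig$values, 0))
  dropped <- FALSE
  if (stats::sd(coords_full[, 1L]) > 0 &&
      abs(cor(coords_full[, 1L], depth)) > depth_cor_max) {
    dropped <- TRUE
    coords <- coords_full[, 2:(d + 1L), drop = FALSE]
    var_share <- var_share_full[2:(d + 1L)]
  } else {
    coords <- coords_full[, seq_len(d), drop = FALSE]
    var_share <- var_share_full[seq_len(d)]
  }
  rownames(coords) <- colnames(X)
  colnames(coords) <- paste0("LSI_", seq_len(d))
  structure(list(coords = coords, var_share = var_share, d = d,
                 dropped_first = dropped),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding:", nrow(x$coords), "cells x", x$d, "components",
      if (x$dropped_first) "(depth component dropped)" else "", "\n")
  invisible(x)
}

#' Align batches in an embedding by gated local centroid matching
#'
#' Iteratively partitions cells into local neighbourhoods (k-means with a
#' fixed seed, preceded by one global pass) and, within each neighbourhood,
#' shifts every batch so its centroid coincides with the neighbourhood
#' centroid. A shift is only applied when it exceeds a noise gate of
#' `gate` times the expected null centroid displacement
#' (sigma * sqrt(d / n_batch)); on batch-free data the embedding is
#' therefore returned (essentially) unchanged.
#'
#' @param embedding An `embedding`.
#' @param batch Batch label per cell.
#' @param n_centers Number of local neighbourhoods (default: n/100, clamped
#'   to \[2, 20\]).
#' @param n_iter Refinement iterations after the global pass.
#' @param gate Noise-gate multiplier. Default 3.
#' @param min_cells Minimum batch cells per neighbourhood to correct.
#' @param seed Seed for the k-means partition.
#' @return A new `embedding` with aligned coordinates.
#' @export
align_batches <- function(embedding, batch, n_centers = NULL, n_iter = 5L,
                          gate = 3, min_cells = 5L, seed = 0L) {
  stopifnot(is(embedding, "embedding"))
  E <- embedding$coords
  batch <- as.character(batch)
  stopifnot(length(batch) == nrow(E))
  if (length(unique(batch)) < 2L) return(embedding)
  d <- ncol(E)
  shift_block <- function(E, idx_list) {
    moved <- FALSE
    for (idx in idx_list) {
      sub <- E[idx, , drop = FALSE]
      ctr <- colMeans(sub)
      ## pooled within-group per-dimension SD as the noise scale
      sig <- sqrt(mean(apply(sub, 2L, var)))
      if (!is.finite(sig) || sig == 0) sig <- 1e-12
      for (b in unique(batch[idx])) {
        sel <- idx[batch[idx] == b]
        if (length(sel) < min_cells) next
        delta <- ctr - colMeans(E[sel, , drop = FALSE])
        thr <- gate * sig * sqrt(d / length(sel))
        if (sqrt(sum(delta^2)) > thr) {
          E[sel, ] <- sweep(E[sel, , drop = FALSE], 2L, delta, "+")
          moved <- TRUE
        }
      }
    }
    list(E = E, moved = moved)
  }
  ## global pass removes constant offsets exactly
  res <- shift_block(E, list(seq_len(nrow(E))))
  E <- res$E
  if (is.null(n_centers))
    n_centers <- max(2L, min(20L, nrow(E) %/% 100L))
  for (it in seq_len(n_iter)) {
    km <- local_seed(seed + it, kmeans(E, centers = n_centers, nstart = 3L,
                                       iter.max = 50L))
    res <- shift_block(E, split(seq_len(nrow(E)), km$cluster))
    E <- res$E
    if (!res$moved) break
  }
  out <- embedding
  out$coords <- E
  out
}
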