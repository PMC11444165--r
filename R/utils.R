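#' @importFrom data.table data.table as.data.table setorder setnames setattr
#'   copy := .N .SD fread fwrite rbindlist
#' @importFrom Matrix sparseMatrix rowSums colSums rowMeans colMeans t
#'   crossprod tcrossprod Diagonal drop0 writeMM readMM
#' @importFrom methods as is new
#' @importFrom stats dhyper pbinom p.adjust quantile rbinom rgamma rnbinom
#'   rnorm runif sd kmeans cor var setNames rmultinom glm quasipoisson coef
#'   binom.test wilcox.test dist median pnorm fisher.test
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar in \[-1, 1\]; 1 for identical partitions.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

## Vectorised two-sided Fisher exact p for 2x2 detection tables
## (k_in successes of n_in draws vs k_out of n_out). Matches fisher.test's
## two-sided rule: sum of hypergeometric point masses <= observed mass
## (with the same 1 + 1e-7 relative tolerance).
fisher_p_two_sided <- function(k_in, n_in, k_out, n_out) {
  stopifnot(length(n_in) == 1L || length(n_in) == length(k_in))
  m <- length(k_in)
  n_in <- rep_len(n_in, m); n_out <- rep_len(n_out, m)
  p <- numeric(m)
  for (i in seq_len(m)) {
    K <- k_in[i] + k_out[i]           # total successes
    N <- n_in[i] + n_out[i]
    lo <- max(0L, K - n_out[i]); hi <- min(K, n_in[i])
    supp <- lo:hi
    d <- dhyper(supp, K, N - K, n_in[i])
    p[i] <- sum(d[d <= d[k_in[i] - lo + 1L] * (1 + 1e-7)])
  }
  pmin(p, 1)
}

## log2 detection-fraction ratio with a small pseudocount on both fractions
log2_frac_ratio <- function(k_in, n_in, k_out, n_out, pseudo) {
  log2((k_in / n_in + pseudo) / (k_out / n_out + pseudo))
}

## Deterministic peak ids from 0-based half-open coordinates
peak_id_string <- function(chrom, start, end) {
  paste0(chrom, ":", start, "-", end)
}
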