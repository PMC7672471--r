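#' Gap penalty configuration
#'
#' Affine gap cost: a run of g gap columns scores `gamma(g) = -d - (g-1)e`,
#' with gap-open penalty `d` and gap-extension penalty `e` (default
#' `e = 0.1 d`). Suggested `d` by use case: 50 for variably spaced complexes
#' (tRNA-gene-like), 200 to discourage gaps in tightly organized promoters
#' (ribosomal-protein-gene-like); the library default is 100.
#'
#' @param d gap-open penalty, > 0.
#' @param e gap-extension penalty, > 0 and <= d.
#' @return list with components `d` and `e`.
#' @export
gap_config <- function(d = 100, e = 0.1 * d) {
  if (!(d > 0) || !(e > 0) || e > d)
    stop("require d > 0, e > 0, e <= d")
  list(d = d, e = e)
}

#' Affine gap run cost
#'
#' @param g gap run length, >= 1.
#' @param cfg a [gap_config()].
#' @return `-d - (g - 1) e`.
#' @export
gap_penalty <- function(g, cfg = gap_config()) {
  if (any(g < 1)) stop("gap length must be >= 1")
  -cfg$d - (g - 1) * cfg$e
}

# Per-column paired-product vectors: for column l with entries
# (q_1w, q_1c, ..., q_Kw, q_Kc) and mean qbar over all 2K entries, the
# K-vector A[k] = (q_kw - qbar)(q_kc - qbar). The similarity of two columns
# is the cosine of their A-vectors, which is exactly the printed score:
#   s = sum_k A_x[k] A_y[k] / (||A_x|| ||A_y||)
paired_product_vectors <- function(values, K) {
  cm <- colMeans(values)
  W <- values[seq(1L, 2L * K, by = 2L), , drop = FALSE]
  C <- values[seq(2L, 2L * K, by = 2L), , drop = FALSE]
  cmM <- matrix(cm, nrow = K, ncol = length(cm), byrow = TRUE)
  (W - cmM) * (C - cmM)
}

#' Column similarity score
#'
#' Similarity between two profile columns (2K-vectors ordered
#' W1,C1,...,WK,CK), defined through Pearson-style centering: with
#' `qbar` the mean of all 2K entries of x and `pbar` that of y,
#' \deqn{s = \frac{\sum_k (q_{kw}-\bar q)(q_{kc}-\bar q)(p_{kw}-\bar p)(p_{kc}-\bar p)}
#'   {\sqrt{\sum_k (q_{kw}-\bar q)^2 (q_{kc}-\bar q)^2}\sqrt{\sum_k (p_{kw}-\bar p)^2 (p_{kc}-\bar p)^2}}}
#' Bounded in [-1, 1] by Cauchy-Schwarz. If either column is degenerate
#' (zero denominator, e.g. constant or all-zero), the score is 0 by
#' convention: empty flanks neither attract nor repel. Note that for K = 1
#' the score can only take values in \{-1, 0, 1\}; K >= 2 is the intended
#' regime.
#'
#' @param x,y numeric vectors of length 2K.
#' @return similarity in [-1, 1].
#' @export
column_similarity <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) %% 2 == 0)
  K <- length(x) / 2L
  A <- paired_product_vectors(matrix(x, ncol = 1), K)
  B <- paired_product_vectors(matrix(y, ncol = 1), K)
  den <- sqrt(sum(A^2)) * sqrt(sum(B^2))
  if (den == 0) return(0)
  sum(A * B) / den
}

# n x m similarity matrix between all column pairs of two profiles.
similarity_matrix <- function(X, Y) {
  A <- paired_product_vectors(X$values, X$K)
  B <- paired_product_vectors(Y$values, Y$K)
  na <- sqrt(colSums(A^2))
  nb <- sqrt(colSums(B^2))
  S <- crossprod(A, B)
  den <- outer(na, nb)
  ok <- den > 0
  S[ok] <- S[ok] / den[ok]
  S[!ok] <- 0
  S
}

#' Reverse a profile
#'
#' Reverses the column order and swaps each experiment's Watson/Crick rows,
#' i.e. views the region from the opposite strand.
#'
#' @param P a [profile_matrix()].
#' @return The reversed ProfileMatrix.
#' @export
reverse_profile <- function(P) {
  idx <- as.vector(rbind(seq(2, 2 * P$K, by = 2), seq(1, 2 * P$K - 1, by = 2)))
  P$values <- P$values[idx, rev(seq_len(P$L)), drop = FALSE]
  rownames(P$values) <- paste0(rep(P$experiments, each = 2), c(":W", ":C"))
  P$gap_counts <- rev(P$gap_counts)
  P
}

#' Affine-gap overlap alignment of two profiles
#'
#' Finds the maximum-scoring overlap alignment (free end gaps) between two
#' normalized profile matrices, using the three-state affine-gap dynamic
#' program. Both orientations of `Y` are scored (reversed = columns flipped
#' and strands swapped) and the better one is returned; ties go to the
#' forward orientation. Traceback starts from the best cell on the
#' lower-right quadrant border and runs to the top or left edge.
#'
#' @param X,Y [profile_matrix()] objects with identical experiment sets.
#'   They are normalized with [normalize_per_region()] if not already.
#' @param cfg a [gap_config()].
#' @return An object of class `PairwiseAlignment`: `score`, `orientation`
#'   (`"forward"`/`"reversed"`), `path` (2-column matrix of 1-based column
#'   indices into X and Y, 0 marking a gap; Y indices refer to the oriented
#'   Y), `start`/`end` DP cells, and the profile sizes `n`, `m`.
#' @export
align_overlap <- function(X, Y, cfg = gap_config()) {
  if (X$K != Y$K || !identical(X$experiments, Y$experiments))
    stop("profiles must share the same experiments in the same order")
  if (!X$is_normalized) X <- normalize_per_region(X)
  if (!Y$is_normalized) Y <- normalize_per_region(Y)
  Yr <- reverse_profile(Y)
  fwd <- overlap_align_cpp(similarity_matrix(X, Y), cfg$d, cfg$e)
  rev_ <- overlap_align_cpp(similarity_matrix(X, Yr), cfg$d, cfg$e)
  if (rev_$score > fwd$score) {
    res <- rev_; orientation <- "reversed"
  } else {
    res <- fwd; orientation <- "forward"
  }
  structure(list(score = res$score, orientation = orientation,
                 path = res$path, start = res$start, end = res$end,
                 n = X$L, m = Y$L),
            class = "PairwiseAlignment")
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  nm <- sum(x$path[, 1] > 0 & x$path[, 2] > 0)
  cat(sprintf("PairwiseAlignment: score %.3f, %s orientation, %d matched column(s), %d gap step(s)\n",
              x$score, x$orientation, nm, nrow(x$path) - nm))
  invisible(x)
}
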