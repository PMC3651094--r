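#' Normalize time series so correlation becomes a matrix product
#'
#' Each column is centered and scaled to unit Euclidean norm, giving the
#' matrix \eqn{U} with the property \eqn{U^T U = R}, the full pairwise
#' Pearson correlation matrix. This turns network construction into (blocked)
#' matrix multiplication.
#'
#' @param ts a `timeseries_set`, or a plain L x N numeric matrix
#' @return object of class `normalized_series`: list with `U` (L x N),
#'   `L`, `N` and the originating mask (if any)
#' @export
normalize_series <- function(ts) {
  mask <- NULL
  if (inherits(ts, "timeseries_set")) {
    mask <- ts$mask
    x <- ts$data
  } else {
    x <- as.matrix(ts)
  }
  if (nrow(x) < 3L) stop("need at least 3 time points")
  ctr <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(ctr^2))
  bad <- which(nrm == 0)
  if (length(bad))
    stop("constant (zero-variance) time series at node(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  U <- sweep(ctr, 2L, nrm, "/")
  structure(list(U = U, L = nrow(U), N = ncol(U), mask = mask),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("normalized_series: %d time points x %d nodes\n", x$L, x$N))
  invisible(x)
}

#' Blocked Pearson correlation
#'
#' Computes \eqn{R = U^T U} one block pair at a time so that at most one
#' dense `block_size` x `block_size` sub-matrix is live at once. Only blocks
#' on or above the block diagonal are emitted: the correlation matrix is
#' symmetric, so the upper block triangle carries all information.
#'
#' @param U a `normalized_series` (or matrix already normalized column-wise)
#' @param block_size columns per block; default 2048
#' @param callback optional `function(block)` invoked per block instead of
#'   accumulating; when supplied the return value is `invisible(NULL)` and
#'   peak memory stays at one block
#' @return (when `callback` is NULL) a list of correlation blocks, each a
#'   list with `row_range`, `col_range` (1-based inclusive index pairs) and
#'   `values` (dense sub-matrix)
#' @export
blocked_correlation <- function(U, block_size = 2048L, callback = NULL) {
  if (inherits(U, "normalized_series")) U <- U$U
  U <- as.matrix(U)
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size < 1L) stop("block_size must be >= 1")
  N <- ncol(U)
  nb <- ceiling(N / block_size)
  out <- if (is.null(callback)) vector("list", nb * (nb + 1L) / 2L) else NULL
  pos <- 0L
  for (bi in seq_len(nb)) {
    ri <- ((bi - 1L) * block_size + 1L):min(bi * block_size, N)
    Ui <- U[, ri, drop = FALSE]
    for (bj in bi:nb) {
      rj <- ((bj - 1L) * block_size + 1L):min(bj * block_size, N)
      vals <- crossprod(Ui, U[, rj, drop = FALSE])
      blk <- list(row_range = c(ri[1L], ri[length(ri)]),
                  col_range = c(rj[1L], rj[length(rj)]),
                  values = vals)
      if (is.null(callback)) {
        pos <- pos + 1L
        out[[pos]] <- blk
      } else {
        callback(blk)
      }
    }
  }
  if (is.null(callback)) out else invisible(NULL)
}

#' Assemble correlation blocks into the full symmetric matrix
#'
#' @param blocks output of [blocked_correlation()]
#' @param N node count
#' @return dense N x N correlation matrix
#' @export
assemble_correlation <- function(blocks, N) {
  R <- matrix(NA_real_, N, N)
  for (b in blocks) {
    ri <- b$row_range[1L]:b$row_range[2L]
    rj <- b$col_range[1L]:b$col_range[2L]
    R[ri, rj] <- b$values
    R[rj, ri] <- t(b$values)
  }
  R
}

#' Full Pearson correlation matrix of a time-series set
#'
#' Convenience wrapper: normalize, compute blocks, assemble.
#' @param ts `timeseries_set` or L x N matrix
#' @param block_size see [blocked_correlation()]
#' @return dense N x N Pearson matrix
#' @export
correlation_matrix <- function(ts, block_size = 2048L) {
  ns <- normalize_series(ts)
  assemble_correlation(blocked_correlation(ns, block_size), ns$N)
}

#' Average correlation matrices across subjects
#'
#' Element-wise arithmetic mean of per-subject Pearson matrices (the group
#' matrix the thresholds are applied to). A Fisher-z average
#' (`fisher = TRUE`) transforms to atanh, averages, and back-transforms.
#'
#' @param matrices list of same-shape numeric matrices
#' @param fisher average in Fisher-z space instead of raw r (default FALSE)
#' @return matrix of the same shape
#' @export
group_average <- function(matrices, fisher = FALSE) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("need at least one matrix")
  d <- dim(matrices[[1L]])
  for (m in matrices)
    if (!identical(dim(m), d)) stop("all matrices must have identical shape")
  if (fisher) {
    acc <- Reduce(`+`, lapply(matrices, function(m) {
      z <- atanh(pmin(pmax(m, -1 + 1e-15), 1 - 1e-15))
      z
    })) / length(matrices)
    out <- tanh(acc)
    # correlation diagonals are exactly 1; keep them so
    if (d[1L] == d[2L]) diag(out) <- mean(vapply(matrices, function(m) mean(diag(m)), 0))
    out
  } else {
    Reduce(`+`, matrices) / length(matrices)
  }
}

#' Lower sparsity bound from the average-degree rule
#'
#' For small-world estimates to be meaningful the average degree \eqn{k}
#' should exceed \eqn{\ln N}; with \eqn{S = k/(N-1)} this gives the lower
#' sparsity bound \eqn{S_1 = \ln(N) / (N-1)}.
#'
#' @param N node count, at least 3
#' @return sparsity fraction
#' @examples
#' 100 * sparsity_lower_bound(58523)  # 0.019 percent
#' @export
sparsity_lower_bound <- function(N) {
  if (!is.numeric(N) || N < 3) stop("N must be at least 3")
  log(N) / (N - 1)
}

#' Bonferroni-corrected critical correlation
#'
#' The smallest correlation significant at two-tailed level `alpha` after
#' Bonferroni correction over all \eqn{N(N-1)/2} node pairs, under the usual
#' t transform \eqn{t = r \sqrt{df / (1 - r^2)}} with \eqn{df = L - 2}.
#' Thresholding the group matrix at this value caps the sparsity at the
#' data-dependent upper bound.
#'
#' @param N node count (number of series compared pairwise)
#' @param L time-series length; df = L - 2
#' @param alpha family-wise two-tailed significance level
#' @return critical correlation in (0, 1)
#' @examples
#' round(bonferroni_threshold(58523, 215), 2)  # 0.43
#' @export
bonferroni_threshold <- function(N, L, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (L < 5) stop("need at least 5 time points")
  if (N < 2) stop("N must be at least 2")
  n_tests <- N * (N - 1) / 2
  a_per <- alpha / n_tests
  df <- L - 2
  tcrit <- stats::qt(a_per / 2, df = df, lower.tail = FALSE)
  tcrit / sqrt(df + tcrit^2)
}

#' Threshold a correlation matrix into a binary graph
#'
#' Edge (i, j), i != j, is present iff \eqn{R_{ij} >} `r_threshold` (strict).
#' The diagonal is ignored. The rule is applied verbatim for negative
#' thresholds too, in which case strongly negative correlations are excluded
#' and everything above the threshold becomes an edge.
#'
#' @param R symmetric correlation (or any score) matrix
#' @param r_threshold scalar cutoff
#' @return a `binary_graph` on `nrow(R)` nodes
#' @export
binarize <- function(R, r_threshold) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("R must be square")
  if (max(abs(R - t(R))) > 1e-9) stop("R must be symmetric (tolerance 1e-9)")
  N <- nrow(R)
  idx <- which(upper.tri(R) & R > r_threshold, arr.ind = TRUE)
  binary_graph(idx, N)
}
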