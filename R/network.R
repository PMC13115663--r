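## Heterogeneous network construction: weighted fusion of similarity views,
## block adjacency assembly, and random-walk-with-restart initial features.

#' Fuse similarity views by a convex weight combination
#'
#' Elementwise weighted sum of same-shaped similarity matrices; the weights
#' are one softmax group of the fusion parameterization, so the result is a
#' convex combination bounded by the elementwise max of the inputs.
#'
#' @param matrices list of similarity matrices over identical ids.
#' @param weights nonnegative weights of the same length (need not be
#'   normalized; they are renormalized to sum to 1).
#' @return fused similarity matrix.
#' @export
fuse_views <- function(matrices, weights) {
  stopifnot(length(matrices) == length(weights), length(matrices) >= 1,
            all(weights >= 0), sum(weights) > 0)
  ids <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(dim(m), dim(matrices[[1]])) ||
        !identical(rownames(m), ids))
      stop("fuse_views: id mismatch between views")
  }
  w <- weights / sum(weights)
  out <- matrix(0, nrow(matrices[[1]]), ncol(matrices[[1]]),
                dimnames = dimnames(matrices[[1]]))
  for (i in seq_along(matrices)) out <- out + w[i] * matrices[[i]]
  out
}

#' Build the heterogeneous adjacency matrix
#'
#' Block layout [[Mm, A], [A^T, Md]] with miRNA nodes first: the fused
#' miRNA similarity in the top-left, the fused disease similarity in the
#' bottom-right, and the (possibly masked) association matrix in the
#' off-diagonal blocks.
#'
#' @param Mm fused miRNA similarity (Nm x Nm).
#' @param Md fused disease similarity (Nd x Nd).
#' @param A association matrix (Nm x Nd).
#' @return (Nm+Nd) square adjacency matrix.
#' @export
build_adjacency <- function(Mm, Md, A) {
  if (nrow(Mm) != nrow(A) || nrow(Md) != ncol(A))
    stop("build_adjacency: dimension mismatch")
  rbind(cbind(Mm, A), cbind(t(A), Md))
}

#' Extract the blocks of a heterogeneous adjacency
#' @param M adjacency from [build_adjacency()].
#' @param n_mirna number of miRNA nodes (the leading block size).
#' @return list(Mm, Md, A).
#' @export
adjacency_blocks <- function(M, n_mirna) {
  n <- nrow(M)
  im <- seq_len(n_mirna)
  id <- (n_mirna + 1):n
  list(Mm = M[im, im, drop = FALSE], Md = M[id, id, drop = FALSE],
       A = M[im, id, drop = FALSE])
}

#' Random walk with restart node features
#'
#' For every node t, iterates D(k) = (1 - r) * An %*% D(k-1) + r * D(0)
#' with D(0) the one-hot vector of t and An the column-normalized
#' adjacency, until the Frobenius norm of the update falls below `tol`.
#' The converged stationary vectors (one column per seed node) form the
#' N x N initial feature matrix; every column sums to 1. Zero-degree nodes
#' receive a self-loop before normalization.
#'
#' @param M nonnegative adjacency matrix.
#' @param restart restart probability r in (0, 1]; default 0.5.
#' @param tol convergence tolerance on the Frobenius update norm.
#' @param max_iter iteration cap.
#' @return N x N feature matrix (column t = stationary distribution of the
#'   walk restarting at node t).
#' @export
rwr_features <- function(M, restart = 0.5, tol = 1e-6, max_iter = 1000) {
  stopifnot(restart > 0, restart <= 1, tol > 0)
  if (min(M) < 0) stop("rwr_features: adjacency must be nonnegative")
  deg <- colSums(M)
  if (any(deg == 0)) {
    idx <- which(deg == 0)
    M[cbind(idx, idx)] <- 1
    deg <- colSums(M)
  }
  An <- sweep(M, 2, deg, "/")
  n <- nrow(M)
  D0 <- diag(n)
  D <- D0
  for (k in seq_len(max_iter)) {
    Dnew <- (1 - restart) * (An %*% D) + restart * D0
    delta <- sqrt(sum((Dnew - D)^2))
    D <- Dnew
    if (delta <= tol) {
      dimnames(D) <- dimnames(M)
      return(D)
    }
  }
  stop("RWR did not converge within ", max_iter,
       " iterations (residual ", format(delta), ")")
}

#' Column-normalize an adjacency matrix (transition-matrix convention)
#' @param M nonnegative matrix; zero-degree columns get a self-loop.
#' @return column-stochastic matrix.
#' @export
column_normalize <- function(M) {
  deg <- colSums(M)
  if (any(deg == 0)) {
    idx <- which(deg == 0)
    M[cbind(idx, idx)] <- 1
    deg <- colSums(M)
  }
  sweep(M, 2, deg, "/")
}
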