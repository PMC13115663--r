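#' @keywords internal
#' @useDynLib mdanet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Numerical helpers shared across modules.

#' Softmax of a numeric vector
#'
#' Maps unconstrained raw weights to a simplex; used for the per-group
#' fusion weight parameterization (view weights and layer weights).
#'
#' @param x numeric vector of raw (unconstrained) values.
#' @return numeric vector of the same length, nonnegative, summing to 1.
#' @export
softmax <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  e <- exp(x - max(x))
  e / sum(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Symmetrize by averaging with the transpose (all similarity outputs pass
## through this so symmetry holds to machine precision).
symmetrize <- function(m) (m + t(m)) / 2

#' Validate a similarity matrix
#'
#' Checks the invariants every similarity view must satisfy: square,
#' symmetric within tolerance, entries in [0, 1], and (optionally) a unit
#' diagonal.
#'
#' @param m numeric matrix.
#' @param unit_diag require `diag(m) == 1`? Default `TRUE`.
#' @param tol symmetry tolerance.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
check_similarity_matrix <- function(m, unit_diag = TRUE, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("similarity matrix must be square")
  if (any(!is.finite(m)))
    stop("similarity matrix contains non-finite entries")
  if (max(abs(m - t(m))) > tol)
    stop("similarity matrix is not symmetric within tolerance ", tol)
  if (min(m) < -tol || max(m) > 1 + tol)
    stop("similarity entries outside [0, 1]")
  if (unit_diag && max(abs(diag(m) - 1)) > tol)
    stop("similarity diagonal is not 1")
  invisible(m)
}

## Derive a stream of child seeds from one integer seed, keeping everything
## below 2^31 so seeds remain valid R integers.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) + 1013904223L + 69069L * seq_len(n)) %% 2147483647L
}
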