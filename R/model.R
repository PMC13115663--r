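## The hybrid-attention graph model: efficient channel attention (ECA)
## recalibration of the input features, two graph convolution layers with a
## multi-head self-attention stage between them, adaptive (softmax) fusion
## of the two layer outputs, and an MLP scoring head over concatenated
## miRNA/disease embedding pairs.

#' Model configuration
#'
#' @param embed_dim embedding size per layer (divisible by `n_heads`).
#' @param n_heads number of self-attention heads.
#' @param n_layers number of graph convolution layers (the architecture is
#'   defined for 2; kept explicit for clarity).
#' @param mlp_hidden hidden width of the scoring MLP (the dimensionality of
#'   the pair representation).
#' @param ablate one of `"none"`, `"attention"` (drop ECA and multi-head
#'   self-attention), `"egcn"` (plain graph convolutions: drop the
#'   multi-head self-attention stage), `"multisource"` (single GIP view per
#'   node type in the fusion).
#' @param mha_residual add a residual connection around the multi-head
#'   self-attention stage (on by default: without it the near-uniform
#'   attention of early training collapses second-layer features toward
#'   the global mean embedding).
#' @param sym_norm_adjacency symmetrically normalize the heterogeneous
#'   adjacency (D^-1/2 M D^-1/2) before the graph convolutions; off by
#'   default (the convolutions use the fused adjacency as constructed).
#' @param lr,weight_decay,epochs optimizer settings (Adam).
#' @param restart,rwr_tol,rwr_max_iter random-walk-with-restart settings.
#' @param decay_mu semantic decay coefficient for the disease DAG view.
#' @param lambda_prime GIP bandwidth scale.
#' @param seed integer seed for parameter initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(embed_dim = 256, n_heads = 4, n_layers = 2,
                         mlp_hidden = 256, ablate = "none",
                         mha_residual = TRUE, sym_norm_adjacency = FALSE,
                         lr = 5e-4, weight_decay = 5e-4, epochs = 2000,
                         restart = 0.5, rwr_tol = 1e-6, rwr_max_iter = 1000,
                         decay_mu = 0.5, lambda_prime = 1, seed = 1L) {
  stopifnot(embed_dim %% n_heads == 0, n_layers >= 1,
            ablate %in% c("none", "attention", "egcn", "multisource"))
  structure(list(embed_dim = embed_dim, n_heads = n_heads,
                 n_layers = n_layers, mlp_hidden = mlp_hidden,
                 ablate = ablate, mha_residual = mha_residual,
                 sym_norm_adjacency = sym_norm_adjacency,
                 lr = lr, weight_decay = weight_decay, epochs = epochs,
                 restart = restart, rwr_tol = rwr_tol,
                 rwr_max_iter = rwr_max_iter, decay_mu = decay_mu,
                 lambda_prime = lambda_prime, seed = as.integer(seed)),
            class = "model_config")
}

#' Adaptive ECA kernel size for a given channel count
#'
#' Nearest odd integer to |log2(C)/2 + 1/2|, the standard adaptive rule for
#' efficient channel attention; at least 1.
#'
#' @param n_channels number of feature channels.
#' @return odd positive integer.
#' @export
eca_kernel_size <- function(n_channels) {
  t <- abs(log2(n_channels) / 2 + 0.5)
  k <- 2 * round((t - 1) / 2) + 1
  max(1L, as.integer(k))
}

glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize model parameters
#'
#' Seeded symmetric-uniform initialization scaled by fan-in/fan-out for all
#' dense weights; fusion logits start at zero (uniform softmax weights so
#' every view contributes equally before training).
#'
#' @param config a [model_config()].
#' @param n_in input feature dimension (number of RWR feature channels,
#'   equal to the node count).
#' @param n_views_mirna,n_views_disease number of similarity views entering
#'   the fusion on each side.
#' @return a named list of parameter arrays.
#' @export
init_params <- function(config, n_in, n_views_mirna = 5, n_views_disease = 3) {
  set.seed(config$seed)
  d <- config$embed_dim
  k <- eca_kernel_size(n_in)
  list(
    a_raw = rep(0, n_views_mirna),
    b_raw = rep(0, n_views_disease),
    g_raw = rep(0, 2),
    eca_kernel = stats::runif(k, -0.1, 0.1),
    W1 = glorot(n_in, d),
    Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
    WO = glorot(d, d),
    W2 = glorot(d, d),
    Wm1 = glorot(2 * d, config$mlp_hidden),
    bm1 = rep(0, config$mlp_hidden),
    wm2 = glorot(config$mlp_hidden, 1),
    ## numeric(1), not the literal 0: these arrays are updated in place by
    ## the optimizer and must never alias R's shared constants
    bm2 = numeric(1)
  )
}

## Zero-padded 1D convolution of a vector with a centered kernel.
conv1d_same <- function(z, kern) {
  k <- length(kern)
  half <- (k - 1) / 2
  n <- length(z)
  zp <- c(rep(0, half), z, rep(0, half))
  out <- numeric(n)
  for (t in seq_len(k)) out <- out + kern[t] * zp[t:(t + n - 1)]
  out
}

#' Efficient channel attention recalibration
#'
#' Per-channel weights are the sigmoid of a 1D convolution over the
#' channel-wise global average of the features; the output scales each
#' channel (column) of the input by its weight.
#'
#' @param X node-by-channel feature matrix.
#' @param kern 1D convolution kernel (odd length).
#' @return list with `out` (recalibrated features, same shape) and
#'   `weights` (per-channel attention in (0, 1)).
#' @export
eca_recalibrate <- function(X, kern) {
  z <- colMeans(X)
  w <- sigmoid(conv1d_same(z, kern))
  list(out = sweep(X, 2, w, "*"), weights = w)
}

#' One graph convolution layer: ReLU(M H W)
#'
#' @param M adjacency matrix of the heterogeneous network.
#' @param H input node features.
#' @param W layer weight matrix.
#' @return nonnegative feature matrix.
#' @export
gcn_layer <- function(M, H, W) {
  out <- relu(M %*% H %*% W)
  if (any(!is.finite(out))) stop("gcn_layer produced non-finite values")
  out
}

row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  e <- exp(S - mx)
  e / rowSums(e)
}

#' Multi-head self-attention over node features
#'
#' Per head i: Attention(H WiQ, H WiK, H WiV) with a row softmax of
#' Q K^T / sqrt(dk); head outputs are concatenated and linearly mixed by
#' WO. The per-head projections are stored as column blocks of `Wq`, `Wk`,
#' `Wv`.
#'
#' @param H node features (columns = embed_dim).
#' @param params list with `Wq`, `Wk`, `Wv`, `WO`.
#' @param n_heads number of heads (embed_dim divisible by it).
#' @param return_attention also return the per-head attention matrices.
#' @return feature matrix of the same shape as `H` (or a list when
#'   `return_attention` is `TRUE`).
#' @export
multi_head_self_attention <- function(H, params, n_heads = 4,
                                      return_attention = FALSE) {
  d <- ncol(H)
  stopifnot(d %% n_heads == 0)
  dk <- d / n_heads
  Q <- H %*% params$Wq
  K <- H %*% params$Wk
  V <- H %*% params$Wv
  O <- matrix(0, nrow(H), d)
  attn <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    P <- row_softmax(tcrossprod(Q[, cols, drop = FALSE],
                                K[, cols, drop = FALSE]) / sqrt(dk))
    O[, cols] <- P %*% V[, cols, drop = FALSE]
    attn[[h]] <- P
  }
  out <- O %*% params$WO
  if (return_attention) list(out = out, attention = attn) else out
}

#' Adaptive fusion of two layer outputs
#'
#' gamma1 * H1 + gamma2 * H2 with (gamma1, gamma2) the softmax of the raw
#' layer weights, so the fusion is a convex combination.
#'
#' @param H1,H2 same-shaped feature matrices.
#' @param gamma_raw length-2 raw (unconstrained) layer weights.
#' @return fused feature matrix.
#' @export
adaptive_fuse <- function(H1, H2, gamma_raw) {
  if (!identical(dim(H1), dim(H2))) stop("adaptive_fuse: shape mismatch")
  g <- softmax(gamma_raw)
  g[1] * H1 + g[2] * H2
}

#' Score miRNA-disease pairs from fused node embeddings
#'
#' The pair representation is the concatenation of the miRNA embedding row
#' and the disease embedding row (disease nodes follow the miRNA block),
#' passed through a one-hidden-layer MLP with ReLU and a sigmoid output.
#'
#' @param H fused node embeddings ((Nm+Nd) x embed_dim).
#' @param pairs two-column integer matrix of (miRNA index, disease index),
#'   1-based within each entity type.
#' @param params list with `Wm1`, `bm1`, `wm2`, `bm2`.
#' @param n_mirna number of miRNA nodes.
#' @return numeric vector of scores strictly inside (0, 1).
#' @export
score_pairs <- function(H, pairs, params, n_mirna) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  n_disease <- nrow(H) - n_mirna
  if (any(pairs[, 1] < 1 | pairs[, 1] > n_mirna |
          pairs[, 2] < 1 | pairs[, 2] > n_disease))
    stop("score_pairs: pair index out of range")
  E <- cbind(H[pairs[, 1], , drop = FALSE],
             H[n_mirna + pairs[, 2], , drop = FALSE])
  Z <- relu(sweep(E %*% params$Wm1, 2, params$bm1, "+"))
  as.vector(sigmoid(Z %*% params$wm2 + params$bm2))
}

#' Binary cross-entropy loss
#'
#' Mean of -[y ln s + (1 - y) ln(1 - s)] with scores clipped to
#' [1e-7, 1 - 1e-7] before the logarithms.
#'
#' @param labels 0/1 vector.
#' @param scores predicted probabilities.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(labels, scores) {
  if (length(labels) == 0) stop("bce_loss: empty pair set")
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  s <- pmin(pmax(scores, 1e-7), 1 - 1e-7)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

#' Full forward pass: adjacency + features -> pair scores
#'
#' Composition: ECA recalibration, first graph convolution, multi-head
#' self-attention, second graph convolution, adaptive layer fusion, MLP
#' pair scoring. Ablation flags in the config replace the attention stages
#' with identity pass-throughs.
#'
#' @param M heterogeneous adjacency.
#' @param X initial node features (RWR output).
#' @param params parameters from [init_params()].
#' @param pairs two-column (miRNA, disease) index matrix.
#' @param config a [model_config()].
#' @param n_mirna number of miRNA nodes.
#' @return numeric score vector, one per queried pair.
#' @export
forward <- function(M, X, params, pairs, config, n_mirna) {
  use_eca <- config$ablate != "attention"
  use_mha <- !(config$ablate %in% c("attention", "egcn"))
  Xa <- if (use_eca) eca_recalibrate(X, params$eca_kernel)$out else X
  H1 <- gcn_layer(M, Xa, params$W1)
  Hmh <- if (use_mha) {
    mh <- multi_head_self_attention(H1, params, config$n_heads)
    if (config$mha_residual) mh + H1 else mh
  } else H1
  H2 <- gcn_layer(M, Hmh, params$W2)
  H <- adaptive_fuse(H1, H2, params$g_raw)
  score_pairs(H, pairs, params, n_mirna)
}
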