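## Training engine: cached forward pass, reverse-mode gradients for every
## parameter (including the softmax-parameterized view-fusion weights,
## whose gradients flow through the fused similarity blocks of the
## adjacency used in both graph convolutions), and an Adam optimizer.
## The backward pass is verified against finite differences in the test
## suite.

fused_adjacency <- function(views_m, views_d, A, alpha, beta) {
  Mm <- Reduce(`+`, Map(`*`, views_m, alpha))
  Md <- Reduce(`+`, Map(`*`, views_d, beta))
  build_adjacency(Mm, Md, A)
}

## Optional symmetric normalization D^-1/2 M D^-1/2 of the propagation
## matrix. Returns the matrix actually used in the convolutions plus the
## elementwise scale needed to map adjacency gradients back onto the fused
## similarity entries (the degree vector is treated as a constant in the
## backward pass).
propagation_matrix <- function(M, config) {
  if (!isTRUE(config$sym_norm_adjacency)) return(list(M = M, scale = NULL))
  dinv <- 1 / sqrt(pmax(rowSums(M), 1e-12))
  scale <- outer(dinv, dinv)
  list(M = M * scale, scale = scale)
}

## Forward pass retaining every intermediate needed by the backward pass.
forward_cache <- function(M, X, params, pairs, config, n_mirna) {
  use_eca <- config$ablate != "attention"
  use_mha <- !(config$ablate %in% c("attention", "egcn"))
  d <- config$embed_dim
  nh <- config$n_heads
  dk <- d / nh

  if (use_eca) {
    z <- colMeans(X)
    p_conv <- conv1d_same(z, params$eca_kernel)
    w_eca <- sigmoid(p_conv)
    Xa <- sweep(X, 2, w_eca, "*")
  } else {
    z <- NULL; w_eca <- NULL; Xa <- X
  }

  U1 <- M %*% Xa
  P1 <- U1 %*% params$W1
  H1 <- relu(P1)

  if (use_mha) {
    Q <- H1 %*% params$Wq
    K <- H1 %*% params$Wk
    V <- H1 %*% params$Wv
    O <- matrix(0, nrow(H1), d)
    Pheads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      P <- row_softmax(tcrossprod(Q[, cols, drop = FALSE],
                                  K[, cols, drop = FALSE]) / sqrt(dk))
      Pheads[[h]] <- P
      O[, cols] <- P %*% V[, cols, drop = FALSE]
    }
    Hmh <- O %*% params$WO
    if (config$mha_residual) Hmh <- Hmh + H1
  } else {
    Q <- K <- V <- O <- NULL; Pheads <- NULL
    Hmh <- H1
  }

  U2 <- M %*% Hmh
  P2 <- U2 %*% params$W2
  H2 <- relu(P2)

  g <- softmax(params$g_raw)
  H <- g[1] * H1 + g[2] * H2

  E <- cbind(H[pairs[, 1], , drop = FALSE],
             H[n_mirna + pairs[, 2], , drop = FALSE])
  Zpre <- sweep(E %*% params$Wm1, 2, params$bm1, "+")
  Z <- relu(Zpre)
  logit <- as.vector(Z %*% params$wm2 + params$bm2)
  s <- sigmoid(logit)

  list(use_eca = use_eca, use_mha = use_mha, d = d, nh = nh, dk = dk,
       z = z, w_eca = w_eca, Xa = Xa, U1 = U1, P1 = P1, H1 = H1,
       Q = Q, K = K, V = V, O = O, Pheads = Pheads, Hmh = Hmh,
       U2 = U2, P2 = P2, H2 = H2, g = g, H = H,
       E = E, Zpre = Zpre, Z = Z, scores = s)
}

## Jacobian-vector product of a softmax group: d loss / d raw given
## d loss / d softmax output.
softmax_backward <- function(w, dw) w * (dw - sum(dw * w))

backward <- function(cache, M, X, params, pairs, labels, config, n_mirna,
                     views_m, views_d, alpha, beta, dM_scale = NULL) {
  n <- length(labels)
  d <- cache$d
  grads <- list()

  dlogit <- (cache$scores - labels) / n
  grads$wm2 <- crossprod(cache$Z, dlogit)
  grads$bm2 <- sum(dlogit)
  dZ <- (dlogit %*% t(params$wm2)) * (cache$Zpre > 0)
  grads$Wm1 <- crossprod(cache$E, dZ)
  grads$bm1 <- colSums(dZ)
  dE <- tcrossprod(dZ, params$Wm1)

  ## scatter-add the pair-row gradients back onto the node embeddings
  dH <- matrix(0, nrow(cache$H), d)
  rs_m <- rowsum(dE[, 1:d, drop = FALSE], pairs[, 1])
  rs_d <- rowsum(dE[, (d + 1):(2 * d), drop = FALSE], pairs[, 2])
  dH[as.integer(rownames(rs_m)), ] <- rs_m
  dd <- n_mirna + as.integer(rownames(rs_d))
  dH[dd, ] <- dH[dd, , drop = FALSE] + rs_d

  g <- cache$g
  dgam <- c(sum(dH * cache$H1), sum(dH * cache$H2))
  grads$g_raw <- softmax_backward(g, dgam)
  dH1 <- g[1] * dH
  dH2 <- g[2] * dH

  ## second graph convolution
  dP2 <- dH2 * (cache$P2 > 0)
  grads$W2 <- crossprod(cache$U2, dP2)
  dU2 <- tcrossprod(dP2, params$W2)
  dM <- tcrossprod(dU2, cache$Hmh)
  dHmh <- crossprod(M, dU2)

  ## multi-head self-attention
  if (cache$use_mha) {
    if (config$mha_residual) dH1 <- dH1 + dHmh
    grads$WO <- crossprod(cache$O, dHmh)
    dO <- tcrossprod(dHmh, params$WO)
    dQ <- matrix(0, nrow(dH1), d)
    dK <- matrix(0, nrow(dH1), d)
    dV <- matrix(0, nrow(dH1), d)
    for (h in seq_len(cache$nh)) {
      cols <- ((h - 1) * cache$dk + 1):(h * cache$dk)
      P <- cache$Pheads[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cache$V[, cols, drop = FALSE]
      dP <- tcrossprod(dOh, Vh)
      dV[, cols] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(cache$dk)
      dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(cache$dk)
    }
    grads$Wq <- crossprod(cache$H1, dQ)
    grads$Wk <- crossprod(cache$H1, dK)
    grads$Wv <- crossprod(cache$H1, dV)
    dH1 <- dH1 + tcrossprod(dQ, params$Wq) + tcrossprod(dK, params$Wk) +
      tcrossprod(dV, params$Wv)
  } else {
    dH1 <- dH1 + dHmh
  }

  ## first graph convolution
  dP1 <- dH1 * (cache$P1 > 0)
  grads$W1 <- crossprod(cache$U1, dP1)
  dU1 <- tcrossprod(dP1, params$W1)
  dM <- dM + tcrossprod(dU1, cache$Xa)
  dXa <- crossprod(M, dU1)

  ## ECA recalibration (input features X are constants)
  if (cache$use_eca) {
    dw <- colSums(dXa * X)
    dp <- dw * cache$w_eca * (1 - cache$w_eca)
    k <- length(params$eca_kernel)
    half <- (k - 1) / 2
    zp <- c(rep(0, half), cache$z, rep(0, half))
    nC <- length(cache$z)
    grads$eca_kernel <- vapply(seq_len(k), function(t)
      sum(dp * zp[t:(t + nC - 1)]), numeric(1))
  }

  ## fusion weights via the similarity blocks of the adjacency
  if (!is.null(dM_scale)) dM <- dM * dM_scale
  nm <- n_mirna
  nn <- nrow(M)
  dMm <- dM[1:nm, 1:nm, drop = FALSE]
  dMd <- dM[(nm + 1):nn, (nm + 1):nn, drop = FALSE]
  dalpha <- vapply(views_m, function(v) sum(dMm * v), numeric(1))
  dbeta <- vapply(views_d, function(v) sum(dMd * v), numeric(1))
  grads$a_raw <- softmax_backward(alpha, dalpha)
  grads$b_raw <- softmax_backward(beta, dbeta)

  grads
}

## Weight decay applies to dense weights only, not to fusion logits,
## biases, or the ECA kernel.
.decayed <- c("W1", "W2", "Wq", "Wk", "Wv", "WO", "Wm1", "wm2")

## The optimizer state lives on one flat vector to keep per-epoch
## allocation overhead small; parameter arrays are refreshed from slices.
adam_init <- function(params) {
  sizes <- vapply(params, length, integer(1))
  ends <- cumsum(sizes)
  starts0 <- ends - sizes  # 0-based slice starts for the C++ kernels
  names(starts0) <- names(params)
  decay_mask <- numeric(sum(sizes))
  for (nm in intersect(.decayed, names(params)))
    decay_mask[(starts0[nm] + 1):ends[nm]] <- 1
  list(pvec = unlist(params, use.names = FALSE),
       m = numeric(sum(sizes)), v = numeric(sum(sizes)), t = 0,
       g = numeric(sum(sizes)), starts0 = starts0,
       decay_mask = decay_mask)
}

## The parameter arrays, the flat vectors, and the moment estimates are all
## private to the training loop, so the C++ kernels update them in place.
adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  scatter_grads_cpp(state$g, grads,
                    as.integer(state$starts0[names(grads)]))
  state$t <- state$t + 1
  adam_update_cpp(state$pvec, state$m, state$v, state$g, state$decay_mask,
                  lr, weight_decay, state$t, beta1, beta2, eps)
  gather_params_cpp(params, state$pvec, as.integer(state$starts0),
                    match(names(grads), names(params)) - 1L)
  list(params = params, state = state)
}

#' Train the model on a fixed set of labelled pairs
#'
#' Builds the uniform-weight heterogeneous adjacency, computes the
#' random-walk-with-restart features once from it (they are treated as
#' constants thereafter), then runs full-batch Adam over the binary
#' cross-entropy. The fused adjacency is rebuilt from the current softmax
#' view weights at every epoch, so the fusion weights receive gradients
#' through both graph convolutions.
#'
#' @param views_m list of miRNA similarity matrices (fusion order:
#'   functional, GIP, lncRNA, sequence, family).
#' @param views_d list of disease similarity matrices (semantic, GIP,
#'   lncRNA).
#' @param A_train association matrix with test-fold positives already
#'   masked out.
#' @param pairs two-column (miRNA, disease) index matrix of training pairs.
#' @param labels 0/1 labels for `pairs`.
#' @param config a [model_config()].
#' @return a `mdanet_fit`: final parameters, the RWR feature matrix, the
#'   per-epoch loss, the fusion-weight trajectory, and the training inputs
#'   needed for scoring.
#' @export
train_model <- function(views_m, views_d, A_train, pairs, labels, config) {
  if (config$ablate == "multisource") {
    views_m <- views_m["gip"]
    views_d <- views_d["gip"]
  }
  n_mirna <- nrow(A_train)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  stopifnot(nrow(pairs) == length(labels), all(labels %in% c(0, 1)))

  nvm <- length(views_m)
  nvd <- length(views_d)
  M0 <- fused_adjacency(views_m, views_d, A_train,
                        rep(1 / nvm, nvm), rep(1 / nvd, nvd))
  X <- rwr_features(M0, config$restart, config$rwr_tol, config$rwr_max_iter)

  params <- init_params(config, n_in = ncol(X),
                        n_views_mirna = nvm, n_views_disease = nvd)
  ## force fresh allocations: the optimizer updates these arrays in place,
  ## so none of them may alias a shared object (e.g. a constant-folded
  ## rep(0, n) from the initializer's constant pool)
  params <- lapply(params, function(p) p + 0)
  state <- adam_init(params)

  ## adjacency template: the association blocks never change, only the
  ## fused similarity blocks are refreshed each epoch
  nn <- n_mirna + ncol(A_train)
  im <- seq_len(n_mirna)
  id <- (n_mirna + 1):nn
  Mtmpl <- matrix(0, nn, nn)
  Mtmpl[im, id] <- A_train
  Mtmpl[id, im] <- t(A_train)

  loss_hist <- numeric(config$epochs)
  weight_hist <- matrix(NA_real_, config$epochs, nvm + nvd + 2)
  colnames(weight_hist) <- c(paste0("alpha_", names(views_m)),
                             paste0("beta_", names(views_d)),
                             "gamma_1", "gamma_2")

  for (epoch in seq_len(config$epochs)) {
    alpha <- softmax(params$a_raw)
    beta <- softmax(params$b_raw)
    Mtmpl[im, im] <- Reduce(`+`, Map(`*`, views_m, alpha))
    Mtmpl[id, id] <- Reduce(`+`, Map(`*`, views_d, beta))
    prop <- propagation_matrix(Mtmpl, config)
    M <- prop$M
    cache <- forward_cache(M, X, params, pairs, config, n_mirna)
    loss_hist[epoch] <- bce_loss(labels, cache$scores)
    if (!is.finite(loss_hist[epoch]))
      stop("training diverged at epoch ", epoch, " (non-finite loss)")
    grads <- backward(cache, M, X, params, pairs, labels, config, n_mirna,
                      views_m, views_d, alpha, beta, prop$scale)
    upd <- adam_step(params, grads, state, config$lr, config$weight_decay)
    params <- upd$params
    state <- upd$state
    weight_hist[epoch, ] <- c(alpha, beta, softmax(params$g_raw))
  }

  structure(list(params = params, X = X, config = config,
                 views_m = views_m, views_d = views_d, A_train = A_train,
                 n_mirna = n_mirna, loss = loss_hist,
                 weights = weight_hist),
            class = "mdanet_fit")
}

#' Score miRNA-disease pairs with a trained model
#'
#' @param fit a `mdanet_fit` from [train_model()].
#' @param pairs two-column (miRNA, disease) index matrix.
#' @return numeric score vector in (0, 1).
#' @export
predict_pairs <- function(fit, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  M <- propagation_matrix(
    fused_adjacency(fit$views_m, fit$views_d, fit$A_train,
                    softmax(fit$params$a_raw), softmax(fit$params$b_raw)),
    fit$config)$M
  forward(M, fit$X, fit$params, pairs, fit$config, fit$n_mirna)
}

#' Score the full miRNA x disease grid with a trained model
#'
#' @param fit a `mdanet_fit`.
#' @return Nm x Nd score matrix (dimnames from the training association
#'   matrix).
#' @export
predict_matrix <- function(fit) {
  nm <- fit$n_mirna
  nd <- ncol(fit$A_train)
  grid <- cbind(rep(seq_len(nm), nd), rep(seq_len(nd), each = nm))
  s <- matrix(predict_pairs(fit, grid), nm, nd)
  dimnames(s) <- dimnames(fit$A_train)
  s
}
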