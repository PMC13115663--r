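test_that("ECA recalibration preserves shape and degenerates correctly", {
  set.seed(51)
  X <- matrix(rnorm(20 * 7), 20, 7)
  kern <- runif(3, -1, 1)
  out <- eca_recalibrate(X, kern)
  expect_identical(dim(out$out), dim(X))
  expect_true(all(out$weights > 0 & out$weights < 1))
  # zero input with a zero kernel: weights sigmoid(0) = 0.5, output 0
  z <- eca_recalibrate(X * 0, kern * 0)
  expect_equal(unname(z$weights), rep(0.5, 7))
  expect_true(all(z$out == 0))
})

test_that("graph convolution layer is ReLU(M H W)", {
  set.seed(52)
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(diag(4), H, diag(3)), pmax(H, 0), ignore_attr = TRUE)
  M <- matrix(runif(16), 4)
  W <- matrix(rnorm(9), 3)
  out <- gcn_layer(M, H, W)
  expect_true(all(out >= 0))
  # explicit 2x2 hand evaluation
  M2 <- matrix(c(1, 2, 0, 1), 2)
  H2 <- matrix(c(1, -1, 2, 0), 2)
  W2 <- matrix(c(1, 0, 0, -1), 2)
  expect_equal(gcn_layer(M2, H2, W2),
               pmax(M2 %*% H2 %*% W2, 0), ignore_attr = TRUE)
})

test_that("multi-head self-attention rows are stochastic and symmetric in inputs", {
  set.seed(53)
  cfg <- tiny_config()
  p <- init_params(cfg, n_in = 5)
  H <- matrix(rnorm(6 * 8), 6, 8)
  res <- multi_head_self_attention(H, p, n_heads = 2, return_attention = TRUE)
  expect_identical(dim(res$out), dim(H))
  for (P in res$attention) {
    expect_equal(unname(rowSums(P)), rep(1, 6), tolerance = 1e-6)
    expect_true(all(P >= 0))
  }
  # a single row attends only to itself: output = H Wv WO
  H1 <- H[1, , drop = FALSE]
  expect_equal(multi_head_self_attention(H1, p, 2),
               H1 %*% p$Wv %*% p$WO, tolerance = 1e-12)
  # identical rows produce identical outputs
  Hsame <- H[rep(1, 4), ]
  out <- multi_head_self_attention(Hsame, p, 2)
  expect_equal(out[rep(1, 4), ], out, tolerance = 1e-12)
})

test_that("adaptive fusion is convex in the two layer outputs", {
  set.seed(54)
  H1 <- matrix(rnorm(12), 4)
  H2 <- matrix(rnorm(12), 4)
  # strongly one-sided raw weights recover the first input
  expect_equal(adaptive_fuse(H1, H2, c(60, -60)), H1, tolerance = 1e-12)
  expect_equal(adaptive_fuse(H1, H2, c(0, 0)), (H1 + H2) / 2)
  f <- adaptive_fuse(H1, H2, c(0.3, -1.2))
  expect_true(all(f >= pmin(H1, H2) - 1e-12 & f <= pmax(H1, H2) + 1e-12))
  expect_error(adaptive_fuse(H1, H2[1:2, ]), "shape mismatch")
})

test_that("pair scoring is sigmoid-bounded, deterministic and order-equivariant", {
  set.seed(55)
  cfg <- tiny_config()
  p <- init_params(cfg, n_in = 5)
  H <- matrix(rnorm(7 * 8), 7, 8)  # 4 miRNAs + 3 diseases
  pairs <- cbind(c(1, 2, 4), c(3, 1, 2))
  s <- score_pairs(H, pairs, p, n_mirna = 4)
  expect_true(all(s > 0 & s < 1))
  expect_identical(score_pairs(H, pairs, p, 4), s)
  # swapping two queried pairs permutes the two outputs
  s2 <- score_pairs(H, pairs[c(2, 1, 3), ], p, 4)
  expect_identical(s2, s[c(2, 1, 3)])
  expect_error(score_pairs(H, cbind(5, 1), p, 4), "out of range")
})

test_that("binary cross-entropy matches its analytic values and a scalar loop", {
  expect_equal(bce_loss(c(1, 0, 1), rep(0.5, 3)), log(2), tolerance = 1e-12)
  y <- c(1, 0, 1, 0)
  expect_lt(bce_loss(y, y), 1e-6)
  set.seed(56)
  lab <- rbinom(50, 1, 0.5)
  sc <- runif(50)
  manual <- 0
  for (i in 1:50)
    manual <- manual - (lab[i] * log(sc[i]) + (1 - lab[i]) * log(1 - sc[i]))
  expect_equal(bce_loss(lab, sc), manual / 50, tolerance = 1e-12)
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
})

test_that("forward pass is deterministic and respects the layer-fusion weights", {
  prob <- tiny_problem()
  cfg <- tiny_config()
  nm <- nrow(prob$A)
  M <- build_adjacency(prob$views_m$functional, prob$views_d$semantic, prob$A)
  X <- rwr_features(M)
  p <- init_params(cfg, n_in = ncol(X))
  pairs <- cbind(c(1, 2, 3), c(1, 2, 3))
  s1 <- forward(M, X, p, pairs, cfg, nm)
  s2 <- forward(M, X, p, pairs, cfg, nm)
  expect_identical(s1, s2)
  expect_length(s1, 3)

  # with the second layer weighted out, W2 cannot influence the scores
  p$g_raw <- c(60, -60)
  base <- forward(M, X, p, pairs, cfg, nm)
  p$W2 <- p$W2 * 0 + 5
  expect_equal(forward(M, X, p, pairs, cfg, nm), base, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on every parameter", {
  prob <- tiny_problem()
  cfg <- tiny_config()
  nm <- nrow(prob$A)
  pairs <- cbind(c(1, 2, 3, 4, 1), c(1, 2, 3, 1, 2))
  labels <- c(1, 0, 1, 0, 1)
  M0 <- mdanet:::fused_adjacency(prob$views_m, prob$views_d, prob$A,
                                 rep(0.2, 5), rep(1 / 3, 3))
  X <- rwr_features(M0)
  params <- init_params(cfg, n_in = ncol(X))

  loss_at <- function(p) {
    al <- softmax(p$a_raw)
    be <- softmax(p$b_raw)
    M <- mdanet:::fused_adjacency(prob$views_m, prob$views_d, prob$A, al, be)
    cache <- mdanet:::forward_cache(M, X, p, pairs, cfg, nm)
    bce_loss(labels, cache$scores)
  }
  al <- softmax(params$a_raw)
  be <- softmax(params$b_raw)
  M <- mdanet:::fused_adjacency(prob$views_m, prob$views_d, prob$A, al, be)
  cache <- mdanet:::forward_cache(M, X, params, pairs, cfg, nm)
  grads <- mdanet:::backward(cache, M, X, params, pairs, labels, cfg, nm,
                             prob$views_m, prob$views_d, al, be)
  eps <- 1e-6
  set.seed(57)
  for (nmn in names(grads)) {
    idx <- sample(length(params[[nmn]]), min(6, length(params[[nmn]])))
    for (i in idx) {
      up <- params; up[[nmn]][i] <- up[[nmn]][i] + eps
      dn <- params; dn[[nmn]][i] <- dn[[nmn]][i] - eps
      numeric_grad <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      analytic <- grads[[nmn]][i]
      if (abs(numeric_grad) + abs(analytic) > 1e-6) {
        expect_lt(abs(numeric_grad - analytic) /
                    (abs(numeric_grad) + abs(analytic)), 1e-4,
                  label = paste("relative gradient error for", nmn))
      }
    }
  }
})

test_that("ablation switches reduce the forward pass as specified", {
  prob <- tiny_problem()
  nm <- nrow(prob$A)
  M <- build_adjacency(prob$views_m$functional, prob$views_d$semantic, prob$A)
  X <- rwr_features(M)
  pairs <- cbind(c(1, 3), c(2, 1))

  # without attention stages the model is a plain two-layer GCN + MLP
  cfg <- tiny_config(ablate = "attention")
  p <- init_params(cfg, n_in = ncol(X))
  H1 <- gcn_layer(M, X, p$W1)
  H2 <- gcn_layer(M, H1, p$W2)
  H <- adaptive_fuse(H1, H2, p$g_raw)
  expect_equal(forward(M, X, p, pairs, cfg, nm),
               score_pairs(H, pairs, p, nm), tolerance = 1e-12)

  # without the enhanced convolution the ECA stage is kept but the
  # self-attention stage disappears
  cfg2 <- tiny_config(ablate = "egcn")
  Xa <- eca_recalibrate(X, p$eca_kernel)$out
  H1b <- gcn_layer(M, Xa, p$W1)
  H2b <- gcn_layer(M, H1b, p$W2)
  Hb <- adaptive_fuse(H1b, H2b, p$g_raw)
  expect_equal(forward(M, X, p, pairs, cfg2, nm),
               score_pairs(Hb, pairs, p, nm), tolerance = 1e-12)
})

test_that("ECA kernel size follows the adaptive odd rule", {
  expect_identical(eca_kernel_size(256), 5L)
  expect_identical(eca_kernel_size(160), 5L)
  expect_identical(eca_kernel_size(64), 3L)
  expect_true(eca_kernel_size(2) %% 2 == 1)
})
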