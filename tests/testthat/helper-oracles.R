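# Independent oracles and small fixtures shared across tests. The oracles
# are deliberately naive (dynamic programming, O(n^2) loops, direct linear
# solves) and never call the code paths they check.

# Levenshtein distance by the textbook dynamic program.
edit_distance_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  d <- matrix(0, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1, m + 1]
}

# AUC as the exhaustive fraction of concordant positive-negative pairs,
# ties counted one half.
auc_concordance <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (q in sn)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# A random valid similarity matrix (symmetric, unit diagonal, [0, 1]).
random_similarity <- function(n, ids = paste0("x", seq_len(n))) {
  s <- matrix(runif(n * n), n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(ids, ids)
  s
}

# Two chain-DAG diseases sharing one parent term plus a third disjoint
# disease: the worked fixture for the semantic similarity equations.
toy_dag_set <- function() {
  edges <- data.frame(
    disease = c("d1", "d2", "d3"),
    child = c("d1", "d2", "d3"),
    parent = c("t", "t", "u"))
  build_dag_set(edges, c("d1", "d2", "d3"))
}

# A small training problem (views, masked matrix, pairs) for model-level
# tests; kept tiny so gradient checks and determinism tests run fast.
tiny_problem <- function(nm = 4, nd = 3, seed = 42) {
  set.seed(seed)
  repeat {
    A <- matrix(rbinom(nm * nd, 1, 0.4), nm, nd,
                dimnames = list(paste0("m", seq_len(nm)),
                                paste0("d", seq_len(nd))))
    if (sum(A) >= 2 && sum(A == 0) >= 2) break
  }
  vm <- list(functional = random_similarity(nm, rownames(A)),
             gip = random_similarity(nm, rownames(A)),
             lncrna = random_similarity(nm, rownames(A)),
             sequence = random_similarity(nm, rownames(A)),
             family = random_similarity(nm, rownames(A)))
  vd <- list(semantic = random_similarity(nd, colnames(A)),
             gip = random_similarity(nd, colnames(A)),
             lncrna = random_similarity(nd, colnames(A)))
  list(A = A, views_m = vm, views_d = vd)
}

tiny_config <- function(...) {
  model_config(embed_dim = 8, n_heads = 2, mlp_hidden = 6, epochs = 3,
               seed = 7, ...)
}

small_bundle <- function(seed = 5, ...) {
  generate_bundle(synthetic_config(n_mirna = 30, n_disease = 20,
                                   n_blocks = 3, seed = seed, ...))
}

small_model_config <- function(...) {
  model_config(embed_dim = 32, n_heads = 4, mlp_hidden = 32, seed = 2, ...)
}
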