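test_that("fold plans partition positives with disjoint 1:1 negatives", {
  set.seed(61)
  A <- matrix(0, 6, 5, dimnames = list(paste0("m", 1:6), paste0("d", 1:5)))
  A[sample(30, 10)] <- 1
  plan <- make_folds(A, k = 5, seed = 3)
  sizes <- vapply(plan$folds, function(f) nrow(f$test_pos), integer(1))
  expect_identical(sizes, rep(2L, 5))

  all_test <- do.call(rbind, lapply(plan$folds, `[[`, "test_pos"))
  expect_identical(nrow(unique(all_test)), 10L)
  expect_true(all(A[all_test] == 1))

  # negatives come from zero entries only and never collide across roles
  for (f in plan$folds) {
    expect_true(all(A[f$test_neg] == 0))
    expect_true(all(A[f$train_neg] == 0))
    both <- rbind(f$test_neg, f$train_neg)
    expect_identical(nrow(unique(both)), nrow(both))
    expect_identical(nrow(f$test_neg), nrow(f$test_pos))
  }

  expect_identical(make_folds(A, 5, 3), plan)          # seeded determinism
  expect_false(identical(make_folds(A, 5, 4), plan))
  expect_error(make_folds(matrix(1, 3, 3), 2), "zero entries")
})

test_that("masking removes exactly the test positives and is reversible", {
  set.seed(62)
  A <- matrix(as.numeric(rbinom(40, 1, 0.4)), 8, 5,
              dimnames = list(paste0("m", 1:8), paste0("d", 1:5)))
  plan <- make_folds(A, k = 4, seed = 1)
  fold <- plan$folds[[2]]
  Am <- mask_test_associations(A, fold)
  expect_equal(sum(Am), sum(A) - nrow(fold$test_pos))
  restored <- Am
  restored[fold$test_pos] <- 1
  expect_identical(restored, A)
  # masked GIP differs from full GIP whenever the fold is non-empty
  expect_gt(max(abs(gip_kernel(Am, "mirna") - gip_kernel(A, "mirna"))), 0)
})

test_that("evaluation metrics match their definitions and the pairwise oracle", {
  perfect <- evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)
  expect_equal(perfect$acc, 1)

  expect_equal(evaluate(c(0.4, 0.6), c(1, 0))$auc, 0)

  set.seed(63)
  for (n in c(6, 37, 200)) {
    lab <- c(1, 0, rbinom(n - 2, 1, 0.4))
    sc <- round(runif(n), 2)  # induce ties
    expect_identical(evaluate(sc, lab)$auc, auc_concordance(sc, lab))
  }

  # permutation invariance
  lab <- rbinom(40, 1, 0.5); lab[1] <- 1; lab[2] <- 0
  sc <- runif(40)
  p <- sample(40)
  expect_equal(evaluate(sc[p], lab[p]), evaluate(sc, lab))
  expect_error(evaluate(runif(4), rep(1, 4)), "both classes")
})

test_that("AUC and AUPR agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  lab <- c(1, 0, rbinom(60, 1, 0.4))
  sc <- runif(62)
  got <- evaluate(sc, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got$auc, ref, tolerance = 1e-12)
})

test_that("no held-out positive reaches any training-time quantity", {
  b <- small_bundle(seed = 9)
  plan <- make_folds(b$A, k = 3, seed = 2)
  for (fold in plan$folds) {
    Am <- mask_test_associations(b$A, fold)
    # the masked matrix driving GIP/adjacency/RWR has zeros at test pairs
    expect_true(all(Am[fold$test_pos] == 0))
    # no training pair coincides with a held-out pair
    tr <- rbind(fold$train_pos, fold$train_neg)
    te <- rbind(fold$test_pos, fold$test_neg)
    key <- function(p) paste(p[, 1], p[, 2])
    expect_length(intersect(key(tr), key(te)), 0)
    # the adjacency and RWR input contain the masked matrix, not A
    v <- compute_views(b, A = Am)
    M <- build_adjacency(fuse_views(v$mirna, rep(0.2, 5)),
                         fuse_views(v$disease, rep(1 / 3, 3)), Am)
    blocks <- adjacency_blocks(M, b$index$n_mirna)
    expect_true(all(blocks$A[fold$test_pos] == 0))
  }
})

test_that("cross-validation is reproducible and training reduces the loss", {
  b <- small_bundle(seed = 5)
  cfg <- small_model_config(epochs = 200)
  r1 <- run_cv(b, cfg, k = 3, seed = 11)
  r2 <- run_cv(b, cfg, k = 3, seed = 11)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_true(all(r1$per_fold$auc >= 0 & r1$per_fold$auc <= 1))
  expect_true(all(r1$per_fold$aupr >= 0 & r1$per_fold$aupr <= 1))
  for (l in r1$loss) expect_lt(l[200], l[1])
})

test_that("ablation variants alter exactly what they claim", {
  b <- small_bundle(seed = 5)
  cfg <- small_model_config(epochs = 20)
  full <- run_cv(b, cfg, k = 2, seed = 3)
  none <- run_ablation(b, "none", cfg, k = 2, seed = 3)
  expect_identical(full$per_fold, none$per_fold)

  # the multisource ablation trains on a single GIP view per node type
  v <- compute_views(b)
  fit <- train_model(v$mirna, v$disease, b$A,
                     cbind(c(1, 2), c(1, 2)), c(1, 0),
                     small_model_config(epochs = 2, ablate = "multisource"))
  expect_identical(names(fit$views_m), "gip")
  expect_identical(names(fit$views_d), "gip")
  expect_error(run_ablation(b, "nonsense", cfg), "variant")
})

test_that("disease hold-out ranking excludes the target and recovers its block", {
  # quick structural checks on a small bundle
  b0 <- small_bundle(seed = 6)
  cfg0 <- small_model_config(epochs = 20)
  out0 <- disease_holdout_rank(b0, "dis-3", top_n = 10, cfg0, seed = 4)
  expect_identical(nrow(out0), 10L)
  expect_identical(out0$rank, 1:10)
  expect_true(all(diff(out0$score) <= 0))
  expect_true(all(out0$mirna %in% b0$index$mirna_ids))
  expect_error(disease_holdout_rank(b0, "no-such-disease", 5, cfg0),
               "unknown")

  # enrichment of the planted block among the top 20 candidates for a
  # held-out disease of the full-size bundle (hypergeometric test)
  b <- generate_bundle(synthetic_config(seed = 5))
  cfg <- model_config(epochs = 500, seed = 2)
  target <- "dis-2"
  out <- disease_holdout_rank(b, target, top_n = 20, cfg, seed = 4)
  jblock <- b$truth[target]
  planted <- b$index$mirna_ids[b$truth[b$index$mirna_ids] == jblock]
  hits <- sum(out$mirna %in% planted)
  pval <- stats::phyper(hits - 1, length(planted),
                        b$index$n_mirna - length(planted), 20,
                        lower.tail = FALSE)
  expect_lt(pval, 0.05)
})
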