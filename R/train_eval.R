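## Evaluation protocol: leakage-aware k-fold cross-validation with 1:1
## negative sampling, ranking metrics (AUC, AUPR, ACC), ablation variants,
## and disease-wise hold-out ranking.

#' Build a k-fold cross-validation plan over the association matrix
#'
#' Known positives are shuffled with the seed and partitioned as evenly as
#' possible into k folds; negatives are sampled uniformly without
#' replacement from the zero entries, one per positive, and partitioned
#' alongside so folds are disjoint in both classes. A fold's training pairs
#' are the positives and negatives of the other k-1 folds.
#'
#' @param A binary association matrix.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return a `fold_plan`: list of k folds, each with `train_pos`,
#'   `test_pos`, `train_neg`, `test_neg` (two-column index matrices).
#' @export
make_folds <- function(A, k = 5, seed = 1L) {
  stopifnot(k >= 2)
  pos <- which(A == 1, arr.ind = TRUE)
  neg_lin <- which(A == 0)
  npos <- nrow(pos)
  if (npos < k) stop("fewer positives than folds")
  if (length(neg_lin) < npos)
    stop("not enough zero entries for 1:1 negative sampling")
  set.seed(seed)
  pos <- pos[sample.int(npos), , drop = FALSE]
  neg_lin <- sample(neg_lin, npos)
  neg <- arrayInd(neg_lin, dim(A))
  fold_id <- rep(seq_len(k), length.out = npos)
  folds <- lapply(seq_len(k), function(f) {
    list(train_pos = pos[fold_id != f, , drop = FALSE],
         test_pos = pos[fold_id == f, , drop = FALSE],
         train_neg = neg[fold_id != f, , drop = FALSE],
         test_neg = neg[fold_id == f, , drop = FALSE])
  })
  structure(list(folds = folds, k = k, seed = seed), class = "fold_plan")
}

#' Mask the test-fold positives out of an association matrix
#'
#' The masked matrix is what feeds the GIP kernels, the heterogeneous
#' adjacency, and the RWR features for that fold, so no held-out
#' association influences any training-time quantity.
#'
#' @param A binary association matrix.
#' @param fold one element of `fold_plan$folds`.
#' @return copy of `A` with the fold's test positives set to 0.
#' @export
mask_test_associations <- function(A, fold) {
  A[fold$test_pos] <- 0
  A
}

auc_rank <- function(scores, labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

aupr_step <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

#' Ranking metrics for scored pairs
#'
#' AUC by the rank (Mann-Whitney) statistic with average tie handling,
#' AUPR by step integration of the precision-recall curve, and accuracy at
#' the 0.5 threshold.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels (both classes must be present).
#' @return list(auc, aupr, acc).
#' @export
evaluate <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2)
    stop("evaluate: both classes must be present")
  list(auc = auc_rank(scores, labels),
       aupr = aupr_step(scores, labels),
       acc = mean((scores >= 0.5) == (labels == 1)))
}

fold_pairs <- function(fold, what) {
  p <- rbind(fold[[paste0(what, "_pos")]], fold[[paste0(what, "_neg")]])
  lab <- c(rep(1, nrow(fold[[paste0(what, "_pos")]])),
           rep(0, nrow(fold[[paste0(what, "_neg")]])))
  list(pairs = p, labels = lab)
}

#' Leakage-aware k-fold cross-validation
#'
#' Per fold: mask the test positives, recompute the GIP views from the
#' masked matrix, train from scratch on the fold's training pairs, and
#' score its test pairs. The association-independent views (functional,
#' sequence, family, lncRNA, semantic) are computed once.
#'
#' @param bundle a data bundle (see [generate_bundle()]).
#' @param config a [model_config()].
#' @param k number of folds.
#' @param seed fold/sampling seed.
#' @return list with `per_fold` (data.frame fold/auc/aupr/acc), `mean`,
#'   `sd`, `loss` (per-fold loss curves) and `fits` (per-fold models,
#'   dropped unless `keep_fits`).
#' @param keep_fits retain the per-fold fitted models (memory-heavy).
#' @export
run_cv <- function(bundle, config = model_config(), k = 5, seed = 1L,
                   keep_fits = FALSE) {
  plan <- make_folds(bundle$A, k, seed)
  base_views <- compute_views(bundle, A = bundle$A,
                              decay_mu = config$decay_mu,
                              lambda_prime = config$lambda_prime)
  res <- vector("list", k)
  loss <- vector("list", k)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- plan$folds[[f]]
    A_mask <- mask_test_associations(bundle$A, fold)
    views_m <- base_views$mirna
    views_d <- base_views$disease
    views_m$gip <- gip_kernel(A_mask, "mirna", config$lambda_prime)
    views_d$gip <- gip_kernel(A_mask, "disease", config$lambda_prime)
    tr <- fold_pairs(fold, "train")
    te <- fold_pairs(fold, "test")
    fit <- train_model(views_m, views_d, A_mask, tr$pairs, tr$labels, config)
    sc <- predict_pairs(fit, te$pairs)
    res[[f]] <- evaluate(sc, te$labels)
    loss[[f]] <- fit$loss
    if (keep_fits) fits[[f]] <- fit
  }
  per_fold <- data.frame(fold = seq_len(k),
                         auc = vapply(res, `[[`, numeric(1), "auc"),
                         aupr = vapply(res, `[[`, numeric(1), "aupr"),
                         acc = vapply(res, `[[`, numeric(1), "acc"))
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, c("auc", "aupr", "acc")]),
       sd = vapply(per_fold[, c("auc", "aupr", "acc")], stats::sd,
                   numeric(1)),
       loss = loss,
       plan = plan,
       fits = if (keep_fits) fits else NULL)
}

#' Cross-validation under an ablation variant
#'
#' Variants: `"none"` (full model), `"attention"` (no ECA, no multi-head
#' self-attention), `"egcn"` (plain graph convolutions without the
#' self-attention stage), `"multisource"` (single GIP view per node type).
#'
#' @param bundle data bundle.
#' @param variant ablation name as above.
#' @param config base [model_config()] (its `ablate` field is overridden).
#' @param k,seed as in [run_cv()].
#' @return as [run_cv()].
#' @export
run_ablation <- function(bundle, variant = "none", config = model_config(),
                         k = 5, seed = 1L) {
  stopifnot(variant %in% c("none", "attention", "egcn", "multisource"))
  config$ablate <- variant
  run_cv(bundle, config, k, seed)
}

#' Disease-wise hold-out ranking
#'
#' Removes every known association of the target disease before any
#' similarity or graph construction, retrains from scratch on the remaining
#' associations (1:1 negatives sampled outside the target disease's
#' column), then scores all candidate miRNAs against the target disease
#' and returns the top `top_n` in descending score order with ties broken
#' by miRNA id.
#'
#' @param bundle data bundle.
#' @param disease_id target disease identifier.
#' @param top_n number of candidates to return.
#' @param config a [model_config()].
#' @param seed negative-sampling seed.
#' @return data.frame(mirna, score, rank) of length min(top_n, Nm).
#' @export
disease_holdout_rank <- function(bundle, disease_id, top_n = 50,
                                 config = model_config(), seed = 1L) {
  ids_d <- bundle$index$disease_ids
  j <- match(disease_id, ids_d)
  if (is.na(j)) stop("unknown disease: ", disease_id)
  A_mask <- bundle$A
  A_mask[, j] <- 0
  if (sum(A_mask) == 0) stop("no training associations left after hold-out")

  pos <- which(A_mask == 1, arr.ind = TRUE)
  zeros <- which(A_mask == 0)
  zeros <- zeros[(arrayInd(zeros, dim(A_mask))[, 2]) != j]
  set.seed(seed)
  neg <- arrayInd(sample(zeros, nrow(pos)), dim(A_mask))
  pairs <- rbind(pos, neg)
  labels <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  stopifnot(all(pairs[, 2] != j))

  views <- compute_views(bundle, A = A_mask, decay_mu = config$decay_mu,
                         lambda_prime = config$lambda_prime)
  fit <- train_model(views$mirna, views$disease, A_mask, pairs, labels,
                     config)
  cand <- cbind(seq_len(bundle$index$n_mirna), j)
  sc <- predict_pairs(fit, cand)
  ids_m <- bundle$index$mirna_ids
  ord <- order(-sc, ids_m)
  n_out <- min(top_n, length(ids_m))
  data.frame(mirna = ids_m[ord][seq_len(n_out)],
             score = sc[ord][seq_len(n_out)],
             rank = seq_len(n_out))
}
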