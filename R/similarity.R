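## The eight similarity views. miRNA side: functional (loaded), sequence
## (Levenshtein), family (shared label), Gaussian interaction profile
## kernel, lncRNA interaction profile. Disease side: MeSH-DAG semantic,
## GIP kernel, lncRNA interaction profile.

#' miRNA sequence similarity from Levenshtein distance
#'
#' S(i, j) = 1 - d(i, j) / max(len_i, len_j) where d is the Levenshtein
#' edit distance between the RNA sequences.
#'
#' @param sequences named character vector id -> RNA sequence (non-empty).
#' @return symmetric similarity matrix with unit diagonal, entries in
#'   [0, 1], dimnames = ids.
#' @export
sequence_similarity <- function(sequences) {
  stopifnot(length(sequences) >= 1, !is.null(names(sequences)))
  if (any(nchar(sequences) == 0)) stop("empty sequence")
  d <- utils::adist(sequences, sequences)
  len <- nchar(sequences)
  denom <- outer(len, len, pmax)
  s <- 1 - d / denom
  dimnames(s) <- list(names(sequences), names(sequences))
  diag(s) <- 1
  symmetrize(s)
}

#' miRNA family similarity
#'
#' 1 when two miRNAs carry the same family label, 0 otherwise; the diagonal
#' is forced to 1 and unannotated miRNAs match nothing off-diagonal.
#'
#' @param ids ordered miRNA ids (defines the matrix coordinates).
#' @param families named character vector miRNA id -> family label; ids
#'   absent from it are treated as unannotated.
#' @return binary similarity matrix with unit diagonal.
#' @export
family_similarity <- function(ids, families) {
  lab <- families[ids]
  s <- outer(lab, lab, function(a, b) as.numeric(!is.na(a) & !is.na(b) & a == b))
  dimnames(s) <- list(ids, ids)
  diag(s) <- 1
  s
}

## Children of a term inside one disease's DAG: terms with an edge
## child -> term.
dag_children <- function(dag, term) dag$edges$child[dag$edges$parent == term]

#' Per-term semantic contribution within one disease's DAG
#'
#' Scheme 1 is the hierarchical decay: the disease's own term contributes 1
#' and each ancestor contributes the maximum over its in-DAG children of
#' `decay_mu` times the child's contribution (computed by a reverse
#' topological sweep from the root). Scheme 2 is the specificity weight
#' -ln(countDAGs(term) / Ndiseases), independent of position in the DAG.
#'
#' @param dag one element of `disease_dag_set$dags` (nodes + edges), whose
#'   root is the disease's own term.
#' @param scheme 1 (hierarchical) or 2 (specificity).
#' @param decay_mu semantic decay coefficient in (0, 1); default 0.5.
#' @param term_frequency named DAG-occurrence counts (scheme 2).
#' @param n_diseases total disease count (scheme 2).
#' @return named numeric vector term -> contribution over the DAG's nodes.
#' @export
semantic_contribution <- function(dag, scheme = 1, decay_mu = 0.5,
                                  term_frequency = NULL, n_diseases = NULL) {
  stopifnot(scheme %in% c(1, 2), decay_mu > 0, decay_mu < 1)
  nodes <- dag$nodes
  if (length(nodes) == 0) return(stats::setNames(numeric(0), character(0)))
  root <- nodes[1]
  if (scheme == 2) {
    tf <- term_frequency[nodes]
    if (any(is.na(tf) | tf < 1))
      stop("term with frequency 0 in scheme-2 contribution")
    return(stats::setNames(-log(as.numeric(tf) / n_diseases), nodes))
  }
  ## Reverse topological order: root first, then ancestors whose children
  ## are already scored. Edges run child -> parent, so process nodes in
  ## topological order of the child->parent graph.
  contrib <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  contrib[root] <- 1
  remaining <- setdiff(nodes, root)
  while (length(remaining)) {
    progressed <- FALSE
    for (term in remaining) {
      ch <- dag_children(dag, term)
      if (length(ch) && all(!is.na(contrib[ch]))) {
        contrib[term] <- max(decay_mu * contrib[ch])
        remaining <- setdiff(remaining, term)
        progressed <- TRUE
      }
    }
    if (!progressed)
      stop("DAG has terms unreachable from the root: ",
           paste(remaining, collapse = ", "))
  }
  contrib
}

#' Disease semantic similarity from MeSH-style DAGs
#'
#' Averages the hierarchical (scheme 1) and specificity-weighted (scheme 2)
#' similarities. For each scheme, the similarity of two diseases is the sum
#' of both diseases' contributions over the shared ancestor terms divided by
#' the sum of their total semantic values. Diseases with an empty DAG get 0
#' to all others and 1 to themselves.
#'
#' @param dag_set a `disease_dag_set` from [read_dag_edges()].
#' @param decay_mu semantic decay coefficient; default 0.5.
#' @return symmetric similarity matrix over `names(dag_set$dags)`.
#' @export
disease_semantic_similarity <- function(dag_set, decay_mu = 0.5) {
  ids <- names(dag_set$dags)
  n <- length(ids)
  c1 <- lapply(dag_set$dags, semantic_contribution, scheme = 1,
               decay_mu = decay_mu)
  c2 <- lapply(dag_set$dags, semantic_contribution, scheme = 2,
               term_frequency = dag_set$term_frequency,
               n_diseases = dag_set$n_diseases)
  v1 <- vapply(c1, sum, numeric(1))
  v2 <- vapply(c2, sum, numeric(1))
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) next
      if (i == j) { s[i, j] <- 1; next }
      shared <- intersect(names(c1[[i]]), names(c1[[j]]))
      if (length(shared) == 0) next
      s1 <- if (v1[i] + v1[j] > 0)
        sum(c1[[i]][shared] + c1[[j]][shared]) / (v1[i] + v1[j]) else 0
      s2 <- if (v2[i] + v2[j] > 0)
        sum(c2[[i]][shared] + c2[[j]][shared]) / (v2[i] + v2[j]) else 0
      s[i, j] <- s[j, i] <- (s1 + s2) / 2
    }
  }
  s[s < 0] <- 0
  s[s > 1] <- 1
  symmetrize(s)
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' K(i, j) = exp(-lambda * ||P_i - P_j||^2) over binary interaction
#' profiles: rows of the association matrix for miRNAs, columns for
#' diseases. The bandwidth is lambda = lambda_prime divided by the mean
#' squared profile norm.
#'
#' @param A binary association matrix (miRNAs x diseases, with dimnames).
#' @param axis `"mirna"` (row profiles) or `"disease"` (column profiles).
#' @param lambda_prime bandwidth scale, > 0; default 1.
#' @return symmetric similarity matrix with unit diagonal, entries (0, 1].
#' @export
gip_kernel <- function(A, axis = c("mirna", "disease"), lambda_prime = 1) {
  axis <- match.arg(axis)
  stopifnot(lambda_prime > 0)
  P <- if (axis == "mirna") A else t(A)
  norms2 <- rowSums(P^2)
  if (mean(norms2) == 0)
    stop("all-zero association matrix: GIP bandwidth undefined")
  lambda <- lambda_prime / mean(norms2)
  ## squared distances via the Gram matrix
  g <- tcrossprod(P)
  d2 <- outer(norms2, norms2, `+`) - 2 * g
  d2[d2 < 0] <- 0
  k <- exp(-lambda * d2)
  dimnames(k) <- list(rownames(P), rownames(P))
  diag(k) <- 1
  symmetrize(k)
}

#' Similarity from binary lncRNA interaction profiles via edit distance
#'
#' Each entity's profile (a row of the interaction matrix) is treated as a
#' string over {0, 1}; similarity is 1 - Levenshtein(row_i, row_j) / L with
#' L the number of lncRNAs.
#'
#' @param interactions binary matrix, rows = entities, columns = lncRNAs.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
profile_edit_similarity <- function(interactions) {
  stopifnot(is.matrix(interactions))
  if (ncol(interactions) == 0) stop("interaction matrix has zero columns")
  if (!all(interactions %in% c(0, 1)))
    stop("interaction matrix must be binary")
  strings <- apply(interactions, 1, paste, collapse = "")
  d <- utils::adist(strings, strings)
  s <- 1 - d / ncol(interactions)
  dimnames(s) <- list(rownames(interactions), rownames(interactions))
  diag(s) <- 1
  symmetrize(s)
}

#' Compute all similarity views for a data bundle
#'
#' Assembles the five miRNA views and three disease views used by the
#' fusion stage. The GIP views depend on the association matrix and must be
#' recomputed from a leakage-masked copy inside cross-validation; the
#' remaining views are association-independent.
#'
#' @param bundle a data bundle (see [generate_bundle()]) with elements
#'   `functional`, `sequences`, `families`, `mirna_lnc`, `disease_lnc`,
#'   `dags`, `index`.
#' @param A association matrix to compute the GIP views from (pass the
#'   masked matrix inside cross-validation). Default `bundle$A`.
#' @param decay_mu semantic decay coefficient.
#' @param lambda_prime GIP bandwidth scale.
#' @return list with `mirna` (functional, gip, lncrna, sequence, family)
#'   and `disease` (semantic, gip, lncrna) similarity matrices.
#' @export
compute_views <- function(bundle, A = bundle$A, decay_mu = 0.5,
                          lambda_prime = 1) {
  ids_m <- bundle$index$mirna_ids
  ids_d <- bundle$index$disease_ids
  list(
    mirna = list(
      functional = bundle$functional[ids_m, ids_m],
      gip = gip_kernel(A, "mirna", lambda_prime),
      lncrna = profile_edit_similarity(bundle$mirna_lnc[ids_m, , drop = FALSE]),
      sequence = sequence_similarity(bundle$sequences[ids_m]),
      family = family_similarity(ids_m, bundle$families)),
    disease = list(
      semantic = disease_semantic_similarity(bundle$dags, decay_mu),
      gip = gip_kernel(A, "disease", lambda_prime),
      lncrna = profile_edit_similarity(bundle$disease_lnc[ids_d, , drop = FALSE]))
  )
}
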