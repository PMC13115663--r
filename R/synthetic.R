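## Planted-block synthetic data generator. A single latent block structure
## simultaneously induces all the correlations the multi-view fusion is
## designed to exploit: associations are enriched within matched
## miRNA/disease blocks, families equal miRNA blocks, sequences mutate from
## per-block ancestors, the functional matrix is a noisy block indicator,
## disease DAGs share per-block term chains, and lncRNA profiles are
## block-prototype bit flips.

#' Synthetic bundle configuration
#'
#' @param n_mirna,n_disease entity counts.
#' @param n_blocks number of latent blocks (matched across entity types).
#' @param within_block_assoc_prob association probability when the miRNA
#'   and disease blocks match.
#' @param background_assoc_prob association probability otherwise.
#' @param similarity_noise_sd Gaussian noise added to the functional
#'   block-indicator matrix before clipping.
#' @param seq_len length of the generated RNA sequences.
#' @param per_family_mutations point substitutions applied to each block
#'   ancestor sequence per miRNA.
#' @param n_lncrna number of lncRNA interaction columns.
#' @param profile_flip_prob per-bit flip probability applied to the block
#'   prototype lncRNA profiles.
#' @param seed integer master seed; all sub-generators derive from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_mirna = 100, n_disease = 60, n_blocks = 5,
                             within_block_assoc_prob = 0.30,
                             background_assoc_prob = 0.02,
                             similarity_noise_sd = 0.05,
                             seq_len = 22, per_family_mutations = 3,
                             n_lncrna = 40, profile_flip_prob = 0.1,
                             seed = 1L) {
  stopifnot(within_block_assoc_prob > background_assoc_prob,
            within_block_assoc_prob <= 1, background_assoc_prob >= 0,
            n_blocks <= min(n_mirna, n_disease))
  structure(list(n_mirna = n_mirna, n_disease = n_disease,
                 n_blocks = n_blocks,
                 within_block_assoc_prob = within_block_assoc_prob,
                 background_assoc_prob = background_assoc_prob,
                 similarity_noise_sd = similarity_noise_sd,
                 seq_len = seq_len,
                 per_family_mutations = per_family_mutations,
                 n_lncrna = n_lncrna, profile_flip_prob = profile_flip_prob,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

draw_blocks <- function(config) {
  set.seed(derive_seeds(config$seed, 1)[1])
  list(mirna = sample.int(config$n_blocks, config$n_mirna, replace = TRUE),
       disease = sample.int(config$n_blocks, config$n_disease,
                            replace = TRUE))
}

#' Latent block labels used by the generator
#'
#' Returns the planted ground truth (miRNA labels followed by disease
#' labels) for the same config/seed as [generate_bundle()], for enrichment
#' and recovery tests.
#'
#' @param config a [synthetic_config()].
#' @return integer vector of length n_mirna + n_disease, with names.
#' @export
planted_truth <- function(config) {
  b <- draw_blocks(config)
  stats::setNames(c(b$mirna, b$disease),
                  c(paste0("mir-", seq_len(config$n_mirna)),
                    paste0("dis-", seq_len(config$n_disease))))
}

rand_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                       replace = TRUE), collapse = "")

mutate_rna <- function(seq, n_mut) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(s), min(n_mut, length(s)))
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "U"), s[p]), 1)
  paste(s, collapse = "")
}

block_profiles <- function(blocks, n_cols, flip_prob, n_blocks) {
  protos <- matrix(stats::rbinom(n_blocks * n_cols, 1, 0.3), n_blocks)
  out <- protos[blocks, , drop = FALSE]
  flips <- matrix(stats::rbinom(length(out), 1, flip_prob), nrow(out))
  out <- (out + flips) %% 2
  storage.mode(out) <- "double"
  out
}

#' Generate a fully self-contained synthetic input bundle
#'
#' @param config a [synthetic_config()].
#' @return list with `A` (binary association matrix), `sequences` (named
#'   RNA strings), `families` (named labels), `functional` (noisy
#'   block-indicator similarity), `mirna_lnc`/`disease_lnc` (binary
#'   interaction matrices), `dags` (a `disease_dag_set`), `dag_edges`
#'   (the raw edge table), `index` (entity index), `truth` (planted block
#'   labels) and `config`.
#' @export
generate_bundle <- function(config = synthetic_config()) {
  bundle <- generate_bundle_once(config, config$seed)
  if (sum(bundle$A) == 0) {
    bundle <- generate_bundle_once(config, derive_seeds(config$seed, 2)[2])
    if (sum(bundle$A) == 0)
      stop("synthetic config produced an all-zero association matrix twice")
  }
  bundle
}

generate_bundle_once <- function(config, seed) {
  seeds <- derive_seeds(seed, 8)
  blocks <- draw_blocks(config)
  mirna_ids <- paste0("mir-", seq_len(config$n_mirna))
  disease_ids <- paste0("dis-", seq_len(config$n_disease))
  index <- entity_index(mirna_ids, disease_ids)

  ## association matrix: Bernoulli with block-matched elevation
  set.seed(seeds[2])
  match_prob <- ifelse(outer(blocks$mirna, blocks$disease, `==`),
                       config$within_block_assoc_prob,
                       config$background_assoc_prob)
  A <- matrix(as.numeric(stats::rbinom(length(match_prob), 1, match_prob)),
              config$n_mirna, dimnames = list(mirna_ids, disease_ids))

  ## sequences: per-block ancestor with point substitutions
  set.seed(seeds[3])
  ancestors <- vapply(seq_len(config$n_blocks), function(b)
    rand_rna(config$seq_len), character(1))
  sequences <- vapply(seq_len(config$n_mirna), function(i)
    mutate_rna(ancestors[blocks$mirna[i]], config$per_family_mutations),
    character(1))
  names(sequences) <- mirna_ids

  families <- stats::setNames(paste0("fam-", blocks$mirna), mirna_ids)

  ## functional similarity: block indicator + truncated Gaussian noise
  set.seed(seeds[4])
  ind <- outer(blocks$mirna, blocks$mirna, function(a, b)
    as.numeric(a == b))
  noise <- matrix(stats::rnorm(length(ind), 0, config$similarity_noise_sd),
                  nrow(ind))
  functional <- symmetrize(ind + noise)
  functional[functional < 0] <- 0
  functional[functional > 1] <- 1
  diag(functional) <- 1
  dimnames(functional) <- list(mirna_ids, mirna_ids)

  ## disease DAGs: per-block term chains over a shared pool, rooted at a
  ## common ancestor term so every DAG shares at least one term
  set.seed(seeds[5])
  edges <- do.call(rbind, lapply(seq_len(config$n_disease), function(j) {
    b <- blocks$disease[j]
    chain <- c(paste0("T-b", b, "-", 1:3), "T-root")
    start <- sample(1:2, 1)
    path <- c(disease_ids[j], chain[start:length(chain)])
    data.frame(disease = disease_ids[j],
               child = path[-length(path)], parent = path[-1])
  }))
  dags <- build_dag_set(edges, disease_ids)

  ## lncRNA interaction profiles: block prototypes with bit flips
  set.seed(seeds[6])
  mirna_lnc <- block_profiles(blocks$mirna, config$n_lncrna,
                              config$profile_flip_prob, config$n_blocks)
  dimnames(mirna_lnc) <- list(mirna_ids, paste0("lnc-", seq_len(config$n_lncrna)))
  set.seed(seeds[7])
  disease_lnc <- block_profiles(blocks$disease, config$n_lncrna,
                                config$profile_flip_prob, config$n_blocks)
  dimnames(disease_lnc) <- list(disease_ids,
                                paste0("lnc-", seq_len(config$n_lncrna)))

  list(A = A, sequences = sequences, families = families,
       functional = functional, mirna_lnc = mirna_lnc,
       disease_lnc = disease_lnc, dags = dags, dag_edges = edges,
       index = index,
       truth = stats::setNames(c(blocks$mirna, blocks$disease),
                               c(mirna_ids, disease_ids)),
       config = config)
}

#' Write a synthetic bundle to disk in the package's file formats
#'
#' @param bundle a bundle from [generate_bundle()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_table(bundle$A, file.path(dir, "associations.tsv"))
  write_fasta(bundle$sequences, file.path(dir, "sequences.fasta"))
  write_family_table(bundle$families, file.path(dir, "families.tsv"))
  write_matrix_tsv(bundle$functional, file.path(dir, "functional.tsv"))
  write_matrix_tsv(bundle$mirna_lnc, file.path(dir, "mirna_lncrna.tsv"))
  write_matrix_tsv(bundle$disease_lnc, file.path(dir, "disease_lncrna.tsv"))
  utils::write.table(bundle$dag_edges, file.path(dir, "dag_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(data.frame(id = names(bundle$truth),
                              block = unname(bundle$truth)),
                   file.path(dir, "planted_blocks.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a bundle previously written by [write_bundle()]
#'
#' @param dir directory containing the bundle files.
#' @return a data bundle as from [generate_bundle()] (without `truth`
#'   unless the truth file is present).
#' @export
read_bundle <- function(dir) {
  A <- read_association_table(file.path(dir, "associations.tsv"))
  index <- entity_index(rownames(A), colnames(A))
  dag_edges <- utils::read.delim(file.path(dir, "dag_edges.tsv"),
                                 header = FALSE, sep = "\t",
                                 col.names = c("disease", "child", "parent"),
                                 stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "planted_blocks.csv")
  truth <- if (file.exists(truth_path)) {
    df <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    stats::setNames(df$block, df$id)
  } else NULL
  list(A = A,
       sequences = read_fasta(file.path(dir, "sequences.fasta")),
       families = read_family_table(file.path(dir, "families.tsv")),
       functional = read_similarity_table(file.path(dir, "functional.tsv"),
                                          ids = index$mirna_ids),
       mirna_lnc = read_interaction_table(file.path(dir, "mirna_lncrna.tsv")),
       disease_lnc = read_interaction_table(file.path(dir, "disease_lncrna.tsv")),
       dags = build_dag_set(dag_edges, index$disease_ids),
       dag_edges = dag_edges,
       index = index, truth = truth)
}
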