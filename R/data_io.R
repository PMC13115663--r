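## Readers and writers for the external file formats: TSV matrices
## (association, similarity, lncRNA interaction), two-column TSV tables
## (miRNA family), FASTA sequences, MeSH-style DAG edge lists, and the
## ranked-prediction / metrics CSV outputs.
##
## TSV dialect: tab-delimited, one header row of column ids, first column
## holds row ids. All matrices are indexed by an entity index (ordered
## miRNA ids and disease ids) which is the coordinate system for every
## downstream computation.

#' Construct an entity index
#'
#' The ordered id lists that every matrix in the pipeline is indexed by:
#' miRNAs first, diseases second.
#'
#' @param mirna_ids character vector of unique miRNA identifiers.
#' @param disease_ids character vector of unique disease identifiers.
#' @return an object of class `entity_index` with elements `mirna_ids`,
#'   `disease_ids`, `n_mirna`, `n_disease`.
#' @export
entity_index <- function(mirna_ids, disease_ids) {
  mirna_ids <- as.character(mirna_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA ids in index")
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids in index")
  if (length(mirna_ids) < 2 || length(disease_ids) < 2)
    stop("need at least two miRNAs and two diseases")
  structure(list(mirna_ids = mirna_ids, disease_ids = disease_ids,
                 n_mirna = length(mirna_ids),
                 n_disease = length(disease_ids)),
            class = "entity_index")
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate column id in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a binary miRNA-disease association matrix from TSV
#'
#' Rows are miRNAs, columns are diseases, cells are 0/1 indicators of a
#' curated association.
#'
#' @param path TSV file: disease ids in the header, miRNA ids in the first
#'   column.
#' @return binary numeric matrix with miRNA rownames and disease colnames.
#' @export
read_association_table <- function(path) {
  m <- read_tsv_matrix(path)
  bad <- which(!(m %in% c(0, 1)) | !is.finite(m), arr.ind = FALSE)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(m))
    stop(sprintf("non-binary cell at row '%s', column '%s' in %s",
                 rownames(m)[ij[1]], colnames(m)[ij[2]], path))
  }
  if (sum(m) < 1) stop("association matrix has no positive entry")
  m
}

#' Write a binary association matrix as TSV
#' @param A binary matrix with row/column names.
#' @param path output file.
#' @export
write_association_table <- function(A, path) {
  write_matrix_tsv(A, path)
}

#' Write any named numeric matrix as TSV (ids in first column and header)
#' @param m numeric matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square similarity matrix from TSV
#'
#' Used for externally supplied (precomputed) views such as the miRNA
#' functional similarity. Loaded matrices are symmetrized by averaging with
#' the transpose and clipped into [0, 1] on ingest; computed views never
#' take this path.
#'
#' @param path TSV file with matching row/column ids.
#' @param ids optional id vector the matrix must match (order enforced).
#' @return symmetric numeric matrix with entries in [0, 1].
#' @export
read_similarity_table <- function(path, ids = NULL) {
  m <- read_tsv_matrix(path)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("similarity TSV must be square with identical row/column ids: ", path)
  if (!is.null(ids)) {
    if (!setequal(rownames(m), ids))
      stop("similarity ids do not match the supplied index: ", path)
    m <- m[ids, ids]
  }
  m <- symmetrize(m)
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' Read a binary interaction matrix (rows = entities, columns = lncRNAs)
#' @param path TSV file.
#' @return binary numeric matrix.
#' @export
read_interaction_table <- function(path) {
  m <- read_tsv_matrix(path)
  if (!all(m %in% c(0, 1)))
    stop("interaction matrix must be binary: ", path)
  m
}

#' Read miRNA sequences from FASTA
#'
#' Sequences are upper-cased and DNA-style T is normalized to U; the
#' resulting alphabet must be {A, C, G, U}.
#'
#' @param path FASTA file.
#' @return named character vector id -> RNA sequence.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  names(seqs) <- ids
  bad <- which(nchar(seqs) == 0 | grepl("[^ACGU]", seqs))
  if (length(bad))
    stop("empty sequence or illegal character in FASTA record '",
         ids[bad[1]], "'")
  seqs
}

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences))
    writeLines(c(paste0(">", id), sequences[[id]]), con)
  invisible(path)
}

#' Read a miRNA family annotation table
#' @param path two-column TSV (miRNA id, family id), no header.
#' @return named character vector miRNA id -> family label.
#' @export
read_family_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("family table needs two columns: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate miRNA id in family table")
  stats::setNames(as.character(df[[2]]), ids)
}

#' Write a family annotation table
#' @param families named character vector miRNA id -> family label.
#' @param path output file.
#' @export
write_family_table <- function(families, path) {
  utils::write.table(data.frame(names(families), unname(families)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-disease MeSH-style DAG edge lists
#'
#' Each row is (disease id, child term, parent term); all rows with the same
#' disease id form that disease's DAG, rooted at the disease's own term.
#' Diseases absent from the file get an empty DAG (their semantic similarity
#' to every other disease is 0; other views carry them).
#'
#' @param path three-column TSV, no header.
#' @param disease_ids the diseases of the entity index; every disease id in
#'   the file must be one of these.
#' @return an object of class `disease_dag_set`: list with `dags` (per
#'   disease: `nodes`, `edges` data.frame(child, parent)), `term_frequency`
#'   (named count of DAGs containing each term) and `n_diseases`.
#' @export
read_dag_edges <- function(path, disease_ids) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("disease", "child", "parent"))
  build_dag_set(df, disease_ids)
}

#' Assemble a disease DAG set from an edge data frame
#'
#' @param edges data.frame with columns disease, child, parent.
#' @param disease_ids diseases of the entity index.
#' @return `disease_dag_set`; see [read_dag_edges()].
#' @export
build_dag_set <- function(edges, disease_ids) {
  unknown <- setdiff(unique(edges$disease), disease_ids)
  if (length(unknown))
    stop("DAG edge references unknown disease: ",
         paste(unknown, collapse = ", "))
  dags <- vector("list", length(disease_ids))
  names(dags) <- disease_ids
  for (d in disease_ids) {
    e <- edges[edges$disease == d, c("child", "parent"), drop = FALSE]
    if (nrow(e) == 0) {
      dags[[d]] <- list(nodes = character(0),
                        edges = data.frame(child = character(0),
                                           parent = character(0)))
      next
    }
    g <- igraph::graph_from_data_frame(e, directed = TRUE)
    if (!igraph::is_dag(g))
      stop("cycle detected in DAG of disease '", d, "'")
    nodes <- unique(c(d, e$child, e$parent))
    # the disease's own term is the most specific node: nothing below it
    if (d %in% e$parent)
      stop("root term '", d, "' has a child term in its own DAG")
    dags[[d]] <- list(nodes = nodes, edges = e)
  }
  terms <- unlist(lapply(dags, `[[`, "nodes"), use.names = FALSE)
  tf <- table(terms)
  structure(list(dags = dags,
                 term_frequency = stats::setNames(as.integer(tf), names(tf)),
                 n_diseases = length(disease_ids)),
            class = "disease_dag_set")
}

#' Flatten a DAG set back to an edge data frame
#' @param dag_set a `disease_dag_set`.
#' @return data.frame(disease, child, parent).
#' @export
dag_set_edges <- function(dag_set) {
  do.call(rbind, lapply(names(dag_set$dags), function(d) {
    e <- dag_set$dags[[d]]$edges
    if (nrow(e) == 0) return(NULL)
    data.frame(disease = d, child = e$child, parent = e$parent)
  }))
}

#' Write ranked predictions to CSV
#'
#' One row per (miRNA, disease) pair, ranked within each disease by
#' descending score; ties are broken by lexicographic miRNA id so the
#' output is deterministic.
#'
#' @param scores numeric matrix of association scores in [0, 1], miRNAs in
#'   rows, diseases in columns, with dimnames.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_predictions <- function(scores, path) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  if (min(scores) < 0 || max(scores) > 1)
    stop("prediction scores must lie in [0, 1]")
  rows <- lapply(colnames(scores), function(d) {
    s <- scores[, d]
    ord <- order(-s, rownames(scores))
    data.frame(mirna = rownames(scores)[ord], disease = d,
               score = s[ord], rank = seq_along(ord))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a predictions CSV written by [write_predictions()]
#' @param path CSV file.
#' @return data.frame(mirna, disease, score, rank).
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a per-fold metrics table to CSV (one row per fold plus a summary)
#' @param report a metric report from [run_cv()].
#' @param path output CSV.
#' @export
write_metrics <- function(report, path) {
  per <- report$per_fold
  summary <- data.frame(fold = c("mean", "sd"),
                        auc = c(mean(per$auc), stats::sd(per$auc)),
                        aupr = c(mean(per$aupr), stats::sd(per$aupr)),
                        acc = c(mean(per$acc), stats::sd(per$acc)))
  per$fold <- as.character(per$fold)
  utils::write.csv(rbind(per, summary), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
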