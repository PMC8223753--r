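#' Association data container
#'
#' Holds a binary miRNA-by-disease association matrix `D` together with a
#' known/unknown mask. Entries flagged known carry an observed label (1 =
#' association reported, 0 = reported absent); unknown entries are the
#' candidates the model is asked to score and always carry `D = 0`.
#'
#' @param D numeric matrix with entries in {0, 1}; rows are miRNAs, columns
#'   diseases. Must carry unique dimnames.
#' @param known logical matrix of the same shape; `TRUE` marks an entry whose
#'   label is observed. Defaults to all-known.
#' @return An object of class `assoc_data`: a list with elements
#'   `mirna` (row labels), `disease` (column labels), `D` and `known`.
#' @export
association_data <- function(D, known = NULL) {
  if (!is.matrix(D)) stop("D must be a matrix")
  if (is.null(rownames(D)) || is.null(colnames(D)))
    stop("D must carry row (miRNA) and column (disease) labels")
  if (anyDuplicated(rownames(D)) || anyDuplicated(colnames(D)))
    stop("association labels must be unique")
  if (!all(D %in% c(0, 1))) stop("association values must be 0 or 1")
  if (is.null(known)) {
    known <- matrix(TRUE, nrow(D), ncol(D), dimnames = dimnames(D))
  }
  if (!is.logical(known) || !identical(dim(known), dim(D)))
    stop("known mask must be a logical matrix shaped like D")
  if (any(D[!known] != 0))
    stop("unknown entries must have association value 0")
  structure(
    list(mirna = rownames(D), disease = colnames(D), D = D, known = known),
    class = "assoc_data"
  )
}

#' @export
print.assoc_data <- function(x, ...) {
  cat(sprintf(
    "assoc_data: %d miRNAs x %d diseases, %d known positives, %d unknown entries\n",
    length(x$mirna), length(x$disease),
    sum(x$D == 1), sum(!x$known)
  ))
  invisible(x)
}

#' Read a miRNA-disease association table
#'
#' Reads a headerless TSV with columns `(mirna, disease)` or
#' `(mirna, disease, value)` where value is 0 or 1. Lines starting with `#`
#' are skipped. Row and column order of the assembled matrix follow first
#' appearance in the file. Pairs absent from the file default to
#' known-negative (value 0, label observed), so that the label-weighting
#' scheme can distinguish observed negatives from masked entries; the
#' cross-validation harness flips held-out positives to unknown.
#'
#' @param path path to the TSV file.
#' @param absent how unlisted pairs are treated: `"known_negative"`
#'   (default) or `"unknown"`.
#' @return An [association_data()] object.
#' @export
read_association_table <- function(path,
                                   absent = c("known_negative", "unknown")) {
  absent <- match.arg(absent)
  tab <- read_tsv_body(path)
  if (nrow(tab) == 0) stop("empty association table: ", path)
  if (ncol(tab) == 2) {
    tab$value <- 1
  } else if (ncol(tab) >= 3) {
    tab <- tab[, 1:3]
    tab[[3]] <- as.numeric(tab[[3]])
    if (!all(tab[[3]] %in% c(0, 1)))
      stop("association values must be 0 or 1")
  }
  names(tab) <- c("mirna", "disease", "value")
  key <- paste(tab$mirna, tab$disease, sep = "\r")
  agg <- tapply(tab$value, key, function(v) length(unique(v)))
  if (any(agg > 1)) {
    bad <- names(agg)[which(agg > 1)[1]]
    stop("contradictory duplicate rows for pair: ",
         gsub("\r", " / ", bad))
  }
  tab <- tab[!duplicated(key), ]
  mir <- unique(tab$mirna)
  dis <- unique(tab$disease)
  D <- matrix(0, length(mir), length(dis), dimnames = list(mir, dis))
  known <- matrix(absent == "known_negative", length(mir), length(dis),
                  dimnames = list(mir, dis))
  idx <- cbind(match(tab$mirna, mir), match(tab$disease, dis))
  D[idx] <- tab$value
  known[idx] <- TRUE
  association_data(D, known)
}

#' Disease term hierarchy (directed acyclic graph)
#'
#' @param edges two-column character matrix or data frame of
#'   `(child, parent)` pairs; may have zero rows.
#' @param nodes optional character vector of additional (possibly isolated)
#'   term identifiers.
#' @return An object of class `disease_dag` with elements `nodes`,
#'   `edges` (child/parent character matrix) and `graph` (an igraph object
#'   with edges pointing child -> parent).
#' @export
disease_dag <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) < 2)
    stop("edges must have (child, parent) columns")
  if (length(edges)) {
    edges <- matrix(as.character(edges[, 1:2]), ncol = 2,
                    dimnames = list(NULL, c("child", "parent")))
  } else {
    edges <- matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("child", "parent")))
  }
  all_nodes <- unique(c(as.vector(t(edges)), as.character(nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, "child"], to = edges[, "parent"],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    member <- igraph::ends(g, cyc[1])[1]
    stop("hierarchy contains a cycle involving term: ", member)
  }
  structure(list(nodes = all_nodes, edges = edges, graph = g),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag: %d terms, %d child->parent edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a disease hierarchy edge list
#'
#' Headerless TSV with columns `(child, parent)`; `#` comment lines skipped.
#' An empty edge file is allowed when `nodes` supplies isolated terms.
#'
#' @inheritParams read_association_table
#' @param nodes optional character vector of isolated terms to include.
#' @return A [disease_dag()] object.
#' @export
read_dag_edges <- function(path, nodes = NULL) {
  tab <- read_tsv_body(path)
  if (nrow(tab) == 0) {
    return(disease_dag(matrix(character(0), ncol = 2), nodes = nodes))
  }
  disease_dag(as.matrix(tab[, 1:2]), nodes = nodes)
}

#' Read a weighted pair table (e.g. gene-gene functional similarity)
#'
#' Headerless TSV with columns `(id_a, id_b, weight)`, weights in `[0, 1]`.
#' Pairs are unordered; the same pair listed twice with conflicting weights
#' is an error.
#'
#' @inheritParams read_association_table
#' @return A data frame with columns `a`, `b`, `w`.
#' @export
read_weighted_pairs <- function(path) {
  tab <- read_tsv_body(path)
  if (nrow(tab) == 0) {
    return(data.frame(a = character(0), b = character(0), w = numeric(0)))
  }
  names(tab) <- c("a", "b", "w")[seq_len(ncol(tab))]
  tab$w <- as.numeric(tab$w)
  weighted_pairs(tab)
}

#' @rdname read_weighted_pairs
#' @param pairs data frame with columns `a`, `b`, `w`.
#' @export
weighted_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs)[, 1:3]
  names(pairs) <- c("a", "b", "w")
  pairs$a <- as.character(pairs$a)
  pairs$b <- as.character(pairs$b)
  pairs$w <- as.numeric(pairs$w)
  if (any(pairs$w < 0 | pairs$w > 1)) stop("pair weights must lie in [0, 1]")
  key <- ifelse(pairs$a < pairs$b,
                paste(pairs$a, pairs$b, sep = "\r"),
                paste(pairs$b, pairs$a, sep = "\r"))
  nuniq <- tapply(pairs$w, key, function(v) length(unique(v)))
  if (any(nuniq > 1)) {
    bad <- names(nuniq)[which(nuniq > 1)[1]]
    stop("conflicting weights for pair: ", gsub("\r", " / ", bad))
  }
  pairs[!duplicated(key), ]
}

#' Validate (and construct) a labeled similarity matrix
#'
#' A similarity matrix is a plain numeric matrix with identical row and
#' column labels, symmetric entries in `[0, 1]`. Asymmetry up to `1e-8`
#' (e.g. from file rounding) is silently averaged away; anything larger is
#' an error.
#'
#' @param values square numeric matrix.
#' @param labels optional labels; taken from dimnames when missing.
#' @return The validated, symmetrized matrix with dimnames set.
#' @export
similarity_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("similarity matrix must be square")
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) stop("similarity matrix needs labels")
  if (anyDuplicated(labels)) stop("similarity labels must be unique")
  dimnames(values) <- list(labels, labels)
  if (any(!is.finite(values))) stop("similarity values must be finite")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8)
    stop(sprintf("similarity matrix asymmetric beyond tolerance (%.3g)", asym))
  values <- (values + t(values)) / 2
  if (any(values < 0) || any(values > 1))
    stop("similarity values must lie in [0, 1]")
  values
}

#' Read / write a labeled square similarity matrix
#'
#' The on-disk format is a TSV whose header row repeats the label column, so
#' `read_similarity_matrix(write_similarity_matrix(x, f))` reproduces `x`
#' within 1e-12. Values are written at 15 significant digits.
#'
#' @param path file path.
#' @return For the reader, a validated similarity matrix.
#' @export
read_similarity_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  labels <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(labels, colnames(m)))
    stop("similarity matrix header and label column disagree")
  similarity_matrix(m, labels)
}

#' @rdname read_similarity_matrix
#' @param sim labeled square similarity matrix.
#' @export
write_similarity_matrix <- function(sim, path) {
  sim <- similarity_matrix(sim)
  df <- data.frame(label = rownames(sim), sim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ranked association predictions
#'
#' Emits a TSV of `(disease, mirna, score, rank)` with, per disease, the
#' `top_k` highest-scoring candidate miRNAs. Training positives (entries of
#' `exclude` that are `TRUE`) are removed from the candidate pool before
#' ranking. Ties are broken by miRNA label order, deterministically.
#'
#' @param scores labeled miRNA-by-disease numeric matrix.
#' @param path output file path.
#' @param top_k number of candidates to keep per disease; capped at the
#'   candidate pool size.
#' @param exclude optional logical matrix (same shape) of pairs to drop from
#'   ranking, typically the training positives.
#' @return The path, invisibly.
#' @export
write_predictions <- function(scores, path, top_k, exclude = NULL) {
  if (!is.matrix(scores) || any(!is.finite(scores)))
    stop("scores must be a finite numeric matrix")
  if (top_k <= 0) stop("top_k must be positive")
  if (is.null(exclude))
    exclude <- matrix(FALSE, nrow(scores), ncol(scores))
  if (is.null(dimnames(exclude))) dimnames(exclude) <- dimnames(scores)
  rows <- lapply(colnames(scores), function(d) {
    keep <- !exclude[, d]
    if (!any(keep)) return(NULL)
    cand <- rownames(scores)[keep]
    sc <- scores[keep, d]
    ord <- order(-sc, cand)
    k <- min(top_k, length(ord))
    data.frame(disease = d, mirna = cand[ord[seq_len(k)]],
               score = sc[ord[seq_len(k)]], rank = seq_len(k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease-gene association table
#'
#' Headerless TSV with columns `(disease, gene)`; `#` comment lines skipped.
#'
#' @inheritParams read_association_table
#' @return Named list mapping each disease to its character vector of genes.
#' @export
read_disease_genes <- function(path) {
  tab <- read_tsv_body(path)
  if (nrow(tab) == 0) return(list())
  split(as.character(tab[[2]]), as.character(tab[[1]]))
}

# Shared TSV body reader: headerless, tab-separated, '#' comments skipped.
read_tsv_body <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    utils::read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, blank.lines.skip = TRUE),
    error = function(e) data.frame()
  )
  tab
}
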