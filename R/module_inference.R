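#' Soft module assignment from a latent factor matrix
#'
#' Each column of the factor matrix is a candidate module. An entity joins
#' module `k` when its loading `G[i, k]` exceeds a per-entity threshold
#' `Th(i) = mean(G[i, ]) + t * sd(G[i, ])` (sample standard deviation),
#' so membership is relative to the entity's own loading profile. Entities
#' may belong to several modules or to none. Modules retaining at most one
#' member are dropped (recorded in `dropped`).
#'
#' @param G non-negative factor matrix with at least 2 columns; rows must be
#'   labeled.
#' @param t threshold multiplier; default 1.5.
#' @return An object of class `module_set`: list with `entity_labels`,
#'   `membership` (named list, one character vector per retained module),
#'   `thresholds`, `t`, `dropped` (indices of modules with <= 1 member) and
#'   `n_modules` (number of factor columns).
#' @export
assign_modules <- function(G, t = 1.5) {
  if (!is.matrix(G) || ncol(G) < 2)
    stop("factor matrix must have at least 2 columns")
  if (any(G < 0)) stop("factor matrix must be non-negative")
  if (is.null(rownames(G))) rownames(G) <- paste0("e", seq_len(nrow(G)))
  mu <- rowMeans(G)
  sdev <- apply(G, 1, stats::sd)
  th <- mu + t * sdev
  members <- lapply(seq_len(ncol(G)), function(k) rownames(G)[G[, k] > th])
  sizes <- lengths(members)
  dropped <- which(sizes <= 1)
  kept <- setdiff(seq_len(ncol(G)), dropped)
  structure(
    list(entity_labels = rownames(G),
         membership = stats::setNames(members[kept], as.character(kept)),
         thresholds = stats::setNames(th, rownames(G)),
         t = t, dropped = dropped, n_modules = ncol(G)),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d retained modules (of %d), %d entities, t = %g\n",
              length(x$membership), x$n_modules, length(x$entity_labels), x$t))
  invisible(x)
}

#' Cosine similarity of two latent vectors
#'
#' `sum(u * v) / (||u|| ||v||)`; lies in `[0, 1]` for non-negative vectors.
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return Scalar similarity.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

# Pairwise cosine similarity of the rows of G. Zero rows get similarity 0 to
# everything (including themselves) and are reported in attr "zero_rows".
latent_cosine_matrix <- function(G) {
  norms <- sqrt(rowSums(G^2))
  zero <- norms == 0
  norms[zero] <- 1
  Gn <- G / norms
  S <- tcrossprod(Gn)
  S[zero, ] <- 0
  S[, zero] <- 0
  S <- pmin(pmax(S, 0), 1)
  dimnames(S) <- list(rownames(G), rownames(G))
  attr(S, "zero_rows") <- which(zero)
  S
}

#' Module-propagated association scores
#'
#' Propagates known associations through soft modules. For each retained
#' miRNA module `k`, the score of pair `(i, j)` is the cosine-similarity-
#' weighted vote of the module's members' known associations with disease
#' `j`, normalized by miRNA `i`'s total similarity to all miRNAs:
#' `Score_k(i, j) = sum_{q in module k} Sim(g_i, g_q) D(q, j) /
#' sum_{q = 1..n_m} Sim(g_i, g_q)`. The final matrix averages the per-module
#' scores over the retained modules (or, with `average_over = "nominal"`,
#' over all factor columns). `module_score_disease` is the disease-side
#' twin, voting over disease modules along the rows of `D`.
#'
#' @param modset a [assign_modules()] result derived from the same factor
#'   matrix `G`.
#' @param G the latent factor matrix the modules were extracted from
#'   (miRNA side for `module_score_mirna`, disease side for
#'   `module_score_disease`).
#' @param D binary association matrix (training positives).
#' @param average_over `"retained"` (default) averages over retained
#'   modules; `"nominal"` divides by the number of factor columns.
#' @return Labeled miRNA-by-disease score matrix (all zeros when no module
#'   is retained).
#' @export
module_score_mirna <- function(modset, G, D,
                               average_over = c("retained", "nominal")) {
  average_over <- match.arg(average_over)
  stopifnot(identical(rownames(G), rownames(D)))
  out <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  if (length(modset$membership) == 0) return(out)
  S <- latent_cosine_matrix(G)
  den <- rowSums(S)
  den[den == 0] <- Inf  # zero latent rows score 0
  acc <- matrix(0, nrow(D), ncol(D))
  for (members in modset$membership) {
    acc <- acc + (S[, members, drop = FALSE] %*% D[members, , drop = FALSE]) / den
  }
  divisor <- if (average_over == "retained") length(modset$membership)
             else modset$n_modules
  out[] <- acc / divisor
  out
}

#' @rdname module_score_mirna
#' @export
module_score_disease <- function(modset, G, D,
                                 average_over = c("retained", "nominal")) {
  average_over <- match.arg(average_over)
  stopifnot(identical(rownames(G), colnames(D)))
  out <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  if (length(modset$membership) == 0) return(out)
  S <- latent_cosine_matrix(G)
  den <- rowSums(S)
  den[den == 0] <- Inf
  acc <- matrix(0, nrow(D), ncol(D))
  for (members in modset$membership) {
    num <- D[, members, drop = FALSE] %*% S[members, , drop = FALSE]
    acc <- acc + sweep(num, 2, den, "/")
  }
  divisor <- if (average_over == "retained") length(modset$membership)
             else modset$n_modules
  out[] <- acc / divisor
  out
}

#' Min-max normalization of a whole matrix
#'
#' Affine rescaling of all entries to `[0, 1]`. A constant matrix maps to
#' all zeros (the degenerate case is documented rather than an error).
#'
#' @param X numeric matrix.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
minmax_normalize <- function(X) {
  rng <- range(X)
  if (rng[1] == rng[2]) return(array(0, dim(X), dimnames = dimnames(X)))
  (X - rng[1]) / (rng[2] - rng[1])
}

#' Fuse reconstruction and module-propagated scores
#'
#' `D2 = minmax(D1) + minmax(Pm) / 2 + minmax(Pd) / 2`, each matrix min-max
#' normalized as a whole; entries of the fused matrix lie in `[0, 2]`.
#'
#' @param D1 reconstruction scores from [predict_scores()].
#' @param Pm,Pd module-propagated scores from [module_score_mirna()] and
#'   [module_score_disease()].
#' @return Fused score matrix.
#' @export
fuse_predictions <- function(D1, Pm, Pd) {
  stopifnot(identical(dim(D1), dim(Pm)), identical(dim(D1), dim(Pd)))
  out <- minmax_normalize(D1) + minmax_normalize(Pm) / 2 + minmax_normalize(Pd) / 2
  dimnames(out) <- dimnames(D1)
  out
}

# Largest fraction of module members sharing one common associated partner.
share_fraction <- function(members, D, margin) {
  block <- if (margin == 1) D[members, , drop = FALSE]
           else t(D[, members, drop = FALSE])
  if (ncol(block) == 0) return(0)
  max(colMeans(block == 1))
}

#' Summary statistics of detected modules
#'
#' Per entity class reports the number of retained modules, their average
#' size, the average within-module similarity (mean off-diagonal pairwise
#' similarity among members, averaged over modules) and the average largest
#' fraction of module members that share one common associated partner (a
#' common disease for miRNA modules, a common miRNA for disease modules).
#'
#' @param modset_m,modset_d module sets for miRNAs and diseases.
#' @param Rm_func,Rd_func functional similarity matrices used for the
#'   within-module similarity.
#' @param D binary association matrix.
#' @return Data frame with one row per entity class and columns `class`,
#'   `n_modules`, `avg_size`, `avg_within_similarity`, `avg_share_fraction`,
#'   `empty` (flag: no retained modules).
#' @export
module_summary <- function(modset_m, modset_d, Rm_func, Rd_func, D) {
  one <- function(modset, R, margin) {
    mem <- modset$membership
    if (length(mem) == 0)
      return(c(n_modules = 0, avg_size = 0, avg_within_similarity = 0,
               avg_share_fraction = 0, empty = 1))
    within <- vapply(mem, function(m) {
      sub <- R[m, m, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    share <- vapply(mem, share_fraction, numeric(1), D = D, margin = margin)
    c(n_modules = length(mem), avg_size = mean(lengths(mem)),
      avg_within_similarity = mean(within), avg_share_fraction = mean(share),
      empty = 0)
  }
  res <- rbind(mirna = one(modset_m, Rm_func, 1),
               disease = one(modset_d, Rd_func, 2))
  data.frame(class = rownames(res), res, row.names = NULL)
}

#' Export module memberships as a TSV
#'
#' One row per (entity, retained module) pair with the entity's loading on
#' that module column and its membership threshold.
#'
#' @param modset a [assign_modules()] result.
#' @param G the factor matrix it came from.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_module_table <- function(modset, G, path) {
  rows <- lapply(names(modset$membership), function(k) {
    m <- modset$membership[[k]]
    data.frame(entity = m, module_id = as.integer(k),
               factor_value = G[m, as.integer(k)],
               threshold = modset$thresholds[m],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(entity = character(0), module_id = integer(0),
                      factor_value = numeric(0), threshold = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
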