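#' Area under the ROC curve (rank-sum estimator)
#'
#' The Mann-Whitney probability that a randomly chosen positive outranks a
#' randomly chosen negative, with ties counting one half.
#'
#' @param scores numeric vector of prediction scores.
#' @param labels binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

cv_result <- function(scheme, method, per_unit_auc, repeats, seed,
                      folds = NA_integer_) {
  structure(
    list(scheme = scheme, method = method,
         per_unit_auc = per_unit_auc,
         mean_auc = mean(per_unit_auc),
         sd_auc = if (length(per_unit_auc) > 1) stats::sd(per_unit_auc) else 0,
         repeats = repeats, folds = folds, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s, %s]: mean AUC %.4f +/- %.4f over %d units\n",
              x$scheme, x$method, x$mean_auc, x$sd_auc,
              length(x$per_unit_auc)))
  invisible(x)
}

# Seeded partition of positive indices into `folds` near-equal parts, one
# partition per repeat. Parts are disjoint and their union is `pos`.
cv_fold_assignments <- function(pos, folds, repeats, seed) {
  with_seed(seed, lapply(seq_len(repeats), function(r) {
    perm <- sample(pos)
    split(perm, rep_len(seq_len(folds), length(perm)))
  }))
}

# Mask a set of positive entries (linear indices into D) out of the
# association data: value -> 0, label -> unknown.
mask_positives <- function(assoc, idx) {
  D <- assoc$D; known <- assoc$known
  D[idx] <- 0
  known[idx] <- FALSE
  association_data(D, known)
}

# Fit on a training association and score with one or both methods.
fit_and_score <- function(assoc_tr, dss, dfs, hp, method, t = 1.5) {
  sims <- compute_similarities(assoc_tr, dss = dss, dfs = dfs)
  fit <- mdn_fit(sims$Rm, sims$Rd, assoc_tr, hp)
  D1 <- predict_scores(fit)
  out <- list(nmtf = D1)
  if (method %in% c("nmtf2", "both")) {
    mods_m <- assign_modules(fit$Gm, t)
    mods_d <- assign_modules(fit$Gd, t)
    Pm <- module_score_mirna(mods_m, fit$Gm, assoc_tr$D)
    Pd <- module_score_disease(mods_d, fit$Gd, assoc_tr$D)
    out$nmtf2 <- fuse_predictions(D1, Pm, Pd)
  }
  out
}

#' Randomly-zeroing cross-validation
#'
#' Known positives are partitioned into `folds` near-equal parts. Per fold,
#' the held-out positives are masked to unknown (value 0, weight 0), the
#' association-derived similarities (miRNA functional similarity and both
#' GIP kernels, hence the integrated networks) are recomputed from the
#' training matrix only, the model is refitted, and the AUC is computed over
#' the held-out positives against every pair that is not a training
#' positive. Disease semantic and gene-functional similarity do not depend
#' on the association matrix and are computed once.
#'
#' @param assoc an [association_data()] object (full data).
#' @param dag a [disease_dag()]; ignored when `dss` is supplied.
#' @param disease_genes,gene_sim gene evidence; ignored when `dfs` supplied.
#' @param hp an [mdn_hyperparams()] list.
#' @param folds number of folds; default 5.
#' @param repeats number of repeated partitions; default 1.
#' @param seed integer seed controlling fold assignment.
#' @param method `"nmtf"` (reconstruction scores), `"nmtf2"`
#'   (module-fused scores) or `"both"` (evaluate both on shared fits).
#' @param t module threshold multiplier for the module-fused scores.
#' @param delta semantic contribution factor.
#' @param dss,dfs optional precomputed similarity matrices.
#' @return A `cv_result` (for `"both"`, a list with elements `nmtf` and
#'   `nmtf2` sharing the same folds and fits).
#' @export
random_zeroing_cv <- function(assoc, dag = NULL, disease_genes = NULL,
                              gene_sim = NULL, hp = mdn_hyperparams(),
                              folds = 5, repeats = 1, seed = 1,
                              method = c("nmtf", "nmtf2", "both"),
                              t = 1.5, delta = 0.5,
                              dss = NULL, dfs = NULL) {
  method <- match.arg(method)
  pos <- which(assoc$D == 1)
  if (length(pos) < folds) stop("need at least one positive per fold")
  if (is.null(dss))
    dss <- disease_semantic_similarity(dag, assoc$disease, delta)
  if (is.null(dfs))
    dfs <- disease_functional_similarity(disease_genes, gene_sim,
                                         assoc$disease)
  assignments <- cv_fold_assignments(pos, folds, repeats, seed)
  auc1 <- c(); auc2 <- c()
  for (parts in assignments) {
    for (test_idx in parts) {
      if (length(test_idx) == 0) {
        warning("fold with zero test positives skipped")
        next
      }
      assoc_tr <- mask_positives(assoc, test_idx)
      scores <- fit_and_score(assoc_tr, dss, dfs, hp, method, t)
      candidate <- which(assoc_tr$D != 1)  # everything except training positives
      labels <- as.integer(candidate %in% test_idx)
      if (method %in% c("nmtf", "both"))
        auc1 <- c(auc1, auc_score(scores$nmtf[candidate], labels))
      if (method %in% c("nmtf2", "both"))
        auc2 <- c(auc2, auc_score(scores$nmtf2[candidate], labels))
    }
  }
  if (method == "nmtf")
    return(cv_result("random_zeroing", "nmtf", auc1, repeats, seed, folds))
  if (method == "nmtf2")
    return(cv_result("random_zeroing", "nmtf2", auc2, repeats, seed, folds))
  list(nmtf = cv_result("random_zeroing", "nmtf", auc1, repeats, seed, folds),
       nmtf2 = cv_result("random_zeroing", "nmtf2", auc2, repeats, seed, folds))
}

#' Single-column (cold-start) cross-validation
#'
#' Simulates a new disease: for each disease column holding at least one
#' known positive, the entire column is masked to unknown, the
#' association-derived similarities are recomputed, the model refitted, and
#' the held-out positives of that column are ranked against the column's
#' remaining miRNAs. Columns without positives are excluded (their AUC is
#' undefined). The reported mean is the arithmetic mean of the per-column
#' AUCs.
#'
#' @inheritParams random_zeroing_cv
#' @return A `cv_result` with one AUC per evaluated disease column (for
#'   `"both"`, a list with elements `nmtf` and `nmtf2`).
#' @export
single_column_cv <- function(assoc, dag = NULL, disease_genes = NULL,
                             gene_sim = NULL, hp = mdn_hyperparams(),
                             method = c("nmtf", "nmtf2", "both"),
                             t = 1.5, delta = 0.5, seed = 1,
                             dss = NULL, dfs = NULL) {
  method <- match.arg(method)
  if (is.null(dss))
    dss <- disease_semantic_similarity(dag, assoc$disease, delta)
  if (is.null(dfs))
    dfs <- disease_functional_similarity(disease_genes, gene_sim,
                                         assoc$disease)
  cols <- which(colSums(assoc$D == 1) > 0)
  if (length(cols) == 0) stop("no disease column has a known positive")
  auc1 <- c(); auc2 <- c()
  for (j in cols) {
    held <- which(assoc$D[, j] == 1)
    idx <- (j - 1) * nrow(assoc$D) + seq_len(nrow(assoc$D))
    assoc_tr <- mask_positives(assoc, idx)
    scores <- fit_and_score(assoc_tr, dss, dfs, hp, method, t)
    labels <- as.integer(seq_len(nrow(assoc$D)) %in% held)
    if (method %in% c("nmtf", "both"))
      auc1 <- c(auc1, auc_score(scores$nmtf[, j], labels))
    if (method %in% c("nmtf2", "both"))
      auc2 <- c(auc2, auc_score(scores$nmtf2[, j], labels))
  }
  if (method == "nmtf")
    return(cv_result("single_column", "nmtf", auc1, 1L, seed))
  if (method == "nmtf2")
    return(cv_result("single_column", "nmtf2", auc2, 1L, seed))
  list(nmtf = cv_result("single_column", "nmtf", auc1, 1L, seed),
       nmtf2 = cv_result("single_column", "nmtf2", auc2, 1L, seed))
}
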