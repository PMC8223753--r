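#' Semantic profile of a disease term in the hierarchy
#'
#' Each disease term contributes a semantic value to itself (1) and to each
#' of its ancestors, decaying by a contribution factor `delta` per hierarchy
#' level: the value of an ancestor `t` is `delta` times the largest value
#' among `t`'s children that lie on a path to the disease. The profile total
#' `DS` is the sum of all contributions.
#'
#' @param dag a [disease_dag()].
#' @param d a term identifier in `dag`.
#' @param delta semantic contribution factor in (0, 1); 0.5 by default.
#' @return A list with `disease`, `DV` (named numeric vector over the term
#'   and its ancestors) and `DS` (sum of `DV`).
#' @export
semantic_profile <- function(dag, d, delta = 0.5) {
  if (!inherits(dag, "disease_dag")) stop("dag must be a disease_dag")
  if (!(d %in% dag$nodes)) stop("term not in hierarchy: ", d)
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  g <- dag$graph
  anc <- igraph::subcomponent(g, d, mode = "out")  # d and all ancestors
  sub <- igraph::induced_subgraph(g, anc)
  ord <- igraph::topo_sort(sub, mode = "out")      # children before parents
  names_ord <- igraph::V(sub)$name[as.integer(ord)]
  DV <- stats::setNames(numeric(length(names_ord)), names_ord)
  DV[d] <- 1
  for (t in names_ord) {
    if (t == d) next
    kids <- igraph::neighbors(sub, t, mode = "in")$name
    DV[t] <- delta * max(DV[kids])
  }
  list(disease = d, DV = DV, DS = sum(DV))
}

#' Disease semantic similarity from shared hierarchy ancestors
#'
#' The similarity of two terms is the summed semantic value both assign to
#' their shared ancestor terms, normalized by the sum of their profile
#' totals. Terms in disjoint branches score 0; a term against itself scores
#' 1.
#'
#' @inheritParams semantic_profile
#' @param diseases character vector of term identifiers to compare.
#' @return A labeled similarity matrix over `diseases`.
#' @export
disease_semantic_similarity <- function(dag, diseases, delta = 0.5) {
  profs <- lapply(diseases, semantic_profile, dag = dag, delta = delta)
  n <- length(diseases)
  S <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n)) {
    for (j in i:n) {
      pi <- profs[[i]]; pj <- profs[[j]]
      shared <- intersect(names(pi$DV), names(pj$DV))
      val <- if (length(shared))
        sum(pi$DV[shared] + pj$DV[shared]) / (pi$DS + pj$DS) else 0
      S[i, j] <- S[j, i] <- val
    }
  }
  diag(S) <- 1
  similarity_matrix(S)
}

# Symmetric gene-gene similarity lookup built from a weighted pair table.
# Self-similarity is 1; unlisted pairs score 0.
gene_sim_lookup <- function(gene_sim) {
  env <- new.env(parent = emptyenv(), size = max(2L * nrow(gene_sim), 16L))
  if (nrow(gene_sim)) {
    key <- ifelse(gene_sim$a < gene_sim$b,
                  paste(gene_sim$a, gene_sim$b, sep = "\r"),
                  paste(gene_sim$b, gene_sim$a, sep = "\r"))
    for (i in seq_along(key)) assign(key[i], gene_sim$w[i], envir = env)
  }
  function(ga, gb) {
    if (length(ga) == 0 || length(gb) == 0)
      return(matrix(0, length(ga), length(gb)))
    out <- matrix(0, length(ga), length(gb))
    for (i in seq_along(ga)) {
      for (j in seq_along(gb)) {
        if (ga[i] == gb[j]) { out[i, j] <- 1; next }
        k <- if (ga[i] < gb[j]) paste(ga[i], gb[j], sep = "\r")
             else paste(gb[j], ga[i], sep = "\r")
        v <- get0(k, envir = env, ifnotfound = 0)
        out[i, j] <- v
      }
    }
    out
  }
}

# Best-match average between two evidence sets given a pairwise similarity
# matrix (rows = set a, cols = set b).
best_match_average <- function(simmat) {
  m <- nrow(simmat); n <- ncol(simmat)
  (sum(apply(simmat, 1, max)) + sum(apply(simmat, 2, max))) / (m + n)
}

#' Disease functional similarity from gene evidence
#'
#' Two diseases are functionally similar when their associated gene sets are
#' similar: each gene of one set is matched to its most similar gene in the
#' other set, and the matched similarities are averaged over both
#' directions. Gene-gene similarity defaults to 1 for identical genes and 0
#' for pairs absent from the table. Diseases with no gene evidence get
#' similarity 0 to everything (flagged), which lets the kernel fallback take
#' over at integration.
#'
#' @param disease_genes named list mapping disease identifier to a character
#'   vector of gene identifiers.
#' @param gene_sim a [weighted_pairs()] data frame of gene-gene similarity.
#' @param diseases character vector of diseases to compare.
#' @return A labeled similarity matrix with attribute `flagged` listing the
#'   diseases that had no gene evidence.
#' @export
disease_functional_similarity <- function(disease_genes, gene_sim, diseases) {
  fs <- gene_sim_lookup(weighted_pairs(gene_sim))
  n <- length(diseases)
  S <- matrix(0, n, n, dimnames = list(diseases, diseases))
  sets <- lapply(diseases, function(d) unique(as.character(disease_genes[[d]])))
  empty <- vapply(sets, function(s) length(s) == 0, logical(1))
  for (i in seq_len(n)) {
    if (empty[i]) next
    for (j in i:n) {
      if (empty[j]) next
      S[i, j] <- S[j, i] <- best_match_average(fs(sets[[i]], sets[[j]]))
    }
  }
  out <- similarity_matrix(pmin(S, 1))
  attr(out, "flagged") <- diseases[empty]
  out
}

#' miRNA functional similarity from associated-disease sets
#'
#' Two miRNAs are functionally similar when the diseases they associate with
#' are semantically similar: best-match averaging of the disease semantic
#' similarity across the two associated-disease sets, in both directions.
#' miRNAs with no known associated disease get similarity 0 (flagged) and
#' fall back to the interaction-profile kernel at integration.
#'
#' @param assoc an [association_data()] object.
#' @param dss disease semantic similarity matrix covering (at least) the
#'   diseases of `assoc`.
#' @return A labeled similarity matrix over the miRNAs of `assoc`, with
#'   attribute `flagged` listing miRNAs without associations.
#' @export
mirna_functional_similarity <- function(assoc, dss) {
  if (!all(assoc$disease %in% rownames(dss)))
    stop("dss must cover every disease in the association data")
  mir <- assoc$mirna
  n <- length(mir)
  DT <- lapply(seq_len(n), function(i) assoc$disease[assoc$D[i, ] == 1])
  empty <- vapply(DT, function(s) length(s) == 0, logical(1))
  S <- matrix(0, n, n, dimnames = list(mir, mir))
  for (i in seq_len(n)) {
    if (empty[i]) next
    for (j in i:n) {
      if (empty[j]) next
      block <- dss[DT[[i]], DT[[j]], drop = FALSE]
      S[i, j] <- S[j, i] <- best_match_average(block)
    }
  }
  out <- similarity_matrix(pmin(S, 1))
  attr(out, "flagged") <- mir[empty]
  out
}

#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' The interaction profile of an entity is its binary row of the association
#' matrix. The kernel similarity of two entities is
#' `exp(-gamma * ||IP_i - IP_j||^2)` with bandwidth
#' `gamma = gamma_prime / mean_i ||IP_i||^2`, i.e. a reference bandwidth
#' normalized by the average squared profile size.
#'
#' @param profiles numeric matrix; one row per entity (labeled), binary in
#'   typical use.
#' @param gamma_prime reference bandwidth, 1 by default.
#' @return A labeled similarity matrix over the profile rows.
#' @export
gip_kernel <- function(profiles, gamma_prime = 1) {
  if (!is.matrix(profiles)) stop("profiles must be a matrix")
  if (gamma_prime <= 0) stop("gamma_prime must be positive")
  sq <- rowSums(profiles^2)
  msq <- mean(sq)
  if (msq == 0) stop("all interaction profiles are zero; bandwidth undefined")
  gamma <- gamma_prime / msq
  gram <- tcrossprod(profiles)
  d2 <- outer(sq, sq, "+") - 2 * gram
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  diag(K) <- 1
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("e", seq_len(nrow(profiles)))
  similarity_matrix(K, rownames(profiles))
}

#' Integrate a primary similarity with a kernel fallback
#'
#' Entrywise: keep the primary similarity where it is positive, otherwise
#' substitute the fallback (typically a GIP kernel). This fills in pairs for
#' which no functional evidence exists.
#'
#' @param primary,fallback labeled similarity matrices over the same
#'   entities in the same order.
#' @return The integrated similarity matrix.
#' @export
integrate_similarity <- function(primary, fallback) {
  if (!identical(rownames(primary), rownames(fallback)))
    stop("primary and fallback similarity labels disagree")
  out <- ifelse(primary > 0, primary, fallback)
  similarity_matrix(out, rownames(primary))
}

#' Build the integrated miRNA and disease similarity networks
#'
#' Convenience wrapper that assembles all five similarity matrices and the
#' two integrated networks: disease semantic similarity (from the term
#' hierarchy), disease functional similarity (from gene evidence), miRNA
#' functional similarity (from associated-disease sets and the semantic
#' similarity), and GIP kernels for both sides computed from the association
#' matrix. The integrated miRNA network is the functional similarity with
#' GIP fallback; the integrated disease network is the functional (gene)
#' similarity with GIP fallback.
#'
#' `dss` and `dfs` do not depend on the association matrix, so
#' cross-validation callers precompute them once and pass them in.
#'
#' @inheritParams mirna_functional_similarity
#' @inheritParams disease_functional_similarity
#' @param dag a [disease_dag()] covering the diseases of `assoc`.
#' @param delta semantic contribution factor.
#' @param gamma_mirna,gamma_disease GIP reference bandwidths.
#' @param dss,dfs optional precomputed semantic / functional disease
#'   similarity matrices.
#' @return A list with `Rm`, `Rd`, `Mfs`, `Dss`, `Dfs`, `gip_m`, `gip_d`.
#' @export
compute_similarities <- function(assoc, dag = NULL, disease_genes = NULL,
                                 gene_sim = NULL, delta = 0.5,
                                 gamma_mirna = 1, gamma_disease = 1,
                                 dss = NULL, dfs = NULL) {
  if (is.null(dss)) {
    if (is.null(dag)) stop("either dag or a precomputed dss is required")
    dss <- disease_semantic_similarity(dag, assoc$disease, delta)
  }
  if (is.null(dfs)) {
    if (is.null(disease_genes) || is.null(gene_sim))
      stop("either gene evidence or a precomputed dfs is required")
    dfs <- disease_functional_similarity(disease_genes, gene_sim,
                                         assoc$disease)
  }
  mfs <- mirna_functional_similarity(assoc, dss)
  gip_m <- gip_kernel(assoc$D, gamma_mirna)
  gip_d <- gip_kernel(t(assoc$D), gamma_disease)
  list(
    Rm = integrate_similarity(mfs, gip_m),
    Rd = integrate_similarity(dfs[assoc$disease, assoc$disease], gip_d),
    Mfs = mfs, Dss = dss, Dfs = dfs, gip_m = gip_m, gip_d = gip_d
  )
}
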