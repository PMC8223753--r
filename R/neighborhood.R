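#' Dynamic neighbor count from a ranked similarity vector
#'
#' Given an entity's similarities to all other entities ranked from high to
#' low, the neighbor count is the length `H` of the longest prefix such that
#' `1 - sim[l] <= epsilon^l` holds for every position `l = 1..H`. Highly
#' similar neighbors keep the dissimilarity `1 - sim` below an exponentially
#' tightening budget; the first position that breaks the budget ends the
#' neighborhood. Returns 0 when even the top neighbor fails.
#'
#' @param ranked_sims numeric vector sorted in descending order, values in
#'   `[0, 1]`, self-similarity excluded.
#' @param epsilon control parameter in (0, 1); default 0.56.
#' @return Integer neighbor count `h`.
#' @export
neighbor_count <- function(ranked_sims, epsilon = 0.56) {
  if (length(ranked_sims) == 0) return(0L)
  if (is.unsorted(rev(ranked_sims))) stop("ranked_sims must be sorted descending")
  ok <- (1 - ranked_sims) <= epsilon^seq_along(ranked_sims)
  if (!ok[1]) return(0L)
  first_fail <- match(FALSE, ok)
  if (is.na(first_fail)) length(ranked_sims) else first_fail - 1L
}

#' Build a dynamic nearest-neighborhood graph and its Laplacian
#'
#' For each entity, the per-entity neighbor count is found with
#' [neighbor_count()] on its non-self similarities; row `i` of the weight
#' matrix keeps the similarity to those top-ranked neighbors and is 0
#' elsewhere. Candidates tied with the last kept neighbor's similarity are
#' all included, making the graph independent of sort order. The (directed)
#' graph Laplacian is `L = (Dout + Din) - (W + t(W))` where `Dout`/`Din`
#' hold row/column sums of the weight matrix; `L` is symmetric positive
#' semidefinite with zero row sums.
#'
#' @param R labeled similarity matrix.
#' @param epsilon dynamic-neighborhood control parameter.
#' @return An object of class `neighborhood_graph`: list with `weights`,
#'   `out_degree`, `in_degree`, `laplacian`, `epsilon`, `neighbor_counts`.
#' @export
build_neighborhood <- function(R, epsilon = 0.56) {
  if (is.null(rownames(R)))
    dimnames(R) <- rep(list(paste0("e", seq_len(nrow(R)))), 2)
  R <- similarity_matrix(R)
  n <- nrow(R)
  W <- matrix(0, n, n, dimnames = dimnames(R))
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    sims <- R[i, cand]
    ord <- order(sims, decreasing = TRUE)
    h <- neighbor_count(unname(sims[ord]), epsilon)
    if (h > 0) {
      cutoff <- sims[ord][h]
      keep <- cand[sims >= cutoff]
      W[i, keep] <- R[i, keep]
    }
  }
  dout <- rowSums(W)
  din <- colSums(W)
  L <- diag(dout + din, n) - (W + t(W))
  dimnames(L) <- dimnames(R)
  structure(
    list(weights = W,
         out_degree = diag(dout, n),
         in_degree = diag(din, n),
         laplacian = L,
         epsilon = epsilon,
         neighbor_counts = rowSums(W > 0)),
    class = "neighborhood_graph"
  )
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat(sprintf(
    "neighborhood_graph: %d entities, epsilon = %g, mean neighbors = %.2f\n",
    nrow(x$weights), x$epsilon, mean(x$neighbor_counts)))
  invisible(x)
}

#' Graph-regularization penalty of a factor matrix
#'
#' Evaluates `trace(t(G) %*% L %*% G)`, which for the neighborhood Laplacian
#' equals the weighted sum over neighbor pairs of squared latent-vector
#' differences: entities that are near neighbors are pushed toward similar
#' latent representations.
#'
#' @param G numeric factor matrix (entities x latent dimensions).
#' @param L Laplacian matrix conformable with `G`.
#' @return Non-negative scalar penalty.
#' @export
regularizer_value <- function(G, L) {
  sum(diag(crossprod(G, L %*% G)))
}
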