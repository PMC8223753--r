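# Shared fixture builders. Everything is generated in code; no data files.

# Random labeled similarity matrix: symmetric, unit diagonal, entries [0,1].
random_sim <- function(n, prefix = "e") {
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- rep(list(paste0(prefix, seq_len(n))), 2)
  m
}

# Random labeled binary association data.
random_assoc <- function(n_m, n_d, density = 0.15) {
  D <- matrix(stats::rbinom(n_m * n_d, 1, density), n_m, n_d,
              dimnames = list(paste0("m", seq_len(n_m)),
                              paste0("d", seq_len(n_d))))
  association_data(D)
}

# Write lines to a temp TSV and return the path.
tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Small hyperparameter set for fast fits in unit tests.
fast_hp <- function(...) {
  args <- utils::modifyList(list(k_m = 4, k_d = 4, max_iter = 150),
                            list(...))
  do.call(mdn_hyperparams, args)
}

# Minimal module_set construction for score tests with hand-chosen modules.
manual_module_set <- function(labels, membership, n_modules) {
  structure(
    list(entity_labels = labels, membership = membership,
         thresholds = stats::setNames(rep(0, length(labels)), labels),
         t = 1.5,
         dropped = setdiff(seq_len(n_modules),
                           as.integer(names(membership))),
         n_modules = n_modules),
    class = "module_set"
  )
}

# Brute-force double-loop oracle for module-propagated miRNA scores.
oracle_module_score_mirna <- function(modset, G, D) {
  n_m <- nrow(D); n_d <- ncol(D)
  out <- matrix(0, n_m, n_d, dimnames = dimnames(D))
  if (length(modset$membership) == 0) return(out)
  for (members in modset$membership) {
    for (i in seq_len(n_m)) {
      den <- 0
      for (q in seq_len(n_m))
        den <- den + cosine_similarity(G[i, ], G[q, ])
      for (j in seq_len(n_d)) {
        num <- 0
        for (q in match(members, rownames(D)))
          num <- num + cosine_similarity(G[i, ], G[q, ]) * D[q, j]
        out[i, j] <- out[i, j] + num / den
      }
    }
  }
  out / length(modset$membership)
}

# Brute-force oracle for the disease-side twin.
oracle_module_score_disease <- function(modset, G, D) {
  n_m <- nrow(D); n_d <- ncol(D)
  out <- matrix(0, n_m, n_d, dimnames = dimnames(D))
  if (length(modset$membership) == 0) return(out)
  for (members in modset$membership) {
    for (j in seq_len(n_d)) {
      den <- 0
      for (q in seq_len(n_d))
        den <- den + cosine_similarity(G[j, ], G[q, ])
      for (i in seq_len(n_m)) {
        num <- 0
        for (q in match(members, colnames(D)))
          num <- num + cosine_similarity(G[j, ], G[q, ]) * D[i, q]
        out[i, j] <- out[i, j] + num / den
      }
    }
  }
  out / length(modset$membership)
}

# Co-membership agreement of a module set with planted partition labels,
# measured on the upper triangle, plus a label-shuffled baseline.
co_membership_agreement <- function(modset, truth, perm) {
  n <- length(truth)
  C <- matrix(0, n, n, dimnames = list(names(truth), names(truth)))
  for (m in modset$membership) C[m, m] <- 1
  P <- outer(truth, truth, "==") * 1
  ut <- upper.tri(C)
  c(agreement = mean((C == P)[ut]),
    shuffled = mean((C[perm, perm] == P)[ut]))
}
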