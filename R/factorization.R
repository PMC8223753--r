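#' Hyperparameters of the tri-factorization model
#'
#' Returns the model's tunable parameters with their default settings:
#' `lambda1`, `lambda2`, `lambda3` balance the three reconstruction terms
#' (miRNA similarity, weighted association matrix, disease similarity);
#' `alpha1`, `alpha2` are ridge penalties on the latent factors; `beta1`,
#' `beta2` weight the dynamic-neighborhood graph regularizers; `omega`
#' enforces near-orthonormal columns of the module-association core `K`.
#' `k_m`, `k_d` are the latent dimensions (number of candidate miRNA /
#' disease modules), `epsilon` the neighborhood control parameter, `w_neg`
#' the label weight of known negatives, `floor` the positivity floor applied
#' after every update, `tol` the absolute objective-change convergence
#' threshold and `max_iter` the iteration cap.
#'
#' @param lambda1,lambda2,lambda3,alpha1,alpha2,beta1,beta2,omega
#'   non-negative model weights.
#' @param k_m,k_d positive latent dimensions; clamped to `n - 1` at fit time
#'   for small inputs.
#' @param epsilon dynamic-neighborhood control parameter in (0, 1).
#' @param w_neg label weight for known negatives, in `[0, 1]`.
#' @param floor positivity floor.
#' @param tol convergence tolerance on the objective change.
#' @param max_iter maximum number of update sweeps.
#' @param seed integer seed for the random factor initialization.
#' @param symmetrize_laplacian if `TRUE`, the factor updates use the
#'   symmetrized neighborhood matrix `W + t(W)` and total degree
#'   `Dout + Din` (the variant consistent with the Laplacian penalty's
#'   gradient); the default uses the one-sided weight matrix and out-degree.
#' @param monotone if `TRUE` (default), each multiplicative sub-update is
#'   guarded by exponent backtracking: when the full update would increase
#'   the objective, the update ratio is raised to successively halved
#'   exponents until the objective no longer increases (the update is
#'   skipped if none helps). This restores the monotone descent that the
#'   raw update rules do not guarantee for the quartic objective terms; see
#'   the methods vignette.
#' @return A list of class `mdn_hyperparams`.
#' @export
mdn_hyperparams <- function(lambda1 = 0.001, lambda2 = 5, lambda3 = 0.1,
                            alpha1 = 0.2, alpha2 = 0.8,
                            beta1 = 90, beta2 = 1.5, omega = 160,
                            k_m = 200, k_d = 200,
                            epsilon = 0.56, w_neg = 0.2,
                            floor = 1e-9, tol = 1e-6, max_iter = 1000,
                            seed = 1L, symmetrize_laplacian = FALSE,
                            monotone = TRUE) {
  hp <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
             alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
             omega = omega, k_m = as.integer(k_m), k_d = as.integer(k_d),
             epsilon = epsilon, w_neg = w_neg, floor = floor, tol = tol,
             max_iter = as.integer(max_iter), seed = as.integer(seed),
             symmetrize_laplacian = isTRUE(symmetrize_laplacian),
             monotone = isTRUE(monotone))
  stopifnot(all(vapply(hp[1:8], function(x) x >= 0, logical(1))),
            hp$k_m >= 1, hp$k_d >= 1,
            hp$epsilon > 0, hp$epsilon < 1,
            hp$w_neg >= 0, hp$w_neg <= 1,
            hp$floor > 0, hp$tol > 0, hp$max_iter >= 1)
  class(hp) <- "mdn_hyperparams"
  hp
}

#' Label weight matrix
#'
#' Entries are 1 on known positives, `w_neg` on known negatives and 0 on
#' unknown pairs, so that unobserved pairs carry no weight in the
#' association reconstruction term while observed absences contribute with a
#' reduced confidence (absence of annotation is weaker evidence than
#' presence).
#'
#' @param assoc an [association_data()] object.
#' @param w_neg weight of known negatives; default 0.2.
#' @return Numeric matrix shaped like `assoc$D`.
#' @export
build_label_weights <- function(assoc, w_neg = 0.2) {
  Y <- matrix(0, nrow(assoc$D), ncol(assoc$D), dimnames = dimnames(assoc$D))
  Y[assoc$known & assoc$D == 1] <- 1
  Y[assoc$known & assoc$D == 0] <- w_neg
  Y
}

fnorm2 <- function(X) sum(X * X)

#' Objective function of the tri-factorization model
#'
#' Sum of the three weighted squared-Frobenius reconstruction residuals
#' (`Rm ~ Gm Sm Gm'`, `Y o (D - Gm K Gd')`, `Rd ~ Gd Sd Gd'`), ridge
#' penalties on `Gm` and `Gd`, the two Laplacian regularizers and the
#' near-orthonormality penalty `||K'K - I||^2`.
#'
#' @param state list with factor matrices `Gm`, `Gd`, `Sm`, `Sd`, `K`.
#' @param Rm,Rd similarity matrices.
#' @param D association matrix; `Y` its label weight matrix.
#' @param Y label weight matrix.
#' @param Lm,Ld neighborhood Laplacians.
#' @param hp an [mdn_hyperparams()] list.
#' @return Finite scalar objective value.
#' @export
objective_value <- function(state, Rm, Rd, D, Y, Lm, Ld, hp) {
  Gm <- state$Gm; Gd <- state$Gd
  obj <- hp$lambda1 * fnorm2(Rm - Gm %*% state$Sm %*% t(Gm)) +
    hp$lambda2 * fnorm2(Y * (D - Gm %*% state$K %*% t(Gd))) +
    hp$lambda3 * fnorm2(Rd - Gd %*% state$Sd %*% t(Gd)) +
    hp$alpha1 * fnorm2(Gm) + hp$alpha2 * fnorm2(Gd) +
    hp$beta1 * regularizer_value(Gm, Lm) +
    hp$beta2 * regularizer_value(Gd, Ld) +
    hp$omega * fnorm2(crossprod(state$K) - diag(ncol(state$K)))
  if (!is.finite(obj)) stop("objective is not finite")
  obj
}

floor_mat <- function(X, floor) {
  X[X < floor] <- floor
  X
}

safe_div <- function(num, den) num / pmax(den, .Machine$double.xmin)

# Update ratios (negative over positive gradient part) for the five factors.
ratio_sm <- function(state, Rm) {
  GtG <- crossprod(state$Gm)
  safe_div(crossprod(state$Gm, Rm %*% state$Gm),
           GtG %*% state$Sm %*% GtG)
}

ratio_sd <- function(state, Rd) {
  GtG <- crossprod(state$Gd)
  safe_div(crossprod(state$Gd, Rd %*% state$Gd),
           GtG %*% state$Sd %*% GtG)
}

ratio_gm <- function(state, Rm, D, Y, A, Adeg, hp) {
  Gm <- state$Gm; Gd <- state$Gd; Sm <- state$Sm; K <- state$K
  num <- 2 * hp$lambda1 * Rm %*% Gm %*% Sm +
    hp$lambda2 * (Y * D) %*% Gd %*% t(K) + hp$beta1 * A %*% Gm
  den <- 2 * hp$lambda1 * Gm %*% Sm %*% crossprod(Gm) %*% Sm +
    hp$lambda2 * (Y * (Gm %*% K %*% t(Gd))) %*% Gd %*% t(K) +
    hp$alpha1 * Gm + hp$beta1 * Adeg %*% Gm
  safe_div(num, den)
}

ratio_gd <- function(state, Rd, D, Y, A, Adeg, hp) {
  Gm <- state$Gm; Gd <- state$Gd; Sd <- state$Sd; K <- state$K
  num <- 2 * hp$lambda3 * Rd %*% Gd %*% Sd +
    hp$lambda2 * t(Y * D) %*% Gm %*% K + hp$beta2 * A %*% Gd
  den <- 2 * hp$lambda3 * Gd %*% Sd %*% crossprod(Gd) %*% Sd +
    hp$lambda2 * t(Y * (Gm %*% K %*% t(Gd))) %*% Gm %*% K +
    hp$alpha2 * Gd + hp$beta2 * Adeg %*% Gd
  safe_div(num, den)
}

ratio_k <- function(state, D, Y, hp) {
  Gm <- state$Gm; Gd <- state$Gd; K <- state$K
  num <- hp$lambda2 * crossprod(Gm, (Y * D) %*% Gd) + 2 * hp$omega * K
  den <- hp$lambda2 * crossprod(Gm, (Y * (Gm %*% K %*% t(Gd))) %*% Gd) +
    2 * hp$omega * K %*% crossprod(K)
  safe_div(num, den)
}

#' Multiplicative update of the miRNA module-relationship core `Sm`
#'
#' `Sm <- Sm o (Gm' Rm Gm) / (Gm' Gm Sm Gm' Gm)`, floored and symmetrized.
#' `update_sd` is the disease-side twin.
#'
#' @inheritParams objective_value
#' @return Updated factor matrix.
#' @export
update_sm <- function(state, Rm, hp) {
  S <- floor_mat(state$Sm * ratio_sm(state, Rm), hp$floor)
  (S + t(S)) / 2
}

#' @rdname update_sm
#' @export
update_sd <- function(state, Rd, hp) {
  S <- floor_mat(state$Sd * ratio_sd(state, Rd), hp$floor)
  (S + t(S)) / 2
}

#' Multiplicative update of the miRNA latent factor `Gm`
#'
#' Ratio of the gradient's negative part
#' `2 l1 Rm Gm Sm + l2 (Y o D) Gd K' + b1 A Gm` to its positive part
#' `2 l1 Gm Sm Gm'Gm Sm + l2 (Y o (Gm K Gd')) Gd K' + a1 Gm + b1 Dm Gm`,
#' floored. `A` is the neighborhood weight matrix and `Dm` its degree
#' diagonal (one-sided by default, symmetrized under
#' `hp$symmetrize_laplacian`). `update_gd` is the disease-side twin.
#'
#' @inheritParams objective_value
#' @param A neighborhood weight matrix (miRNA side for `update_gm`,
#'   disease side for `update_gd`).
#' @param Adeg matching degree diagonal matrix.
#' @return Updated factor matrix.
#' @export
update_gm <- function(state, Rm, D, Y, A, Adeg, hp) {
  floor_mat(state$Gm * ratio_gm(state, Rm, D, Y, A, Adeg, hp), hp$floor)
}

#' @rdname update_gm
#' @export
update_gd <- function(state, Rd, D, Y, A, Adeg, hp) {
  floor_mat(state$Gd * ratio_gd(state, Rd, D, Y, A, Adeg, hp), hp$floor)
}

#' Multiplicative update of the module-association core `K`
#'
#' `K <- K o (l2 Gm'(Y o D)Gd + 2 w K) / (l2 Gm'(Y o (Gm K Gd'))Gd +
#' 2 w K K'K)`, floored.
#'
#' @inheritParams objective_value
#' @return Updated core matrix.
#' @export
update_k <- function(state, D, Y, hp) {
  floor_mat(state$K * ratio_k(state, D, Y, hp), hp$floor)
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit the modularity-preserving tri-factorization model
#'
#' Builds the dynamic neighborhood graphs from `Rm` and `Rd`, initializes
#' the factors with seeded uniform-random positive entries, then cycles the
#' five multiplicative updates (`Sm`, `Sd`, `Gm`, `Gd`, `K`) until the
#' absolute objective change drops below `hp$tol` or `hp$max_iter` sweeps
#' are reached. Every factor entry is floored at `hp$floor` after each
#' update, so all factors stay strictly positive.
#'
#' @param Rm,Rd integrated miRNA / disease similarity matrices whose labels
#'   match `assoc`.
#' @param assoc an [association_data()] object.
#' @param hp an [mdn_hyperparams()] list.
#' @return An object of class `mdn_fit`: list with the factor matrices
#'   `Gm`, `Gd`, `Sm`, `Sd`, `K`, the `objective_trace` (initial value
#'   first), `iterations`, `converged`, the two `neighborhood` graphs, the
#'   label weight matrix `Y` and the (possibly clamped) `hp`.
#' @export
mdn_fit <- function(Rm, Rd, assoc, hp = mdn_hyperparams()) {
  stopifnot(inherits(assoc, "assoc_data"))
  if (!identical(rownames(Rm), assoc$mirna) ||
      !identical(rownames(Rd), assoc$disease))
    stop("similarity labels must match the association data")
  n_m <- length(assoc$mirna); n_d <- length(assoc$disease)
  if (hp$k_m > n_m - 1 || hp$k_d > n_d - 1) {
    hp$k_m <- min(hp$k_m, n_m - 1L)
    hp$k_d <- min(hp$k_d, n_d - 1L)
    warning(sprintf("latent dimensions clamped to (%d, %d) for a %d x %d problem",
                    hp$k_m, hp$k_d, n_m, n_d))
  }
  D <- assoc$D
  Y <- build_label_weights(assoc, hp$w_neg)
  nb_m <- build_neighborhood(Rm, hp$epsilon)
  nb_d <- build_neighborhood(Rd, hp$epsilon)
  if (hp$symmetrize_laplacian) {
    Am <- nb_m$weights + t(nb_m$weights); Am_deg <- nb_m$out_degree + nb_m$in_degree
    Ad <- nb_d$weights + t(nb_d$weights); Ad_deg <- nb_d$out_degree + nb_d$in_degree
  } else {
    Am <- nb_m$weights; Am_deg <- nb_m$out_degree
    Ad <- nb_d$weights; Ad_deg <- nb_d$out_degree
  }
  # Uniform-random positive init: latent factors scaled so the initial
  # bipartite reconstruction sits near the data scale, the core K with
  # near-unit-norm columns (the regime where its orthogonality update is
  # well behaved).
  sc <- max(mean(D), 0.01)
  state <- with_seed(hp$seed, {
    gm <- matrix(stats::runif(n_m * hp$k_m), n_m) * sqrt(sc / hp$k_m)
    gd <- matrix(stats::runif(n_d * hp$k_d), n_d) * sqrt(sc / hp$k_d)
    k0 <- matrix(stats::runif(hp$k_m * hp$k_d), hp$k_m) * sqrt(3 / hp$k_m)
    sm <- matrix(stats::runif(hp$k_m^2), hp$k_m); sm <- (sm + t(sm)) / 2
    sd_ <- matrix(stats::runif(hp$k_d^2), hp$k_d); sd_ <- (sd_ + t(sd_)) / 2
    list(Gm = floor_mat(gm, hp$floor), Gd = floor_mat(gd, hp$floor),
         Sm = floor_mat(sm, hp$floor), Sd = floor_mat(sd_, hp$floor),
         K = floor_mat(k0, hp$floor))
  })
  obj_fun <- function(st) objective_value(st, Rm, Rd, D, Y,
                                          nb_m$laplacian, nb_d$laplacian, hp)
  # Apply one multiplicative sub-update, backtracking the exponent of the
  # update ratio when it would increase the objective (monotone safeguard).
  apply_update <- function(state, field, ratio, cur_obj) {
    etas <- if (hp$monotone) c(1, 0.5, 0.25, 0.125) else 1
    for (eta in etas) {
      cand <- floor_mat(state[[field]] * ratio^eta, hp$floor)
      if (field %in% c("Sm", "Sd")) cand <- (cand + t(cand)) / 2
      st2 <- state
      st2[[field]] <- cand
      new_obj <- obj_fun(st2)
      if (!hp$monotone || new_obj <= cur_obj)
        return(list(state = st2, obj = new_obj))
    }
    list(state = state, obj = cur_obj)  # skip: no exponent helped
  }
  trace <- obj_fun(state)
  cur <- trace
  iter <- 0L
  converged <- FALSE
  while (iter < hp$max_iter) {
    iter <- iter + 1L
    step <- apply_update(state, "Sm", ratio_sm(state, Rm), cur)
    step <- apply_update(step$state, "Sd", ratio_sd(step$state, Rd), step$obj)
    step <- apply_update(step$state, "Gm",
                         ratio_gm(step$state, Rm, D, Y, Am, Am_deg, hp),
                         step$obj)
    step <- apply_update(step$state, "Gd",
                         ratio_gd(step$state, Rd, D, Y, Ad, Ad_deg, hp),
                         step$obj)
    step <- apply_update(step$state, "K", ratio_k(step$state, D, Y, hp),
                         step$obj)
    state <- step$state
    cur <- step$obj
    trace <- c(trace, cur)
    if (abs(trace[iter + 1] - trace[iter]) < hp$tol) {
      converged <- TRUE
      break
    }
  }
  rownames(state$Gm) <- assoc$mirna
  rownames(state$Gd) <- assoc$disease
  structure(
    c(state,
      list(objective_trace = trace, iterations = iter, converged = converged,
           neighborhood_m = nb_m, neighborhood_d = nb_d, Y = Y,
           mirna = assoc$mirna, disease = assoc$disease, hp = hp)),
    class = "mdn_fit"
  )
}

#' @export
print.mdn_fit <- function(x, ...) {
  cat(sprintf(
    "mdn_fit: %d miRNAs x %d diseases, k = (%d, %d), %d iterations (%s), objective %.6g -> %.6g\n",
    length(x$mirna), length(x$disease), x$hp$k_m, x$hp$k_d, x$iterations,
    if (x$converged) "converged" else "iteration cap",
    x$objective_trace[1], utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Reconstructed association scores
#'
#' The predicted association probability matrix `D1 = Gm K Gd'`: the inner
#' product of each miRNA's and disease's latent module loadings through the
#' module-association core.
#'
#' @param fit an [mdn_fit()] object.
#' @return Labeled non-negative miRNA-by-disease score matrix.
#' @export
predict_scores <- function(fit) {
  scores <- fit$Gm %*% fit$K %*% t(fit$Gd)
  dimnames(scores) <- list(fit$mirna, fit$disease)
  scores
}
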