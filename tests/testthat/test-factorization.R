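scalar_state <- function(v = 1) {
  list(Gm = matrix(v), Gd = matrix(v), Sm = matrix(v), Sd = matrix(v),
       K = matrix(v))
}
one <- matrix(1)

test_that("label weights encode positive / negative / unknown classes", {
  D <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
  known <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, dimnames = dimnames(D))
  Y <- build_label_weights(association_data(D, known), w_neg = 0.2)
  expect_equal(Y["m1", "d1"], 1)     # known positive
  expect_equal(Y["m2", "d1"], 0.2)   # known negative
  expect_equal(Y["m1", "d2"], 0)     # unknown
})

test_that("objective evaluates exactly on degenerate cases", {
  hp0 <- mdn_hyperparams(lambda1 = 0, lambda2 = 0, lambda3 = 0, alpha1 = 0,
                         alpha2 = 0, beta1 = 0, beta2 = 0, omega = 0,
                         k_m = 1, k_d = 1)
  st <- scalar_state()
  expect_equal(objective_value(st, one, one, one, one, matrix(0), matrix(0),
                               hp0), 0)

  # scalar all-ones case under defaults: every residual term vanishes,
  # leaving the two ridge penalties alpha1 + alpha2 = 1.0
  hp <- mdn_hyperparams(k_m = 1, k_d = 1)
  expect_equal(objective_value(st, one, one, one, one, matrix(0), matrix(0),
                               hp), 1.0)

  # orthonormal K contributes nothing through the omega term
  st2 <- scalar_state()
  st2$K <- matrix(1)  # K'K = I for the 1x1 case
  hp_om <- mdn_hyperparams(lambda1 = 0, lambda2 = 0, lambda3 = 0,
                           alpha1 = 0, alpha2 = 0, beta1 = 0, beta2 = 0,
                           omega = 5, k_m = 1, k_d = 1)
  expect_equal(objective_value(st2, one, one, one, one, matrix(0), matrix(0),
                               hp_om), 0)
})

test_that("multiplicative updates hit their scalar fixed points and targets", {
  hp <- mdn_hyperparams(k_m = 1, k_d = 1)
  st <- scalar_state()

  # ratio 1 everywhere: nothing moves
  expect_equal(update_sm(st, one, hp), one)
  expect_equal(update_sd(st, one, hp), one)
  expect_equal(update_k(st, one, one, hp), one)

  # scalar S update: Gm = 1, Rm = 2, Sm = 1 -> 2
  expect_equal(update_sm(st, matrix(2), hp), matrix(2))

  # scalar G update with only the lambda1 term active: Rm = 2 -> Gm = 2
  hp_g <- mdn_hyperparams(lambda2 = 0, alpha1 = 0, beta1 = 0, k_m = 1, k_d = 1)
  expect_equal(update_gm(st, matrix(2), one, one, matrix(0), matrix(0), hp_g),
               matrix(2))

  # scalar K update: lambda2 = 1, omega = 0, D = 2 -> K = 2
  hp_k <- mdn_hyperparams(lambda2 = 1, omega = 0, k_m = 1, k_d = 1)
  expect_equal(update_k(st, matrix(2), one, hp_k), matrix(2))

  # orthonormal K with lambda2 = 0 is a fixed point of the K update
  hp_o <- mdn_hyperparams(lambda2 = 0, k_m = 1, k_d = 1)
  expect_equal(update_k(st, one, one, hp_o), one)

  # zero numerator floors the entry instead of zeroing it
  out <- update_sm(st, matrix(0), hp)
  expect_equal(out[1, 1], hp$floor)
})

test_that("a full sweep at an elementwise fixed point changes nothing", {
  # ridge terms off so the all-ones state has unit update ratios throughout
  hp <- mdn_hyperparams(alpha1 = 0, alpha2 = 0, k_m = 1, k_d = 1)
  st <- scalar_state()
  A <- matrix(0); Adeg <- matrix(0)
  st2 <- st
  st2$Sm <- update_sm(st2, one, hp)
  st2$Sd <- update_sd(st2, one, hp)
  st2$Gm <- update_gm(st2, one, one, one, A, Adeg, hp)
  st2$Gd <- update_gd(st2, one, one, one, A, Adeg, hp)
  st2$K <- update_k(st2, one, one, hp)
  expect_equal(st2, st, tolerance = 1e-12)
})

test_that("fitting is deterministic and decreases the objective", {
  set.seed(21)
  Rm <- random_sim(15, "m"); Rd <- random_sim(10, "d")
  assoc <- random_assoc(15, 10, 0.2)
  hp <- fast_hp(seed = 2)
  f1 <- mdn_fit(Rm, Rd, assoc, hp)
  f2 <- mdn_fit(Rm, Rd, assoc, hp)
  expect_identical(predict_scores(f1), predict_scores(f2))
  expect_identical(f1$objective_trace, f2$objective_trace)

  tr <- f1$objective_trace
  expect_lt(tr[length(tr)], tr[1])
  expect_true(all(diff(tr) <= 0))

  # positivity floor and core symmetry hold after fitting
  expect_true(all(f1$Gm >= hp$floor) && all(f1$Gd >= hp$floor))
  expect_true(all(f1$K >= hp$floor))
  expect_lt(max(abs(f1$Sm - t(f1$Sm))), 1e-8)
  expect_lt(max(abs(f1$Sd - t(f1$Sd))), 1e-8)

  # prediction scores are the factor product, non-negative
  expect_equal(predict_scores(f1), f1$Gm %*% f1$K %*% t(f1$Gd),
               ignore_attr = TRUE)
  expect_true(all(predict_scores(f1) >= 0))
})

test_that("unknown-labeled entries cannot influence the fit", {
  set.seed(31)
  D <- matrix(rbinom(60, 1, 0.3), 10, 6,
              dimnames = list(paste0("m", 1:10), paste0("d", 1:6)))
  known <- matrix(TRUE, 10, 6, dimnames = dimnames(D))
  known[D == 0][1:10] <- FALSE  # mask ten zero entries as unknown
  assoc <- association_data(D, known)
  Y <- build_label_weights(assoc)
  hp <- fast_hp()

  # perturb D wherever Y = 0: objective and every update ratio unchanged
  D_pert <- D
  D_pert[Y == 0] <- 7
  st <- list(Gm = matrix(runif(40), 10), Gd = matrix(runif(24), 6),
             Sm = diag(4) + 0.1, Sd = diag(4) + 0.1,
             K = matrix(runif(16), 4))
  L0 <- matrix(0, 10, 10); L0d <- matrix(0, 6, 6)
  Rm10 <- random_sim(10, "m"); Rd6 <- random_sim(6, "d")
  expect_identical(
    objective_value(st, Rm10, Rd6, D, Y, L0, L0d, hp),
    objective_value(st, Rm10, Rd6, D_pert, Y, L0, L0d, hp))
  A <- matrix(0, 10, 10); Ad <- A
  expect_identical(update_gm(st, Rm10, D, Y, A, Ad, hp),
                   update_gm(st, Rm10, D_pert, Y, A, Ad, hp))
  expect_identical(update_k(st, D, Y, hp), update_k(st, D_pert, Y, hp))
})

test_that("oversized latent dimensions are clamped with a warning", {
  set.seed(41)
  Rm <- random_sim(8, "m"); Rd <- random_sim(6, "d")
  assoc <- random_assoc(8, 6, 0.3)
  expect_warning(
    f <- mdn_fit(Rm, Rd, assoc, mdn_hyperparams(max_iter = 20)),
    "clamped")
  expect_equal(f$hp$k_m, 7)
  expect_equal(f$hp$k_d, 5)
})

test_that("the fit converges on a planted instance before the iteration cap", {
  ds <- generate_planted(30, 20, 4, 4, 0.6, 0.02, seed = 0)
  sims <- compute_similarities(ds$assoc, ds$dag, ds$disease_genes, ds$gene_sim)
  f <- mdn_fit(sims$Rm, sims$Rd, ds$assoc,
               mdn_hyperparams(k_m = 5, k_d = 5, seed = 0))
  expect_true(f$converged)
  expect_lt(f$iterations, 1000)
})
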