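test_that("module thresholds use mean + t * sample sd per row", {
  G <- rbind(e1 = c(0.9, 0.1, 0.1, 0.1, 0.1),
             e2 = c(0.9, 0.1, 0.1, 0.1, 0.1))
  ms <- assign_modules(G, t = 1.5)
  expect_equal(unname(ms$thresholds["e1"]),
               0.26 + 1.5 * sd(G[1, ]), tolerance = 1e-12)
  # both rows load only on column 1, so module 1 retains both members
  expect_equal(ms$membership, list(`1` = c("e1", "e2")))
  expect_setequal(ms$dropped, 2:5)

  # constant rows have sd 0 and the strict inequality fails
  Gc <- rbind(c1 = c(0.3, 0.3, 0.3))
  expect_equal(length(assign_modules(Gc, 1.5)$membership), 0)

  # t = 0 degenerates to "above the row mean"
  G0 <- rbind(a = c(0.8, 0.2), b = c(0.7, 0.3))
  ms0 <- assign_modules(G0, t = 0)
  expect_equal(ms0$membership, list(`1` = c("a", "b")))

  expect_error(assign_modules(matrix(1, 3, 1), 1.5), "2 columns")
})

test_that("cosine similarity behaves on canonical vectors", {
  expect_equal(cosine_similarity(c(2, 4), c(1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero")
})

test_that("module scores match the hand-worked three-miRNA example", {
  # latent vectors chosen so cos(m1,m2) = 0.8 and cos(m1,m3) = 0.5
  G <- rbind(m1 = c(1, 0), m2 = c(0.8, 0.6), m3 = c(0.5, sqrt(3) / 2))
  D <- matrix(c(0, 1, 0), 3, 1, dimnames = list(rownames(G), "d1"))
  ms <- manual_module_set(rownames(G), list(`1` = c("m1", "m2")), 2)
  P <- module_score_mirna(ms, G, D)
  expect_equal(P["m1", "d1"], 0.8 / 2.3, tolerance = 1e-12)
})

test_that("module scores equal the brute-force double-loop oracle", {
  set.seed(13)
  for (rep in 1:3) {
    n_m <- sample(5:12, 1); n_d <- sample(3:8, 1); k <- 3
    Gm <- matrix(runif(n_m * k) + 0.05, n_m,
                 dimnames = list(paste0("m", seq_len(n_m)), NULL))
    Gd <- matrix(runif(n_d * k) + 0.05, n_d,
                 dimnames = list(paste0("d", seq_len(n_d)), NULL))
    D <- matrix(rbinom(n_m * n_d, 1, 0.4), n_m, n_d,
                dimnames = list(rownames(Gm), rownames(Gd)))
    ms_m <- assign_modules(Gm, t = 0.5)
    ms_d <- assign_modules(Gd, t = 0.5)
    expect_lt(max(abs(module_score_mirna(ms_m, Gm, D) -
                        oracle_module_score_mirna(ms_m, Gm, D))), 1e-10)
    expect_lt(max(abs(module_score_disease(ms_d, Gd, D) -
                        oracle_module_score_disease(ms_d, Gd, D))), 1e-10)
  }
})

test_that("module scores cover degenerate and analytic cases", {
  G <- matrix(runif(12) + 0.1, 4,
              dimnames = list(paste0("m", 1:4), NULL))
  D <- matrix(rbinom(8, 1, 0.5), 4, 2,
              dimnames = list(rownames(G), c("d1", "d2")))

  # no retained modules: all-zero score matrix
  none <- manual_module_set(rownames(G), setNames(list(), character(0)), 3)
  expect_true(all(module_score_mirna(none, G, D) == 0))

  # one module of all miRNAs with identical latent vectors:
  # every score equals the column mean of D
  G_same <- matrix(rep(c(1, 2, 3), each = 4), 4,
                   dimnames = dimnames(G))
  all_mod <- manual_module_set(rownames(G), list(`1` = rownames(G)), 3)
  P <- module_score_mirna(all_mod, G_same, D)
  for (j in 1:2) expect_equal(unname(P[, j]), rep(mean(D[, j]), 4),
                              tolerance = 1e-12)

  # permuting module indexing leaves the score matrix unchanged
  two <- manual_module_set(rownames(G),
                           list(`1` = c("m1", "m2"), `2` = c("m3", "m4")), 3)
  two_swapped <- manual_module_set(rownames(G),
                                   list(`2` = c("m3", "m4"),
                                        `1` = c("m1", "m2")), 3)
  expect_equal(module_score_mirna(two, G, D),
               module_score_mirna(two_swapped, G, D))
})

test_that("min-max fusion respects its bounds and degenerate rules", {
  expect_true(all(minmax_normalize(matrix(5, 3, 3)) == 0))
  X <- matrix(c(0, 1, 2, 1), 2)
  expect_equal(minmax_normalize(X), X / 2)

  D1 <- matrix(5, 2, 2); P0 <- matrix(0, 2, 2)
  expect_true(all(fuse_predictions(D1, P0, P0) == 0))

  set.seed(17)
  A <- matrix(runif(20, -2, 7), 4)
  D2 <- fuse_predictions(A, A, A)
  expect_equal(D2, 2 * minmax_normalize(A))
  expect_true(all(D2 >= 0 & D2 <= 2))
})

test_that("module summaries report sizes, similarity and sharing", {
  labels_m <- paste0("m", 1:8)
  labels_d <- paste0("d", 1:4)
  D <- matrix(0, 8, 4, dimnames = list(labels_m, labels_d))
  D[1:3, "d1"] <- 1            # module 1's members all share d1
  D[4:8, c("d2", "d3")] <- 1
  Rm <- matrix(0.5, 8, 8, dimnames = list(labels_m, labels_m)); diag(Rm) <- 1
  Rd <- matrix(0.3, 4, 4, dimnames = list(labels_d, labels_d)); diag(Rd) <- 1
  ms_m <- manual_module_set(labels_m,
                            list(`1` = labels_m[1:3], `2` = labels_m[4:8]), 4)
  ms_d <- manual_module_set(labels_d, setNames(list(), character(0)), 4)

  out <- module_summary(ms_m, ms_d, Rm, Rd, D)
  mir <- out[out$class == "mirna", ]
  expect_equal(mir$n_modules, 2)
  expect_equal(mir$avg_size, 4)          # sizes 3 and 5
  expect_equal(mir$avg_within_similarity, 0.5)
  expect_equal(mir$avg_share_fraction, 1)  # both modules share a partner

  dis <- out[out$class == "disease", ]
  expect_equal(dis$n_modules, 0)
  expect_equal(dis$empty, 1)
  expect_equal(dis$avg_size, 0)
})

test_that("module tables export entity, module, loading and threshold", {
  G <- rbind(e1 = c(0.9, 0.1, 0.1), e2 = c(0.85, 0.1, 0.1),
             e3 = c(0.1, 0.1, 0.1))
  ms <- assign_modules(G, t = 1)
  f <- tempfile()
  write_module_table(ms, G, f)
  tab <- read.delim(f)
  expect_named(tab, c("entity", "module_id", "factor_value", "threshold"))
  expect_setequal(tab$entity, c("e1", "e2"))
  expect_true(all(tab$factor_value > tab$threshold))
})
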