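test_that("semantic profiles decay along the hierarchy with the max rule", {
  dag <- toy_dag_chain_and_siblings()
  p <- semantic_profile(dag, "d", 0.5)
  expect_equal(p$DV, c(d = 1, p = 0.5, r = 0.25))
  expect_equal(p$DS, 1.75)

  iso <- disease_dag(matrix(character(0), ncol = 2), nodes = "solo")
  p_iso <- semantic_profile(iso, "solo", 0.5)
  expect_equal(p_iso$DV, c(solo = 1))
  expect_equal(p_iso$DS, 1)

  # diamond: two parents under one root; root takes the max, not the sum
  diamond <- disease_dag(rbind(c("d", "p1"), c("d", "p2"),
                               c("p1", "r"), c("p2", "r")))
  pd <- semantic_profile(diamond, "d", 0.5)
  expect_equal(pd$DV[["r"]], 0.25)
  expect_equal(pd$DS, 1 + 0.5 + 0.5 + 0.25)

  expect_error(semantic_profile(dag, "nope"), "not in hierarchy")
})

test_that("semantic similarity matches the hand-computed sibling case", {
  dag <- toy_dag_chain_and_siblings()
  S <- disease_semantic_similarity(dag, c("d", "e"), 0.5)
  expect_equal(S["d", "e"], 3 / 7, tolerance = 1e-12)
  expect_equal(S["d", "d"], 1)

  # disjoint components share no ancestors
  two <- disease_dag(rbind(c("a", "ra"), c("b", "rb")))
  S2 <- disease_semantic_similarity(two, c("a", "b"), 0.5)
  expect_equal(S2["a", "b"], 0)
})

test_that("disease functional similarity follows best-match averaging", {
  gs <- data.frame(a = c("g1", "g1", "g2"), b = c("g2", "g3", "g3"),
                   w = c(0.6, 0.2, 0.8))
  genes <- list(A = "g1", B = "g1", C = "g2", D2 = c("g1", "g2"), E = "g3")

  S_same <- disease_functional_similarity(genes, gs, c("A", "B"))
  expect_equal(S_same["A", "B"], 1)

  S_pair <- disease_functional_similarity(genes, gs, c("A", "C"))
  expect_equal(S_pair["A", "C"], 0.6, tolerance = 1e-12)

  S_best <- disease_functional_similarity(genes, gs, c("D2", "E"))
  expect_equal(S_best["D2", "E"], (0.2 + 0.8 + 0.8) / 3, tolerance = 1e-12)

  # no gene evidence: flagged, similarity 0 off-diagonal
  S_empty <- disease_functional_similarity(genes, gs, c("A", "unknown_d"))
  expect_equal(S_empty["A", "unknown_d"], 0)
  expect_identical(attr(S_empty, "flagged"), "unknown_d")
})

test_that("miRNA functional similarity follows best-match over disease sets", {
  dag <- toy_dag_chain_and_siblings()
  dss <- disease_semantic_similarity(dag, c("d", "e"), 0.5)

  mk <- function(D) association_data(D)
  D <- matrix(0, 3, 2, dimnames = list(c("m1", "m2", "m3"), c("d", "e")))
  D["m1", "d"] <- 1          # DT1 = {d}
  D["m2", "e"] <- 1          # DT2 = {e}
  D["m3", c("d", "e")] <- 1  # DT3 = {d, e}
  M <- mirna_functional_similarity(mk(D), dss)

  expect_equal(M["m1", "m1"], 1)
  expect_equal(M["m1", "m2"], 3 / 7, tolerance = 1e-12)
  expect_equal(M["m3", "m2"], (3 / 7 + 1 + 1) / 3, tolerance = 1e-12)
})

test_that("miRNA functional similarity ignores disease column order", {
  set.seed(11)
  ds <- generate_planted(12, 8, 2, 2, 0.7, 0.1, seed = 4)
  dss <- disease_semantic_similarity(ds$dag, ds$assoc$disease, 0.5)
  M1 <- mirna_functional_similarity(ds$assoc, dss)
  perm <- sample(ncol(ds$assoc$D))
  assoc_p <- association_data(ds$assoc$D[, perm])
  M2 <- mirna_functional_similarity(assoc_p, dss)
  expect_equal(M1, M2, tolerance = 1e-12)
})

test_that("GIP kernel matches hand-computed cases and brute force", {
  same <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), NULL))
  expect_equal(gip_kernel(same)["a", "b"], 1)

  disjoint <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                     dimnames = list(c("a", "b"), NULL))
  expect_equal(gip_kernel(disjoint)["a", "b"], exp(-2), tolerance = 1e-12)

  nested <- matrix(c(1, 1, 1, 0), 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), NULL))
  expect_equal(gip_kernel(nested)["a", "b"], exp(-2 / 3), tolerance = 1e-12)

  expect_error(gip_kernel(matrix(0, 2, 3)), "zero")

  # brute-force per-pair evaluation on random binary profiles
  set.seed(3)
  for (rep in 1:5) {
    P <- matrix(rbinom(60, 1, 0.4), 10, 6,
                dimnames = list(paste0("m", 1:10), NULL))
    if (all(P == 0)) next
    K <- gip_kernel(P)
    gamma <- 1 / mean(rowSums(P^2))
    for (i in 1:10) for (j in 1:10) {
      expect_equal(K[i, j],
                   if (i == j) 1 else exp(-gamma * sum((P[i, ] - P[j, ])^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("similarity integration keeps positive primaries, else fallback", {
  lab <- c("a", "b")
  prim <- matrix(c(1, 0.7, 0.7, 1), 2, dimnames = list(lab, lab))
  fall <- matrix(c(1, 0.2, 0.2, 1), 2, dimnames = list(lab, lab))
  expect_equal(integrate_similarity(prim, fall)["a", "b"], 0.7)
  prim["a", "b"] <- prim["b", "a"] <- 0
  expect_equal(integrate_similarity(prim, fall)["a", "b"], 0.2)
  fall["a", "b"] <- fall["b", "a"] <- 0
  expect_equal(integrate_similarity(prim, fall)["a", "b"], 0)

  rownames(fall) <- colnames(fall) <- c("a", "x")
  expect_error(integrate_similarity(prim, fall), "labels")
})

test_that("all similarity outputs are symmetric with unit diagonal in [0,1]", {
  ds <- generate_planted(15, 10, 3, 2, 0.6, 0.05, seed = 6)
  sims <- compute_similarities(ds$assoc, ds$dag, ds$disease_genes, ds$gene_sim)
  for (nm in c("Rm", "Rd", "Mfs", "Dss", "gip_m", "gip_d")) {
    S <- sims[[nm]]
    expect_true(all(S >= 0 & S <= 1), info = nm)
    expect_equal(S, t(S), tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_true(all(diag(sims$Rm) == 1))
  expect_true(all(diag(sims$Rd) == 1))
})
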