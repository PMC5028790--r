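test_that("pathway enumeration matches definitions on simple topologies", {
  # chain A -> B -> C: one 2-step path A..C, no direct one
  W <- matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  W["A", "B"] <- 1L; W["B", "C"] <- 1L
  p <- enumerate_directed_paths(W, 3)
  expect_equal(p$counts["A", "C", 1], 0)
  expect_equal(p$counts["A", "C", 2], 1)
  expect_equal(p$counts["A", "B", 1], 1)

  # two node-disjoint indirect routes and no direct interaction:
  # the pair still accumulates imputed-win evidence
  ids <- c("A", "B", "C", "D")
  W <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  W["A", "B"] <- 1L; W["B", "D"] <- 1L
  W["A", "C"] <- 1L; W["C", "D"] <- 1L
  p <- enumerate_directed_paths(W, 3)
  expect_equal(p$counts["A", "D", 1], 0)
  expect_equal(p$counts["A", "D", 2], 2)

  expect_error(enumerate_directed_paths(W, 0), "max_len")
})

test_that("pathway counts equal the exhaustive DFS oracle", {
  set.seed(5)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    W <- random_winloss(n)
    p <- enumerate_directed_paths(W, 3)
    oracle <- oracle_path_counts((W > 0) * 1, 3)
    expect_equal(unname(p$counts[, , 2]), oracle[, , 2])
    expect_equal(unname(p$counts[, , 3]), oracle[, , 3])
    expect_equal(unname(p$counts[, , 1]), unname(W) * 1) # raw direct counts
  }
  # the DFS fallback (max_len > 3) agrees too
  W <- random_winloss(6)
  p4 <- enumerate_directed_paths(W, 4)
  oracle4 <- oracle_path_counts((W > 0) * 1, 4)
  expect_equal(unname(p4$counts[, , 4]), oracle4[, , 4])
})

test_that("triad transitivity classifies oriented triads", {
  ids <- LETTERS[1:3]
  W <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  W["A", "B"] <- 1L; W["B", "C"] <- 1L; W["A", "C"] <- 1L
  tr <- compute_transitivity(W)
  expect_equal(tr$t, 1)
  expect_equal(tr$n_transitive, 1L)

  W["A", "C"] <- 0L; W["C", "A"] <- 1L
  tr <- compute_transitivity(W)
  expect_equal(tr$t, 0)
  expect_equal(tr$n_cyclic, 1L)

  # no closed triads -> undefined
  W0 <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  W0["A", "B"] <- 1L
  expect_true(is.na(compute_transitivity(W0)$t))
  expect_error(compute_transitivity(W0[1:2, 1:2]), "3 animals")
})

test_that("transitivity equals brute-force triad classification", {
  set.seed(21)
  for (rep in 1:20) {
    W <- random_winloss(6, n_events = 30)
    tr <- compute_transitivity(W)
    o <- oracle_triads(W)
    expect_equal(tr$n_transitive, o$n_transitive)
    expect_equal(tr$n_cyclic, o$n_cyclic)
  }
})

test_that("win imputation weights satisfy the direct-dominance constraint", {
  # g is always < 1 (a direct win beats any single imputed win), decays
  # with length, grows with transitivity, vanishes at t <= 0.5
  for (t in c(0, 0.3, 0.5, 0.8, 0.95, 1))
    for (len in 2:4) {
      g <- indirect_weight(t, len)
      expect_lt(g, 1)
      expect_gte(g, 0)
    }
  expect_equal(indirect_weight(0.5, 2), 0)
  expect_equal(indirect_weight(0.4, 3), 0)
  expect_gt(indirect_weight(0.9, 2), indirect_weight(0.9, 3))
  expect_gt(indirect_weight(1, 2), indirect_weight(0.8, 2))
  expect_error(indirect_weight(0.9, 2, beta = 1.5), "beta")
})

test_that("imputed wins combine direct counts and weighted path counts", {
  ids <- c("A", "B", "C", "D")
  W <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  W["A", "B"] <- 1L; W["B", "D"] <- 1L
  W["A", "C"] <- 1L; W["C", "D"] <- 1L
  p <- enumerate_directed_paths(W, 3)

  # no indirect contribution when t is uninformative
  expect_equal(impute_wins(p, 0.5), unname(W) * 1, ignore_attr = TRUE)

  # hand evaluation at t = 1: two 2-step A->D paths, weight 0.5 each
  wi <- impute_wins(p, 1)
  expect_equal(wi["A", "D"], 0 + 0.5 * 2)
  expect_equal(wi["A", "B"], 1)  # direct win only; no indirect A..B route
  expect_equal(wi["D", "A"], 0)

  # indirect evidence is always strictly weaker per path than direct
  wi2 <- impute_wins(p, 0.9)
  expect_lt(wi2["A", "D"], p$counts["A", "D", 2])
})

test_that("dominance probabilities are Beta tail probabilities", {
  # symmetric evidence and no evidence are perfectly ambiguous
  W <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  DP <- dominance_probability(W)
  expect_equal(DP["A", "B"], 0.5)
  DP0 <- dominance_probability(matrix(0, 2, 2))
  expect_equal(DP0[1, 2], 0.5)

  # 5-0 wins against the quadrature oracle: 1 - BetaCDF(0.5; 6, 1)
  W <- matrix(c(0, 0, 5, 0), 2, 2)
  DP <- dominance_probability(W)
  expect_equal(DP[1, 2], oracle_beta_tail(6, 1), tolerance = 1e-9)
  expect_equal(DP[2, 1], oracle_beta_tail(1, 6), tolerance = 1e-9)

  # random weighted evidence against quadrature
  set.seed(3)
  for (rep in 1:20) {
    a <- runif(1, 0, 20); b <- runif(1, 0, 20)
    Wr <- matrix(c(0, b, a, 0), 2, 2)
    expect_equal(dominance_probability(Wr)[1, 2],
                 oracle_beta_tail(a + 1, b + 1), tolerance = 1e-8)
  }
  expect_error(dominance_probability(matrix(-1, 2, 2)), "nonnegative")
})

test_that("DP complementarity, certainty folding and DC bounds hold", {
  set.seed(9)
  for (rep in 1:10) {
    W <- random_winloss(7, n_events = 40)
    fit <- dominance_fit(W)
    off <- !diag(7)
    expect_true(all(abs(fit$DP[off] + t(fit$DP)[off] - 1) < 1e-12))
    expect_true(all(fit$certainty[off] >= 0.5 - 1e-12))
    expect_true(all(fit$certainty[off] <= 1 + 1e-12))
    expect_equal(fit$certainty, t(fit$certainty))
    expect_true(all(fit$DC >= 0.5 & fit$DC <= 1))
  }
  expect_equal(dyadic_certainty(matrix(c(NA, 0.2, 0.8, NA), 2, 2))[1, 2],
               0.8)
  expect_error(average_dominance_certainty(matrix(NA_real_, 1, 1)),
               "2 animals")
})

test_that("consistent extra pathways raise DP; contradictions lower certainty", {
  ids <- LETTERS[1:6]
  base <- matrix(0L, 6, 6, dimnames = list(ids, ids))
  base["A", "B"] <- 1L; base["B", "D"] <- 1L
  fit1 <- dominance_fit(base)

  # an additional node-disjoint same-direction path A->C->D
  W2 <- base
  W2["A", "C"] <- 1L; W2["C", "D"] <- 1L
  fit2 <- dominance_fit(W2)
  expect_gte(fit2$DP["A", "D"], fit1$DP["A", "D"])

  # an opposite-direction path D->E->A must not increase certainty of A-D
  W3 <- W2
  W3["D", "E"] <- 1L; W3["E", "A"] <- 1L
  fit3 <- dominance_fit(W3)
  expect_lte(fit3$certainty["A", "D"], fit2$certainty["A", "D"])
})

test_that("dominance outputs are equivariant under id relabeling", {
  set.seed(13)
  W <- random_winloss(6, n_events = 25)
  perm <- sample(rownames(W))
  Wp <- W[perm, perm]
  f <- dominance_fit(W)
  fp <- dominance_fit(Wp)
  expect_equal(fp$DP[rownames(W), colnames(W)], f$DP)
  expect_equal(fp$DC[names(f$DC)], f$DC)
  expect_equal(fp$transitivity$t, f$transitivity$t)
})
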