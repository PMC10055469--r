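test_that("EE witnesses round-trip and the identity witness embeds UE in EE", {
  tr <- parse_newick("((a,b),c);")
  ue <- sample_ue_point(tr, 4, seed = 21)
  idw <- ee_witness(tr, ue, replicate(3, diag(4), simplify = FALSE))
  expect_equal(make_ee_point(idw)$values, ue$values)

  w <- suppressWarnings(sample_ee_witness(tr, 4, seed = 22))
  P <- suppressWarnings(make_ee_point(w))
  expect_equal(sum(P$values), 1, tolerance = 1e-12)
  back <- star_action(P, w$mats)
  expect_equal(back$values, w$ue_point$values, tolerance = 1e-10)

  bad <- w$mats; bad[[1]] <- matrix(0.25, 4, 4)      # singular Markov matrix
  expect_error(ee_witness(tr, ue, bad), "singular")
  bad2 <- w$mats; bad2[[1]][1, ] <- c(2, -1, 0, 0)   # negative entries
  expect_error(ee_witness(tr, ue, bad2), "nonnegative")
})

test_that("cofactor matrices satisfy the adjugate identity", {
  expect_equal(cofactor_matrix(diag(3)), diag(3))
  expect_equal(cofactor_matrix(matrix(c(1, 3, 2, 4), 2, 2, byrow = TRUE)),
               matrix(c(4, -2, -3, 1), 2, 2, byrow = TRUE))
  set.seed(30)
  for (k in 2:4) {
    A <- matrix(rnorm(k^2), k)
    expect_equal(t(cofactor_matrix(A)), det(A) * solve(A), tolerance = 1e-10)
  }
  ## defined (and rank-consistent) for singular input
  S <- outer(1:3, 1:3)
  expect_equal(S %*% t(cofactor_matrix(S)), det(S) * diag(3), tolerance = 1e-10)
})

test_that("triple invariants vanish on matching triples and separate mismatched ones", {
  tr <- parse_newick("((a,b),c);")
  for (kap in 3:4) {
    basis <- uephylo:::ue_null_basis(tr, kap)
    hits <- 0
    for (s in 1:25) {
      w <- suppressWarnings(sample_ee_witness(tr, kap, seed = 400 + s, basis = basis))
      P <- suppressWarnings(make_ee_point(w))
      expect_lt(triple_symmetry_residual(P, c("a", "b", "c")), 1e-9)
      if (triple_symmetry_residual(P, c("a", "c", "b")) > 1e-3 &&
          triple_symmetry_residual(P, c("b", "c", "a")) > 1e-3) hits <- hits + 1
    }
    expect_gte(hits, 22)
  }
  ## uniform tensor: all residuals zero, ranking degenerate
  U <- spt_uniform(c("a", "b", "c"), 4)
  rank_u <- infer_rooted_triple(U)
  expect_true(attr(rank_u, "degenerate"))
  expect_equal(max(rank_u$residual), 0)
})

test_that("Qa and Qb symmetry verdicts agree (conjugacy)", {
  verdicts <- function(P, triple) {
    kap <- P$kappa
    agree <- TRUE
    for (k in 0:(kap - 1)) {
      Q <- triple_invariant_matrices(P, triple, k)
      scl <- function(M) max(abs(M))
      ra <- max(abs(Q$Qa - t(Q$Qa))) / max(scl(Q$Qa), 1e-300)
      rb <- max(abs(Q$Qb - t(Q$Qb))) / max(scl(Q$Qb), 1e-300)
      agree <- agree && ((ra < 1e-8) == (rb < 1e-8))
    }
    agree
  }
  for (s in 1:100) {
    P <- random_prob_tensor(c("a", "b", "c"), 3, seed = 6000 + s)
    expect_true(verdicts(P, c("a", "b", "c")))
  }
})

test_that("the block-matrix construction obeys the rank-2kappa factorization", {
  set.seed(31)
  kap <- 4
  ## synthetic instance of the block lemma: F := -E D^-1 C B^-1 A
  A <- matrix(rnorm(kap^2), kap); C <- matrix(rnorm(kap^2), kap)
  B <- diag(kap) + 0.1 * matrix(rnorm(kap^2), kap)
  E <- diag(kap) + 0.1 * matrix(rnorm(kap^2), kap)
  D <- diag(kap) + 0.1 * matrix(rnorm(kap^2), kap)
  Ff <- -E %*% solve(D) %*% C %*% solve(B) %*% A
  Z <- matrix(0, kap, kap)
  block <- rbind(cbind(Z, A, B), cbind(D, Z, C), cbind(E, Ff, Z))
  expect_equal(rel_rank(block), 2 * kap)
  ## the triangular factorization reproduces the block matrix entrywise
  ## (for arbitrary A..F, not only when the condition matrix G vanishes)
  A2 <- matrix(rnorm(kap^2), kap); F2 <- matrix(rnorm(kap^2), kap)
  for (Ftest in list(Ff, F2)) {
    G <- C %*% solve(B) %*% A2 + D %*% solve(E) %*% Ftest
    blk <- rbind(cbind(Z, A2, B), cbind(D, Z, C), cbind(E, Ftest, Z))
    I <- diag(kap)
    L1 <- rbind(cbind(I, Z, Z), cbind(Z, I, D), cbind(Z, Z, E))
    L2 <- rbind(cbind(Z, Z, I),
                cbind(Z, -G, C %*% solve(B)),
                cbind(I, solve(E) %*% Ftest, Z))
    L3 <- rbind(cbind(I, Z, Z), cbind(Z, I, Z), cbind(Z, A2, B))
    expect_equal(L1 %*% L2 %*% L3, blk, tolerance = 1e-10)
  }

  ## EE points: rank 2kappa on the matching triple, larger on mismatched
  tr <- parse_newick("((a,b),c);")
  w <- suppressWarnings(sample_ee_witness(tr, kap, seed = 55))
  P <- suppressWarnings(make_ee_point(w))
  for (fam in c("a", "b")) {
    expect_equal(rel_rank(ottaviani_block(P, c("a", "b", "c"), 0, fam)), 2 * kap)
  }
  expect_gt(rel_rank(ottaviani_block(P, c("a", "c", "b"), 0, "a")), 2 * kap)
  ## generic tensors exceed rank 2kappa
  over <- 0
  for (s in 1:50) {
    R <- random_prob_tensor(c("a", "b", "c"), 4, seed = 7000 + s)
    if (rel_rank(ottaviani_block(R, c("a", "b", "c"), 0, "a")) > 2 * kap) over <- over + 1
  }
  expect_gte(over, 48)
})

test_that("two-state tensors carry no rooted-triple signal", {
  for (s in 1:100) {
    P <- random_prob_tensor(c("a", "b", "c"), 2, seed = 8000 + s)
    for (triple in list(c("a", "b", "c"), c("a", "c", "b"), c("b", "c", "a"))) {
      expect_lt(triple_symmetry_residual(P, triple), 1e-12)
    }
  }
  expect_error(infer_rooted_triple(random_prob_tensor(c("a", "b", "c"), 2, seed = 1)),
               "kappa = 2")
})

test_that("rooted-triple inference recovers constructed and coalescent triples", {
  tr <- parse_newick("((a,b),c);")
  w <- suppressWarnings(sample_ee_witness(tr, 4, seed = 91))
  P <- suppressWarnings(make_ee_point(w))
  expect_equal(infer_rooted_triple(P)$triple[1], "((a,b),c)")

  ## a CK distribution lies in UE, hence EE, of its own triple
  Pck <- ck_distribution_exact_3taxon(ck_triple_spec(), jc_model(4))
  rk <- infer_rooted_triple(Pck)
  expect_equal(rk$triple[1], "((a,b),c)")
  expect_lt(rk$residual[1], 1e-12)
})

test_that("EE local dimension matches the known 3-taxon values and bounds", {
  tr <- parse_newick("((a,b),c);")
  expect_equal(ee_local_dimension(tr, 2, seed = 5), 7)   # fills the simplex
  d3 <- ee_local_dimension(tr, 3, seed = 5)
  expect_lte(d3, 25)                                      # strictly below dim(simplex) = 26
  d4 <- ee_local_dimension(tr, 4, seed = 5)
  expect_lte(d4, 57)                                      # (k^3 + 4k^2 - 3k)/2 - 1 at k = 4
  expect_lt(d4, 63)
  expect_error(ee_local_dimension(tr, 5, seed = 1), "kappa")
})
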