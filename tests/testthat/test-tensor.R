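test_that("marginalization matches direct summation and preserves mass", {
  P <- random_prob_tensor(c("a", "b", "c"), 3, seed = 11)
  M <- marginalize(P, c("b", "c"))
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    oracle[j, k] <- oracle[j, k] + P$values[i, j, k]
  }
  expect_equal(M$values, oracle)
  expect_equal(sum(M$values), 1)
  expect_identical(marginalize(P, P$taxa), P)

  U <- spt_uniform(c("a", "b", "c", "d"), 2)
  expect_equal(marginalize(U, c("a", "c"))$values, spt_uniform(c("a", "c"), 2)$values)
  expect_error(marginalize(P, "zz"), "unknown")
})

test_that("slices sum to the complementary marginalization", {
  P <- random_prob_tensor(c("a", "b", "c"), 4, seed = 2)
  acc <- Reduce(`+`, lapply(0:3, function(k) spt_slice(P, "b", k)$values))
  expect_equal(acc, marginalize(P, c("a", "c"))$values)
  U <- spt_uniform(c("a", "b", "c"), 2)
  expect_equal(unique(as.vector(spt_slice(U, "a", 0)$values)), 1 / 8)
  expect_error(spt_slice(P, "b", 4), "out of range")
})

test_that("index exchange permutes entries and is an involution", {
  v <- numeric(8)
  ## pattern-lex coordinates: p010 is index 3, p001 is index 2
  v[3] <- 0.2; v[2] <- 0.1; v[1] <- 0.7
  P <- spt(v, c("a", "b", "c"), 2)
  E <- exchange_indices(P, "b", "c")
  w <- spt_flat(E)
  expect_equal(w[3], 0.1)
  expect_equal(w[2], 0.2)
  expect_equal(exchange_indices(E, "b", "c")$values, P$values)

  S <- spt(matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2), c("x", "y"), 2)
  expect_equal(exchange_indices(S, "x", "y")$values, S$values)
  expect_error(exchange_indices(P, "b", "b"), "differ")
})

test_that("flattenings use lexicographic tuple order and reshape back", {
  P <- random_prob_tensor(c("a", "b", "c", "d"), 2, seed = 3)
  Fl <- flatten_tensor(P, c("a", "b"), c("c", "d"))
  for (i in 0:1) for (j in 0:1) for (k in 0:1) for (l in 0:1) {
    expect_equal(Fl[i * 2 + j + 1, k * 2 + l + 1], P$values[i + 1, j + 1, k + 1, l + 1])
  }
  ## reshaping the matching flattening back recovers the tensor
  back <- aperm(array(t(Fl), dim = rep(2, 4)), 4:1)
  expect_equal(back, P$values)
  ## permuting side_A's internal order permutes rows by the tuple permutation
  Fl2 <- flatten_tensor(P, c("b", "a"), c("c", "d"))
  expect_equal(Fl2, Fl[c(1, 3, 2, 4), ])
  ## one-vs-rest flattening of a 3-way kappa=4 tensor is 4 x 16
  P3 <- random_prob_tensor(c("a", "b", "c"), 4, seed = 4)
  expect_equal(dim(flatten_tensor(P3, "a", c("b", "c"))), c(4, 16))
  expect_error(flatten_tensor(P, c("a", "b"), c("b", "c")), "overlap")
})

test_that("the * action matches its bilinear form and preserves mass", {
  P <- random_prob_tensor(c("x", "y"), 3, seed = 5)
  M1 <- matrix(runif(9), 3); M2 <- matrix(runif(9), 3)
  expect_equal(star_action(P, list(M1, M2))$values, t(M1) %*% P$values %*% M2)

  P3 <- random_prob_tensor(c("a", "b", "c"), 4, seed = 6)
  expect_equal(star_action(P3, list(NULL, NULL, NULL))$values, P3$values)

  ## invertible round trip
  set.seed(7)
  mats <- replicate(3, {
    R <- matrix(abs(rnorm(16)), 4); diag(R) <- 0; diag(R) <- -rowSums(R)
    uephylo:::mat_exp(0.3 * R)
  }, simplify = FALSE)
  Q <- star_action(P3, mats)
  expect_equal(sum(Q$values), 1, tolerance = 1e-12)  # Markov preserves mass
  expect_true(all(Q$values >= -1e-15))
  back <- star_action(Q, lapply(mats, solve))
  expect_equal(back$values, P3$values, tolerance = 1e-12)

  ## named subset application targets the right axis
  Pn <- star_action(P3, list(b = mats[[2]]))
  expect_equal(Pn$values, star_action(P3, list(NULL, mats[[2]], NULL))$values)
  expect_error(star_action(P3, list(M1, M1, M1)), "wrong dimensions")
})

test_that("marginalizing over a Markov-acted axis commutes with the action", {
  P <- random_prob_tensor(c("a", "b", "c"), 3, seed = 8)
  set.seed(9)
  R <- matrix(abs(rnorm(9)), 3); diag(R) <- 0; diag(R) <- -rowSums(R)
  Mk <- uephylo:::mat_exp(0.2 * R)
  Mb <- matrix(runif(9), 3)
  lhs <- marginalize(star_action(P, list(NULL, Mb, Mk)), c("a", "b"))
  rhs <- star_action(marginalize(P, c("a", "b")), list(NULL, Mb))
  expect_equal(lhs$values, rhs$values, tolerance = 1e-12)
})

test_that("multinomial sampling is reproducible and consistent", {
  P <- random_prob_tensor(c("a", "b", "c"), 4, seed = 10)
  A <- multinomial_sample(P, 500, seed = 123)
  B <- multinomial_sample(P, 500, seed = 123)
  expect_identical(A$values, B$values)
  expect_equal(sum(A$values), 1)
  expect_true(all(abs(A$values * 500 - round(A$values * 500)) < 1e-9))

  ## point mass reproduces exactly
  pm <- spt(c(1, rep(0, 63)), c("a", "b", "c"), 4)
  expect_equal(multinomial_sample(pm, 7, seed = 1)$values, pm$values)

  ## law of large numbers at s = 1e6
  big <- multinomial_sample(P, 1e6, seed = 99)
  expect_lt(max(abs(big$values - P$values)), 5e-3)
  neg <- P; neg$values[1] <- -0.1
  expect_error(multinomial_sample(neg, 10, seed = 1), "negative")
})

test_that("pattern-count files round-trip and reject malformed input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#taxa: a,b,c", "AAA\t5", "AAC\t5"), tmp)
  P <- read_pattern_counts(tmp)
  expect_equal(P$kappa, 4)
  expect_equal(sort(spt_flat(P), decreasing = TRUE)[1:2], c(0.5, 0.5))
  expect_equal(attr(P, "total"), 10)

  ## sampled tensor round trip preserves counts
  Q <- multinomial_sample(random_prob_tensor(c("a", "b"), 4, seed = 3), 1000, seed = 5)
  write_pattern_counts(Q, tmp, total = 1000)
  Q2 <- read_pattern_counts(tmp)
  expect_equal(Q2$values, Q$values)
  expect_equal(attr(Q2, "total"), 1000)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_pattern_counts(empty), "no patterns")
  writeLines(c("#taxa: a,b", "AAA\t5"), empty)
  expect_error(read_pattern_counts(empty), "length")
  writeLines(c("#taxa: a,b", "AZ\t5"), empty)
  expect_error(read_pattern_counts(empty), "unknown state")
  writeLines(c("#taxa: a,b", "AA\t-5"), empty)
  expect_error(read_pattern_counts(empty), "negative")
})
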