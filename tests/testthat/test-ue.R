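test_that("the 3-taxon 2-state constraint system reduces to the known five equations", {
  t3 <- parse_newick("(a,(b,c));")
  cs <- full_constraints(t3, 2)
  M <- constraint_matrix(cs, dedupe = TRUE)
  expect_equal(nrow(M), 5)          # two slice symmetries + three marginal ones
  expect_equal(numerical_rank(M), 3)
  ## affine solution dimension with sum-to-one appended
  expect_equal(8 - numerical_rank(rbind(M, rep(1, 8))), 4)
  expect_equal(dimension_recursive(t3, 2), list(c = 5, d = 4))
  expect_equal(dimension_rank_oracle(t3, 2), list(c = 5, d = 4))

  ## a tensor satisfying exactly the five equations: p010=p001, p101=p110,
  ## p010+p011 = p100+p101 (and the two implied marginal identities)
  v <- c(0.3, 0.08, 0.08, 0.1, 0.12, 0.06, 0.06, 0.2)
  names(v) <- all_patterns(3, 2)
  expect_equal(v[["010"]], v[["001"]]); expect_equal(v[["101"]], v[["110"]])
  expect_equal(v[["010"]] + v[["011"]], v[["100"]] + v[["101"]])
  P <- spt(unname(v), c("a", "b", "c"), 2)
  res <- vapply(cs$equations, function(e) sum(spt_flat(P)[e$idx] * e$coef), numeric(1))
  expect_lt(max(abs(res)), 1e-15)
  expect_true(is_member(P, t3, tol = 1e-14)$member)
})

test_that("cherry and single-leaf constraint systems have known dimensions", {
  ch <- parse_newick("(a,b);")
  for (kap in 2:4) {
    cs <- full_constraints(ch, kap)
    expect_equal(kap^2 - numerical_rank(constraint_matrix(cs)), kap * (kap + 1) / 2)
  }
  leaf <- rooted_tree(uephylo:::new_leaf("a"))
  expect_length(full_constraints(leaf, 3)$equations, 0)
  expect_equal(dimension_recursive(leaf, 3)$c, 3)
})

test_that("vertex constraint sets follow the per-vertex construction", {
  t3 <- parse_newick("(a,(b,c));")
  ## root: symmetry of the {a,b} marginal (1 equation at kappa=2)
  root_cs <- vertex_constraints(t3, 2, 1)
  expect_length(root_cs$equations, 1)
  e <- root_cs$equations[[1]]
  ## sum_c p_{01c} = sum_c p_{10c}
  expect_setequal(e$idx[e$coef > 0], c(3, 4))
  expect_setequal(e$idx[e$coef < 0], c(5, 6))
  ## MRCA(b,c): slice symmetries p_{ijk} = p_{ikj}, one per a-state
  in_cs <- vertex_constraints(t3, 2, 2)
  expect_length(in_cs$equations, 2)
  expect_setequal(vapply(in_cs$equations, function(e) sort(e$idx)[1], numeric(1)), c(2, 6))

  ## cherry vertex equation count: choose(kappa,2) * kappa^(#taxa outside)
  t4 <- parse_newick("((a,b),(c,d));")
  for (kap in 2:3) {
    ch_cs <- vertex_constraints(t4, kap, 2)  # the (a,b) cherry node
    expect_length(ch_cs$equations, choose(kap, 2) * kap^2)
  }
  expect_error(vertex_constraints(t3, 2, 5), "out of range")
})

test_that("reduced and full systems define the same cone", {
  cases <- list(
    list(nwk = "(a,(b,c));", kap = 2, c = 5),
    list(nwk = "((a,b),(c,d));", kap = 2, c = 8),
    list(nwk = "(((a,b),c),d);", kap = 3, c = dimension_recursive(parse_newick("(((a,b),c),d);"), 3)$c)
  )
  for (cs in cases) {
    tr <- parse_newick(cs$nwk)
    kap <- cs$kap
    n <- length(tr$taxa)
    rank_full <- numerical_rank(constraint_matrix(full_constraints(tr, kap)))
    rank_red <- numerical_rank(constraint_matrix(reduced_constraints(tr, kap)))
    expect_equal(rank_full, rank_red)
    expect_equal(kap^n - rank_full, cs$c)
  }
})

test_that("closed forms match hand-evaluated dimensions", {
  expect_equal(closed_form_dimension("caterpillar", 3, 2), 4)
  expect_equal(closed_form_dimension("caterpillar", 4, 4), 129)
  expect_equal(closed_form_dimension("caterpillar", 5, 4), 513)
  expect_equal(closed_form_dimension("balanced", 2, 2), 7)
  expect_equal(closed_form_dimension("balanced", 2, 4), 93)
  ## caterpillar dimension grows strictly with n
  for (kap in 2:4) {
    d <- vapply(1:10, function(n) closed_form_dimension("caterpillar", n, kap), numeric(1))
    expect_true(all(diff(d) > 0))
  }
  expect_error(closed_form_dimension("balanced", 1.5, 2), "integer")
})

test_that("membership separates CK points, mixtures and generic tensors", {
  m <- jc_model(4)
  spec <- ck_triple_spec()
  P <- ck_distribution_exact_3taxon(spec, m)
  good <- parse_newick("((a,b),c);")
  expect_true(is_member(P, good, tol = 1e-10)$member)
  expect_false(is_member(P, parse_newick("((a,c),b);"), tol = 1e-9)$member)

  ## mixtures of two CK distributions on the same tree stay in the model
  P2 <- ck_distribution_exact_3taxon(spec, jc_model(4, rate = 0.35))
  mix <- mixture(list(P, P2), c(0.3, 0.7))
  expect_true(is_member(mix, good, tol = 1e-10)$member)

  ## generic tensors violate the constraints by a bounded-away margin
  worst <- Inf
  for (s in 1:20) {
    R <- random_prob_tensor(c("a", "b", "c"), 4, seed = 100 + s)
    worst <- min(worst, is_member(R, good)$max_residual)
  }
  expect_gt(worst, 1e-3)
  expect_error(is_member(P, parse_newick("((a,b),d);")), "mismatch")
})

test_that("sampled UE points are members, span the model, and are exchangeable", {
  tr <- parse_newick("(((a,b),c),d);")
  kap <- 2
  d <- dimension_recursive(tr, kap)$d
  basis <- uephylo:::ue_null_basis(tr, kap)
  pts <- lapply(1:(3 * d), function(s) spt_flat(sample_ue_point(tr, kap, seed = s, basis = basis)))
  for (p in pts[1:5]) {
    P <- spt(p, tr$taxa, kap)
    expect_true(is_member(P, tr, tol = 1e-12)$member)
    expect_true(all(p >= kap^-4 / 2 - 1e-15))
  }
  ## affine span: subtract one point, stack, rank = d
  Mstack <- do.call(rbind, lapply(pts[-1], function(p) p - pts[[1]]))
  expect_equal(rel_rank(Mstack), d)

  ## exchanging a 2-clade fixes the sampled tensor
  P <- sample_ue_point(tr, kap, seed = 77, basis = basis)
  expect_equal(exchange_indices(P, "a", "b")$values, P$values, tolerance = 1e-12)

  ## the uniform tensor is a member for every topology
  U <- spt_uniform(c("a", "b", "c", "d"), 2)
  for (nwk in c("(((a,b),c),d);", "((a,c),(b,d));")) {
    expect_true(is_member(U, parse_newick(nwk), tol = 1e-14)$member)
  }
})

test_that("the dimension table ranks caterpillars above balanced shapes", {
  d2 <- dimension_table(4, 2)
  expect_equal(nrow(d2), 2)
  expect_equal(d2$d[1], 8)                        # caterpillar
  expect_equal(d2$d[2], 7)                        # balanced
  expect_match(attr(d2, "argmax"), "t4")
  d4 <- dimension_table(4, 4)
  expect_setequal(d4$d, c(129, 93))
  d3 <- dimension_table(3, 2)
  expect_equal(nrow(d3), 1)                       # single shape on 3 taxa
  expect_error(dimension_table(9, 2), "n <= 8")
})

test_that("constraint export writes both text and triplet formats", {
  tmp_txt <- withr::local_tempfile(fileext = ".txt")
  tmp_tri <- withr::local_tempfile(fileext = ".tsv")
  cs <- full_constraints(parse_newick("(a,(b,c));"), 2)
  nun <- export_constraints(cs, tmp_txt, tmp_tri)
  expect_equal(nun, 5)
  lines <- readLines(tmp_txt)
  expect_length(lines, 5)
  expect_true(all(grepl("= 0$", lines)))
  tri <- utils::read.table(tmp_tri, header = TRUE, sep = "\t")
  expect_named(tri, c("eq", "coord", "coef"))
  expect_setequal(unique(tri$coef), c(1, -1))
})
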