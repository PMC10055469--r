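## The UE model: linear symmetry constraints on site-pattern tensors.
##
## Coordinates are the kappa^n tensor entries in pattern-lexicographic order
## (first taxon most significant; see spt_flat/all_patterns). Every symmetry
## equation is a homogeneous difference of two disjoint groups of coordinates,
## so all coefficients are +-1.

## Powers used to map a 0-based state vector (taxa order) to a 1-based flat
## coordinate index.
coord_powers <- function(n, kappa) kappa^(n - seq_len(n))

## Offsets of all state combinations over the axes `free_pos` (0 if none).
free_offsets <- function(free_pos, pw, kappa) {
  off <- 0
  for (p in free_pos) off <- as.vector(outer(off, (0:(kappa - 1)) * pw[p], "+"))
  off
}

## Symmetry equations for taxa at axis positions pos_a/pos_b: for every state
## assignment to `fixed_pos` and every state pair i < j, the sum of
## coordinates over `free_pos` with (a=i,b=j) equals the one with (a=j,b=i).
build_sym_equations <- function(n, kappa, pos_a, pos_b, fixed_pos, free_pos, scope, pair) {
  pw <- coord_powers(n, kappa)
  foff <- free_offsets(free_pos, pw, kappa)
  goff <- free_offsets(fixed_pos, pw, kappa)  # one equation per fixed assignment
  eqs <- vector("list", length(goff) * kappa * (kappa - 1) / 2)
  prov <- character(length(eqs))
  m <- 0L
  for (g in goff) {
    for (i in 0:(kappa - 2)) for (j in (i + 1):(kappa - 1)) {
      plus  <- 1 + g + i * pw[pos_a] + j * pw[pos_b] + foff
      minus <- 1 + g + j * pw[pos_a] + i * pw[pos_b] + foff
      m <- m + 1L
      eqs[[m]] <- list(idx = c(plus, minus),
                       coef = c(rep(1, length(plus)), rep(-1, length(minus))))
      prov[m] <- sprintf("%s {%s} %d~%d", scope, paste(pair, collapse = ","), i, j)
    }
  }
  list(equations = eqs, provenance = prov)
}

new_constraint_set <- function(n_coords, kappa, taxa, equations, provenance) {
  structure(list(n_coords = n_coords, kappa = kappa, taxa = taxa,
                 equations = equations, provenance = provenance),
            class = "ue_constraints")
}

#' @export
print.ue_constraints <- function(x, ...) {
  cat(sprintf("UE constraint set: %d equations on %d coordinates (kappa = %d, %d taxa)\n",
              length(x$equations), x$n_coords, x$kappa, length(x$taxa)))
  invisible(x)
}

#' Full UE symmetry constraint system of a rooted tree
#'
#' For every taxon subset `Y` with at least two elements and every cherry
#' `{a,b}` of the induced subtree on `Y`, emits the equations stating that the
#' `Y`-marginal of the tensor is invariant under exchanging the `a` and `b`
#' indices. The equation set defines the cone over the UE model (sum-to-one is
#' handled separately where affine dimension is needed).
#'
#' @param tree a `ue_tree`.
#' @param kappa number of states.
#' @return a `ue_constraints` object.
#' @export
full_constraints <- function(tree, kappa) {
  tx <- tree$taxa
  n <- length(tx)
  eqs <- list(); prov <- character(0)
  if (n >= 2) {
    for (sz in 2:n) {
      for (Y in utils::combn(tx, sz, simplify = FALSE)) {
        sub <- restrict_tree(tree, Y)
        for (ch in two_clades(sub)) {
          pos_a <- match(ch[1], tx); pos_b <- match(ch[2], tx)
          fixed <- match(setdiff(Y, ch), tx)
          free  <- match(setdiff(tx, Y), tx)
          b <- build_sym_equations(n, kappa, pos_a, pos_b, fixed, free,
                                   scope = paste0("Y={", paste(Y, collapse = ","), "}"),
                                   pair = ch)
          eqs <- c(eqs, b$equations); prov <- c(prov, b$provenance)
        }
      }
    }
  }
  new_constraint_set(kappa^n, kappa, tx, eqs, prov)
}

## Fixed pair-choice rule for the vertex constraint sets: the lexicographically
## smallest leaf label in each child subtree of v.
vertex_pair <- function(v) c(min(v$left), min(v$right))

#' Symmetry constraints associated with one internal vertex
#'
#' Implements the reduced per-vertex equation sets: with `a`, `b` the
#' lexicographically smallest labels in the two child subtrees of `v` (so
#' `v = MRCA(a,b)`), the tensor is marginalized over the other descendants of
#' `v`, and each slice determined by the states of the taxa outside `desc(v)`
#' is required to be symmetric in the `a,b` indices.
#'
#' @param tree a `ue_tree`.
#' @param kappa number of states.
#' @param v index of the internal vertex in preorder (1 = root); leaves have
#'   empty constraint sets and are not indexed.
#' @return a `ue_constraints` object.
#' @export
vertex_constraints <- function(tree, kappa, v) {
  nodes <- internal_nodes(tree)
  if (v < 1 || v > length(nodes)) stop("v out of range (internal vertices: ", length(nodes), ")")
  nd <- nodes[[v]]
  tx <- tree$taxa
  n <- length(tx)
  pair <- vertex_pair(nd)
  desc <- c(nd$left, nd$right)
  pos_a <- match(pair[1], tx); pos_b <- match(pair[2], tx)
  free  <- match(setdiff(desc, pair), tx)       # marginalized within desc(v)
  fixed <- match(setdiff(tx, desc), tx)         # slice indices outside desc(v)
  b <- build_sym_equations(n, kappa, pos_a, pos_b, fixed, free,
                           scope = sprintf("v=%d", v), pair = pair)
  new_constraint_set(kappa^n, kappa, tx, b$equations, b$provenance)
}

#' Reduced (per-vertex) UE constraint system
#'
#' Union of [vertex_constraints()] over the internal vertices; defines the
#' same cone as [full_constraints()] with far fewer equations.
#' @inheritParams full_constraints
#' @return a `ue_constraints` object.
#' @export
reduced_constraints <- function(tree, kappa) {
  nodes <- internal_nodes(tree)
  eqs <- list(); prov <- character(0)
  for (v in seq_along(nodes)) {
    cs <- vertex_constraints(tree, kappa, v)
    eqs <- c(eqs, cs$equations); prov <- c(prov, cs$provenance)
  }
  new_constraint_set(kappa^length(tree$taxa), kappa, tree$taxa, eqs, prov)
}

#' Dense matrix of a constraint set
#' @param cs a `ue_constraints`.
#' @param dedupe drop duplicate equations (rank is unaffected either way).
#' @return numeric matrix, one row per equation.
#' @export
constraint_matrix <- function(cs, dedupe = FALSE) {
  eqs <- cs$equations
  if (dedupe) eqs <- unique_equations(eqs)
  M <- matrix(0, nrow = length(eqs), ncol = cs$n_coords)
  for (r in seq_along(eqs)) M[r, eqs[[r]]$idx] <- M[r, eqs[[r]]$idx] + eqs[[r]]$coef
  M
}

unique_equations <- function(eqs) {
  keys <- vapply(eqs, function(e) {
    o <- order(e$idx)
    k1 <- paste(e$idx[o], e$coef[o], collapse = ";")
    k2 <- paste(e$idx[o], -e$coef[o], collapse = ";")
    min(k1, k2)  # an equation and its negation are the same constraint
  }, character(1))
  eqs[!duplicated(keys)]
}

#' Numerical rank of a matrix
#'
#' Counts singular values above `max(dim(M)) * eps * sigma_max` by default, or
#' above an absolute tolerance when given. Constraint matrices here have +-1
#' entries, so conditioning is benign.
#' @param M numeric matrix.
#' @param tol optional absolute singular-value tolerance (e.g. `1e-9`).
#' @return integer rank.
#' @export
numerical_rank <- function(M, tol = NULL) {
  if (!length(M) || all(M == 0)) return(0L)
  sv <- svd(M, nu = 0, nv = 0)$d
  thresh <- if (is.null(tol)) max(dim(M)) * .Machine$double.eps * sv[1] else tol
  sum(sv > thresh)
}

#' UE model dimension by the structural recursion
#'
#' Cone dimension `c` satisfies `c(leaf) = kappa` and, splitting at the root
#' into subtrees A and B, `c(tree) = c(A) * c(B) - choose(kappa, 2)`; the
#' affine dimension is `d = c - 1`.
#' @param tree a `ue_tree`.
#' @param kappa number of states.
#' @return list with elements `c` (cone dimension) and `d` (affine dimension).
#' @export
dimension_recursive <- function(tree, kappa) {
  rec <- function(node) {
    if (is_leaf(node)) return(kappa)
    rec(node$kids[[1]]) * rec(node$kids[[2]]) - choose(kappa, 2)
  }
  cc <- rec(tree$root)
  list(c = cc, d = cc - 1)
}

#' UE model dimension by numerical rank of the full constraint system
#'
#' Independent verification of the recursion: `c = kappa^n - rank`, `d = c - 1`.
#' @inheritParams dimension_recursive
#' @param tol absolute rank tolerance passed to [numerical_rank()].
#' @return list with elements `c` and `d`.
#' @export
dimension_rank_oracle <- function(tree, kappa, tol = NULL) {
  n <- length(tree$taxa)
  if (kappa^n > 4096) stop("size guard: kappa^n must be <= 4096")
  M <- constraint_matrix(full_constraints(tree, kappa))
  cc <- kappa^n - numerical_rank(M, tol)
  list(c = cc, d = cc - 1)
}

#' Closed-form UE dimensions for caterpillar and balanced shapes
#'
#' Caterpillar on `n` taxa: `d = (kappa^n + kappa)/2 - 1`. Balanced tree on
#' `n = 2^level` taxa: evaluated through the recursion (for 4 taxa this equals
#' `kappa*(kappa^3 + 2*kappa^2 - kappa + 2)/4 - 1`).
#' @param shape `"caterpillar"` or `"balanced"`.
#' @param n_or_level taxon count for caterpillars; level `l` (so `n = 2^l`)
#'   for balanced trees.
#' @param kappa number of states.
#' @return affine dimension `d`.
#' @export
closed_form_dimension <- function(shape = c("caterpillar", "balanced"), n_or_level, kappa) {
  shape <- match.arg(shape)
  if (shape == "caterpillar") {
    n <- n_or_level
    if (n < 1) stop("n must be >= 1")
    return((kappa^n + kappa) / 2 - 1)
  }
  l <- n_or_level
  if (l < 0 || l != round(l)) stop("balanced requires integer level (n = 2^level)")
  cc <- kappa
  if (l > 0) for (i in 1:l) cc <- cc^2 - choose(kappa, 2)
  cc - 1
}

#' Test UE membership of a probability tensor
#'
#' Evaluates every full-model symmetry equation on the tensor and reports the
#' maximum absolute violation.
#' @param P a probability `spt` on the tree's taxa.
#' @param tree a `ue_tree`.
#' @param tol residual tolerance for membership.
#' @return list with `member` (logical) and `max_residual`.
#' @export
is_member <- function(P, tree, tol = 1e-9) {
  if (!setequal(P$taxa, tree$taxa)) stop("taxa mismatch between tensor and tree")
  Pv <- P
  if (!identical(P$taxa, tree$taxa)) {
    Pv <- spt(aperm(P$values, match(tree$taxa, P$taxa)), tree$taxa, P$kappa)
  }
  v <- spt_flat(Pv)
  cs <- full_constraints(tree, P$kappa)
  res <- vapply(cs$equations, function(e) abs(sum(v[e$idx] * e$coef)), numeric(1))
  mx <- if (length(res)) max(res) else 0
  list(member = mx <= tol, max_residual = mx)
}

## Orthonormal basis of the null space of the full constraint matrix
## (the cone L(tree)); columns span dimension c.
ue_null_basis <- function(tree, kappa, tol = NULL) {
  n <- length(tree$taxa)
  M <- constraint_matrix(full_constraints(tree, kappa))
  if (!nrow(M)) return(diag(kappa^n))
  sv <- svd(M, nv = ncol(M))
  thresh <- if (is.null(tol)) max(dim(M)) * .Machine$double.eps * sv$d[1] else tol
  null_idx <- which(c(sv$d, rep(0, ncol(M) - length(sv$d))) <= thresh)
  sv$v[, null_idx, drop = FALSE]
}

#' Sample a generic point of the UE model
#'
#' Returns `uniform + eps * w` where `w` is the projection of a seeded random
#' direction onto the constraint null space with its sum component removed,
#' and `eps` is chosen so that all entries stay at or above `kappa^-n / 2`.
#' The output is an exact model point (up to numerical null-space accuracy)
#' and, over many seeds, spans the full affine dimension.
#'
#' @param tree a `ue_tree`.
#' @param kappa number of states.
#' @param seed integer seed.
#' @param basis optional precomputed null-space basis (from repeated calls).
#' @return a probability `spt` on `tree$taxa`.
#' @export
sample_ue_point <- function(tree, kappa, seed, basis = NULL) {
  n <- length(tree$taxa)
  if (is.null(basis)) basis <- ue_null_basis(tree, kappa)
  set.seed(seed)
  w <- basis %*% stats::rnorm(ncol(basis))
  w <- w - mean(w)                       # all-ones lies in the null space
  mx <- max(abs(w))
  u <- kappa^-n
  v <- if (mx < 1e-14) rep(u, kappa^n) else as.vector(u + (u / (2 * mx)) * w)
  spt(v, tree$taxa, kappa)
}

#' UE dimensions across all tree shapes on n taxa
#'
#' The model dimension depends only on the unlabelled shape, so one labelled
#' representative per shape is tabulated.
#' @param n number of taxa (`<= 8`).
#' @param kappa number of states.
#' @return a data.frame with columns `shape` (canonical Newick on labels
#'   `t1..tn`) and `d`, sorted by decreasing `d`; attributes `argmax` and
#'   `argmin` name the extremal shapes.
#' @export
dimension_table <- function(n, kappa) {
  if (n > 8) stop("size guard: n <= 8")
  shapes <- tree_shapes(n)
  rows <- lapply(shapes, function(s) {
    tr <- shape_to_tree(s)
    data.frame(shape = canonical_topology(tr),
               d = dimension_recursive(tr, kappa)$d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$d), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "argmax") <- out$shape[1]
  attr(out, "argmin") <- out$shape[nrow(out)]
  out
}

#' Export a constraint set to plain text
#'
#' Writes a human-readable listing (one `+pattern ... -pattern ... = 0` row
#' per deduplicated equation) and a machine-readable sparse triplet file with
#' columns `eq`, `coord`, `coef` (1-based coordinate = position in
#' [all_patterns()] order).
#' @param cs a `ue_constraints`.
#' @param text_path,triplet_path output file paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the deduplicated equation count.
#' @export
export_constraints <- function(cs, text_path = NULL, triplet_path = NULL) {
  eqs <- unique_equations(cs$equations)
  pats <- all_patterns(length(cs$taxa), cs$kappa)
  if (!is.null(text_path)) {
    lines <- vapply(eqs, function(e) {
      paste0(paste0(ifelse(e$coef > 0, "+", "-"), pats[e$idx], collapse = " "), " = 0")
    }, character(1))
    writeLines(lines, text_path)
  }
  if (!is.null(triplet_path)) {
    rows <- unlist(lapply(seq_along(eqs), function(r) {
      sprintf("%d\t%d\t%d", r, eqs[[r]]$idx, as.integer(eqs[[r]]$coef))
    }))
    writeLines(c("eq\tcoord\tcoef", rows), triplet_path)
  }
  invisible(length(eqs))
}
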