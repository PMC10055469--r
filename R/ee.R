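## The EE model: UE tensors acted on per-index by invertible Markov matrices,
## the cofactor (adjugate) rooted-triple invariants, and the associated
## block-matrix rank conditions.

#' Construct an EE witness
#'
#' A witness certifies EE membership of the tensor
#' `make_ee_point(w) = ue_point * (M_1^-1, ..., M_n^-1)`: acting back with the
#' `M_i` recovers the UE point.
#'
#' @param topology a `ue_tree`.
#' @param ue_point a probability `spt` in the UE model of `topology`.
#' @param mats list of invertible `kappa x kappa` Markov matrices, one per
#'   taxon in `ue_point$taxa` order.
#' @return an object of class `"ee_witness"`.
#' @export
ee_witness <- function(topology, ue_point, mats) {
  kap <- ue_point$kappa
  if (length(mats) != length(ue_point$taxa)) stop("one matrix per taxon required")
  for (M in mats) {
    if (!all(dim(M) == c(kap, kap))) stop("matrix has wrong dimensions")
    if (any(M < -1e-12)) stop("Markov matrices must be nonnegative")
    if (max(abs(rowSums(M) - 1)) > 1e-12) stop("Markov matrix rows must sum to 1")
    if (abs(det(M)) <= 1e-10) stop("Markov matrix is (numerically) singular")
  }
  structure(list(topology = topology, ue_point = ue_point, mats = mats),
            class = "ee_witness")
}

#' Tensor of an EE witness
#'
#' Applies the inverse Markov matrices to the witness's UE point. Mass is
#' preserved; entries below `-1e-12` flag the witness as lying outside the
#' probability simplex (a warning, since the algebraic invariants are still
#' meaningful there).
#' @param w an `ee_witness`.
#' @return an `spt` `P` with `star_action(P, w$mats) = w$ue_point`.
#' @export
make_ee_point <- function(w) {
  P <- star_action(w$ue_point, lapply(w$mats, solve))
  if (min(P$values) < -1e-12) {
    warning("EE point lies outside the probability simplex")
    attr(P, "outside_simplex") <- TRUE
  }
  P
}

#' Sample a seeded EE witness on a 3-taxon tree
#'
#' Draws a generic UE point and per-taxon Markov matrices `expm(tau * R)` with
#' seeded random sum-zero-row rate matrices `R` and `tau` uniform in
#' `tau_range`, guaranteeing positivity and invertibility.
#' @param tree a 3-leaf `ue_tree`.
#' @param kappa number of states.
#' @param seed integer seed.
#' @param tau_range range of matrix "lengths".
#' @param basis optional precomputed UE null-space basis.
#' @return an `ee_witness`.
#' @export
sample_ee_witness <- function(tree, kappa, seed, tau_range = c(0.05, 0.5), basis = NULL) {
  ue <- sample_ue_point(tree, kappa, seed, basis = basis)
  ## RNG state after sample_ue_point is seeded; continue the stream
  mats <- lapply(seq_along(ue$taxa), function(i) {
    R <- matrix(abs(stats::rnorm(kappa^2)), kappa, kappa)
    diag(R) <- 0
    diag(R) <- -rowSums(R)
    tau <- stats::runif(1, tau_range[1], tau_range[2])
    mat_exp(tau * R)
  })
  ee_witness(tree, ue, mats)
}

## Dense matrix exponential by scaling-and-squaring on the Taylor series;
## only used for small (kappa <= 8) matrices.
mat_exp <- function(A) {
  s <- max(0L, ceiling(log2(max(1, norm(A, "1")))))
  A <- A / 2^s
  E <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in 1:20) {
    term <- term %*% A / k
    E <- E + term
  }
  if (s > 0) for (i in seq_len(s)) E <- E %*% E
  E
}

#' Matrix of cofactors
#'
#' `Cof(A)[i,j] = (-1)^(i+j) det(A[-i,-j])`, so `A %*% t(Cof(A)) = det(A) I`.
#' Defined for singular `A` as well.
#' @param A square numeric matrix.
#' @return the cofactor matrix.
#' @export
cofactor_matrix <- function(A) {
  k <- nrow(A)
  stopifnot(ncol(A) == k)
  if (k == 1) return(matrix(1, 1, 1))
  C <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    C[i, j] <- (-1)^(i + j) * det(A[-i, -j, drop = FALSE])
  }
  C
}

## Marginals/slice of a 3-way tensor permuted to triple order (x, y, z):
## m_a = P_{+..} (rows y, cols z), m_b = P_{.+.} (rows x, cols z),
## slices = list over k of P_{..k} (rows x, cols y).
triple_parts <- function(P, triple) {
  if (length(P$taxa) != 3) stop("a 3-way tensor is required")
  x <- triple[1]; y <- triple[2]; z <- triple[3]
  if (!setequal(c(x, y, z), P$taxa)) stop("triple must name the tensor's taxa")
  v <- aperm(P$values, match(c(x, y, z), P$taxa))
  list(
    m_a = apply(v, c(2, 3), sum),
    m_b = apply(v, c(1, 3), sum),
    slices = lapply(seq_len(P$kappa), function(k) v[, , k])
  )
}

#' Cofactor invariant matrices of a rooted triple
#'
#' For the rooted triple `((x,y),z)` and slice state `k` of `z`, returns the
#' two matrices
#' `Qa = P_{+..} Cof(P_{.+.})^T P_{..k}` and
#' `Qb = P_{..k} Cof(P_{+..}) P_{.+.}^T`,
#' where marginals are stored rows-first-listed-taxon. Both are symmetric for
#' every tensor in the EE model on `((x,y),z)`.
#'
#' @param P a 3-way `spt`.
#' @param triple character vector `c(x, y, z)` meaning `((x,y),z)`.
#' @param k slice state of the outgroup taxon `z`, in `0..kappa-1`.
#' @return list with matrices `Qa` and `Qb`.
#' @export
triple_invariant_matrices <- function(P, triple, k) {
  if (k < 0 || k >= P$kappa) stop("state out of range")
  tp <- triple_parts(P, triple)
  Sk <- tp$slices[[k + 1]]
  list(Qa = tp$m_a %*% t(cofactor_matrix(tp$m_b)) %*% Sk,
       Qb = Sk %*% cofactor_matrix(tp$m_a) %*% t(tp$m_b))
}

#' Scale-normalized symmetry residual of a rooted triple
#'
#' Maximum over slice states and both invariant families of the relative
#' asymmetry `max|Q - Q^T| / max|Q|` of the cofactor invariant matrices. The
#' invariants are homogeneous of degree `kappa + 1`, so raw magnitudes carry
#' no meaning across inputs; the relative form is scale-invariant. When a `Q`
#' matrix itself vanishes to within the floating-point floor of its
#' degree-(kappa+1) magnitude bound (e.g. on the uniform tensor, whose
#' singular marginals annihilate the adjugate), the residual for that slice
#' is 0. Zero (to tolerance) is necessary for EE membership on the triple;
#' for `kappa = 2` the invariants vanish identically and the residual carries
#' no signal.
#'
#' @param P a 3-way `spt`.
#' @param triple character vector `c(x, y, z)` meaning `((x,y),z)`.
#' @return nonnegative residual.
#' @export
triple_symmetry_residual <- function(P, triple) {
  tp <- triple_parts(P, triple)
  kap <- P$kappa
  na <- max(abs(tp$m_a)); nb <- max(abs(tp$m_b))
  worst <- 0
  for (k in seq_len(kap)) {
    Sk <- tp$slices[[k]]
    ns <- max(abs(Sk))
    Qa <- tp$m_a %*% t(cofactor_matrix(tp$m_b)) %*% Sk
    Qb <- Sk %*% cofactor_matrix(tp$m_a) %*% t(tp$m_b)
    floor_scale <- .Machine$double.eps * na * nb^(kap - 1) * ns * kap^2
    ra <- max(abs(Qa - t(Qa))) / max(max(abs(Qa)), floor_scale)
    rb <- max(abs(Qb - t(Qb))) / max(max(abs(Qb)), floor_scale)
    worst <- max(worst, ra, rb)
  }
  worst
}

#' Block matrix for the rank form of the triple invariants
#'
#' Assembles the `3 kappa x 3 kappa` block matrix whose rank drops to
#' `2 kappa` exactly when the corresponding cofactor invariant family is
#' symmetric (given invertibility of the off-diagonal blocks): writing the
#' symmetry condition as `C B^-1 A + D E^-1 F = 0`, the block matrix is
#' `[0 A B; D 0 C; E F 0]`.
#'
#' @param P a 3-way `spt`.
#' @param triple character vector `c(x, y, z)` meaning `((x,y),z)`.
#' @param k slice state in `0..kappa-1`.
#' @param family `"a"` (invariant `Qa`) or `"b"` (invariant `Qb`).
#' @return a `3*kappa` square numeric matrix.
#' @export
ottaviani_block <- function(P, triple, k, family = c("a", "b")) {
  family <- match.arg(family)
  if (k < 0 || k >= P$kappa) stop("state out of range")
  tp <- triple_parts(P, triple)
  Sk <- tp$slices[[k + 1]]
  Z <- matrix(0, P$kappa, P$kappa)
  if (family == "a") {
    A <- Sk;        B <- tp$m_b
    C <- tp$m_a;    D <- -t(Sk)
    E <- t(tp$m_b); Ff <- t(tp$m_a)
  } else {
    A <- t(tp$m_b); B <- t(tp$m_a)
    C <- Sk;        D <- -tp$m_b
    E <- tp$m_a;    Ff <- t(Sk)
  }
  rbind(cbind(Z, A, B), cbind(D, Z, C), cbind(E, Ff, Z))
}

#' Rank a 3-way tensor's rooted triples by symmetry residual
#'
#' Scores each of the three rooted triples on the taxa by
#' [triple_symmetry_residual()] and ranks ascending (smallest = best
#' supported). For `kappa = 2` the invariants are identically zero and the
#' function refuses.
#'
#' @param P a 3-way `spt` with `kappa >= 3`.
#' @param tie_tol residual difference below which the top triples are flagged
#'   as tied.
#' @return a data.frame with columns `triple` and `residual`, ascending, with
#'   attribute `"degenerate"` set when the top two scores tie.
#' @export
infer_rooted_triple <- function(P, tie_tol = 1e-12) {
  if (P$kappa == 2) {
    stop("kappa = 2 carries no rooted-triple signal: the cofactor invariants vanish identically on all 2-state tensors")
  }
  tx <- sort(P$taxa)
  triples <- list(c(tx[1], tx[2], tx[3]), c(tx[1], tx[3], tx[2]), c(tx[2], tx[3], tx[1]))
  lab <- vapply(triples, function(tr) sprintf("((%s,%s),%s)", tr[1], tr[2], tr[3]), character(1))
  res <- vapply(triples, function(tr) triple_symmetry_residual(P, tr), numeric(1))
  o <- order(res, lab)
  out <- data.frame(triple = lab[o], residual = res[o], stringsAsFactors = FALSE)
  attr(out, "degenerate") <- (out$residual[2] - out$residual[1]) < tie_tol
  out
}

#' Local dimension of the 3-taxon EE model
#'
#' Numerical rank of the Jacobian of the parameterization
#' `(UE affine coordinates, off-diagonal entries of the three Markov matrices
#' M_i) -> ue_point(u) * (M_1^-1, M_2^-1, M_3^-1)`
#' at a seeded generic point (generic UE point; `M_i = expm(0.1 R_i)` with
#' seeded sum-zero `R_i`). All derivative directions lie in the sum-zero
#' hyperplane, so the reported rank is the model's local dimension inside the
#' probability simplex.
#'
#' @param tree a 3-leaf `ue_tree`.
#' @param kappa number of states (2, 3 or 4).
#' @param seed integer seed.
#' @return integer local dimension estimate.
#' @export
ee_local_dimension <- function(tree, kappa, seed) {
  if (!(kappa %in% 2:4)) stop("kappa must be 2, 3 or 4")
  if (length(tree$taxa) != 3) stop("a 3-leaf tree is required")
  n <- 3
  basis <- ue_null_basis(tree, kappa)
  ## sum-zero affine directions inside the cone
  B <- basis - matrix(colMeans(basis), nrow(basis), ncol(basis), byrow = TRUE)
  qrB <- qr(B)
  d <- dimension_recursive(tree, kappa)$d
  if (qrB$rank != d) stop("internal error: UE affine basis is rank deficient")
  B <- qr.Q(qrB)[, seq_len(d), drop = FALSE]

  P0 <- sample_ue_point(tree, kappa, seed)
  mats <- lapply(1:3, function(i) {
    R <- matrix(stats::rnorm(kappa^2), kappa, kappa)
    diag(R) <- 0
    diag(R) <- -rowSums(R)
    mat_exp(0.1 * R)
  })
  invs <- lapply(mats, solve)

  cols <- list()
  ## UE-coordinate directions
  for (i in seq_len(d)) {
    Bi <- spt(B[, i], P0$taxa, kappa)  # flat pattern-lex vector
    cols[[length(cols) + 1L]] <- spt_flat(star_action(Bi, invs))
  }
  ## Markov off-diagonal directions: d/dtheta M^-1 = -M^-1 (dM) M^-1 with
  ## dM = E_ij - E_ii (the diagonal absorbs the row-sum constraint)
  for (t in 1:3) {
    for (i in 1:kappa) for (j in setdiff(1:kappa, i)) {
      dM <- matrix(0, kappa, kappa)
      dM[i, j] <- 1; dM[i, i] <- -1
      dInv <- -invs[[t]] %*% dM %*% invs[[t]]
      dmats <- invs
      dmats[[t]] <- dInv
      cols[[length(cols) + 1L]] <- spt_flat(star_action(P0, dmats))
    }
  }
  J <- do.call(cbind, cols)
  sv <- svd(J, nu = 0, nv = 0)$d
  sum(sv > 1e-8 * sv[1])
}
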