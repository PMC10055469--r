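## Substitution models: rate matrix Q (rows sum to 0) with stationary
## distribution pi, matrix exponentials via spectral decomposition, and the
## Markov-on-tree site-pattern distribution (no coalescent).

#' Construct a substitution model
#'
#' @param Q `kappa x kappa` rate matrix: nonnegative off-diagonals, rows
#'   summing to zero.
#' @param pi stationary distribution; computed from `Q` when `NULL`.
#' @param name optional model name.
#' @return an object of class `"sub_model"` with fields `kappa`, `Q`, `pi`.
#' @export
substitution_model <- function(Q, pi = NULL, name = "custom") {
  kap <- nrow(Q)
  stopifnot(ncol(Q) == kap, kap >= 2)
  offd <- Q; diag(offd) <- 0
  if (any(offd < 0)) stop("off-diagonal rates must be >= 0")
  if (max(abs(rowSums(Q))) > 1e-12) stop("rows of Q must sum to 0")
  if (is.null(pi)) {
    ns <- svd(t(Q))
    v <- abs(ns$u[, kap])
    pi <- v / sum(v)
  }
  stopifnot(length(pi) == kap, all(pi > 0))
  if (abs(sum(pi) - 1) > 1e-12) stop("pi must sum to 1")
  if (max(abs(pi %*% Q)) > 1e-10) stop("pi is not stationary for Q")
  structure(list(kappa = kap, Q = Q, pi = pi, name = name), class = "sub_model")
}

#' @export
print.sub_model <- function(x, ...) {
  cat(sprintf("%s substitution model, kappa = %d\n", x$name, x$kappa))
  invisible(x)
}

#' Jukes-Cantor model on kappa states
#'
#' All off-diagonal rates equal (`rate`), diagonal `-(kappa-1)*rate`; uniform
#' stationary distribution.
#' @param kappa number of states (`>= 2`).
#' @param rate off-diagonal rate (default 1).
#' @return a `sub_model`.
#' @export
jc_model <- function(kappa = 4, rate = 1) {
  Q <- matrix(rate, kappa, kappa)
  diag(Q) <- -(kappa - 1) * rate
  substitution_model(Q, pi = rep(1 / kappa, kappa), name = sprintf("JC%d", kappa))
}

#' Kimura 2-parameter model
#'
#' The 4-state K2P rate matrix on states `A,G,C,T`
#' with rows `(-4,1,2,1), (1,-4,1,2), (2,1,-4,1), (1,2,1,-4)` and uniform
#' equilibrium distribution.
#' @return a `sub_model`.
#' @export
k2p_model <- function() {
  Q <- matrix(c(-4, 1, 2, 1,
                 1, -4, 1, 2,
                 2, 1, -4, 1,
                 1, 2, 1, -4), 4, 4, byrow = TRUE)
  substitution_model(Q, pi = rep(0.25, 4), name = "K2P")
}

#' Detailed-balance (time reversibility) check
#' @param m a `sub_model`.
#' @param tol tolerance.
#' @return `TRUE` if `pi_i Q_ij = pi_j Q_ji` for all `i, j`.
#' @export
is_time_reversible <- function(m, tol = 1e-10) {
  W <- diag(m$pi) %*% m$Q
  max(abs(W - t(W))) <= tol
}

## Spectral decomposition of a reversible Q: exp(tQ) = sum_j e^(lambda_j t) A_j
## with distinct eigenvalues lambda_j and projectors A_j. Uses the
## pi-symmetrization D^(1/2) Q D^(-1/2).
model_spectrum <- function(m, tol = 1e-9) {
  if (!is_time_reversible(m)) stop("spectral form requires a reversible (GTR-type) rate matrix")
  d <- sqrt(m$pi)
  S <- (d %o% (1 / d)) * m$Q           # D^(1/2) Q D^(-1/2), symmetric
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- e$values
  groups <- split(seq_along(lam), cumsum(c(TRUE, diff(lam) < -tol)))
  lambda <- numeric(0); proj <- list()
  for (g in groups) {
    V <- e$vectors[, g, drop = FALSE]
    A <- ((1 / d) %o% d) * (V %*% t(V))  # D^(-1/2) V V^T D^(1/2)
    lambda <- c(lambda, mean(lam[g]))
    proj[[length(proj) + 1L]] <- A
  }
  list(lambda = lambda, proj = proj)
}

#' Transition matrix exp(tQ)
#'
#' Computed by spectral decomposition for reversible models, with a
#' scaling-and-squaring fallback otherwise.
#' @param m a `sub_model`.
#' @param t substitution length (`>= 0`).
#' @return a `kappa x kappa` Markov matrix.
#' @export
transition_matrix <- function(m, t) {
  if (t < 0) stop("t must be >= 0")
  if (is_time_reversible(m)) {
    sp <- model_spectrum(m)
    M <- Reduce(`+`, Map(function(l, A) exp(l * t) * A, sp$lambda, sp$proj))
  } else {
    M <- mat_exp(t * m$Q)
  }
  M[M < 0 & M > -1e-14] <- 0
  M
}

#' Markov-on-tree site-pattern distribution (no coalescent)
#'
#' The standard tensor of joint leaf-state probabilities for a substitution
#' process run down a metric tree: the root state is drawn from `root_dist`
#' and evolves along each edge by `exp(slen * Q)`.
#'
#' @param tree a `ue_tree` with substitution lengths (`slen`) on all non-root
#'   edges.
#' @param m a `sub_model`.
#' @param root_dist root state distribution (default the model's `pi`).
#' @return a probability `spt` on `tree$taxa`.
#' @export
markov_tree_distribution <- function(tree, m, root_dist = NULL) {
  if (is.null(root_dist)) root_dist <- m$pi
  kap <- m$kappa
  ## cond(node): matrix [state at node, leaf pattern] with pattern index
  ## column-major over the node's leaves, first leaf fastest
  cond <- function(node) {
    if (is_leaf(node)) return(diag(kap))
    out <- NULL
    for (child in node$kids) {
      sl <- child$slen
      if (is.na(sl)) stop("substitution length missing on an edge")
      A <- transition_matrix(m, sl) %*% cond(child)
      out <- if (is.null(out)) A else {
        c1 <- ncol(out); c2 <- ncol(A)
        out[, rep(seq_len(c1), times = c2), drop = FALSE] *
          A[, rep(seq_len(c2), each = c1), drop = FALSE]
      }
    }
    out
  }
  root <- tree$root
  C <- if (is_leaf(root)) diag(kap) else cond(root)
  joint <- as.vector(root_dist %*% C)
  order_labels <- node_labels(root)
  vals <- array(joint, dim = rep(kap, length(order_labels)))
  perm <- match(tree$taxa, order_labels)
  spt(aperm(vals, perm), tree$taxa, kap)
}

#' Convex mixture of site-pattern tensors
#'
#' @param dists list of `spt` objects on the same taxa and state count.
#' @param weights nonnegative weights summing to 1 (default uniform).
#' @return an `spt`.
#' @export
mixture <- function(dists, weights = NULL) {
  stopifnot(length(dists) >= 1)
  if (is.null(weights)) weights <- rep(1 / length(dists), length(dists))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) stop("weights must be nonnegative and sum to 1")
  t0 <- dists[[1]]$taxa; k0 <- dists[[1]]$kappa
  acc <- array(0, dim = dim(dists[[1]]$values))
  for (i in seq_along(dists)) {
    if (!identical(dists[[i]]$taxa, t0) || dists[[i]]$kappa != k0) stop("mismatched shapes")
    acc <- acc + weights[i] * dists[[i]]$values
  }
  spt(acc, t0, k0)
}
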