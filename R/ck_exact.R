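## Exact coalescent-mixture (CK) site-pattern distributions by closed-form
## spectral integration over coalescent histories.
##
## A lineage is a pair (taxa, C) with C[s, p] = P(leaf pattern p | lineage
## state s at its current top); pattern index is column-major over the
## lineage's taxa, first taxon fastest. All waiting-time integrals reduce to
## rational functions of the rate-matrix eigenvalues because exp(Qt) is a
## finite sum of e^(lambda t) projectors, so no quadrature or Monte Carlo is
## involved.

new_lineage <- function(taxa, C) list(taxa = taxa, C = C)

merge_lineages <- function(l1, l2) {
  c1 <- ncol(l1$C); c2 <- ncol(l2$C)
  C <- l1$C[, rep(seq_len(c1), times = c2), drop = FALSE] *
       l2$C[, rep(seq_len(c2), each = c1), drop = FALSE]
  new_lineage(c(l1$taxa, l2$taxa), C)
}

## Joint pattern array (axes in sorted taxon order) for a single completed
## lineage, tying the root state to `pi`.
lineage_to_array <- function(lin, pi, kappa, taxa_sorted) {
  vec <- as.vector(pi %*% lin$C)
  arr <- array(vec, dim = rep(kappa, length(lin$taxa)))
  aperm(arr, match(taxa_sorted, lin$taxa))
}

## Exact distribution of the Kingman coalescent in an unbounded (root)
## population entered by the given lineages, substitution rate `rs` per
## coalescent unit. Recursive spectral expansion: advancing all k lineages to
## the first coalescence time contributes e^(sum lambda * rs * w), and
## integrating the Exp(choose(k,2)) waiting time gives a rational weight.
root_population_exact <- function(lins, sp, rs, pi, kappa, taxa_sorted) {
  k <- length(lins)
  if (k == 1) return(lineage_to_array(lins[[1]], pi, kappa, taxa_sorted))
  nd <- length(sp$lambda)
  total <- choose(k, 2)
  acc <- array(0, dim = rep(kappa, length(taxa_sorted)))
  pairs <- utils::combn(k, 2, simplify = FALSE)
  combos <- expand.grid(rep(list(seq_len(nd)), k))
  for (pr in pairs) {
    for (r in seq_len(nrow(combos))) {
      mm <- as.integer(combos[r, ])
      w <- 1 / (total - rs * sum(sp$lambda[mm]))
      adv <- vector("list", k)
      dead <- FALSE
      for (t in seq_len(k)) {
        Ct <- sp$proj[[mm[t]]] %*% lins[[t]]$C
        if (max(abs(Ct)) < 1e-300) { dead <- TRUE; break }
        adv[[t]] <- new_lineage(lins[[t]]$taxa, Ct)
      }
      if (dead) next
      merged <- merge_lineages(adv[[pr[1]]], adv[[pr[2]]])
      rest <- adv[-pr]
      acc <- acc + w * root_population_exact(c(rest, list(merged)),
                                             sp, rs, pi, kappa, taxa_sorted)
    }
  }
  acc
}

## Cases for two lineages traversing an internal edge of coalescent duration
## tau and substitution rate r: either no coalescence (probability e^(-tau)),
## or coalescence at t in (0, tau) expanded spectrally, with the t-integral
## in closed form. Returns list of (weight, lineages).
cherry_edge_cases <- function(l1, l2, tau, r, m, sp) {
  kap <- m$kappa
  nd <- length(sp$lambda)
  cases <- list()
  Mtau <- transition_matrix(m, tau * r)
  cases[[1]] <- list(weight = exp(-tau),
                     lineages = list(new_lineage(l1$taxa, Mtau %*% l1$C),
                                     new_lineage(l2$taxa, Mtau %*% l2$C)))
  if (tau > 0) {
    for (m1 in seq_len(nd)) for (m2 in seq_len(nd)) {
      base <- merge_lineages(new_lineage(l1$taxa, sp$proj[[m1]] %*% l1$C),
                             new_lineage(l2$taxa, sp$proj[[m2]] %*% l2$C))
      if (max(abs(base$C)) < 1e-300) next
      for (m3 in seq_len(nd)) {
        C3 <- sp$proj[[m3]] %*% base$C
        if (max(abs(C3)) < 1e-300) next
        cc <- (sp$lambda[m1] + sp$lambda[m2] - sp$lambda[m3]) * r - 1
        tint <- if (abs(cc) < 1e-12) tau * exp(sp$lambda[m3] * r * tau) else
          (exp(cc * tau) - 1) / cc * exp(sp$lambda[m3] * r * tau)
        if (tint == 0) next
        cases[[length(cases) + 1L]] <-
          list(weight = tint, lineages = list(new_lineage(base$taxa, C3)))
      }
    }
  }
  cases
}

pendant_lineage <- function(node, m) {
  new_lineage(node$label, transition_matrix(m, node$slen))
}

#' Exact CK site-pattern distribution on small species trees
#'
#' Computes the coalescent-mixture distribution exactly, by enumerating
#' coalescent histories and evaluating all waiting-time integrals in closed
#' form through the spectral decomposition of the rate matrix. Supported
#' shapes are those whose non-root internal edges each subtend a cherry: all
#' 2- and 3-taxon trees and the balanced 4-taxon tree.
#'
#' @param spec a `coal_spec` (reversible substitution model required).
#' @param m a `sub_model`.
#' @return a probability `spt` on the species-tree taxa (sorted order).
#' @export
ck_distribution_exact <- function(spec, m) {
  tree <- spec$species
  root <- tree$root
  if (is_leaf(root)) stop("at least 2 taxa required")
  sp <- model_spectrum(m)
  kap <- m$kappa
  taxa_sorted <- sort(tree$taxa)
  child_cases <- lapply(root$kids, function(child) {
    if (is_leaf(child)) {
      return(list(list(weight = 1, lineages = list(pendant_lineage(child, m)))))
    }
    if (!all(vapply(child$kids, is_leaf, logical(1)))) {
      stop("exact CK supports species trees whose non-root internal edges subtend cherries; use ck_distribution_mc for this shape")
    }
    l1 <- pendant_lineage(child$kids[[1]], m)
    l2 <- pendant_lineage(child$kids[[2]], m)
    tau <- child$clen
    r <- if (tau > 0) child$slen / tau else 0
    cherry_edge_cases(l1, l2, tau, r, m, sp)
  })
  acc <- array(0, dim = rep(kap, length(taxa_sorted)))
  for (ca in child_cases[[1]]) for (cb in child_cases[[2]]) {
    lins <- c(ca$lineages, cb$lineages)
    acc <- acc + ca$weight * cb$weight *
      root_population_exact(lins, sp, spec$rate_scale, m$pi, kap, taxa_sorted)
  }
  spt(acc, taxa_sorted, kap)
}

#' Exact CK distribution on a 3-taxon species tree
#'
#' @inheritParams ck_distribution_exact
#' @return a probability `spt`.
#' @export
ck_distribution_exact_3taxon <- function(spec, m) {
  if (length(spec$species$taxa) != 3) stop("a 3-taxon species tree is required")
  ck_distribution_exact(spec, m)
}

#' Closed-form 2-taxon CK distribution matrix
#'
#' For a 2-taxon species tree `(a:x, b:(ell-x))` (substitution lengths; root
#' population unbounded), the site-pattern matrix is
#' `F = diag(pi) M_ell sum_j A_j / (1 - 2 lambda_j rate_scale)`
#' where `exp(Qt) = sum_j e^(lambda_j t) A_j`. `F` is symmetric and does not
#' depend on how `ell` is split between the two pendants; `x` is accepted for
#' interface symmetry with the quadrature check.
#'
#' @param x pendant substitution length of the first taxon (`0 <= x <= ell`).
#' @param ell total pendant substitution length.
#' @param m a reversible `sub_model`.
#' @param rate_scale substitution length per coalescent unit in the root.
#' @return a symmetric `kappa x kappa` matrix summing to 1.
#' @export
ck_distribution_exact_2taxon <- function(x, ell, m, rate_scale = 1) {
  if (x < 0 || x > ell) stop("need 0 <= x <= ell")
  sp <- model_spectrum(m)
  S <- Reduce(`+`, Map(function(l, A) A / (1 - 2 * l * rate_scale), sp$lambda, sp$proj))
  diag(m$pi) %*% transition_matrix(m, ell) %*% S
}

#' Quadrature check of the 2-taxon CK distribution
#'
#' Direct numerical evaluation of
#' `F = integral diag(pi) M_x M_(2 t rate_scale) M_(ell-x) e^(-t) dt`,
#' used as an independent oracle for [ck_distribution_exact_2taxon()].
#' @inheritParams ck_distribution_exact_2taxon
#' @return a `kappa x kappa` matrix.
#' @export
ck_2taxon_quadrature <- function(x, ell, m, rate_scale = 1) {
  if (x < 0 || x > ell) stop("need 0 <= x <= ell")
  kap <- m$kappa
  Mx <- transition_matrix(m, x)
  My <- transition_matrix(m, ell - x)
  Fm <- matrix(0, kap, kap)
  for (i in 1:kap) for (j in 1:kap) {
    f <- function(t) {
      vapply(t, function(tt) {
        (diag(m$pi) %*% Mx %*% transition_matrix(m, 2 * tt * rate_scale) %*% My)[i, j] * exp(-tt)
      }, numeric(1))
    }
    Fm[i, j] <- stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  Fm
}

#' Exponent-basis decomposition of the exact 3-taxon CK distribution
#'
#' Represents every tensor entry exactly as a finite sum
#' `sum_q c_q * e^q`, grouped by the exponent `q` (a linear combination of
#' rate-matrix eigenvalues and branch lengths). Because entries are never
#' collapsed to a single float, differences of entries can be examined
#' coefficient-by-coefficient: a leading nonzero coefficient certifies a
#' nonzero difference regardless of how small `e^q` is, which is how
#' vanishingly small slice asymmetries (of order `e^-20` and below) are
#' detected reliably.
#'
#' @inheritParams ck_distribution_exact
#' @return an object of class `"ck3_expsum"`: list with `exponents` (numeric,
#'   decreasing), `tensors` (list of coefficient arrays over sorted taxa),
#'   `taxa`, `kappa`.
#' @export
ck3_exponent_decomposition <- function(spec, m) {
  tree <- spec$species
  if (length(tree$taxa) != 3) stop("a 3-taxon species tree is required")
  root <- tree$root
  kids <- root$kids
  cherry_idx <- which(vapply(kids, function(k) !is_leaf(k), logical(1)))
  if (length(cherry_idx) != 1) stop("tree must be a cherry plus outgroup")
  ch <- kids[[cherry_idx]]
  out <- kids[[-cherry_idx + 3L]]  # the other child
  if (!all(vapply(ch$kids, is_leaf, logical(1)))) stop("malformed 3-taxon tree")
  xs <- ch$kids[[1]]; ys <- ch$kids[[2]]
  sx <- xs$slen; sy <- ys$slen; sz <- out$slen
  tau <- ch$clen
  r <- if (tau > 0) ch$slen / tau else 0
  rs <- spec$rate_scale
  sp <- model_spectrum(m)
  lam <- sp$lambda; A <- sp$proj; nd <- length(lam)
  kap <- m$kappa
  pi <- m$pi
  taxa_sorted <- sort(tree$taxa)
  acc <- new.env(parent = emptyenv())
  add_term <- function(coef, q, lin) {
    if (coef == 0) return(invisible())
    arr <- lineage_to_array(lin, pi, kap, taxa_sorted)
    key <- sprintf("%.9g", q)
    prev <- if (is.null(acc[[key]])) {
      list(q = q, T = array(0, dim = rep(kap, 3)))
    } else acc[[key]]
    prev$T <- prev$T + coef * arr
    acc[[key]] <- prev
  }
  lx <- xs$label; ly <- ys$label; lz <- out$label

  ## coalescence inside the internal edge at time t, then two root lineages
  if (tau > 0) {
    for (p1 in 1:nd) for (p2 in 1:nd) {
      D <- merge_lineages(new_lineage(lx, A[[p1]]), new_lineage(ly, A[[p2]]))
      for (m3 in 1:nd) {
        C3 <- A[[m3]] %*% D$C
        if (max(abs(C3)) < 1e-300) next
        for (p3 in 1:nd) {
          lin <- merge_lineages(new_lineage(D$taxa, C3), new_lineage(lz, A[[p3]]))
          wint <- 1 / (1 - rs * (lam[m3] + lam[p3]))
          q0 <- lam[p1] * sx + lam[p2] * sy + lam[p3] * sz
          cc <- (lam[p1] + lam[p2] - lam[m3]) * r - 1
          if (abs(cc) < 1e-12) {
            add_term(tau * wint, q0 + lam[m3] * r * tau, lin)
          } else {
            add_term(wint / cc, q0 + (lam[p1] + lam[p2]) * r * tau - tau, lin)
            add_term(-wint / cc, q0 + lam[m3] * r * tau, lin)
          }
        }
      }
    }
  }

  ## no coalescence inside the internal edge: three root lineages
  labels <- c(lx, ly, lz)
  extra <- c(r * tau, r * tau, 0)  # internal-edge advancement of x,y chains
  slen3 <- c(sx, sy, sz)
  pair_sets <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (p1 in 1:nd) for (p2 in 1:nd) for (p3 in 1:nd) {
    pp <- c(p1, p2, p3)
    w1 <- 1 / (3 - rs * sum(lam[pp]))
    q0 <- sum(lam[pp] * (slen3 + extra)) - tau
    for (ps in pair_sets) {
      other <- setdiff(1:3, ps)
      D <- merge_lineages(new_lineage(labels[ps[1]], A[[pp[ps[1]]]]),
                          new_lineage(labels[ps[2]], A[[pp[ps[2]]]]))
      for (v in 1:nd) {
        Cv <- A[[v]] %*% D$C
        if (max(abs(Cv)) < 1e-300) next
        w2 <- 1 / (1 - rs * (lam[v] + lam[pp[other]]))
        lin <- merge_lineages(new_lineage(D$taxa, Cv),
                              new_lineage(labels[other], A[[pp[other]]]))
        add_term(w1 * w2, q0, lin)
      }
    }
  }

  terms <- as.list(acc)
  qs <- vapply(terms, function(t) t$q, numeric(1))
  o <- order(qs, decreasing = TRUE)
  structure(list(exponents = unname(qs[o]),
                 tensors = unname(lapply(terms[o], function(t) t$T)),
                 taxa = taxa_sorted, kappa = kap),
            class = "ck3_expsum")
}

#' Evaluate an exponent-basis CK decomposition to a tensor
#' @param es a `ck3_expsum`.
#' @return a probability `spt`.
#' @export
ck3_eval <- function(es) {
  acc <- array(0, dim = rep(es$kappa, 3))
  for (i in seq_along(es$exponents)) {
    acc <- acc + exp(es$exponents[i]) * es$tensors[[i]]
  }
  spt(acc, es$taxa, es$kappa)
}

#' Exponent-basis coefficients of a slice asymmetry
#'
#' For the pair `(a, b)` and outgroup slice `z = k`, returns the coefficients
#' `c_q` of `P[a=i, b=j, z=k] - P[a=j, b=i, z=k]` by exponent, largest
#' exponent first. A nonzero leading coefficient certifies that the
#' asymmetry, `sum_q c_q e^q`, is nonzero even when far below double
#' precision relative to the tensor entries.
#'
#' @param es a `ck3_expsum`.
#' @param a,b the exchanged taxa.
#' @param z the sliced taxon.
#' @param i,j,k 0-based states (`i`,`j` for `a`,`b`; `k` for `z`).
#' @param drop_tol coefficients below this magnitude are treated as exact
#'   zeros (they arise from floating-point accumulation of cancelling terms).
#' @return data.frame with columns `exponent` and `coef`, decreasing exponent,
#'   zero rows removed.
#' @export
ck3_slice_asymmetry <- function(es, a, b, z, i, j, k, drop_tol = 1e-12) {
  pos <- match(c(a, b, z), es$taxa)
  if (any(is.na(pos))) stop("unknown taxa")
  idx1 <- idx2 <- integer(3)
  idx1[pos] <- c(i, j, k) + 1L
  idx2[pos] <- c(j, i, k) + 1L
  coefs <- vapply(es$tensors, function(T) {
    T[idx1[1], idx1[2], idx1[3]] - T[idx2[1], idx2[2], idx2[3]]
  }, numeric(1))
  scale <- vapply(es$tensors, function(T) max(abs(T)), numeric(1))
  keep <- abs(coefs) > drop_tol * pmax(scale, 1)
  data.frame(exponent = es$exponents[keep], coef = coefs[keep])
}
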