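## Multispecies coalescent gene-tree sampling and Monte-Carlo
## coalescent-mixture (CK) site-pattern distributions.
##
## Units: species-tree edges carry a coalescent duration `clen` (time in 2N
## generations; pair coalescence rate 1) and a substitution length `slen`.
## Within an edge, a lineage accrues substitution length at rate slen/clen per
## coalescent unit; in the root population the rate is `rate_scale`
## (mu = 1/2N corresponds to rate_scale = 1, the default, under which a tree
## with equal clen and slen is the standard one-rate setup).

#' Construct a coalescent specification
#'
#' @param species a `ue_tree` with `clen` and `slen` on all non-root edges.
#'   A pendant edge with `clen = 0` and `slen > 0` is allowed (a pure
#'   substitution burst); an internal edge with `clen = 0` and `slen > 0` is
#'   ambiguous and rejected.
#' @param rate_scale substitution length per coalescent unit in the root
#'   population (and anywhere `clen` carries no `slen`).
#' @return an object of class `"coal_spec"`.
#' @export
coalescent_spec <- function(species, rate_scale = 1) {
  stopifnot(rate_scale > 0)
  check <- function(node, is_root = FALSE) {
    if (!is_root) {
      if (is.na(node$clen) || is.na(node$slen)) stop("clen/slen missing on an edge")
      if (node$clen < 0 || node$slen < 0) stop("negative edge length")
      if (!is_leaf(node) && node$clen == 0 && node$slen > 0) {
        stop("internal edge with zero coalescent duration but positive substitution length")
      }
    }
    if (!is_leaf(node)) for (k in node$kids) check(k)
  }
  check(species$root, is_root = TRUE)
  structure(list(species = species, rate_scale = rate_scale), class = "coal_spec")
}

## Kingman process on `lineages` (list of list(node, psub)) for a population
## of coalescent duration d and substitution rate `rate` per coalescent unit.
## psub = substitution length accumulated since the lineage's node was formed.
run_population <- function(lineages, d, rate) {
  elapsed <- 0
  k <- length(lineages)
  while (k >= 2) {
    t <- stats::rexp(1, rate = choose(k, 2))
    if (elapsed + t > d) break
    elapsed <- elapsed + t
    for (i in seq_len(k)) lineages[[i]]$psub <- lineages[[i]]$psub + t * rate
    pair <- sample.int(k, 2)
    l1 <- lineages[[pair[1]]]; l2 <- lineages[[pair[2]]]
    n1 <- l1$node; n1$slen <- l1$psub; n1$clen <- NA_real_
    n2 <- l2$node; n2$slen <- l2$psub; n2$clen <- NA_real_
    merged <- list(node = new_inode(n1, n2), psub = 0)
    lineages <- c(lineages[-pair], list(merged))
    k <- k - 1L
  }
  if (is.finite(d)) {
    rem <- d - elapsed
    for (i in seq_along(lineages)) lineages[[i]]$psub <- lineages[[i]]$psub + rem * rate
  }
  lineages
}

#' Sample a gene tree under the multispecies coalescent
#'
#' One lineage per taxon; within each species-tree edge lineages coalesce as
#' a Kingman process truncated at the edge's coalescent duration, survivors
#' enter the parent population, and the root population runs to completion.
#' Gene-tree branch lengths are in substitution units (accumulated per edge
#' at that edge's rate; pendant edges contribute their full `slen`).
#'
#' @param spec a `coal_spec`.
#' @param seed optional integer seed (the caller may instead manage the RNG).
#' @return a `ue_tree` gene tree whose `slen` are substitution lengths.
#' @export
sample_gene_tree <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rs <- spec$rate_scale
  traverse <- function(node) {
    ## returns the lineages leaving this node's edge upward
    if (is_leaf(node)) {
      lin <- list(list(node = new_leaf(node$label), psub = 0))
    } else {
      lin <- c(traverse(node$kids[[1]]), traverse(node$kids[[2]]))
    }
    d <- node$clen
    if (is.na(d)) return(lin)  # root: handled by caller
    if (d == 0) {
      for (i in seq_along(lin)) lin[[i]]$psub <- lin[[i]]$psub + node$slen
      return(lin)
    }
    run_population(lin, d, node$slen / d)
  }
  lin <- traverse(spec$species$root)
  lin <- run_population(lin, Inf, rs)
  stopifnot(length(lin) == 1)
  root <- lin[[1]]$node
  rooted_tree(root)
}

#' Monte-Carlo CK site-pattern distribution
#'
#' Average of the exact per-gene-tree Markov distributions over `n_genes`
#' gene trees sampled under the multispecies coalescent (Monte Carlo over
#' gene trees only; no site sampling noise).
#'
#' @param spec a `coal_spec`.
#' @param m a `sub_model`.
#' @param n_genes number of gene trees (`>= 1`).
#' @param seed integer seed.
#' @return a probability `spt` on the species-tree taxa.
#' @export
ck_distribution_mc <- function(spec, m, n_genes, seed) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  acc <- NULL
  for (g in seq_len(n_genes)) {
    gt <- sample_gene_tree(spec)
    P <- markov_tree_distribution(gt, m)
    acc <- if (is.null(acc)) P$values else acc + P$values
  }
  spt(acc / n_genes, sort(spec$species$taxa), m$kappa)
}
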