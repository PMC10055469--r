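## Shared fixtures: all inputs are generated in code.

## Quartet coalescent spec in the study conditions used throughout: balanced
## species tree, all coalescent durations 1, mutation scale theta/2 = 0.05
## expected substitutions per coalescent unit.
ck_quartet_spec <- function(theta2 = 0.05) {
  tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  coalescent_spec(scale_tree_lengths(tr, sub = theta2), rate_scale = theta2)
}

ck_triple_spec <- function(newick = "((a:1,b:1):1,c:2);", rate_scale = 1) {
  coalescent_spec(parse_newick(newick), rate_scale = rate_scale)
}

## A random probability tensor (not in any UE model, generically).
random_prob_tensor <- function(taxa, kappa, seed) {
  set.seed(seed)
  v <- stats::runif(kappa^length(taxa))
  spt(v / sum(v), taxa, kappa)
}

## Relative-tolerance numerical rank used for "generic full rank" assertions.
rel_rank <- function(M, rel = 1e-8) {
  sv <- svd(M, nu = 0, nv = 0)$d
  sum(sv > rel * sv[1])
}
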