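## Flattening-rank quartet inference: the SVD score, per-split rank tables,
## exact quartet amalgamation, and the sampling consistency experiment.

#' SVD score of a flattening matrix
#'
#' The sum of the `choose(kappa, 2)` smallest singular values of a
#' `kappa^2 x kappa^2` matrix. It vanishes exactly when the matrix has at
#' least that many zero singular values, i.e. rank at most
#' `choose(kappa + 1, 2)` — the bound attained by the flattening matching the
#' tree's split.
#'
#' @param M a `kappa^2 x kappa^2` numeric matrix.
#' @param kappa number of states.
#' @return nonnegative score.
#' @export
svd_score <- function(M, kappa) {
  if (!all(dim(M) == kappa^2)) stop("matrix must be kappa^2 x kappa^2")
  sv <- svd(M, nu = 0, nv = 0)$d
  sum(sv[(kappa^2 - choose(kappa, 2) + 1):kappa^2])
}

quartet_splits <- function(taxa4) {
  tx <- sort(taxa4)
  list(list(A = tx[c(1, 2)], B = tx[c(3, 4)]),
       list(A = tx[c(1, 3)], B = tx[c(2, 4)]),
       list(A = tx[c(1, 4)], B = tx[c(2, 3)]))
}

#' Flattening ranks and SVD scores of the three quartet splits
#'
#' @param P an `spt` on exactly 4 taxa (marginalize first otherwise).
#' @param tol absolute singular-value tolerance for the rank (default the
#'   relative machine-precision rule of [numerical_rank()]).
#' @return a data.frame with columns `split`, `rank`, `score`.
#' @export
quartet_flattening_ranks <- function(P, tol = NULL) {
  if (length(P$taxa) != 4) stop("4 taxa required")
  rows <- lapply(quartet_splits(P$taxa), function(s) {
    Fl <- flatten_tensor(P, s$A, s$B)
    data.frame(split = split_string(s$A, s$B),
               rank = numerical_rank(Fl, tol),
               score = svd_score(Fl, P$kappa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Infer one quartet split by minimizing the SVD score
#'
#' Marginalizes to the four taxa, scores all three splits, and returns the
#' argmin (lexicographic tie-break; ties within `1e-12` flagged degenerate).
#'
#' @param P an `spt` on at least 4 taxa.
#' @param taxa4 the four taxa to use (defaults to all of `P$taxa`).
#' @return an object of class `"quartet_call"`: list with `taxa`, `split`,
#'   `table` (the score table), `degenerate`.
#' @export
infer_quartet <- function(P, taxa4 = NULL) {
  if (is.null(taxa4)) taxa4 <- P$taxa
  if (length(taxa4) != 4) stop("fewer than 4 taxa")
  Pm <- marginalize(P, taxa4)
  tab <- quartet_flattening_ranks(Pm)
  o <- order(tab$score, tab$split)
  structure(list(taxa = sort(taxa4),
                 split = tab$split[o[1]],
                 table = tab,
                 degenerate = (tab$score[o[2]] - tab$score[o[1]]) < 1e-12),
            class = "quartet_call")
}

#' @export
print.quartet_call <- function(x, ...) {
  cat("Quartet call:", x$split, if (x$degenerate) "(degenerate tie)" else "", "\n")
  print(x$table)
  invisible(x)
}

## All unrooted binary topologies on X, represented as rooted trees with the
## first (sorted) taxon attached at the root; each unrooted tree once.
enumerate_unrooted <- function(X) {
  X <- sort(X)
  if (length(X) < 4) stop("need at least 4 taxa")
  rest <- enumerate_rooted_binary(X[-1])
  lapply(rest, function(tr) rooted_tree(new_inode(new_leaf(X[1]), tr$root)))
}

#' Exact amalgamation of quartet calls
#'
#' Exhaustively searches all unrooted binary topologies on `X` for the one
#' displaying every called split. If none does, returns an incompatibility
#' report naming the conflicting quartets of the closest tree; by exactness,
#' whenever the calls are jointly displayed on some tree, that tree is
#' returned.
#'
#' @param calls named character vector mapping sorted comma-joined 4-subsets
#'   to split strings (as produced by [displayed_quartets()]), or a list of
#'   `quartet_call` objects covering every 4-subset of `X`.
#' @param X the taxon set (`|X| <= 8`); inferred from the calls when `NULL`.
#' @return on success, a `ue_tree` whose unrooted topology displays all calls
#'   (rooting is arbitrary; attribute `"arbitrarily_rooted"` is `TRUE`);
#'   otherwise a list with `status = "incompatible"` and `conflicts`.
#' @export
amalgamate_exact <- function(calls, X = NULL) {
  if (is.list(calls) && length(calls) && inherits(calls[[1]], "quartet_call")) {
    nm <- vapply(calls, function(q) paste(q$taxa, collapse = ","), character(1))
    calls <- stats::setNames(vapply(calls, function(q) q$split, character(1)), nm)
  }
  if (is.null(X)) X <- sort(unique(unlist(strsplit(names(calls), ","))))
  if (length(X) > 8) stop("exhaustive amalgamation limited to 8 taxa")
  need <- vapply(utils::combn(sort(X), 4, simplify = FALSE), paste,
                 character(1), collapse = ",")
  missing <- setdiff(need, names(calls))
  if (length(missing)) stop("missing 4-subsets: ", paste(missing, collapse = "; "))
  calls <- calls[need]
  best <- list(); best_bad <- NULL; best_n <- Inf
  for (tr in enumerate_unrooted(X)) {
    disp <- displayed_quartets(tr)[need]
    bad <- need[disp != calls]
    if (!length(bad)) {
      attr(tr, "arbitrarily_rooted") <- TRUE
      return(tr)
    }
    if (length(bad) < best_n) {
      best_n <- length(bad); best <- list(tr); best_bad <- bad
    } else if (length(bad) == best_n) {
      best[[length(best) + 1L]] <- tr; best_bad <- union(best_bad, bad)
    }
  }
  list(status = "incompatible", conflicts = unname(best_bad),
       closest = vapply(best, canonical_topology, character(1)))
}

#' Infer an unrooted species-tree topology by SVD quartets
#'
#' Calls [infer_quartet()] on every 4-subset and amalgamates exactly.
#'
#' @param P an `spt` on `4..8` taxa (e.g. from [read_pattern_counts()]).
#' @return list with `tree` (a `ue_tree`, arbitrarily rooted, or `NULL`),
#'   `status` (`"ok"` or `"incompatible"`), `conflicts`, and `report` (a
#'   data.frame of per-quartet scores and calls).
#' @export
infer_unrooted_tree <- function(P) {
  X <- sort(P$taxa)
  if (length(X) < 4 || length(X) > 8) stop("4 to 8 taxa supported")
  quads <- utils::combn(X, 4, simplify = FALSE)
  qc <- lapply(quads, function(q) infer_quartet(P, q))
  report <- do.call(rbind, lapply(qc, function(q) {
    data.frame(quartet = paste(q$taxa, collapse = ","), split = q$split,
               degenerate = q$degenerate,
               score_min = min(q$table$score), score_2nd = sort(q$table$score)[2],
               stringsAsFactors = FALSE)
  }))
  am <- amalgamate_exact(qc, X)
  if (inherits(am, "ue_tree")) {
    list(tree = am, status = "ok", conflicts = character(0), report = report)
  } else {
    list(tree = NULL, status = "incompatible", conflicts = am$conflicts,
         report = report)
  }
}

#' Sampling consistency experiment for quartet inference
#'
#' For each sample size `s`, draws `reps` empirical tensors of `s` sites from
#' the given 4-taxon distribution and records how often the SVD-score argmin
#' recovers `true_split`.
#'
#' @param dist a 4-taxon probability `spt`.
#' @param true_split split string (e.g. `"ab|cd"`, sides sorted).
#' @param sample_sizes vector of site counts.
#' @param reps replicates per sample size.
#' @param seed integer master seed (per-replicate seeds are drawn from it).
#' @return data.frame with columns `s`, `correct`, `reps`, `frequency`.
#' @export
consistency_experiment <- function(dist, true_split, sample_sizes, reps, seed) {
  if (length(dist$taxa) != 4) stop("4-taxon distribution required")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, reps * length(sample_sizes))
  rows <- list()
  for (si in seq_along(sample_sizes)) {
    s <- sample_sizes[si]
    correct <- 0L
    for (r in seq_len(reps)) {
      Ph <- multinomial_sample(dist, s, seed = sub_seeds[(si - 1) * reps + r])
      if (infer_quartet(Ph)$split == true_split) correct <- correct + 1L
    }
    rows[[si]] <- data.frame(s = s, correct = correct, reps = reps,
                             frequency = correct / reps)
  }
  do.call(rbind, rows)
}
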