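## Rooted binary leaf-labelled trees.
##
## Internal representation is a recursive node list:
##   leaf:     list(label = "a", clen = <coalescent length>, slen = <subst length>)
##   internal: list(kids = list(left, right), clen = ..., slen = ...)
## clen/slen are the lengths of the edge *above* the node (NA at the root:
## the root population is implicitly unbounded). A tree object wraps the root
## node together with the ordered taxon list used for tensor axis assignment
## (sorted label order unless supplied).

new_leaf <- function(label, clen = NA_real_, slen = NA_real_) {
  list(label = label, clen = clen, slen = slen)
}

new_inode <- function(left, right, clen = NA_real_, slen = NA_real_) {
  list(kids = list(left, right), clen = clen, slen = slen)
}

is_leaf <- function(node) !is.null(node$label)

node_labels <- function(node) {
  if (is_leaf(node)) return(node$label)
  c(node_labels(node$kids[[1]]), node_labels(node$kids[[2]]))
}

#' Construct a rooted binary tree object
#'
#' Wraps a recursive node structure into a tree object, validating that every
#' internal node is binary and leaf labels are unique.
#'
#' @param root recursive node structure (see [parse_newick()]).
#' @param taxa optional ordered character vector of taxon labels; defaults to
#'   sorted label order. This order fixes the axis order of site-pattern
#'   tensors built on the tree.
#' @return An object of class `"ue_tree"` with elements `root` and `taxa`.
#' @export
rooted_tree <- function(root, taxa = NULL) {
  labs <- node_labels(root)
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ", paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (is.null(taxa)) taxa <- sort(labs)
  if (!setequal(taxa, labs)) stop("taxa must be a permutation of the leaf labels")
  structure(list(root = root, taxa = taxa), class = "ue_tree")
}

#' @export
print.ue_tree <- function(x, ...) {
  cat("Rooted binary tree on", length(x$taxa), "taxa:", write_newick(x), "\n")
  invisible(x)
}

#' Number of taxa of a tree
#' @param tree a `ue_tree`.
#' @return integer leaf count.
#' @export
ntaxa <- function(tree) length(tree$taxa)

#' Parse a rooted binary metric tree from a Newick string
#'
#' Strict dialect: binary topology, labels matching `[A-Za-z0-9_]+`, optional
#' branch lengths after `:`, trailing semicolon required, no internal-node
#' labels. Both the coalescent and substitution edge lengths of the returned
#' tree are set to the parsed lengths; callers may rescale either
#' independently afterwards.
#'
#' @param text a single Newick string such as `"((a:2,c:0):1,b:1);"`.
#' @return A `ue_tree` whose nodes carry `clen` and `slen` equal to the parsed
#'   branch lengths (`NA` where absent). Child order follows the input.
#' @examples
#' tr <- parse_newick("((a:2,c:0):1,b:1);")
#' two_clades(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("[[:space:]]", "", text)
  chars <- strsplit(s, "")[[1]]
  pos <- 1L
  n <- length(chars)
  peek <- function() if (pos <= n) chars[pos] else ""
  fail <- function(msg) stop(sprintf("Newick parse error at position %d: %s", pos, msg), call. = FALSE)

  read_number <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9eE.+-]", chars[pos])) pos <<- pos + 1L
    if (pos == start) fail("expected a branch length")
    val <- suppressWarnings(as.numeric(paste(chars[start:(pos - 1L)], collapse = "")))
    if (is.na(val)) fail("malformed branch length")
    if (val < 0) fail("negative branch length")
    val
  }
  read_label <- function() {
    start <- pos
    while (pos <= n && grepl("[A-Za-z0-9_]", chars[pos])) pos <<- pos + 1L
    if (pos == start) fail("expected a taxon label")
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  read_subtree <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      left <- read_subtree()
      if (peek() != ",") fail("expected ',' (binary trees only)")
      pos <<- pos + 1L
      right <- read_subtree()
      if (peek() == ",") fail("non-binary node (more than two children)")
      if (peek() != ")") fail("expected ')'")
      pos <<- pos + 1L
      if (grepl("[A-Za-z0-9_]", peek())) fail("internal-node labels are not accepted")
      node <- new_inode(left, right)
    } else {
      node <- new_leaf(read_label())
    }
    if (peek() == ":") {
      pos <<- pos + 1L
      len <- read_number()
      node$clen <- len
      node$slen <- len
    }
    node
  }

  root <- read_subtree()
  if (peek() != ";") fail("expected trailing ';'")
  pos <- pos + 1L
  if (pos <= n) fail("trailing characters after ';'")
  if (is_leaf(root)) return(rooted_tree(root))
  rooted_tree(root)
}

#' Serialize a tree to Newick
#'
#' @param tree a `ue_tree`.
#' @param lengths which edge lengths to write: `"coal"`, `"sub"`, or `"none"`.
#'   Lengths are omitted automatically when absent (`NA`).
#' @param canonical if `TRUE`, children are recursively sorted by smallest
#'   contained leaf label, so topologically identical trees serialize
#'   identically.
#' @return a Newick string terminated by `";"`.
#' @export
write_newick <- function(tree, lengths = c("coal", "sub", "none"), canonical = FALSE) {
  lengths <- match.arg(lengths)
  fmt_len <- function(node) {
    len <- switch(lengths, coal = node$clen, sub = node$slen, none = NA_real_)
    if (is.na(len)) "" else paste0(":", format(len, digits = 15))
  }
  rec <- function(node) {
    if (is_leaf(node)) return(paste0(node$label, fmt_len(node)))
    kids <- node$kids
    if (canonical) {
      mins <- vapply(kids, function(k) min(node_labels(k)), character(1))
      kids <- kids[order(mins)]
    }
    paste0("(", rec(kids[[1]]), ",", rec(kids[[2]]), ")", fmt_len(node))
  }
  paste0(rec(tree$root), ";")
}

#' Canonical topology string
#'
#' Lengths are dropped and children sorted recursively by smallest contained
#' leaf label; two trees are isomorphic as rooted leaf-labelled topologies
#' iff their canonical strings are equal.
#'
#' @param tree a `ue_tree`.
#' @return a Newick string.
#' @export
canonical_topology <- function(tree) write_newick(tree, lengths = "none", canonical = TRUE)

#' Restrict a rooted tree to a taxon subset
#'
#' Returns the induced rooted topology on `Y` with all degree-2 nodes
#' suppressed; edge lengths (both kinds) are summed across suppressed nodes.
#'
#' @param tree a `ue_tree`.
#' @param Y nonempty character vector of taxon labels, a subset of
#'   `tree$taxa`.
#' @return a `ue_tree` on `Y`.
#' @export
restrict_tree <- function(tree, Y) {
  if (length(Y) < 1) stop("Y must be nonempty")
  unknown <- setdiff(Y, tree$taxa)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  add_len <- function(a, b) if (is.na(a)) b else if (is.na(b)) a else a + b
  rec <- function(node) {
    if (is_leaf(node)) {
      if (node$label %in% Y) return(node) else return(NULL)
    }
    l <- rec(node$kids[[1]])
    r <- rec(node$kids[[2]])
    if (is.null(l) && is.null(r)) return(NULL)
    if (is.null(l) || is.null(r)) {
      kept <- if (is.null(l)) r else l
      kept$clen <- add_len(kept$clen, node$clen)
      kept$slen <- add_len(kept$slen, node$slen)
      return(kept)
    }
    new_inode(l, r, clen = node$clen, slen = node$slen)
  }
  root <- rec(tree$root)
  root$clen <- NA_real_
  root$slen <- NA_real_
  rooted_tree(root)
}

#' Cherries (2-clades) of a rooted tree
#'
#' @param tree a `ue_tree`.
#' @return a list of sorted character pairs, one per cherry; empty for a
#'   single leaf.
#' @export
two_clades <- function(tree) {
  out <- list()
  rec <- function(node) {
    if (is_leaf(node)) return(invisible())
    l <- node$kids[[1]]; r <- node$kids[[2]]
    if (is_leaf(l) && is_leaf(r)) out[[length(out) + 1L]] <<- sort(c(l$label, r$label))
    rec(l); rec(r)
  }
  rec(tree$root)
  out
}

#' Most recent common ancestor of two taxa
#'
#' @param tree a `ue_tree`.
#' @param a,b taxon labels (possibly equal, in which case the leaf itself is
#'   returned).
#' @return the subtree node rooted at the MRCA; its leaf labels are available
#'   via [mrca_clade()].
#' @export
mrca <- function(tree, a, b) {
  if (!all(c(a, b) %in% tree$taxa)) stop("unknown labels")
  rec <- function(node) {
    labs <- node_labels(node)
    if (!all(c(a, b) %in% labs)) return(NULL)
    if (is_leaf(node)) return(node)
    for (k in node$kids) {
      found <- rec(k)
      if (!is.null(found)) return(found)
    }
    node
  }
  rec(tree$root)
}

#' Leaf set of the MRCA of two taxa
#' @inheritParams mrca
#' @return sorted character vector of leaf labels descending from the MRCA.
#' @export
mrca_clade <- function(tree, a, b) sort(node_labels(mrca(tree, a, b)))

## Canonical string for an unrooted quartet split.
split_string <- function(pair1, pair2) {
  p1 <- sort(pair1); p2 <- sort(pair2)
  if (p1[1] > p2[1]) { tmp <- p1; p1 <- p2; p2 <- tmp }
  paste0(p1[1], p1[2], "|", p2[1], p2[2])
}

#' Unrooted quartets displayed by a rooted tree
#'
#' For each 4-subset of the taxa the induced (restricted) tree is computed and
#' its unrooted split read off its cherry structure.
#'
#' @param tree a `ue_tree` with at least 4 taxa.
#' @return a named character vector: names are the sorted 4-subsets joined by
#'   `","`, values canonical split strings like `"ab|cd"`.
#' @export
displayed_quartets <- function(tree) {
  tx <- sort(tree$taxa)
  if (length(tx) < 4) stop("fewer than 4 taxa")
  quads <- utils::combn(tx, 4, simplify = FALSE)
  out <- vapply(quads, function(q) {
    sub <- restrict_tree(tree, q)
    ch <- two_clades(sub)[[1]]  # every rooted binary 4-tree has a cherry
    split_string(ch, setdiff(q, ch))
  }, character(1))
  names(out) <- vapply(quads, paste, character(1), collapse = ",")
  out
}

#' Enumerate all rooted binary leaf-labelled trees
#'
#' Generates each of the `(2n-3)!!` rooted binary topologies on the given
#' labels exactly once, by leaf insertion on every edge (including the root
#' stem).
#'
#' @param labels distinct character labels, `1 <= n <= 8`.
#' @return a list of `ue_tree` objects (topological; no lengths).
#' @export
enumerate_rooted_binary <- function(labels) {
  n <- length(labels)
  if (n < 1 || n > 8) stop("n must be between 1 and 8")
  if (anyDuplicated(labels)) stop("labels must be distinct")
  grow <- function(node, lab) {
    ## all trees obtained by inserting `lab` on the edge above any node of
    ## `node`'s subtree (grafting at that edge), plus above the subtree root
    res <- list(new_inode(node, new_leaf(lab)))
    if (!is_leaf(node)) {
      for (sub in grow(node$kids[[1]], lab)) {
        res[[length(res) + 1L]] <- new_inode(sub, node$kids[[2]])
      }
      for (sub in grow(node$kids[[2]], lab)) {
        res[[length(res) + 1L]] <- new_inode(node$kids[[1]], sub)
      }
    }
    res
  }
  trees <- list(new_leaf(labels[1]))
  if (n > 1) {
    for (k in 2:n) {
      trees <- unlist(lapply(trees, grow, lab = labels[k]), recursive = FALSE)
    }
  }
  lapply(trees, rooted_tree)
}

## Unlabelled rooted binary tree shapes on n leaves, as nested structures with
## leaves marked by "x". Used by dimension_table: UE model dimension depends
## only on the shape.
tree_shapes <- function(n) {
  stopifnot(n >= 1)
  memo <- list()
  shape_str <- function(s) {
    if (identical(s, "x")) return("x")
    kids <- sort(vapply(s, shape_str, character(1)))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  rec <- function(m) {
    key <- as.character(m)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (m == 1) return(list("x"))
    out <- list()
    seen <- character(0)
    for (a in 1:(m %/% 2)) {
      for (sa in rec(a)) for (sb in rec(m - a)) {
        s <- list(sa, sb)
        k <- shape_str(s)
        if (!(k %in% seen)) { seen <- c(seen, k); out[[length(out) + 1L]] <- s }
      }
    }
    memo[[key]] <<- out
    out
  }
  rec(n)
}

## Turn a shape into a labelled representative tree on labels t1..tn
## (left-to-right assignment).
shape_to_tree <- function(shape) {
  counter <- 0L
  rec <- function(s) {
    if (identical(s, "x")) {
      counter <<- counter + 1L
      return(new_leaf(paste0("t", counter)))
    }
    new_inode(rec(s[[1]]), rec(s[[2]]))
  }
  rooted_tree(rec(shape))
}

#' Test ultrametricity of the coalescent edge lengths
#'
#' @param tree a `ue_tree` with coalescent lengths on all non-root edges.
#' @param tol tolerance on root-to-leaf sum differences.
#' @return `TRUE` if all root-to-leaf coalescent path lengths agree.
#' @export
is_ultrametric <- function(tree, tol = 1e-9) {
  depths <- c()
  rec <- function(node, acc) {
    len <- if (is.na(node$clen)) 0 else node$clen
    if (is_leaf(node)) {
      depths <<- c(depths, acc + len)
    } else {
      for (k in node$kids) rec(k, acc + len)
    }
  }
  rec(tree$root, 0)
  diff(range(depths)) <= tol
}

## Collect internal nodes of a tree in preorder; each entry records the leaf
## label sets of its two child subtrees.
internal_nodes <- function(tree) {
  out <- list()
  rec <- function(node) {
    if (is_leaf(node)) return(invisible())
    out[[length(out) + 1L]] <<- list(
      left  = node_labels(node$kids[[1]]),
      right = node_labels(node$kids[[2]])
    )
    rec(node$kids[[1]]); rec(node$kids[[2]])
  }
  rec(tree$root)
  out
}

#' Rescale the edge lengths of a tree
#'
#' Multiplies coalescent and/or substitution lengths by constant factors —
#' the usual way to set a mutation scale (substitution length per coalescent
#' unit) after parsing a tree given in coalescent units.
#' @param tree a `ue_tree`.
#' @param coal factor applied to `clen`.
#' @param sub factor applied to `slen`.
#' @return a `ue_tree`.
#' @export
scale_tree_lengths <- function(tree, coal = 1, sub = 1) {
  rec <- function(node) {
    if (!is.na(node$clen)) node$clen <- node$clen * coal
    if (!is.na(node$slen)) node$slen <- node$slen * sub
    if (!is_leaf(node)) node$kids <- lapply(node$kids, rec)
    node
  }
  tree$root <- rec(tree$root)
  tree
}
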