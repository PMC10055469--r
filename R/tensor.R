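## Site-pattern tensors: an n-way kappa x ... x kappa array of reals with one
## axis per taxon (axis i <-> taxa[i], states 0..kappa-1).

#' Construct a site-pattern tensor
#'
#' @param values numeric array with `length(taxa)` dimensions, each of extent
#'   `kappa`; a plain vector of length `kappa^n` is accepted and reshaped
#'   (first taxon slowest, i.e. pattern-lexicographic order).
#' @param taxa ordered character vector of taxon labels.
#' @param kappa number of states (`>= 2`).
#' @return An object of class `"spt"`: a list with `taxa`, `kappa`, `values`.
#' @export
spt <- function(values, taxa, kappa) {
  n <- length(taxa)
  stopifnot(kappa >= 2, n >= 1)
  if (n * log2(kappa) > 24) stop("tensor too large (guard: kappa^n <= 2^24)")
  if (is.null(dim(values))) {
    stopifnot(length(values) == kappa^n)
    values <- array(values, dim = rep(kappa, n))
    values <- aperm(values, n:1)  # flat input is pattern-lexicographic
  }
  stopifnot(length(dim(values)) == n, all(dim(values) == kappa))
  if (any(!is.finite(values))) stop("tensor entries must be finite")
  structure(list(taxa = taxa, kappa = kappa, values = values), class = "spt")
}

#' @export
print.spt <- function(x, ...) {
  cat(sprintf("Site-pattern tensor: %d taxa (%s), kappa = %d, mass = %.6g\n",
              length(x$taxa), paste(x$taxa, collapse = ","), x$kappa, sum(x$values)))
  invisible(x)
}

#' Uniform probability tensor
#' @inheritParams spt
#' @return an `spt` with all entries `kappa^-n`.
#' @export
spt_uniform <- function(taxa, kappa) {
  n <- length(taxa)
  spt(array(kappa^-n, dim = rep(kappa, n)), taxa, kappa)
}

axis_of <- function(P, taxon) {
  i <- match(taxon, P$taxa)
  if (is.na(i)) stop("unknown taxon: ", taxon)
  i
}

#' Flatten a tensor to the pattern-lexicographic vector
#'
#' Entry order matches [all_patterns()]: the first taxon's state is the most
#' significant index. This is the coordinate order used by the constraint
#' machinery and the pattern-count file format.
#' @param P an `spt`.
#' @return numeric vector of length `kappa^n`.
#' @export
spt_flat <- function(P) {
  n <- length(P$taxa)
  if (n == 1) return(as.vector(P$values))
  as.vector(aperm(P$values, n:1))
}

#' All site patterns in lexicographic order
#'
#' @param n number of taxa.
#' @param kappa number of states. For `kappa = 4` the DNA alphabet
#'   `A,G,C,T` (mapping to states 0..3 in that order) is used; otherwise the
#'   digits `0..kappa-1`.
#' @return character vector of `kappa^n` pattern strings.
#' @export
all_patterns <- function(n, kappa) {
  alph <- state_alphabet(kappa)
  g <- expand.grid(rev(replicate(n, alph, simplify = FALSE)),
                   stringsAsFactors = FALSE)
  do.call(paste0, rev(g))
}

state_alphabet <- function(kappa) {
  if (kappa == 4) c("A", "G", "C", "T") else as.character(0:(kappa - 1))
}

#' Marginalize a tensor to a taxon subset
#'
#' Sums over the removed axes; total mass is preserved and the result's taxon
#' order is the induced order.
#' @param P an `spt`.
#' @param keep nonempty character vector of taxa to retain.
#' @return an `spt` on `keep` (in induced order).
#' @export
marginalize <- function(P, keep) {
  if (length(keep) < 1) stop("keep must be nonempty")
  idx <- sort(vapply(keep, axis_of, integer(1), P = P))
  n <- length(P$taxa)
  if (length(idx) == n) return(P)
  v <- apply(P$values, idx, sum)
  if (is.null(dim(v))) v <- array(v, dim = P$kappa)
  spt(v, P$taxa[idx], P$kappa)
}

#' Slice a tensor at a fixed state of one taxon
#'
#' @param P an `spt` with at least 2 taxa.
#' @param taxon label of the axis to fix.
#' @param state integer state in `0..kappa-1`.
#' @return an `spt` on the remaining taxa (the conditional-up-to-normalization
#'   distribution given `taxon = state`).
#' @export
spt_slice <- function(P, taxon, state) {
  if (state < 0 || state >= P$kappa) stop("state out of range")
  k <- axis_of(P, taxon)
  n <- length(P$taxa)
  idx <- rep(list(quote(expr = )), n)
  idx[[k]] <- state + 1L
  v <- do.call(`[`, c(list(P$values), idx, list(drop = FALSE)))
  v <- array(v, dim = rep(P$kappa, n - 1))
  spt(v, P$taxa[-k], P$kappa)
}

#' Exchange two taxon indices of a tensor
#'
#' Returns the tensor with the `a`- and `b`-axes transposed (values permuted;
#' the taxon order itself is unchanged). Applying twice is the identity.
#' @param P an `spt`.
#' @param a,b distinct taxon labels.
#' @return an `spt`.
#' @export
exchange_indices <- function(P, a, b) {
  if (a == b) stop("a and b must differ")
  ia <- axis_of(P, a); ib <- axis_of(P, b)
  perm <- seq_along(P$taxa)
  perm[ia] <- ib; perm[ib] <- ia
  spt(aperm(P$values, perm), P$taxa, P$kappa)
}

#' Flatten a tensor according to a bipartition of (a subset of) its taxa
#'
#' The tensor is first marginalized to the union of the two sides. Row index
#' tuples run over `side_A` states lexicographically (first listed taxon most
#' significant); columns likewise for `side_B`.
#' @param P an `spt`.
#' @param side_A,side_B disjoint nonempty ordered character vectors of taxa.
#' @return a `kappa^|A| x kappa^|B|` numeric matrix.
#' @export
flatten_tensor <- function(P, side_A, side_B) {
  if (length(intersect(side_A, side_B))) stop("overlapping sides")
  if (!length(side_A) || !length(side_B)) stop("both sides must be nonempty")
  M <- marginalize(P, c(side_A, side_B))
  perm <- match(c(side_A, side_B), M$taxa)
  v <- aperm(M$values, perm)
  p <- length(side_A); q <- length(side_B)
  ## reverse within each side so that, column-major, the first listed taxon of
  ## each side is most significant -> lexicographic tuple order
  v <- aperm(v, c(p:1, (p + q):(p + 1)))
  dim(v) <- c(P$kappa^p, P$kappa^q)
  v
}

#' Act on each tensor index by a matrix (the `*` action)
#'
#' `(P *_k M)` replaces the mode-`k` fibers `v` of `P` by `v M`; this function
#' applies one matrix per taxon in order. For a 2-taxon tensor,
#' `star_action(P, list(M1, M2))` equals `t(M1) %*% P$values %*% M2`.
#' Markov matrices preserve total mass.
#'
#' @param P an `spt`.
#' @param mats list of `kappa x kappa` matrices, one per taxon (in `P$taxa`
#'   order), or a named list covering a subset of taxa; `NULL` entries mean
#'   identity.
#' @return an `spt`.
#' @export
star_action <- function(P, mats) {
  n <- length(P$taxa)
  if (!is.null(names(mats)) && any(nzchar(names(mats)))) {
    full <- rep(list(NULL), n)
    for (nm in names(mats)) full[[axis_of(P, nm)]] <- mats[[nm]]
    mats <- full
  }
  if (length(mats) != n) stop("need one matrix per taxon")
  v <- P$values
  kap <- P$kappa
  for (k in seq_len(n)) {
    M <- mats[[k]]
    if (is.null(M)) next
    if (!all(dim(M) == c(kap, kap))) stop("matrix ", k, " has wrong dimensions")
    perm <- c(k, seq_len(n)[-k])
    vk <- aperm(v, perm)
    dm <- dim(vk)
    dim(vk) <- c(kap, kap^(n - 1))
    vk <- crossprod(M, vk)          # t(M) %*% vk : out[i,] = sum_j v[j,] M[j,i]
    dim(vk) <- dm
    v <- aperm(vk, order(perm))
  }
  spt(v, P$taxa, P$kappa)
}

#' Empirical site-pattern frequencies from multinomial sampling
#'
#' Draws `s` iid sites from the probability tensor `P` and returns the
#' empirical frequency tensor (entries are multiples of `1/s`).
#' @param P a probability `spt` (nonnegative entries).
#' @param s number of sites (`>= 1`).
#' @param seed integer RNG seed.
#' @return an `spt` of empirical frequencies.
#' @export
multinomial_sample <- function(P, s, seed) {
  if (any(P$values < 0)) stop("negative entries in P")
  stopifnot(s >= 1)
  set.seed(seed)
  counts <- stats::rmultinom(1, size = s, prob = as.vector(P$values))
  spt(array(counts / s, dim = dim(P$values)), P$taxa, P$kappa)
}

#' Read site-pattern counts from TSV
#'
#' Format: a header line `#taxa: t1,t2,...,tn`, then rows
#' `pattern<TAB>count`. Patterns are strings of `n` state characters
#' (`A,G,C,T` for `kappa = 4`, digits otherwise). Unlisted patterns get count
#' 0.
#'
#' @param path file path.
#' @param taxa optional taxon order override (defaults to the header's).
#' @param kappa number of states; inferred from the pattern alphabet when
#'   `NULL`.
#' @return an `spt` of normalized frequencies, with attribute `"total"`
#'   holding the summed counts.
#' @export
read_pattern_counts <- function(path, taxa = NULL, kappa = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no patterns in ", path)
  hdr <- grep("^#taxa:", lines, value = TRUE)
  if (!length(hdr)) stop("missing '#taxa:' header in ", path)
  file_taxa <- trimws(strsplit(sub("^#taxa:", "", hdr[1]), ",")[[1]])
  if (is.null(taxa)) taxa <- file_taxa
  if (!setequal(taxa, file_taxa)) stop("taxa mismatch with header")
  rows <- lines[!grepl("^#", lines)]
  if (!length(rows)) stop("no patterns in ", path)
  parts <- strsplit(rows, "\t")
  pats <- vapply(parts, `[`, character(1), 1)
  cnts <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (any(is.na(cnts))) stop("malformed count")
  if (any(cnts < 0)) stop("negative count")
  n <- length(file_taxa)
  if (any(nchar(pats) != n)) stop("pattern length != number of taxa")
  if (is.null(kappa)) kappa <- if (any(grepl("[A-Za-z]", pats))) 4 else
    max(as.integer(unlist(strsplit(pats, "")))) + 1L
  alph <- state_alphabet(kappa)
  v <- numeric(kappa^n)
  names(v) <- all_patterns(n, kappa)
  chars <- strsplit(pats, "")
  bad <- vapply(chars, function(cc) any(!(cc %in% alph)), logical(1))
  if (any(bad)) stop("unknown state character in pattern: ", pats[which(bad)[1]])
  v[pats] <- v[pats] + cnts
  total <- sum(v)
  if (total <= 0) stop("no patterns (zero total count)")
  P <- spt(unname(v) / total, file_taxa, kappa)
  if (!identical(taxa, file_taxa)) {
    P <- spt(aperm(P$values, match(taxa, file_taxa)), taxa, kappa)
  }
  attr(P, "total") <- total
  P
}

#' Write site-pattern counts to TSV
#'
#' Inverse of [read_pattern_counts()]; only nonzero entries are written, at
#' full precision, so write-then-read round-trips counts exactly.
#' @param P an `spt`.
#' @param path file path.
#' @param total optional scale: entries are written as `value * total`
#'   (e.g. the site count for an empirical frequency tensor).
#' @return `path`, invisibly.
#' @export
write_pattern_counts <- function(P, path, total = 1) {
  v <- spt_flat(P) * total
  pats <- all_patterns(length(P$taxa), P$kappa)
  nz <- which(v != 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#taxa: ", paste(P$taxa, collapse = ",")), con)
  writeLines(sprintf("%s\t%.17g", pats[nz], v[nz]), con)
  invisible(path)
}
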