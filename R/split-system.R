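# Split algebra on 0/1 membership matrices.
#
# A tree is stored as an `stree`: its sorted leaf labels, a logical flag
# `rooted`, and an n x m 0/1 matrix whose columns are the nontrivial full
# splits in canonical form.  Conventions:
#   * rooted:   a column marks the members of a cluster (the split side that
#               does not contain the root) with 1.
#   * unrooted: the side containing the lexicographically smallest taxon of
#               the leaf set is marked 1, so column equality is bipartition
#               equality.
# All consensus / supertree machinery works on this representation; ape
# `phylo` objects are used at the I/O boundary only.

#' Construct a tree from its leaf set and split matrix
#'
#' Low-level constructor. `mat` columns are canonicalised, deduplicated,
#' filtered to nontrivial splits and sorted; pairwise compatibility is
#' checked so that the object always encodes a valid phylogenetic tree
#' (internal nodes of degree >= 3; polytomies allowed).
#'
#' @param taxa Character vector of leaf labels (need not be sorted).
#' @param mat 0/1 matrix with `length(taxa)` rows, one column per split
#'   (1 = cluster member when rooted, otherwise the side holding the
#'   alphabetically smallest taxon). `NULL` or zero columns give a star.
#' @param rooted Logical; cluster semantics when `TRUE`.
#' @param check Validate pairwise compatibility (default `TRUE`).
#' @return An object of class `stree`.
#' @export
stree <- function(taxa, mat = NULL, rooted = FALSE, check = TRUE) {
  if (length(taxa) < 1L) stop("a tree needs at least one leaf")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) {
    stop("duplicate leaf labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  ord <- order(taxa, method = "radix")
  taxa_sorted <- taxa[ord]
  n <- length(taxa)
  if (is.null(mat) || NCOL(mat) == 0L || n < 4L - rooted) {
    m <- matrix(0L, nrow = n, ncol = 0L, dimnames = list(taxa_sorted, NULL))
    t <- structure(list(taxa = taxa_sorted, mat = m, rooted = rooted),
                   class = "stree")
    return(t)
  }
  mat <- as.matrix(mat)
  if (nrow(mat) != n) stop("split matrix must have one row per taxon")
  storage.mode(mat) <- "integer"
  if (!all(mat %in% c(0L, 1L))) stop("split matrix entries must be 0/1")
  if (!is.null(rownames(mat))) {
    mat <- mat[match(taxa_sorted, rownames(mat)), , drop = FALSE]
  } else {
    mat <- mat[ord, , drop = FALSE]
  }
  dimnames(mat) <- list(taxa_sorted, NULL)
  mat <- canonicalize_cols(mat, rooted)
  mat <- mat[, nontrivial_cols(mat, rooted), drop = FALSE]
  mat <- dedupe_cols(mat)
  if (check && ncol(mat) > 1L && !splits_pairwise_compatible(mat, rooted)) {
    stop("splits are not pairwise compatible; they do not define a tree")
  }
  structure(list(taxa = taxa_sorted, mat = mat, rooted = rooted),
            class = "stree")
}

#' @export
print.stree <- function(x, ...) {
  cat(sprintf("%s tree: %d leaves, %d nontrivial split%s\n",
              if (x$rooted) "rooted" else "unrooted",
              length(x$taxa), ncol(x$mat), if (ncol(x$mat) == 1L) "" else "s"))
  cat(write_newick(x), "\n")
  invisible(x)
}

# canonical polarity: unrooted columns are flipped so row 1 (smallest taxon)
# carries 1; rooted columns are cluster indicators and stay as given.
canonicalize_cols <- function(mat, rooted) {
  if (!rooted && nrow(mat) > 0L && ncol(mat) > 0L) {
    flip <- mat[1L, ] == 0L
    if (any(flip)) mat[, flip] <- 1L - mat[, flip, drop = FALSE]
  }
  mat
}

# nontrivial: both sides >= 2; the rooted "other side" includes the root.
nontrivial_cols <- function(mat, rooted) {
  cs <- colSums(mat)
  n <- nrow(mat)
  if (rooted) cs >= 2L & cs <= n - 1L else cs >= 2L & cs <= n - 2L
}

split_keys <- function(mat) {
  if (ncol(mat) == 0L) return(character(0))
  unname(apply(mat, 2L, paste, collapse = ""))
}

dedupe_cols <- function(mat) {
  k <- split_keys(mat)
  keep <- !duplicated(k)
  mat <- mat[, keep, drop = FALSE]
  mat[, order(k[keep]), drop = FALSE]
}

# four-gametes / nesting test for two canonical columns over one universe
split_pair_compatible <- function(a, b, rooted) {
  if (rooted) {
    !(any(a & b) && any(a & !b) && any(!a & b))
  } else {
    !(any(a & b) && any(a & !b) && any(!a & b) && any(!a & !b))
  }
}

splits_pairwise_compatible <- function(mat, rooted) {
  m <- ncol(mat)
  if (m < 2L) return(TRUE)
  M <- mat
  W <- 1L - mat
  n11 <- crossprod(M)            # |A int B|
  n10 <- crossprod(M, W)         # |A \ B|
  n01 <- crossprod(W, M)
  bad <- n11 > 0 & n10 > 0 & n01 > 0
  if (!rooted) bad <- bad & crossprod(W) > 0
  diag(bad) <- FALSE
  !any(bad)
}

#' Extract the splits of a tree
#'
#' Returns the full splits displayed by `t` as a canonical 0/1 matrix over
#' its sorted leaf set. With `include_trivial = TRUE` the trivial splits are
#' appended: singleton sides and, for rooted trees, the full leaf-set
#' cluster (the split whose other side is the root alone) together with the
#' empty cluster.
#'
#' @param t An `stree`.
#' @param include_trivial Include trivial full splits (Spl0) as well.
#' @return Integer 0/1 matrix, one column per split, rows named by taxa.
#' @export
tree_splits <- function(t, include_trivial = FALSE) {
  stopifnot(inherits(t, "stree"))
  if (!include_trivial) return(t$mat)
  n <- length(t$taxa)
  singles <- diag(1L, n)
  rownames(singles) <- t$taxa
  extra <- if (t$rooted) {
    cbind(singles, matrix(1L, n, 1L), matrix(0L, n, 1L))
  } else {
    # canonical form of a singleton side {x}, x != taxa[1], is its complement
    cbind(canonicalize_cols(singles, FALSE), matrix(1L, n, 1L))
  }
  rownames(extra) <- t$taxa
  dedupe_cols(cbind(t$mat, extra))
}

#' Restrict a tree to a subset of its leaves
#'
#' The result displays exactly the restrictions of `t`'s splits to `s`,
#' with degenerate and trivial splits suppressed.
#'
#' @param t An `stree`.
#' @param s Character vector of retained leaves, a subset of `t$taxa`.
#' @return An `stree` on `s`.
#' @export
restrict_tree <- function(t, s) {
  stopifnot(inherits(t, "stree"))
  s <- as.character(s)
  if (!all(s %in% t$taxa)) {
    stop("not leaves of the tree: ",
         paste(setdiff(s, t$taxa), collapse = ", "))
  }
  if (length(s) < 1L) stop("restriction to an empty leaf set")
  sub <- t$mat[match(sort_taxa(s), t$taxa), , drop = FALSE]
  stree(sort_taxa(s), sub, rooted = t$rooted, check = FALSE)
}

#' Does a tree display a split?
#'
#' `sides` is a two-element list of disjoint taxon sets whose union is a
#' subset of the tree's leaves. The split is displayed if some edge removal
#' separates the two sides, i.e. if it occurs among the full splits of the
#' restriction to its own support.
#'
#' @param t An `stree`.
#' @param sides List of two character vectors (for rooted trees the first
#'   element is read as the cluster side).
#' @return Logical.
#' @export
displays_split <- function(t, sides) {
  stopifnot(inherits(t, "stree"), is.list(sides), length(sides) == 2L)
  a <- as.character(sides[[1L]]); b <- as.character(sides[[2L]])
  if (length(intersect(a, b)) > 0L) stop("split sides must be disjoint")
  supp <- c(a, b)
  if (!all(supp %in% t$taxa)) stop("split support exceeds the leaf set")
  r <- restrict_tree(t, supp)
  v <- integer(length(r$taxa))
  v[match(a, r$taxa)] <- 1L
  col <- matrix(v, ncol = 1L)
  if (!t$rooted) col <- canonicalize_cols(col, FALSE)
  key <- paste(col[, 1L], collapse = "")
  key %in% split_keys(tree_splits(r, include_trivial = TRUE))
}

#' Does one tree display another?
#'
#' `t` displays `t2` when every nontrivial split of `t2` is a split of the
#' restriction of `t` to `t2`'s leaves.
#'
#' @param t,t2 `stree` objects with `t2$taxa` a subset of `t$taxa` and a
#'   shared rootedness flag.
#' @return Logical.
#' @export
displays_tree <- function(t, t2) {
  stopifnot(inherits(t, "stree"), inherits(t2, "stree"))
  if (t$rooted != t2$rooted) stop("trees differ in rootedness")
  if (!all(t2$taxa %in% t$taxa)) stop("leaf set of t2 is not a subset")
  r <- restrict_tree(t, t2$taxa)
  all(split_keys(t2$mat) %in% split_keys(r$mat))
}

#' Compatibility of a set of full splits
#'
#' For full splits over one universe, set compatibility is equivalent to
#' pairwise compatibility; the pairwise test is the four-gametes condition
#' (a pair is incompatible exactly when row patterns 00, 01, 10 and 11 all
#' occur; rooted clusters carry an implicit root row supplying 11).
#'
#' @param mat Canonical 0/1 split matrix (columns = splits, one universe).
#' @param rooted Cluster semantics when `TRUE`.
#' @return Logical.
#' @export
splits_compatible <- function(mat, rooted = FALSE) {
  if (is.list(mat)) stop("pad partial splits to one universe first")
  splits_pairwise_compatible(as.matrix(mat), rooted)
}

#' Is a full split compatible with a tree?
#'
#' True when some tree on the same leaf set displays both `t` and the split,
#' i.e. when the split passes the pairwise test against every split of `t`.
#'
#' @param x 0/1 vector over `t$taxa` in canonical orientation.
#' @param t An `stree` whose leaf set is the split's universe.
#' @return Logical.
#' @export
split_compatible_with_tree <- function(x, t) {
  stopifnot(inherits(t, "stree"), length(x) == length(t$taxa))
  x <- as.integer(x)
  if (ncol(t$mat) == 0L) return(TRUE)
  all(vapply(seq_len(ncol(t$mat)), function(j) {
    split_pair_compatible(x, t$mat[, j], t$rooted)
  }, logical(1L)))
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of nontrivial full splits between two trees on
#' the same leaf set: `|Spl(t1) \\ Spl(t2)| + |Spl(t2) \\ Spl(t1)|`.
#'
#' @param t1,t2 `stree` objects with identical leaf sets and rootedness.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "stree"), inherits(t2, "stree"))
  if (!identical(t1$taxa, t2$taxa)) stop("leaf sets differ")
  if (t1$rooted != t2$rooted) stop("trees differ in rootedness")
  k1 <- split_keys(t1$mat)
  k2 <- split_keys(t2$mat)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Build the unique tree displaying a compatible split set
#'
#' @param mat Canonical 0/1 matrix of pairwise-compatible plenary splits
#'   over `taxa` (may have zero columns: the star tree).
#' @param taxa Leaf labels.
#' @param rooted Logical.
#' @return An `stree` whose nontrivial split set equals the nontrivial
#'   columns of `mat`.
#' @export
tree_from_splits <- function(mat, taxa, rooted = FALSE) {
  t <- stree(taxa, mat, rooted = rooted, check = TRUE)
  t
}

# keyed membership columns as taxon-name list (used by reduction & reports)
col_taxa <- function(t, j) t$taxa[t$mat[, j] == 1L]

# byte-wise (locale-independent) label ordering, used everywhere a taxon
# order or a canonical "smallest taxon" is needed
sort_taxa <- function(x) sort(x, method = "radix")
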