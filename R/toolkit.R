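# Support/conflict evaluation of a supertree against its input trees,
# property audits, and the synthetic-profile generator used throughout the
# test-suite and examples.

#' Support, conflict, or irrelevance of an input tree for a supertree cluster
#'
#' Rooted setting. With `S' = cluster` intersected with the input tree's
#' leaves: the tree *supports* the cluster when `S'` is a nontrivial
#' cluster of the tree; it is *in conflict* when the split
#' `S' | (leaves \\ S')` is incompatible with the tree (no tree on those
#' leaves displays both); otherwise it is *irrelevant* (in particular
#' whenever `|S'| <= 1`).
#'
#' @param t A rooted `stree` (an input tree).
#' @param cluster Character vector of taxa (a nontrivial supertree cluster).
#' @return `"support"`, `"conflict"`, or `"irrelevant"`.
#' @export
support_conflict <- function(t, cluster) {
  stopifnot(inherits(t, "stree"))
  if (!t$rooted) stop("support/conflict is defined for rooted trees")
  sp <- intersect(cluster, t$taxa)
  if (length(sp) <= 1L || length(sp) >= length(t$taxa)) return("irrelevant")
  v <- as.integer(t$taxa %in% sp)
  key <- paste(v, collapse = "")
  if (key %in% split_keys(t$mat)) return("support")
  if (!split_compatible_with_tree(v, t)) return("conflict")
  "irrelevant"
}

#' Support/conflict report for a supertree
#'
#' @param p A rooted `tree_profile`.
#' @param supertree An `stree` on the profile's leaf set.
#' @return A data frame with one row per (input tree, nontrivial supertree
#'   cluster) pair, the label, and per-cluster support/conflict/irrelevant
#'   marginals as an attribute `"marginals"`.
#' @export
support_report <- function(p, supertree) {
  stopifnot(inherits(p, "tree_profile"), inherits(supertree, "stree"))
  if (!p$rooted) stop("support/conflict is defined for rooted profiles")
  m <- ncol(supertree$mat)
  rows <- expand.grid(tree = seq_along(p$trees), cluster = seq_len(m))
  rows$cluster_taxa <- vapply(rows$cluster, function(s)
    paste(col_taxa(supertree, s), collapse = ","), character(1L))
  rows$label <- vapply(seq_len(nrow(rows)), function(i)
    support_conflict(p$trees[[rows$tree[i]]],
                     col_taxa(supertree, rows$cluster[i])), character(1L))
  marg <- do.call(rbind, lapply(seq_len(m), function(s) {
    lab <- rows$label[rows$cluster == s]
    data.frame(cluster = paste(col_taxa(supertree, s), collapse = ","),
               support = sum(lab == "support"),
               conflict = sum(lab == "conflict"),
               irrelevant = sum(lab == "irrelevant"))
  }))
  attr(rows, "marginals") <- marg
  rows
}

# is plenary split x (canonical 0/1 over p$taxa) compatible with input tree t?
plenary_split_compatible_with_input <- function(x, t, taxa) {
  idx <- match(t$taxa, taxa)
  sub <- as.integer(x[idx])
  # restriction degenerate -> compatible with anything
  if (min(sum(sub), sum(1L - sub)) < 2L - t$rooted) return(TRUE)
  if (!t$rooted) sub <- canonicalize_cols(matrix(sub, ncol = 1L), FALSE)[, 1L]
  split_compatible_with_tree(sub, t)
}

# does input tree t display the restriction of plenary split x nontrivially?
plenary_split_in_input <- function(x, t, taxa) {
  idx <- match(t$taxa, taxa)
  sub <- as.integer(x[idx])
  if (!t$rooted) sub <- canonicalize_cols(matrix(sub, ncol = 1L), FALSE)[, 1L]
  paste(sub, collapse = "") %in% split_keys(t$mat)
}

#' Audit the Cotton-Wilkinson display properties of a supertree
#'
#' Checks the four guarantees of the majority-rule (+) method on a
#' produced supertree:
#' * `cw1` it displays every majority plenary split (plenary splits
#'    displayed by more than half of the input trees);
#' * `cw2` it is compatible with every majority partial split (input tree
#'    full splits displayed, as partial splits, by more than half of the
#'    trees);
#' * `cw3` each of its splits is compatible with a majority of the input
#'    trees;
#' * `cw4` each of its plenary splits extends at least one input tree's
#'    nontrivial full split.
#'
#' @param p A `tree_profile`.
#' @param supertree An `stree` on the profile's leaf set.
#' @return Named logical vector `c(cw1, cw2, cw3, cw4)`.
#' @export
cw_audit <- function(p, supertree) {
  stopifnot(inherits(p, "tree_profile"), inherits(supertree, "stree"))
  taxa <- p$taxa
  k <- length(p$trees)
  sup_keys <- split_keys(supertree$mat)

  # cw1: plenary splits can only be displayed by plenary input trees
  plen <- Filter(function(t) identical(t$taxa, taxa), p$trees)
  cw1 <- TRUE
  if (length(plen) > 0L) {
    U <- union_split_mat(plen)
    for (i in seq_len(ncol(U))) {
      key <- split_keys(U)[i]
      ndisp <- sum(vapply(plen, function(t) key %in% split_keys(t$mat),
                          logical(1L)))
      if (ndisp > k / 2 && !(key %in% sup_keys)) cw1 <- FALSE
    }
  }

  # cw2: majority partial splits, candidates = input tree full splits
  cw2 <- TRUE
  cand <- list()
  for (t in p$trees) for (j in seq_len(ncol(t$mat))) {
    cand <- c(cand, list(list(taxa = t$taxa, col = t$mat[, j],
                              rooted = t$rooted)))
  }
  for (cd in cand) {
    ndisp <- sum(vapply(p$trees, function(t) {
      if (!all(cd$taxa %in% t$taxa)) return(FALSE)
      a <- cd$taxa[cd$col == 1L]; bb <- cd$taxa[cd$col == 0L]
      displays_split(t, list(a, bb))
    }, logical(1L)))
    if (ndisp > k / 2) {
      # supertree must be compatible with the partial split: test against
      # the restriction of the supertree to the split's support
      r <- restrict_tree(supertree, cd$taxa)
      v <- as.integer(r$taxa %in% cd$taxa[cd$col == 1L])
      if (min(sum(v), sum(1L - v)) >= 2L - r$rooted) {
        if (!r$rooted) v <- canonicalize_cols(matrix(v, ncol = 1L), FALSE)[, 1L]
        if (!split_compatible_with_tree(v, r)) cw2 <- FALSE
      }
    }
  }

  # cw3: each supertree split compatible with a majority of input trees
  cw3 <- all(vapply(seq_len(ncol(supertree$mat)), function(s) {
    x <- supertree$mat[, s]
    sum(vapply(p$trees, plenary_split_compatible_with_input, logical(1L),
               x = x, taxa = taxa)) > k / 2
  }, logical(1L)))

  # cw4: each supertree split extends some input nontrivial full split
  cw4 <- all(vapply(seq_len(ncol(supertree$mat)), function(s) {
    x <- supertree$mat[, s]
    any(vapply(p$trees, plenary_split_in_input, logical(1L),
               x = x, taxa = taxa))
  }, logical(1L)))

  c(cw1 = cw1, cw2 = cw2, cw3 = cw3, cw4 = cw4)
}

# ---- synthetic profiles ----------------------------------------------

random_binary_tree <- function(taxa, rooted) {
  split_rec <- function(set) {
    if (length(set) == 1L) return(list())
    if (length(set) == 2L) return(list(set[1L], set[2L]))
    cut <- sample(seq_len(length(set) - 1L), 1L)
    perm <- sample(set)
    a <- sort_taxa(perm[seq_len(cut)]); b <- sort_taxa(perm[-seq_len(cut)])
    c(list(a, b), split_rec(a), split_rec(b))
  }
  clusters <- Filter(function(cl) length(cl) >= 2L, split_rec(sort_taxa(taxa)))
  n <- length(taxa)
  mat <- vapply(clusters, function(cl) as.integer(sort_taxa(taxa) %in% cl),
                integer(n))
  mat <- matrix(mat, nrow = n, dimnames = list(sort_taxa(taxa), NULL))
  stree(sort_taxa(taxa), mat, rooted = rooted, check = FALSE)
}

# replace one random split of t by a random alternative compatible with the
# remaining splits (keeps the tree valid; used to inject conflict)
perturb_tree <- function(t) {
  m <- ncol(t$mat)
  if (m == 0L) return(t)
  drop <- sample.int(m, 1L)
  rest <- t$mat[, -drop, drop = FALSE]
  keys <- split_keys(t$mat)
  for (try in 1:25) {
    alt <- random_binary_tree(t$taxa, t$rooted)
    pool <- alt$mat[, sample.int(ncol(alt$mat)), drop = FALSE]
    for (j in seq_len(ncol(pool))) {
      x <- pool[, j]
      key <- paste(x, collapse = "")
      if (key %in% keys) next
      ok <- all(vapply(seq_len(ncol(rest)), function(i)
        split_pair_compatible(x, rest[, i], t$rooted), logical(1L)))
      if (ok) {
        return(stree(t$taxa, cbind(rest, x), rooted = t$rooted, check = FALSE))
      }
    }
  }
  t
}

#' Generate a synthetic profile from a random model tree
#'
#' Draws a random binary model tree on `n_taxa` leaves, then derives each
#' input tree by (i) keeping each leaf independently with probability
#' `1 - deletion_probability` (topped up at random to the structural floor
#' of 3 leaves rooted / 4 unrooted), (ii) restricting the model tree to the
#' kept leaves, (iii) contracting each nontrivial split independently with
#' probability `contraction_probability`, and (iv) applying
#' `perturbation_count` random split replacements (each swaps one split
#' for a random alternative compatible with the remainder). With all three
#' distortion knobs at zero the profile is a set of exact restrictions of
#' one tree, so the optimal adjusted score is zero. Fully deterministic
#' given `seed`.
#'
#' @param n_taxa Number of taxa in the union leaf set (>= 4).
#' @param k_trees Number of input trees (>= 1).
#' @param deletion_probability Per-leaf deletion probability in `[0, 1)`.
#' @param contraction_probability Per-split contraction probability.
#' @param perturbation_count Split replacements per tree (integer).
#' @param rooted Rootedness of the profile.
#' @param seed Integer seed; fully determines the output.
#' @return List with `profile` (a `tree_profile`) and `model_tree`.
#' @export
generate_profile <- function(n_taxa, k_trees,
                             deletion_probability = 0.2,
                             contraction_probability = 0,
                             perturbation_count = 0,
                             rooted = TRUE, seed = 1L) {
  stopifnot(n_taxa >= 4L, k_trees >= 1L,
            deletion_probability >= 0, deletion_probability < 1)
  floor_n <- if (rooted) 3L else 4L
  if (n_taxa < floor_n) stop("n_taxa below the structural floor")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  model <- random_binary_tree(taxa, rooted)
  trees <- vector("list", k_trees)
  for (j in seq_len(k_trees)) {
    keep <- taxa[stats::runif(n_taxa) >= deletion_probability]
    if (length(keep) < floor_n) {
      keep <- sort_taxa(c(keep, sample(setdiff(taxa, keep),
                                  floor_n - length(keep))))
    }
    tj <- restrict_tree(model, keep)
    if (contraction_probability > 0 && ncol(tj$mat) > 0L) {
      keep_cols <- stats::runif(ncol(tj$mat)) >= contraction_probability
      tj <- stree(tj$taxa, tj$mat[, keep_cols, drop = FALSE],
                  rooted = rooted, check = FALSE)
    }
    if (perturbation_count > 0) {
      for (i in seq_len(perturbation_count)) tj <- perturb_tree(tj)
    }
    trees[[j]] <- tj
  }
  list(profile = tree_profile(trees, rooted = rooted), model_tree = model)
}
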