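# Consensus machinery for profiles of plenary trees (equal leaf sets):
# strict and majority-rule consensus, median score, split tallies, the
# polynomial-time majority-rule (+) consensus, completion of a
# representative selection, and its adjusted Robinson-Foulds score.

check_equal_leaves <- function(trees) {
  taxa <- trees[[1L]]$taxa
  for (t in trees) {
    if (!identical(t$taxa, taxa)) stop("trees must share one leaf set")
  }
  taxa
}

as_tree_list <- function(p) {
  if (inherits(p, "tree_profile")) p$trees
  else if (inherits(p, "stree")) list(p)
  else p
}

#' Strict consensus
#'
#' The tree displaying exactly the plenary splits present in every tree.
#'
#' @param trees List of `stree`s (or a `tree_profile`) on one leaf set.
#' @return An `stree`.
#' @export
strict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  taxa <- check_equal_leaves(trees)
  keys <- Reduce(intersect, lapply(trees, function(t) split_keys(t$mat)))
  keep <- split_keys(trees[[1L]]$mat) %in% keys
  stree(taxa, trees[[1L]]$mat[, keep, drop = FALSE],
        rooted = trees[[1L]]$rooted, check = FALSE)
}

#' Majority-rule consensus
#'
#' The tree of all plenary splits displayed by more than half of the trees
#' (strict majority, also for even tree counts). Majority splits are always
#' mutually compatible, so the tree exists and is unique.
#'
#' @param p A `tree_profile` (or list of `stree`s) with equal leaf sets.
#' @return An `stree`.
#' @export
majority_consensus <- function(p) {
  trees <- as_tree_list(p)
  taxa <- check_equal_leaves(trees)
  k <- length(trees)
  all_keys <- unlist(lapply(trees, function(t) split_keys(t$mat)))
  tab <- table(all_keys)
  maj <- names(tab)[tab > k / 2]
  mat <- keyed_mat(trees, maj)
  stree(taxa, mat, rooted = trees[[1L]]$rooted, check = FALSE)
}

# collect the named split columns (by key) from wherever they occur
keyed_mat <- function(trees, keys) {
  if (length(keys) == 0L) return(NULL)
  pool <- do.call(cbind, lapply(trees, `[[`, "mat"))
  pool <- pool[, match(keys, split_keys(pool)), drop = FALSE]
  pool
}

#' Total Robinson-Foulds distance from a tree to a profile
#'
#' @param t An `stree` on the profile's leaf set.
#' @param p A `tree_profile` (equal leaf sets).
#' @return `sum_i d(t, T_i)`.
#' @export
profile_distance <- function(t, p) {
  trees <- as_tree_list(p)
  check_equal_leaves(c(list(t), trees))
  sum(vapply(trees, rf_distance, integer(1L), t1 = t))
}

#' Median score of a consensus profile
#'
#' The minimum total Robinson-Foulds distance from any tree on the shared
#' leaf set to the profile, attained by the majority-rule consensus (a
#' median tree).
#'
#' @param p A `tree_profile` with equal leaf sets.
#' @return Integer.
#' @export
median_score <- function(p) {
  profile_distance(majority_consensus(p), p)
}

#' Tally a plenary split against a profile
#'
#' Counts the trees displaying the split (`n_display`) and the trees
#' incompatible with it (`n_incompatible`); the remainder of the profile is
#' irrelevant to the split. A displaying tree is never counted as
#' incompatible.
#'
#' @param x Canonical 0/1 vector over the shared leaf set.
#' @param p A `tree_profile` of plenary trees.
#' @return List with `n_display`, `n_incompatible`, `n_irrelevant`, `k`.
#' @export
tally_split <- function(x, p) {
  trees <- as_tree_list(p)
  check_equal_leaves(trees)
  x <- as.integer(x)
  key <- paste(x, collapse = "")
  disp <- vapply(trees, function(t) key %in% split_keys(t$mat), logical(1L))
  comp <- vapply(trees, function(t) split_compatible_with_tree(x, t),
                 logical(1L))
  nd <- sum(disp)
  ni <- sum(!comp)
  stopifnot(all(!(disp & !comp)))   # displayed implies compatible
  list(n_display = nd, n_incompatible = ni,
       n_irrelevant = length(trees) - nd - ni, k = length(trees))
}

# distinct split columns occurring anywhere in a list of plenary trees
union_split_mat <- function(trees) {
  pool <- do.call(cbind, lapply(trees, `[[`, "mat"))
  if (is.null(pool) || ncol(pool) == 0L) {
    return(matrix(0L, length(trees[[1L]]$taxa), 0L,
                  dimnames = list(trees[[1L]]$taxa, NULL)))
  }
  dedupe_cols(pool)
}

# per distinct split X: n_display and n_incompatible over the trees
tally_all <- function(trees) {
  U <- union_split_mat(trees)
  m <- ncol(U)
  keysets <- lapply(trees, function(t) split_keys(t$mat))
  keys <- split_keys(U)
  nd <- ni <- integer(m)
  for (i in seq_len(m)) {
    nd[i] <- sum(vapply(keysets, function(ks) keys[i] %in% ks, logical(1L)))
    ni[i] <- sum(vapply(trees, function(t)
      !split_compatible_with_tree(U[, i], t), logical(1L)))
  }
  list(mat = U, keys = keys, n_display = nd, n_incompatible = ni)
}

#' Majority-rule (+) consensus of a profile of plenary trees
#'
#' The tree displaying exactly the plenary splits X whose displaying trees
#' outnumber the trees incompatible with X (ties excluded). Candidate
#' splits are drawn from the union of the input split sets: a split
#' displayed by no tree can never qualify. The result is an optimal
#' candidate tree for the profile and the strict consensus of all optimal
#' candidate trees.
#'
#' @param p A `tree_profile` (or list of `stree`s) with equal leaf sets.
#' @return An `stree`.
#' @export
majority_plus_consensus <- function(p) {
  trees <- as_tree_list(p)
  taxa <- check_equal_leaves(trees)
  tl <- tally_all(trees)
  keep <- tl$n_display > tl$n_incompatible
  mat <- tl$mat[, keep, drop = FALSE]
  if (ncol(mat) > 1L && !splits_pairwise_compatible(mat, trees[[1L]]$rooted)) {
    stop("internal error: winning splits are not mutually compatible")
  }
  stree(taxa, mat, rooted = trees[[1L]]$rooted, check = FALSE)
}

#' Completion of a representative selection
#'
#' Inserts into each tree every plenary split X (from the union of splits
#' over the selection) that is compatible with that tree and whose
#' displaying trees outnumber its incompatible trees. Idempotent; only adds
#' splits.
#'
#' @param r List of plenary `stree`s (a representative selection) or a
#'   `tree_profile`.
#' @return List of completed `stree`s, same length and order.
#' @export
completion <- function(r) {
  trees <- as_tree_list(r)
  taxa <- check_equal_leaves(trees)
  tl <- tally_all(trees)
  win <- which(tl$n_display > tl$n_incompatible)
  lapply(trees, function(t) {
    add <- Filter(function(i) split_compatible_with_tree(tl$mat[, i], t), win)
    if (length(add) == 0L) return(t)
    stree(taxa, cbind(t$mat, tl$mat[, add, drop = FALSE]),
          rooted = t$rooted, check = TRUE)
  })
}

#' Adjusted score of a representative selection
#'
#' Counts, over the distinct plenary splits X occurring in the selection,
#' the number of incompatible trees when X wins its tally (display count
#' strictly above incompatible count) and the number of displaying trees
#' otherwise. This equals the total Robinson-Foulds distance from the
#' majority-rule (+) consensus of the selection to its completion; both
#' quantities are computed and cross-checked on every call.
#'
#' @param r List of plenary `stree`s or a `tree_profile`.
#' @return Non-negative integer.
#' @export
adjusted_score <- function(r) {
  trees <- as_tree_list(r)
  check_equal_leaves(trees)
  tl <- tally_all(trees)
  win <- tl$n_display > tl$n_incompatible
  s <- sum(ifelse(win, tl$n_incompatible, tl$n_display))
  # independent route: distance from the consensus to the completion
  target <- majority_plus_consensus(trees)
  comp <- completion(trees)
  s2 <- sum(vapply(comp, rf_distance, integer(1L), t1 = target))
  if (s != s2) {
    stop(sprintf("internal error: adjusted score mismatch (%d vs %d)", s, s2))
  }
  as.integer(s)
}
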