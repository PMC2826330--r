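# Reducible-set data reduction: when a taxon set S is separated from the
# rest by a full split (trivial ones included) in every input tree, the
# problem splits into a reduced profile (S contracted to a supertaxon) and
# a satellite profile (everything outside S contracted to an attachment
# leaf). The subproblems are solved independently and spliced; the result
# is the S-restricted majority-rule (+) supertree, which need not equal
# the unrestricted one.

#' Is a taxon set reducible in a profile?
#'
#' `s` is reducible when every input tree has a full split (trivial splits
#' and the whole-leaf-set split count) one side of which is exactly
#' `s` intersected with that tree's leaves. Trees meeting `s` in zero or
#' one leaf, or entirely contained in it, are separated trivially.
#'
#' @param s Character vector of taxa with `1 < |s| < |L(P)| - 1`.
#' @param p A `tree_profile`.
#' @return Logical; when `TRUE`, carries a `"witnesses"` attribute listing
#'   the separating side per tree.
#' @export
is_reducible <- function(s, p) {
  stopifnot(inherits(p, "tree_profile"))
  s <- unique(as.character(s))
  nl <- length(p$taxa)
  if (!(length(s) > 1L && length(s) < nl - 1L)) {
    stop("reducible-set size must satisfy 1 < |s| < |taxa| - 1")
  }
  if (!all(s %in% p$taxa)) stop("unknown taxa in candidate set")
  wit <- vector("list", length(p$trees))
  for (j in seq_along(p$trees)) {
    t <- p$trees[[j]]
    inter <- intersect(s, t$taxa)
    v <- as.integer(t$taxa %in% inter)
    full <- tree_splits(t, include_trivial = TRUE)
    keys0 <- split_keys(full)
    key_i <- paste(v, collapse = "")
    key_c <- paste(1L - v, collapse = "")
    hit <- if (t$rooted) {
      key_i %in% keys0 || key_c %in% keys0
    } else {
      paste(canonicalize_cols(matrix(v, ncol = 1L), FALSE)[, 1L],
            collapse = "") %in% keys0
    }
    if (!hit) return(FALSE)
    wit[[j]] <- inter
  }
  structure(TRUE, witnesses = wit)
}

#' Find pairwise-disjoint reducible sets greedily
#'
#' Candidate sets are the nontrivial clusters of the input trees, visited
#' in order of decreasing size (ties broken by sorted taxon labels). A
#' candidate is accepted when it respects the size bounds, is disjoint
#' from every previously accepted set, and [is_reducible()] holds.
#' User-supplied sets (e.g. named clades) are validated the same way,
#' before the greedy scan.
#'
#' @param p A rooted `tree_profile` (the candidate pool is cluster-based).
#' @param user_sets Optional list of character vectors to try first.
#' @return List of character vectors (possibly empty).
#' @export
find_reducible_sets <- function(p, user_sets = NULL) {
  stopifnot(inherits(p, "tree_profile"))
  if (!p$rooted) stop("reducible-set search uses clusters; profile must be rooted")
  nl <- length(p$taxa)
  accepted <- list()
  consider <- function(s) {
    s <- sort_taxa(unique(as.character(s)))
    if (!(length(s) > 1L && length(s) < nl - 1L)) return(FALSE)
    if (any(vapply(accepted, function(a) length(intersect(a, s)) > 0L,
                   logical(1L)))) return(FALSE)
    if (!isTRUE(is_reducible(s, p))) return(FALSE)
    accepted[[length(accepted) + 1L]] <<- s
    TRUE
  }
  for (s in user_sets) {
    if (!consider(s)) {
      stop("user-supplied set is not an acceptable reducible set: ",
           paste(s, collapse = ","))
    }
  }
  cand <- list()
  for (t in p$trees) {
    for (j in seq_len(ncol(t$mat))) cand <- c(cand, list(sort_taxa(col_taxa(t, j))))
  }
  cand <- unique(cand)
  if (length(cand)) {
    keys <- vapply(cand, paste, character(1L), collapse = ",")
    ord <- order(-lengths(cand), keys, method = "radix")
    for (s in cand[ord]) consider(s)
  }
  accepted
}

fresh_label <- function(base, taxa) {
  lab <- base
  while (lab %in% taxa) lab <- paste0(lab, "_")
  lab
}

# contract the minimal subtree of `t` spanning the leaves `inside` to the
# single leaf `label`; returns NULL when fewer than 2 leaves remain.
# An edge survives the contraction exactly when `inside` lies entirely on
# one of its sides (otherwise the edge is interior to the spanning subtree
# and disappears). Works for rooted and unrooted trees alike.
contract_side <- function(t, inside, label) {
  outside <- setdiff(t$taxa, inside)
  new_taxa <- c(outside, label)
  if (length(new_taxa) < 2L) return(NULL)
  cols <- list()
  for (j in seq_len(ncol(t$mat))) {
    side1 <- col_taxa(t, j)
    in1 <- intersect(side1, inside)
    if (length(in1) > 0L && length(in1) < length(inside)) next  # interior edge
    members <- if (length(in1) == length(inside)) {
      c(setdiff(side1, inside), label)     # contracted clade keeps the label
    } else {
      side1                                # label lands on the other side
    }
    cols <- c(cols, list(as.integer(sort_taxa(new_taxa) %in% members)))
  }
  mat <- if (length(cols)) matrix(unlist(cols), ncol = length(cols)) else NULL
  if (!is.null(mat)) rownames(mat) <- sort_taxa(new_taxa)
  stree(new_taxa, mat, rooted = t$rooted, check = FALSE)
}

#' Reduced profile: contract a reducible set to a supertaxon
#'
#' Each tree's minimal subtree spanning its share of `s` is contracted to
#' the supertaxon leaf; trees disjoint from `s` are unchanged, and trees
#' left with fewer than two leaves are dropped.
#'
#' @param p A `tree_profile`; `s` must be reducible in it.
#' @param s Character vector (a reducible set).
#' @param supertaxon Label for the contracted clade (default
#'   `"BETA_<first taxon>"`, uniquified against the leaf set).
#' @param validate Re-check reducibility (disable when the caller already
#'   validated `s` against an ancestor profile, as the pipeline does when
#'   contracting several disjoint sets in sequence).
#' @return A `tree_profile`; the supertaxon label is attached as
#'   `attr(, "supertaxon")`.
#' @export
reduce_profile <- function(p, s, supertaxon = NULL, validate = TRUE) {
  if (validate && !isTRUE(is_reducible(s, p))) {
    stop("set is not reducible in this profile")
  }
  s <- sort_taxa(unique(as.character(s)))
  if (is.null(supertaxon)) supertaxon <- fresh_label(paste0("BETA_", s[1L]),
                                                     p$taxa)
  if (supertaxon %in% p$taxa) stop("supertaxon label collides with a taxon")
  out <- list()
  for (t in p$trees) {
    inter <- intersect(s, t$taxa)
    if (length(inter) == 0L) { out <- c(out, list(t)); next }
    rt <- contract_side(t, inter, supertaxon)
    if (!is.null(rt)) out <- c(out, list(rt))
  }
  if (length(out) == 0L) stop("reduction left no usable trees")
  structure(tree_profile(out, rooted = p$rooted), supertaxon = supertaxon)
}

#' Satellite profile: restrict a profile to a reducible set
#'
#' Everything outside `s` in each tree is contracted to the attachment
#' leaf; trees entirely inside `s` are kept as they are.
#'
#' @param p A `tree_profile`; `s` must be reducible in it.
#' @param s Character vector (a reducible set).
#' @param attachment Label for the contracted outside (default
#'   `"RHO_<first taxon>"`, uniquified).
#' @param validate Re-check reducibility (see [reduce_profile()]).
#' @return A `tree_profile` with `attr(, "attachment")`; some trees may
#'   carry no information (see [compress_satellite()]).
#' @export
satellite_profile <- function(p, s, attachment = NULL, validate = TRUE) {
  if (validate && !isTRUE(is_reducible(s, p))) {
    stop("set is not reducible in this profile")
  }
  s <- sort_taxa(unique(as.character(s)))
  if (is.null(attachment)) attachment <- fresh_label(paste0("RHO_", s[1L]),
                                                     p$taxa)
  if (attachment %in% p$taxa) stop("attachment label collides with a taxon")
  out <- list()
  for (t in p$trees) {
    inter <- intersect(s, t$taxa)
    outside <- setdiff(t$taxa, inter)
    if (length(outside) == 0L) { out <- c(out, list(t)); next }
    st <- contract_side(t, outside, attachment)
    if (!is.null(st)) out <- c(out, list(st))
    else out <- c(out, list(stree(attachment, NULL, rooted = p$rooted)))
  }
  structure(tree_profile(out, rooted = p$rooted), attachment = attachment)
}

#' Drop uninformative satellite trees
#'
#' Removes trees that carry fewer than two satellite taxa (in particular
#' the bare attachment leaf): they constrain nothing within the set.
#'
#' @param sat A satellite `tree_profile` (with its `"attachment"` attribute).
#' @return A `tree_profile`, or `NULL` when no informative tree remains.
#' @export
compress_satellite <- function(sat) {
  rho <- attr(sat, "attachment")
  keep <- vapply(sat$trees, function(t)
    length(setdiff(t$taxa, rho)) >= 2L, logical(1L))
  if (!any(keep)) return(NULL)
  structure(tree_profile(sat$trees[keep], rooted = sat$rooted),
            attachment = rho)
}

#' Splice a satellite supertree into a reduced supertree
#'
#' Identifies the supertaxon leaf of `t_red` with the attachment leaf of
#' `t_sat` and suppresses the resulting degree-two junction. The splits of
#' the combined tree are those of both parts with the marker leaves
#' replaced by the opposite part's taxa, plus the junction split itself.
#'
#' @param t_red `stree` containing leaf `supertaxon`.
#' @param t_sat `stree` containing leaf `attachment`.
#' @param supertaxon,attachment Marker leaf labels.
#' @return An `stree` on the disjoint union of the non-marker leaves.
#' @export
combine_trees <- function(t_red, t_sat, supertaxon, attachment) {
  stopifnot(inherits(t_red, "stree"), inherits(t_sat, "stree"))
  if (t_red$rooted != t_sat$rooted) stop("rootedness mismatch")
  if (!supertaxon %in% t_red$taxa) stop("supertaxon leaf missing from t_red")
  if (!attachment %in% t_sat$taxa) stop("attachment leaf missing from t_sat")
  red_taxa <- setdiff(t_red$taxa, supertaxon)
  sat_taxa <- setdiff(t_sat$taxa, attachment)
  if (length(intersect(red_taxa, sat_taxa)) > 0L) {
    stop("leaf sets overlap outside the marker leaves")
  }
  universe <- sort_taxa(c(red_taxa, sat_taxa))
  subst_cols <- function(t, marker, replacement) {
    lapply(seq_len(ncol(t$mat)), function(j) {
      side <- col_taxa(t, j)
      if (marker %in% side) side <- c(setdiff(side, marker), replacement)
      as.integer(universe %in% side)
    })
  }
  cols <- c(subst_cols(t_red, supertaxon, sat_taxa),
            subst_cols(t_sat, attachment, red_taxa),
            list(as.integer(universe %in% sat_taxa)))    # junction split
  mat <- matrix(unlist(cols), nrow = length(universe),
                dimnames = list(universe, NULL))
  stree(universe, mat, rooted = t_red$rooted, check = TRUE)
}

# satellite supertrees can lose taxa whose only occurrences were in
# compressed-away trees; reattach them, maximally unresolved, at the root
pad_with_taxa <- function(t, missing) {
  if (length(missing) == 0L) return(t)
  taxa <- sort_taxa(c(t$taxa, missing))
  mat <- matrix(0L, length(taxa), ncol(t$mat), dimnames = list(taxa, NULL))
  mat[match(t$taxa, taxa), ] <- t$mat
  stree(taxa, mat, rooted = t$rooted, check = FALSE)
}

#' Divide-and-conquer majority-rule (+) supertree via reducible sets
#'
#' Contracts each reducible set to a supertaxon, solves the reduced
#' profile and each compressed satellite profile independently with the
#' exact pipeline (recursing into satellites whose matrix still has more
#' than `recurse_u` question marks while `recursion_depth` allows), and
#' splices the results. The output is the S-restricted majority-rule (+)
#' supertree for the chosen sets: optimal candidate trees need not
#' display a reducible set, so this is a heuristic relative to the
#' unrestricted optimum, with scores additive across subproblems.
#'
#' @param p A rooted `tree_profile`.
#' @param sets List of reducible sets (character vectors); `NULL` runs
#'   [find_reducible_sets()].
#' @param time_limit Seconds per ILP solve.
#' @param recursion_depth Remaining recursion levels for large satellites.
#' @param recurse_u Question-mark threshold above which a satellite is
#'   decomposed further instead of solved directly.
#' @return List with `supertree`, `total_score`, `subproblems` (data
#'   frame: label, n, m, U, score), `sets`, `partial` (any subproblem
#'   verification undecided).
#' @export
reduced_supertree <- function(p, sets = NULL, time_limit = 60,
                              recursion_depth = 2L, recurse_u = 40L) {
  stopifnot(inherits(p, "tree_profile"))
  if (is.null(sets)) sets <- find_reducible_sets(p)
  if (length(sets) == 0L) {
    fit <- majority_plus_supertree(p, time_limit = time_limit)
    return(list(supertree = fit$supertree, total_score = fit$score,
                subproblems = data.frame(label = "direct", n = fit$n,
                                         m = fit$m, U = fit$U,
                                         score = fit$score),
                sets = list(), partial = fit$partial))
  }
  # validate and contract all (pairwise disjoint) sets on the root problem
  for (a in seq_along(sets)) for (b in seq_len(a - 1L)) {
    if (length(intersect(sets[[a]], sets[[b]])) > 0L) {
      stop("reducible sets must be pairwise disjoint")
    }
  }
  # validate every set against the original profile; the sequential
  # contractions below stay valid because the sets are pairwise disjoint
  for (s in sets) {
    if (!isTRUE(is_reducible(s, p))) {
      stop("set is not reducible in this profile: ", paste(s, collapse = ","))
    }
  }
  red <- p
  markers <- character(length(sets))
  for (i in seq_along(sets)) {
    red <- reduce_profile(red, sets[[i]],
                          supertaxon = fresh_label(sprintf("BETA%d", i),
                                                   c(p$taxa, markers)),
                          validate = FALSE)
    markers[i] <- attr(red, "supertaxon")
  }
  fit_red <- majority_plus_supertree(red, time_limit = time_limit)
  subs <- data.frame(label = "reduced", n = length(red$taxa),
                     m = fit_red$m, U = fit_red$U, score = fit_red$score)
  total <- fit_red$score
  partial <- fit_red$partial
  supertree <- fit_red$supertree

  for (i in seq_along(sets)) {
    s <- sets[[i]]
    sat <- satellite_profile(p, s,
                             attachment = fresh_label(sprintf("RHO%d", i),
                                                      c(p$taxa, markers)),
                             validate = FALSE)
    rho <- attr(sat, "attachment")
    csat <- compress_satellite(sat)
    if (is.null(csat)) {
      sat_tree <- stree(c(s, rho), NULL, rooted = p$rooted)  # star: no signal
      sc <- 0L; nn <- length(s) + 1L; mm <- 0L; uu <- 0L
    } else {
      mx <- build_matrix(csat)
      if (mx$U > recurse_u && recursion_depth > 0L) {
        sub <- reduced_supertree(csat, sets = NULL, time_limit = time_limit,
                                 recursion_depth = recursion_depth - 1L,
                                 recurse_u = recurse_u)
        sat_tree <- sub$supertree; sc <- sub$total_score
        partial <- partial || sub$partial
      } else {
        fit_sat <- majority_plus_supertree(csat, time_limit = time_limit)
        sat_tree <- fit_sat$supertree; sc <- fit_sat$score
        partial <- partial || fit_sat$partial
      }
      nn <- length(csat$taxa); mm <- mx$M |> ncol(); uu <- mx$U
      if (!rho %in% sat_tree$taxa) {
        sat_tree <- pad_with_taxa(sat_tree, rho)   # all trees lay inside s
      }
      sat_tree <- pad_with_taxa(sat_tree, setdiff(s, sat_tree$taxa))
    }
    subs <- rbind(subs, data.frame(label = sprintf("satellite%d", i),
                                   n = nn, m = mm, U = uu, score = sc))
    total <- total + sc
    supertree <- combine_trees(supertree, sat_tree, markers[i], rho)
  }
  list(supertree = supertree, total_score = as.integer(total),
       subproblems = subs, sets = sets, partial = partial)
}
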