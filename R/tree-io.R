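# Newick I/O and conversion between ape `phylo` objects and `stree`.
# Branch lengths and support values are parsed and discarded: the supertree
# method is topology-only. Degree-two nodes are suppressed on input.

#' Parse a Newick string into a tree
#'
#' @param text A single Newick description (trailing `;` optional).
#' @param rooted Interpret the tree as rooted (cluster semantics)?
#' @return An `stree`.
#' @export
parse_newick <- function(text, rooted = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty tree string")
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  np <- sum(strsplit(text, "")[[1]] == "(")
  nc <- sum(strsplit(text, "")[[1]] == ")")
  if (np != nc) {
    stop(sprintf("malformed parentheses in %s ('(' x %d vs ')' x %d)",
                 shQuote(substr(text, 1, 40)), np, nc))
  }
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(ph)) stop("Newick parse error in ", shQuote(text))
  if (anyDuplicated(ph$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(ph$tip.label[duplicated(ph$tip.label)]), collapse = ", "))
  }
  phylo_to_stree(ph, rooted = rooted)
}

#' Convert an ape phylo object to an stree
#'
#' @param ph A `phylo` object.
#' @param rooted Cluster semantics when `TRUE`; otherwise the tree is read
#'   as an unrooted topology whatever its internal representation.
#' @return An `stree`.
#' @export
phylo_to_stree <- function(ph, rooted = FALSE) {
  stopifnot(inherits(ph, "phylo"))
  ph <- ape::collapse.singles(ph)
  taxa <- ph$tip.label
  n <- length(taxa)
  if (n == 1L) return(stree(taxa, NULL, rooted = rooted))
  pp <- ape::prop.part(ph)      # tip-index sets, one per internal node
  cols <- lapply(pp, function(idx) {
    v <- integer(n)
    v[idx] <- 1L
    v
  })
  mat <- do.call(cbind, cols)
  rownames(mat) <- taxa
  # the root clade (all tips) is trivial in both conventions and is dropped
  # by the constructor; for unrooted input, clades and their complements
  # collapse onto one canonical bipartition there as well.
  stree(taxa, mat, rooted = rooted, check = TRUE)
}

#' Serialize a tree to Newick
#'
#' Children are emitted sorted by their smallest leaf label, so equal trees
#' always serialize identically. Unrooted trees are written rooted at the
#' node adjacent to their alphabetically smallest leaf.
#'
#' @param t An `stree`.
#' @return A Newick string (with trailing semicolon).
#' @export
write_newick <- function(t) {
  stopifnot(inherits(t, "stree"))
  taxa <- t$taxa
  n <- length(taxa)
  if (n == 1L) return(paste0(quote_label(taxa), ";"))
  clusters <- lapply(seq_len(ncol(t$mat)), function(j) col_taxa(t, j))
  if (!t$rooted) {
    # represent each bipartition by its side not containing taxa[1]
    clusters <- lapply(clusters, function(cl) {
      if (taxa[1L] %in% cl) setdiff(taxa, cl) else cl
    })
  }
  paste0(build_newick(taxa, clusters), ";")
}

build_newick <- function(set, clusters) {
  inside <- Filter(function(cl) length(cl) < length(set), clusters)
  # maximal clusters strictly inside `set`
  maximal <- list()
  for (cl in inside) {
    if (!any(vapply(inside, function(o) {
      length(o) > length(cl) && all(cl %in% o)
    }, logical(1L)))) {
      maximal <- c(maximal, list(cl))
    }
  }
  maximal <- unique(maximal)
  covered <- unlist(maximal)
  loose <- setdiff(set, covered)
  parts <- c(
    lapply(sort_taxa(loose), quote_label),
    lapply(maximal, function(cl) {
      build_newick(cl, Filter(function(o) all(o %in% cl) &&
                                length(o) < length(cl), clusters))
    })
  )
  keys <- c(sort_taxa(loose),
            vapply(maximal, function(cl) sort_taxa(cl)[1L], character(1L)))
  parts <- unlist(parts)[order(keys, method = "radix")]
  if (length(parts) == 1L) parts else
    paste0("(", paste(parts, collapse = ","), ")")
}

quote_label <- function(x) {
  if (grepl("[ ()\\[\\]:;,']", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Convert an stree to an ape phylo object
#'
#' @param x An `stree`.
#' @param ... Unused.
#' @return A `phylo` object.
#' @importFrom ape as.phylo
#' @method as.phylo stree
#' @export
as.phylo.stree <- function(x, ...) {
  ape::read.tree(text = write_newick(x))
}

#' Read a profile of trees from Newick text or file
#'
#' One tree per line (blank lines and `#` comments skipped). All trees in a
#' profile share one rootedness flag; leaf sets may differ and overlap
#' partially.
#'
#' @param x Path to a Newick file, or a character vector of Newick strings.
#' @param rooted Logical rootedness flag for the whole profile.
#' @return A `tree_profile`: list of `stree`s plus the union leaf set.
#' @export
read_profile <- function(x, rooted = FALSE) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no trees found")
  tree_profile(lapply(lines, parse_newick, rooted = rooted), rooted = rooted)
}

#' Construct a profile from a list of trees
#'
#' @param trees List of `stree` objects (ordered; order is part of the
#'   profile identity).
#' @param rooted Logical; must match every tree's flag.
#' @return A `tree_profile` with elements `trees`, `taxa` (sorted union
#'   leaf set) and `rooted`.
#' @export
tree_profile <- function(trees, rooted = FALSE) {
  stopifnot(length(trees) >= 1L,
            all(vapply(trees, inherits, logical(1L), "stree")))
  flags <- vapply(trees, `[[`, logical(1L), "rooted")
  if (!all(flags == rooted)) stop("all trees must share the profile's rootedness flag")
  structure(list(trees = trees,
                 taxa = sort_taxa(unique(unlist(lapply(trees, `[[`, "taxa")))),
                 rooted = rooted),
            class = "tree_profile")
}

#' @export
print.tree_profile <- function(x, ...) {
  cat(sprintf("%s profile: %d trees, %d taxa in the union leaf set\n",
              if (x$rooted) "rooted" else "unrooted",
              length(x$trees), length(x$taxa)))
  for (t in x$trees) cat(" ", write_newick(t), "\n")
  invisible(x)
}

#' Write a profile to a Newick file
#'
#' @param p A `tree_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "tree_profile"))
  writeLines(vapply(p$trees, write_newick, character(1L)), path)
  invisible(path)
}

# all trees plenary with the same leaf set?
is_consensus_profile <- function(p) {
  all(vapply(p$trees, function(t) identical(t$taxa, p$taxa), logical(1L)))
}
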