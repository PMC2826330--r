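# MRP-style matrix representation M(P) of a profile and fill-in semantics.
#
# Columns correspond one-to-one to the nontrivial splits of the input trees,
# in profile order; within a tree, splits are kept in canonical sorted order
# so the encoding is deterministic. Entry conventions:
#   * rooted:   cluster members 0, taxa on the root-containing side 1;
#   * unrooted: the side holding the smallest taxon of that tree's leaf set
#               is 1 (the polarity is immaterial to the method).
# Entries for taxa absent from a column's tree are NA (the "?" of the
# printed matrix); filling them in yields a restricted representative
# selection: each column becomes a plenary split extending its source split,
# and the columns of one tree must stay pairwise compatible.

#' Build the matrix representation of a profile
#'
#' @param p A `tree_profile`.
#' @return A `split_matrix`: integer matrix `M` (0/1/NA) with taxa as rows,
#'   `col_tree` mapping each column to its input-tree index, `col_split`
#'   giving the source-split index within that tree, the profile, and the
#'   question-mark count `U`.
#' @export
build_matrix <- function(p) {
  stopifnot(inherits(p, "tree_profile"))
  taxa <- p$taxa
  n <- length(taxa)
  cols <- list(); col_tree <- integer(0); col_split <- integer(0)
  for (j in seq_along(p$trees)) {
    t <- p$trees[[j]]
    mj <- ncol(t$mat)
    if (mj == 0L) next            # still in the profile; contributes no column
    idx <- match(t$taxa, taxa)
    for (s in seq_len(mj)) {
      v <- rep(NA_integer_, n)
      if (p$rooted) {
        v[idx] <- 1L - t$mat[, s]          # cluster -> 0, root side -> 1
      } else {
        v[idx] <- t$mat[, s]               # canonical side of t's universe -> 1
      }
      cols <- c(cols, list(v))
    }
    col_tree <- c(col_tree, rep(j, mj))
    col_split <- c(col_split, seq_len(mj))
  }
  M <- if (length(cols)) do.call(cbind, cols) else
    matrix(NA_integer_, n, 0L)
  rownames(M) <- taxa
  structure(list(M = M, taxa = taxa, col_tree = col_tree,
                 col_split = col_split, rooted = p$rooted, profile = p,
                 U = sum(is.na(M)), k = length(p$trees)),
            class = "split_matrix")
}

#' @export
print.split_matrix <- function(x, ...) {
  cat(sprintf("matrix representation: n = %d taxa, m = %d columns, k = %d trees, U = %d (%.1f%% ?)\n",
              nrow(x$M), ncol(x$M), x$k, x$U, 100 * pct_unknown(x)))
  invisible(x)
}

#' Fraction of question marks in a matrix representation
#'
#' @param mx A `split_matrix`.
#' @return `U / (n * m)` (0 when the matrix has no columns).
#' @export
pct_unknown <- function(mx) {
  nm <- length(mx$M)
  if (nm == 0L) 0 else mx$U / nm
}

# plenary canonical split column from one fully-filled matrix column
filled_col_to_split <- function(v, rooted) {
  v <- as.integer(v)
  if (rooted) col <- 1L - v else col <- v
  col <- matrix(col, ncol = 1L)
  if (!rooted) col <- canonicalize_cols(col, FALSE)
  col[, 1L]
}

#' Decode a fill-in into a restricted representative selection
#'
#' @param mx A `split_matrix`.
#' @param fill Complete 0/1 matrix of `dim(mx$M)` agreeing with `mx$M` on
#'   all non-NA entries.
#' @return List of plenary `stree`s, one per input tree (trees contributing
#'   no columns decode to the star on the union leaf set).
#' @export
decode_fillin <- function(mx, fill) {
  stopifnot(inherits(mx, "split_matrix"))
  fill <- as.matrix(fill)
  storage.mode(fill) <- "integer"
  if (!identical(dim(fill), dim(mx$M))) stop("fill-in has wrong dimensions")
  if (anyNA(fill)) stop("fill-in must be complete")
  known <- !is.na(mx$M)
  if (!all(fill[known] == mx$M[known])) {
    stop("fill-in disagrees with a fixed matrix entry")
  }
  taxa <- mx$taxa
  out <- vector("list", mx$k)
  for (j in seq_len(mx$k)) {
    cols <- which(mx$col_tree == j)
    if (length(cols) == 0L) {
      out[[j]] <- stree(taxa, NULL, rooted = mx$rooted)
      next
    }
    mat <- vapply(cols, function(i) filled_col_to_split(fill[, i], mx$rooted),
                  integer(length(taxa)))
    rownames(mat) <- taxa
    if (anyDuplicated(split_keys(mat))) {
      stop("fill-in collapses two columns of tree ", j, " onto one split")
    }
    if (!splits_pairwise_compatible(mat, mx$rooted)) {
      bad <- incompatible_pair(mat, mx$rooted)
      stop(sprintf("fill-in of tree %d has incompatible columns %d and %d",
                   j, cols[bad[1L]], cols[bad[2L]]))
    }
    tj <- stree(taxa, mat, rooted = mx$rooted, check = FALSE)
    if (ncol(tj$mat) != length(cols)) {
      stop("fill-in of tree ", j, " produced a trivial plenary split")
    }
    out[[j]] <- tj
  }
  out
}

incompatible_pair <- function(mat, rooted) {
  m <- ncol(mat)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    if (!split_pair_compatible(mat[, a], mat[, b], rooted)) return(c(a, b))
  }
  NULL
}

# per-tree enumeration of valid fills: for tree j, all assignments of its
# NA entries keeping columns pairwise compatible and splits distinct.
# Returns, per tree, a list of complete column submatrices.
tree_fill_options <- function(mx, j) {
  cols <- which(mx$col_tree == j)
  n <- nrow(mx$M)
  if (length(cols) == 0L) return(list(matrix(0L, n, 0L)))
  sub <- mx$M[, cols, drop = FALSE]
  nas <- which(is.na(sub))
  opts <- list()
  n_na <- length(nas)
  for (code in 0:(2^n_na - 1L)) {
    f <- sub
    if (n_na > 0L) {
      bits <- as.integer(intToBits(code)[seq_len(n_na)])
      f[nas] <- bits
    }
    spl <- vapply(seq_along(cols), function(i)
      filled_col_to_split(f[, i], mx$rooted), integer(n))
    spl <- matrix(spl, nrow = n)
    if (anyDuplicated(split_keys(spl))) next
    if (!splits_pairwise_compatible(spl, mx$rooted)) next
    opts <- c(opts, list(f))
    if (n_na == 0L) break
  }
  opts
}

#' Enumerate all valid fill-ins of a matrix representation
#'
#' Yields every 0/1 completion of the question marks under which each
#' tree's columns stay pairwise compatible, in a deterministic order
#' (per-tree assignments enumerated in binary counting order, trees
#' combined odometer-style). Intended as a brute-force oracle for small
#' instances.
#'
#' @param mx A `split_matrix`.
#' @param limit Maximum number of fill-ins to return (`Inf` for all).
#' @param u_max Refuse instances with more than this many question marks.
#' @return List of complete 0/1 matrices.
#' @export
enumerate_fillins <- function(mx, limit = Inf, u_max = 20L) {
  stopifnot(inherits(mx, "split_matrix"))
  if (mx$U > u_max) {
    stop(sprintf("U = %d question marks exceeds the enumeration bound %d; brute force is infeasible",
                 mx$U, u_max))
  }
  per_tree <- lapply(seq_len(mx$k), tree_fill_options, mx = mx)
  counts <- vapply(per_tree, length, integer(1L))
  if (any(counts == 0L)) return(list())
  out <- list()
  idx <- rep(1L, mx$k)
  repeat {
    fill <- mx$M
    for (j in seq_len(mx$k)) {
      cols <- which(mx$col_tree == j)
      if (length(cols)) fill[, cols] <- per_tree[[j]][[idx[j]]]
    }
    out <- c(out, list(fill))
    if (length(out) >= limit) break
    # odometer increment
    j <- 1L
    while (j <= mx$k) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= counts[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > mx$k) break
  }
  out
}

#' Export a matrix representation as TSV or a NEXUS character block
#'
#' @param mx A `split_matrix`.
#' @param path Output file.
#' @param format `"tsv"` (taxa x columns, `?` for unknowns) or `"nexus"`
#'   (a DATA block with a 0/1/? character matrix, as used for MRP
#'   cross-checks).
#' @return `path`, invisibly.
#' @export
export_matrix <- function(mx, path, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  M <- mx$M
  ch <- ifelse(is.na(M), "?", as.character(M))
  dim(ch) <- dim(M)
  if (format == "tsv") {
    lines <- c(paste(c("taxon", paste0("c", seq_len(ncol(M)))), collapse = "\t"),
               vapply(seq_len(nrow(M)), function(i)
                 paste(c(mx$taxa[i], ch[i, ]), collapse = "\t"),
                 character(1L)))
  } else {
    rows <- vapply(seq_len(nrow(M)), function(i)
      paste0(format(mx$taxa[i], width = max(nchar(mx$taxa)) + 2L),
             paste(ch[i, ], collapse = "")), character(1L))
    lines <- c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(M), ncol(M)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX", paste0("    ", rows), "  ;", "END;")
  }
  writeLines(lines, path)
  invisible(path)
}
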