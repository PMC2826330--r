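# ILP construction for the optimal-candidate-supertree problem.
#
# The model is assembled from Boolean definitions over binary variables and
# emitted as linear rows via the standard linearizations
#   x <=> a AND b :  x <= a, x <= b, x >= a + b - 1
# (OR and NOT by De Morgan / polarity flips), with constant propagation:
# fixed matrix entries fix their dependent pattern terms before any row is
# emitted, so the emitted model is usually far smaller than the nominal
# family counts.
#
# Variable families (nominal sizes before propagation in `nominal_counts`):
#   F(x,i)        fill-in entries, fixed wherever M(P) is 0/1
#   Gamma(r,p,q,ab) row r shows pattern ab in columns p,q
#   B(p,q,ab)     pattern ab occurs in some row of columns p,q
#   C(p,q)        columns p,q compatible (four-gametes; rooted trees carry
#                 an implicit root row, so pattern 11 is always present)
#   delta1/delta2, E(p,q)  columns represent the same split (equality, or
#                 equality-or-complement when unrooted)
#   D(p)          column p duplicates an earlier column
#   S1(i,j)       split of column i occurs in tree j
#   S2(i,j)       split of column i compatible with tree j
#   w(i)          sum_j S1 + S2 > k  (display count beats incompatible count)
#   z(i,j)        w(i) and tree j incompatible and i is the first column of
#                 its split  -- one objective unit per distinct majority
#                 split per incompatible tree
# Objective: minimize sum_i (1 - w_i) + sum_ij z_ij, the adjusted score.

# ---- literal-based model builder --------------------------------------

# literals: TRUE/FALSE constants, or +v / -v for variable v and its negation
lit_not <- function(l) if (is.logical(l)) !l else -l

# encode a literal into a numeric scalar for storage in matrices
enc_lit <- function(l) {
  if (is.logical(l)) { if (l) Inf else -Inf } else as.numeric(l)
}
dec_lit <- function(e) {
  if (is.infinite(e)) e > 0 else as.integer(e)
}

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$nv <- 0L
  b$names <- character(0)
  b$ri <- b$vi <- integer(0)      # triplet constraint storage
  b$av <- numeric(0)
  b$lo <- b$hi <- numeric(0)
  b$nrow <- 0L
  b$obj <- numeric(0)
  b$obj_const <- 0
  b$infeasible <- FALSE
  b
}

nb_var <- function(b, name) {
  b$nv <- b$nv + 1L
  b$names[b$nv] <- name
  b$obj[b$nv] <- 0
  b$nv
}

# sum_i coef_i * lit_i  in [lo, hi]
nb_con <- function(b, lits, coefs, lo, hi) {
  vs <- integer(0); as <- numeric(0)
  for (i in seq_along(lits)) {
    l <- lits[[i]]; cf <- coefs[i]
    if (is.logical(l)) {
      if (l) { lo <- lo - cf; hi <- hi - cf }
    } else if (l > 0) {
      vs <- c(vs, l); as <- c(as, cf)
    } else {
      lo <- lo - cf; hi <- hi - cf
      vs <- c(vs, -l); as <- c(as, -cf)
    }
  }
  if (anyDuplicated(vs)) {
    as <- as.numeric(tapply(as, vs, sum))
    vs <- sort(unique(vs))
  }
  keep <- as != 0
  vs <- vs[keep]; as <- as[keep]
  if (length(vs) == 0L) {
    if (lo > 1e-9 || hi < -1e-9) b$infeasible <- TRUE
    return(invisible(NULL))
  }
  b$nrow <- b$nrow + 1L
  b$ri <- c(b$ri, rep(b$nrow, length(vs)))
  b$vi <- c(b$vi, vs)
  b$av <- c(b$av, as)
  b$lo[b$nrow] <- lo
  b$hi[b$nrow] <- hi
  invisible(NULL)
}

# x <=> AND(lits); returns a literal (possibly constant or an alias)
nb_and <- function(b, lits, name) {
  out <- list()
  for (l in lits) {
    if (is.logical(l)) { if (!l) return(FALSE) }
    else out <- c(out, list(l))
  }
  if (length(out) == 0L) return(TRUE)
  vals <- vapply(out, as.numeric, numeric(1L))
  vals <- unique(vals)
  if (any(vals %in% -vals)) return(FALSE)   # l and not-l together
  if (length(vals) == 1L) return(as.integer(vals))
  out <- lapply(vals, as.integer)
  x <- nb_var(b, name)
  for (l in out) nb_con(b, list(x, l), c(1, -1), -Inf, 0)        # x <= l
  nb_con(b, c(list(x), out), c(-1, rep(1, length(out))),
         -Inf, length(out) - 1)                                  # x >= sum-(t-1)
  x
}

nb_or <- function(b, lits, name) {
  lit_not(nb_and(b, lapply(lits, lit_not), name))
}

# indicator for a sum of mutually exclusive literals (at most one is 1)
nb_sum_ind <- function(b, lits, name) {
  const1 <- 0L
  free <- list()
  for (l in lits) {
    if (is.logical(l)) { if (l) const1 <- const1 + 1L }
    else free <- c(free, list(l))
  }
  if (const1 > 1L) stop("internal error: exclusive sum exceeds 1")
  if (const1 == 1L) {
    for (l in free) nb_con(b, list(l), 1, 0, 0)   # the rest must be 0
    return(TRUE)
  }
  if (length(free) == 0L) return(FALSE)
  if (length(free) == 1L) return(free[[1L]])
  x <- nb_var(b, name)
  nb_con(b, c(list(x), free), c(-1, rep(1, length(free))), 0, 0)
  x
}

# indicator for (number of true literals) >= tau
nb_threshold <- function(b, lits, tau, name) {
  free <- list()
  for (l in lits) {
    if (is.logical(l)) { if (l) tau <- tau - 1L }
    else free <- c(free, list(l))
  }
  nf <- length(free)
  if (tau <= 0L) return(TRUE)
  if (tau > nf) return(FALSE)
  if (nf == 1L) return(free[[1L]])          # tau == 1
  w <- nb_var(b, name)
  # w = 0  =>  sum < tau ;  w = 1  =>  sum >= tau
  nb_con(b, c(free, list(w)), c(rep(1, nf), -(nf - tau + 1)), -Inf, tau - 1)
  nb_con(b, c(free, list(w)), c(rep(1, nf), -tau), 0, Inf)
  w
}

obj_add <- function(b, l, cf) {
  if (is.logical(l)) { if (l) b$obj_const <- b$obj_const + cf }
  else if (l > 0) b$obj[l] <- b$obj[l] + cf
  else { b$obj_const <- b$obj_const + cf; b$obj[-l] <- b$obj[-l] - cf }
  invisible(NULL)
}

# ---- the supertree ILP ------------------------------------------------

#' Build the optimal-candidate-supertree ILP for a matrix representation
#'
#' Encodes, over binary variables, the requirement that the filled-in
#' matrix is a restricted representative selection (per-tree pairwise
#' column compatibility via the four-gametes patterns) together with the
#' bookkeeping needed to express the adjusted score, which is minimized.
#'
#' @param mx A `split_matrix`.
#' @param forbid_split Optional plenary split (canonical 0/1 vector over
#'   `mx$taxa`): adds per-column match indicators and the requirement that
#'   no majority column realizes this split (the verification sub-ILP).
#' @param score_cap Optional integer: adds the constraint
#'   objective <= `score_cap`.
#' @return An `ilp_model` list: `nvar`, `varnames`, constraint triplets
#'   (`ri`, `vi`, `av`) with row bounds `lo`/`hi`, objective `obj` +
#'   `obj_const`, `sense = "min"`, branching priority, decoding metadata
#'   and nominal Table-style family counts.
#' @export
build_ilp <- function(mx, forbid_split = NULL, score_cap = NULL) {
  stopifnot(inherits(mx, "split_matrix"))
  M <- mx$M
  n <- nrow(M); m <- ncol(M); k <- mx$k
  rooted <- mx$rooted
  b <- new_builder()

  # F literals: fill-in variables first (they are the branching skeleton)
  Fenc <- matrix(NA_real_, n, m)
  Fpos <- which(is.na(M), arr.ind = TRUE)
  if (nrow(Fpos) > 0L) {
    ord <- order(Fpos[, "col"], Fpos[, "row"])
    Fpos <- Fpos[ord, , drop = FALSE]
    for (t in seq_len(nrow(Fpos))) {
      v <- nb_var(b, sprintf("F_%d_%d", Fpos[t, 1L], Fpos[t, 2L]))
      Fenc[Fpos[t, 1L], Fpos[t, 2L]] <- v
    }
  }
  fixed <- !is.na(M)
  Fenc[fixed] <- ifelse(M[fixed] == 1L, Inf, -Inf)
  litF <- function(r, c, a) {            # literal for F_rc == a
    l <- dec_lit(Fenc[r, c])
    if (is.logical(l)) xor(!l, a == 1L) else if (a == 1L) l else -l
  }

  patterns <- if (rooted) c("00", "01", "10") else c("00", "01", "10", "11")
  Cenc <- matrix(NA_real_, m, m)
  Eenc <- matrix(NA_real_, m, m)
  if (m >= 2L) {
    for (p in seq_len(m - 1L)) for (q in (p + 1L):m) {
      same_tree <- mx$col_tree[p] == mx$col_tree[q]
      Bab <- list()
      need <- if (!same_tree) unique(c(patterns, "01", "10",
                                       if (!rooted) c("00", "11")))
              else patterns
      for (ab in need) {
        a <- as.integer(substr(ab, 1L, 1L)); d <- as.integer(substr(ab, 2L, 2L))
        gam <- vector("list", n)
        for (r in seq_len(n)) {
          gam[[r]] <- nb_and(b, list(litF(r, p, a), litF(r, q, d)),
                             sprintf("G_%d_%d_%d_%s", r, p, q, ab))
        }
        Bab[[ab]] <- nb_or(b, gam, sprintf("B_%d_%d_%s", p, q, ab))
      }
      C <- lit_not(nb_and(b, Bab[patterns], sprintf("nC_%d_%d", p, q)))
      Cenc[p, q] <- enc_lit(C)
      if (same_tree) {
        nb_con(b, list(C), 1, 1, 1)           # same-tree columns compatible
      } else {
        E <- if (rooted) {
          nb_and(b, list(lit_not(Bab[["01"]]), lit_not(Bab[["10"]])),
                 sprintf("E_%d_%d", p, q))
        } else {
          d1 <- nb_and(b, list(lit_not(Bab[["01"]]), lit_not(Bab[["10"]])),
                       sprintf("d1_%d_%d", p, q))
          d2 <- nb_and(b, list(lit_not(Bab[["00"]]), lit_not(Bab[["11"]])),
                       sprintf("d2_%d_%d", p, q))
          nb_or(b, list(d1, d2), sprintf("E_%d_%d", p, q))
        }
        Eenc[p, q] <- enc_lit(E)
      }
    }
  }
  getE <- function(p, q) dec_lit(Eenc[min(p, q), max(p, q)])
  getC <- function(p, q) dec_lit(Cenc[min(p, q), max(p, q)])

  # D_p: column p repeats the split of an earlier (cross-tree) column
  Denc <- numeric(m)
  for (p in seq_len(m)) {
    prev <- which(seq_len(m) < p & mx$col_tree != mx$col_tree[p])
    Denc[p] <- enc_lit(nb_or(b, lapply(prev, getE, p = p),
                             sprintf("D_%d", p)))
  }

  # S1 (occurrence), S2 (compatibility), w (majority), z (penalty units)
  wenc <- numeric(m)
  zlits <- list()
  for (i in seq_len(m)) {
    qlits <- vector("list", 2L * k)
    S2i <- vector("list", k)
    for (j in seq_len(k)) {
      cols_j <- which(mx$col_tree == j)
      if (mx$col_tree[i] == j) {
        S1 <- TRUE; S2 <- TRUE
      } else {
        S1 <- nb_sum_ind(b, lapply(cols_j, getE, p = i),
                         sprintf("S1_%d_%d", i, j))
        S2 <- nb_and(b, lapply(cols_j, getC, p = i),
                     sprintf("S2_%d_%d", i, j))
      }
      qlits[[2L * j - 1L]] <- S1
      qlits[[2L * j]] <- S2
      S2i[[j]] <- S2
    }
    w <- nb_threshold(b, qlits, k + 1L, sprintf("w_%d", i))
    wenc[i] <- enc_lit(w)
    obj_add(b, TRUE, 1); obj_add(b, w, -1)        # (1 - w_i)
    for (j in seq_len(k)) {
      if (mx$col_tree[i] == j) next
      z <- nb_and(b, list(w, lit_not(S2i[[j]]), lit_not(dec_lit(Denc[i]))),
                  sprintf("z_%d_%d", i, j))
      obj_add(b, z, 1)
      zlits <- c(zlits, list(z))
    }
  }

  # verification extras: forbid any majority column from matching the split
  if (!is.null(forbid_split)) {
    stopifnot(length(forbid_split) == n)
    pat <- if (rooted) 1L - as.integer(forbid_split) else
      as.integer(forbid_split)
    for (i in seq_len(m)) {
      eq <- nb_and(b, lapply(seq_len(n), function(r) litF(r, i, pat[r])),
                   sprintf("mu_eq_%d", i))
      mu <- if (rooted) eq else {
        cp <- nb_and(b, lapply(seq_len(n), function(r) litF(r, i, 1L - pat[r])),
                     sprintf("mu_cp_%d", i))
        nb_or(b, list(eq, cp), sprintf("mu_%d", i))
      }
      nb_con(b, list(dec_lit(wenc[i]), mu), c(1, 1), -Inf, 1)
    }
  }
  if (!is.null(score_cap)) {
    vs <- which(b$obj != 0)
    nb_con(b, as.list(as.integer(vs)), b$obj[vs],
           -Inf, score_cap - b$obj_const)
  }

  structure(list(
    nvar = b$nv, varnames = b$names,
    ri = b$ri, vi = b$vi, av = b$av, lo = b$lo, hi = b$hi,
    obj = b$obj, obj_const = b$obj_const, sense = "min",
    infeasible_at_build = b$infeasible,
    branch_order = seq_len(nrow(Fpos)),      # F variables lead the search
    F_pos = Fpos, w_enc = wenc, mx = mx,
    nominal_counts = c(F = n * m, Gamma = 2 * m * (m - 1) * n,
                       B = 2 * m * (m - 1), delta = m * (m - 1) / 2,
                       E = 2 * m * (m - 1), C = 2 * m * (m - 1),
                       D = m, S = m * k, w = m, z = m * k)
  ), class = "ilp_model")
}

#' @export
print.ilp_model <- function(x, ...) {
  cat(sprintf("ILP model: %d binary variables, %d constraints (after constant propagation)\n",
              x$nvar, length(x$lo)))
  cat("nominal family sizes:",
      paste(names(x$nominal_counts), x$nominal_counts, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Export an ILP model in LP or MPS format
#'
#' @param model An `ilp_model`.
#' @param path Output file.
#' @param format `"lp"` (CPLEX LP) or `"mps"` (free MPS).
#' @return `path`, invisibly.
#' @export
export_ilp <- function(model, path, format = c("lp", "mps")) {
  format <- match.arg(format)
  nm <- model$varnames
  rows <- split(seq_along(model$ri), model$ri)
  term_str <- function(ids) {
    paste(vapply(ids, function(t) {
      a <- model$av[t]
      sprintf("%s%g %s", if (a >= 0) "+ " else "- ", abs(a), nm[model$vi[t]])
    }, character(1L)), collapse = " ")
  }
  if (format == "lp") {
    objv <- which(model$obj != 0)
    lines <- c("Minimize",
               paste(" obj:",
                     if (length(objv)) paste(sprintf("%+g %s", model$obj[objv],
                                                     nm[objv]),
                                             collapse = " ") else "0"),
               "Subject To")
    cn <- 0L
    for (r in names(rows)) {
      ids <- rows[[r]]
      lo <- model$lo[as.integer(r)]; hi <- model$hi[as.integer(r)]
      if (is.finite(lo) && is.finite(hi) && lo == hi) {
        cn <- cn + 1L
        lines <- c(lines, sprintf(" c%d: %s = %g", cn, term_str(ids), lo))
      } else {
        if (is.finite(hi)) {
          cn <- cn + 1L
          lines <- c(lines, sprintf(" c%d: %s <= %g", cn, term_str(ids), hi))
        }
        if (is.finite(lo)) {
          cn <- cn + 1L
          lines <- c(lines, sprintf(" c%d: %s >= %g", cn, term_str(ids), lo))
        }
      }
    }
    lines <- c(lines, "Binary", paste(" ", nm[seq_len(model$nvar)]), "End")
  } else {
    lines <- c("NAME MAJPLUS", "ROWS", " N  obj")
    rtype <- character(0)
    for (r in seq_along(model$lo)) {
      lo <- model$lo[r]; hi <- model$hi[r]
      ty <- if (is.finite(lo) && is.finite(hi) && lo == hi) "E"
            else if (is.finite(hi)) "L" else "G"
      rtype[r] <- ty
      lines <- c(lines, sprintf(" %s  c%d", ty, r))
    }
    lines <- c(lines, "COLUMNS")
    for (v in seq_len(model$nvar)) {
      if (model$obj[v] != 0) {
        lines <- c(lines, sprintf("    %s  obj  %g", nm[v], model$obj[v]))
      }
      ids <- which(model$vi == v)
      for (t in ids) {
        lines <- c(lines, sprintf("    %s  c%d  %g", nm[v], model$ri[t],
                                  model$av[t]))
      }
    }
    lines <- c(lines, "RHS")
    for (r in seq_along(model$lo)) {
      rhs <- if (rtype[r] == "G") model$lo[r] else model$hi[r]
      if (rhs != 0) lines <- c(lines, sprintf("    RHS  c%d  %g", r, rhs))
    }
    lines <- c(lines, "BOUNDS")
    for (v in seq_len(model$nvar)) {
      lines <- c(lines, sprintf(" BV BND  %s", nm[v]))
    }
    lines <- c(lines, "ENDATA")
  }
  writeLines(lines, path)
  invisible(path)
}
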