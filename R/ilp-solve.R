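# Solving the supertree ILP, verifying splits, and the exact pipeline.

#' Solve an ILP model
#'
#' The default backend is the package's exact branch-and-bound solver for
#' binary programs (compiled code; branches on the fill-in variables and
#' fixes everything else by bound propagation). A custom backend may be
#' supplied as a function `function(model, time_limit, feasibility_only)`
#' returning a list with `status`, `objective`, `x` — e.g. a wrapper around
#' an external solver fed by [export_ilp()].
#'
#' @param model An `ilp_model`.
#' @param time_limit Seconds before giving up with status `"timeout"`.
#' @param feasibility_only Stop at the first feasible assignment.
#' @param backend `"bnb"` or a function (see above).
#' @return List with `status` (`"optimal"`, `"feasible"`, `"infeasible"`,
#'   `"timeout"`), `objective` (includes the model's constant term), `x`
#'   (0/1 assignment), `nodes`.
#' @export
solve_ilp <- function(model, time_limit = 60, feasibility_only = FALSE,
                      backend = "bnb") {
  stopifnot(inherits(model, "ilp_model"))
  if (isTRUE(model$infeasible_at_build)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_integer_, model$nvar), nodes = 0))
  }
  if (model$nvar == 0L) {
    return(list(status = if (feasibility_only) "feasible" else "optimal",
                objective = model$obj_const, x = integer(0), nodes = 1))
  }
  res <- if (is.function(backend)) {
    backend(model, time_limit, feasibility_only)
  } else if (identical(backend, "bnb")) {
    .bnb_solve(model$nvar, model$obj, model$ri, model$vi, model$av,
               model$lo, model$hi, model$branch_order,
               feasibility_only, time_limit)
  } else stop("unknown backend: ", backend)
  if (!is.na(res$objective)) {
    res$objective <- res$objective + model$obj_const
  }
  res
}

# fill matrix from a solved assignment
fill_from_solution <- function(model, x) {
  mx <- model$mx
  fill <- mx$M
  if (nrow(model$F_pos) > 0L) {
    fill[model$F_pos] <- x[seq_len(nrow(model$F_pos))]
  }
  fill
}

#' Solve the optimal-candidate-supertree problem for a profile
#'
#' Builds the matrix representation and ILP, solves it, decodes the
#' optimal fill-in into a restricted representative selection `G*`, and
#' cross-checks the solver objective against the combinatorially computed
#' adjusted score of `G*` (a mismatch is an internal error).
#'
#' @param p A `tree_profile`.
#' @param time_limit Seconds for the solve.
#' @param backend Passed to [solve_ilp()].
#' @return List with `status`, `score` (minimum adjusted score),
#'   `selection` (list of plenary `stree`s), `candidate` (the optimal
#'   candidate supertree, the majority-rule (+) consensus of the
#'   selection), `model`, `matrix`, `nodes`.
#' @export
solve_supertree <- function(p, time_limit = 60, backend = "bnb") {
  stopifnot(inherits(p, "tree_profile"))
  mx <- build_matrix(p)
  if (ncol(mx$M) == 0L) {          # every input is a star
    star <- stree(p$taxa, NULL, rooted = p$rooted)
    sel <- rep(list(star), mx$k)
    return(list(status = "optimal", score = 0L, selection = sel,
                candidate = star, model = NULL, matrix = mx, nodes = 0))
  }
  model <- build_ilp(mx)
  res <- solve_ilp(model, time_limit = time_limit, backend = backend)
  if (res$status == "timeout") {
    return(list(status = "timeout", score = NA_integer_, selection = NULL,
                candidate = NULL, model = model, matrix = mx,
                nodes = res$nodes))
  }
  if (res$status != "optimal") {
    stop("internal error: base model reported ", res$status)
  }
  fill <- fill_from_solution(model, res$x)
  sel <- decode_fillin(mx, fill)
  s_comb <- adjusted_score(sel)
  if (abs(res$objective - s_comb) > 1e-6) {
    stop(sprintf("internal error: solver objective %g != adjusted score %d",
                 res$objective, s_comb))
  }
  cand <- majority_plus_consensus(sel)
  list(status = "optimal", score = as.integer(round(res$objective)),
       selection = sel, candidate = cand, model = model, matrix = mx,
       nodes = res$nodes)
}

#' Verify which splits of an optimal candidate tree survive in Maj+(P)
#'
#' For each nontrivial split of the candidate, a sub-ILP asks for a
#' restricted representative selection with the same optimal score whose
#' majority-rule (+) consensus avoids the split (per-column match
#' indicators plus a score cap). Feasible: some optimal candidate lacks
#' the split, so it is excluded from the strict consensus. Infeasible:
#' the split is in every optimal candidate and is retained. Timeouts are
#' reported as `"undecided"` and the final tree flagged partial rather
#' than guessing.
#'
#' @param fit Result of [solve_supertree()] with status `"optimal"`.
#' @param time_limit Seconds per sub-ILP.
#' @param backend Passed to [solve_ilp()].
#' @return List with `table` (data frame: split, status), `supertree`
#'   (Maj+(P) built from the retained splits), `partial` (TRUE when any
#'   split was undecided).
#' @export
verify_splits <- function(fit, time_limit = 60, backend = "bnb") {
  stopifnot(fit$status == "optimal")
  cand <- fit$candidate
  mx <- fit$matrix
  m_cand <- ncol(cand$mat)
  status <- character(m_cand)
  for (s in seq_len(m_cand)) {
    sub <- build_ilp(mx, forbid_split = cand$mat[, s], score_cap = fit$score)
    r <- solve_ilp(sub, time_limit = time_limit, feasibility_only = TRUE,
                   backend = backend)
    status[s] <- switch(r$status,
                        feasible = "excluded",
                        infeasible = "in_majority_plus",
                        timeout = "undecided",
                        stop("unexpected status ", r$status))
  }
  keep <- status == "in_majority_plus"
  final <- stree(cand$taxa, cand$mat[, keep, drop = FALSE],
                 rooted = cand$rooted, check = FALSE)
  table <- data.frame(
    split = vapply(seq_len(m_cand), function(s)
      paste(col_taxa(cand, s), collapse = ","), character(1L)),
    status = status, stringsAsFactors = FALSE)
  list(table = table, supertree = final, partial = any(status == "undecided"))
}

#' Majority-rule (+) supertree of a profile
#'
#' The full exact pipeline: encode, solve for an optimal candidate
#' supertree, then verify each of its splits to obtain the strict
#' consensus of all optimal candidates.
#'
#' @param p A `tree_profile` (or anything [read_profile()] accepts via
#'   `trees`/`rooted` arguments).
#' @param time_limit Seconds for the base solve and for each verification
#'   sub-ILP.
#' @param verify Set `FALSE` to skip verification and return the single
#'   optimal candidate instead of Maj+(P).
#' @param backend Passed to [solve_ilp()].
#' @return Object of class `majplus_fit`: `supertree` (an `stree`),
#'   `candidate`, `score`, `selection`, `verification` (data frame or
#'   NULL), `partial`, `matrix` statistics (`n`, `m`, `k`, `U`), `nodes`.
#' @export
majority_plus_supertree <- function(p, time_limit = 60, verify = TRUE,
                                    backend = "bnb") {
  t0 <- proc.time()[["elapsed"]]
  fit <- solve_supertree(p, time_limit = time_limit, backend = backend)
  if (fit$status != "optimal") {
    stop("base solve did not reach optimality (status ", fit$status, ")")
  }
  ver <- NULL; partial <- FALSE
  final <- fit$candidate
  if (verify && ncol(fit$candidate$mat) > 0L && !is.null(fit$model)) {
    v <- verify_splits(fit, time_limit = time_limit, backend = backend)
    ver <- v$table; final <- v$supertree; partial <- v$partial
  }
  structure(list(supertree = final, candidate = fit$candidate,
                 score = fit$score, selection = fit$selection,
                 verification = ver, partial = partial,
                 n = length(p$taxa), m = ncol(fit$matrix$M),
                 k = fit$matrix$k, U = fit$matrix$U,
                 nodes = fit$nodes,
                 seconds = proc.time()[["elapsed"]] - t0),
            class = "majplus_fit")
}

#' @export
print.majplus_fit <- function(x, ...) {
  cat(sprintf("majority-rule (+) supertree fit: n = %d, m = %d, k = %d, U = %d\n",
              x$n, x$m, x$k, x$U))
  cat(sprintf("optimal adjusted score: %d\n", x$score))
  if (!is.null(x$verification)) {
    cat(sprintf("verification: %d of %d candidate splits retained%s\n",
                sum(x$verification$status == "in_majority_plus"),
                nrow(x$verification),
                if (x$partial) " (PARTIAL: undecided splits present)" else ""))
  }
  cat("supertree:", write_newick(x$supertree), "\n")
  invisible(x)
}

#' Brute-force optimum by fill-in enumeration (oracle)
#'
#' Enumerates every valid fill-in of the matrix representation, scores the
#' decoded restricted representative selections combinatorially, and
#' returns the minimum adjusted score, all optimal selections, and the
#' strict consensus of their majority-rule (+) consensus trees. Entirely
#' independent of the ILP path; intended for small instances.
#'
#' @param p A `tree_profile`.
#' @param u_max Enumeration bound on the number of question marks.
#' @return List with `score`, `optima` (list of selections), `supertree`
#'   (the strict consensus over optima), `n_fillins`.
#' @export
brute_force_optimal <- function(p, u_max = 20L) {
  stopifnot(inherits(p, "tree_profile"))
  mx <- build_matrix(p)
  if (ncol(mx$M) == 0L) {
    star <- stree(p$taxa, NULL, rooted = p$rooted)
    return(list(score = 0L, optima = list(rep(list(star), mx$k)),
                supertree = star, n_fillins = 1L))
  }
  fills <- enumerate_fillins(mx, u_max = u_max)
  if (length(fills) == 0L) stop("internal error: no valid fill-in exists")
  best <- Inf; optima <- list(); cons_keys <- NULL; cons_tpl <- NULL
  for (f in fills) {
    sel <- decode_fillin(mx, f)
    tl <- tally_all(sel)
    win <- tl$n_display > tl$n_incompatible
    s <- sum(ifelse(win, tl$n_incompatible, tl$n_display))
    if (s > best) next
    mp_keys <- tl$keys[win]
    if (s < best) {
      best <- s; optima <- list(sel)
      cons_keys <- mp_keys
      cons_tpl <- tl$mat[, win, drop = FALSE]
    } else {
      optima <- c(optima, list(sel))
      keep <- cons_keys %in% mp_keys
      cons_keys <- cons_keys[keep]
      cons_tpl <- cons_tpl[, keep, drop = FALSE]
    }
  }
  supertree <- stree(p$taxa, cons_tpl, rooted = p$rooted, check = FALSE)
  list(score = as.integer(best), optima = optima, supertree = supertree,
       n_fillins = length(fills))
}
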