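# reducible sets, reduced / satellite / compressed profiles, splicing,
# and the divide-and-conquer pipeline

decomposable_profile <- function() {
  # clades {a,b,c} and {x,y,z} are separated in every tree
  rp("(((a,b),c),((x,y),z));",
     "(((a,b),(x,y)),w);",
     "((a,(b,c)),(x,(y,z)),w);", rooted = TRUE)
}

test_that("reducibility requires a separating full split in every tree", {
  p <- decomposable_profile()
  r <- is_reducible(c("a", "b", "c"), p)
  expect_true(isTRUE(r))
  expect_length(attr(r, "witnesses"), 3L)
  expect_true(isTRUE(is_reducible(c("x", "y", "z"), p)))
  # {a,b}: third tree clusters a with neither side matching {a,b}
  expect_false(isTRUE(is_reducible(c("a", "b"), p)))
  # trees disjoint from the set separate it trivially
  p2 <- rp("((a,b),c);", "((x,y),z);", rooted = TRUE)
  expect_true(isTRUE(is_reducible(c("a", "b"), p2)))
  # no split side of ((a,c),(b,d)) equals {a,b}
  p3 <- rp("((a,c),(b,d));", "(a,b,c,d,e);")
  expect_false(isTRUE(is_reducible(c("a", "b"), p3)))
  expect_error(is_reducible(c("a"), p), "size")
  expect_error(is_reducible(p$taxa, p), "size")
})

test_that("greedy search returns disjoint reducible clusters, largest first", {
  p <- decomposable_profile()
  sets <- find_reducible_sets(p)
  expect_identical(sets, list(c("a", "b", "c"), c("x", "y", "z")))
  # identical trees: the largest nontrivial proper cluster is found
  p2 <- rp("(((a,b),c),(d,e));", "(((a,b),c),(d,e));", rooted = TRUE)
  sets2 <- find_reducible_sets(p2)
  expect_identical(sets2[[1]], c("a", "b", "c"))
  # validated user sets come first; invalid ones are rejected
  expect_identical(find_reducible_sets(p, user_sets = list(c("x", "y", "z"))),
                   list(c("x", "y", "z"), c("a", "b", "c")))
  expect_error(find_reducible_sets(p, user_sets = list(c("a", "w"))),
               "not an acceptable")
  # profiles can lack reducible sets entirely
  p3 <- rp("((a,c),(b,d));", "((a,b),(c,d));", "((a,d),(b,c));",
           rooted = TRUE)
  expect_identical(find_reducible_sets(p3), list())
})

test_that("reduction contracts the clade to a supertaxon", {
  p <- decomposable_profile()
  red <- reduce_profile(p, c("a", "b", "c"), supertaxon = "B1")
  expect_identical(attr(red, "supertaxon"), "B1")
  expect_identical(write_newick(red$trees[[1]]), "(B1,((x,y),z));")
  expect_identical(write_newick(red$trees[[2]]), "((B1,(x,y)),w);")
  # a tree disjoint from the set is untouched
  p2 <- rp("((a,b),c);", "((x,y),z);", rooted = TRUE)
  red2 <- reduce_profile(p2, c("a", "b"), supertaxon = "B1")
  expect_same_tree(red2$trees[[2]], p2$trees[[2]])
  # a tree entirely inside the set collapses and is dropped
  p3 <- rp("((a,b),c);", "((x,y),(a,c));", rooted = TRUE)
  red3 <- reduce_profile(p3, c("a", "b", "c"), supertaxon = "B1")
  expect_length(red3$trees, 1L)
  expect_identical(write_newick(red3$trees[[1]]), "(B1,(x,y));")
  expect_error(reduce_profile(p3, c("x", "a"), supertaxon = "B1"),
               "not reducible")
})

test_that("satellites keep only structure inside the set", {
  p <- decomposable_profile()
  sat <- satellite_profile(p, c("a", "b", "c"), attachment = "R1")
  expect_identical(write_newick(sat$trees[[1]]), "(R1,((a,b),c));")
  expect_identical(write_newick(sat$trees[[2]]), "(R1,(a,b));")
  expect_identical(write_newick(sat$trees[[3]]), "(R1,(a,(b,c)));")
  # a tree inside the set is kept whole; one outside carries only R1
  p2 <- rp("((a,b),c);", "((x,y),z);", rooted = TRUE)
  sat2 <- satellite_profile(p2, c("a", "b", "c"), attachment = "R1")
  expect_same_tree(sat2$trees[[1]], p2$trees[[1]])
  expect_identical(sat2$trees[[2]]$taxa, "R1")
  cs <- compress_satellite(sat2)
  expect_length(cs$trees, 1L)
  # compression can empty a satellite completely
  p3 <- rp("((x,y),(z,a));", "((x,z),(y,b));", rooted = TRUE)
  sat3 <- satellite_profile(p3, c("a", "b"), attachment = "R1")
  expect_null(compress_satellite(sat3))
})

test_that("splicing identifies the marker leaves and keeps both structures", {
  t_red <- parse_newick("(B,(x,y));", rooted = TRUE)
  t_sat <- parse_newick("(R,(p,q));", rooted = TRUE)
  comb <- combine_trees(t_red, t_sat, "B", "R")
  expect_identical(write_newick(comb), "((p,q),(x,y));")
  # a single-cherry satellite replaces the supertaxon by the cherry
  t_sat2 <- parse_newick("(R,p,q);", rooted = TRUE)
  comb2 <- combine_trees(t_red, t_sat2, "B", "R")
  expect_identical(write_newick(comb2), "((p,q),(x,y));")
  # restriction round-trip: collapsing the satellite side recovers t_red
  back <- restrict_tree(comb, c("x", "y"))
  expect_same_tree(back, restrict_tree(t_red, c("x", "y")))
  expect_error(combine_trees(t_red, t_sat, "nope", "R"), "missing")
  expect_error(combine_trees(parse_newick("(B,(p,x));", rooted = TRUE),
                             t_sat, "B", "R"), "overlap")
})

test_that("contraction outputs are valid trees in degenerate layouts too", {
  set.seed(53)
  for (rep in 1:10) {
    g <- generate_profile(8, 3, deletion_probability = 0.3, seed = 900 + rep,
                          rooted = TRUE)
    p <- g$profile
    cands <- find_reducible_sets(p)
    for (s in cands) {
      red <- reduce_profile(p, s)
      sat <- satellite_profile(p, s)
      for (t in c(red$trees, sat$trees)) {
        expect_s3_class(t, "stree")
        if (ncol(t$mat) > 0) {
          expect_true(splits_compatible(t$mat, rooted = TRUE))
        }
      }
      # fresh labels never collide with taxa
      expect_false(attr(red, "supertaxon") %in% p$taxa)
      expect_false(attr(sat, "attachment") %in% p$taxa)
    }
  }
})

test_that("subproblem scores add up and match the direct optimum on fixtures", {
  p <- decomposable_profile()
  res <- reduced_supertree(p)
  expect_identical(sum(res$subproblems$score), res$total_score)
  direct <- majority_plus_supertree(p)
  expect_identical(res$total_score, direct$score)
  expect_same_tree(res$supertree, direct$supertree)
  # second fixture: every tree displays the set against the rest
  p2 <- rp("((a,b),(c,d));", "((a,b),(c,d));", "(((a,b),c),d);",
           rooted = TRUE)
  r2 <- reduced_supertree(p2, sets = list(c("a", "b")))
  d2 <- majority_plus_supertree(p2)
  expect_identical(r2$total_score, d2$score)
  expect_same_tree(r2$supertree, d2$supertree)
  # the unrestricted optimum never exceeds the S-restricted one
  set.seed(61)
  for (rep in 1:6) {
    g <- generate_profile(7, 3, deletion_probability = 0.25,
                          perturbation_count = 1, seed = 950 + rep,
                          rooted = TRUE)
    p3 <- g$profile
    sets <- find_reducible_sets(p3)
    if (length(sets) == 0L) next
    if (build_matrix(p3)$U > 16L) next
    r3 <- reduced_supertree(p3, sets = sets)
    d3 <- majority_plus_supertree(p3)
    expect_lte(d3$score, r3$total_score)
  }
})

test_that("empty set lists fall through to the direct pipeline", {
  p <- rp("((a,c),(b,d));", "((a,b),(c,d));", "((a,d),(b,c));",
          rooted = TRUE)
  res <- reduced_supertree(p)
  direct <- majority_plus_supertree(p)
  expect_identical(res$total_score, direct$score)
  expect_same_tree(res$supertree, direct$supertree)
  expect_identical(res$subproblems$label, "direct")
})
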