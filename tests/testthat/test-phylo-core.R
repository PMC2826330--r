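# tree & split algebra: parsing, splits, restriction, display,
# compatibility, Robinson-Foulds distance, reconstruction

test_that("newick parsing handles quartets, stars, rooted caterpillars", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_identical(tree_keys(t1), "1100")          # ab|cd only
  expect_identical(ncol(parse_newick("(a,b,c);")$mat), 0L)
  t3 <- parse_newick("((a,b),c);", rooted = TRUE)
  expect_identical(tree_keys(t3), "110")           # cluster {a,b}
  t4 <- parse_newick("((((a,b),c),d),e);", rooted = TRUE)
  expect_identical(tree_keys(t4), c("11000", "11100", "11110"))
  t5 <- parse_newick("((a,b),(c,d),e);")
  expect_identical(tree_keys(t5), c("11000", "11001"))  # ab|cde, cd|abe
})

test_that("parser rejects malformed input and duplicate labels", {
  expect_error(parse_newick("((a,b),(c,d);"), "parenthes")
  expect_error(parse_newick("((a,b),(a,d));"), "duplicate")
  expect_error(parse_newick("   "), "empty")
})

test_that("branch lengths are discarded and degree-2 nodes suppressed", {
  t <- parse_newick("((a:1.2,b:0.1):0.5,(c:3,d:1):2);")
  expect_identical(tree_keys(t), "1100")
  t2 <- parse_newick("(((a,b)));", rooted = TRUE)
  expect_identical(ncol(t2$mat), 0L)
})

test_that("newick round-trips deterministically", {
  for (nwk in c("((a,b),(c,d));", "((a,b),(c,d),e);", "(a,b,c);")) {
    t <- parse_newick(nwk)
    expect_same_tree(parse_newick(write_newick(t)), t)
  }
  t <- parse_newick("((((a,b),c),d),e);", rooted = TRUE)
  expect_same_tree(parse_newick(write_newick(t), rooted = TRUE), t)
  # writer output is invariant under input rotation
  expect_identical(write_newick(parse_newick("((d,c),(b,a));")),
                   write_newick(parse_newick("((a,b),(c,d));")))
})

test_that("restriction keeps exactly the surviving splits", {
  t5 <- parse_newick("((a,b),(c,d),e);")
  expect_identical(ncol(restrict_tree(t5, c("a", "c", "d"))$mat), 0L)
  expect_same_tree(restrict_tree(t5, t5$taxa), t5)
  expect_identical(ncol(restrict_tree(parse_newick("((a,b),(c,d));"),
                                      c("a", "c", "d"))$mat), 0L)
  t <- parse_newick("((((a,b),c),d),e);", rooted = TRUE)
  expect_identical(tree_keys(restrict_tree(t, c("a", "b", "d", "e"))),
                   c("1100", "1110"))   # clusters {a,b} and {a,b,d}
  expect_error(restrict_tree(t5, c("a", "zz")), "not leaves")
})

test_that("display of splits and trees follows edge separation", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_true(displays_split(t1, list(c("a", "b"), c("c", "d"))))
  expect_false(displays_split(t1, list(c("a", "c"), c("b", "d"))))
  # any tree displays its own restrictions
  t5 <- parse_newick("((a,b),(c,d),e);")
  for (s in list(c("a", "b", "c"), c("a", "c", "d", "e"), t5$taxa)) {
    expect_true(displays_tree(t5, restrict_tree(t5, s)))
  }
  expect_false(displays_tree(parse_newick("((a,c),(b,d));"),
                             parse_newick("((a,b),(c,d));")))
})

test_that("pairwise compatibility follows the four-gametes condition", {
  nested <- cbind(c(1L, 1L, 0L, 0L, 0L), c(1L, 1L, 1L, 0L, 0L))
  expect_true(splits_compatible(nested))
  clash <- cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  expect_false(splits_compatible(clash))
  expect_false(split_compatible_with_tree(
    c(1, 1, 0, 0, 0), parse_newick("((a,c),(b,d),e);")))
  expect_true(split_compatible_with_tree(
    c(1, 1, 0, 0, 0), parse_newick("((a,b),(c,d),e);")))
})

test_that("four-gametes agrees with exhaustive refinement search (<= 6 taxa)", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(4:6, 1L)
    taxa <- letters[seq_len(n)]
    x <- c(1L, sample(0:1, n - 1L, replace = TRUE))
    y <- c(1L, sample(0:1, n - 1L, replace = TRUE))
    ok_nt <- function(v) min(sum(v), n - sum(v)) >= 2L
    if (!ok_nt(x) || !ok_nt(y)) next
    fast <- splits_compatible(cbind(x, y))
    all_bin <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    slow <- any(vapply(all_bin, function(ph) {
      t <- phylo_to_stree(ph, rooted = FALSE)
      displays_split(t, list(taxa[x == 1L], taxa[x == 0L])) &&
        displays_split(t, list(taxa[y == 1L], taxa[y == 0L]))
    }, logical(1L)))
    expect_identical(fast, slow)
  }
})

test_that("rf distance is the symmetric split difference and a metric", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,c),(b,d));")
  expect_identical(rf_distance(t1, t1), 0L)
  expect_identical(rf_distance(t1, t2), 2L)
  star6 <- parse_newick("(a,b,c,d,e,f);")
  bin6 <- parse_newick("(((a,b),c),((d,e),f));")
  expect_identical(rf_distance(bin6, star6), 6L - 3L)
  expect_error(rf_distance(t1, parse_newick("((a,b),(c,e));")), "differ")
  # metric axioms on random triples, against phangorn as the oracle
  skip_if_not_installed("phangorn")
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:8, 1L)
    trees <- replicate(3, majplus:::random_binary_tree(letters[1:n], FALSE),
                       simplify = FALSE)
    d12 <- rf_distance(trees[[1]], trees[[2]])
    d13 <- rf_distance(trees[[1]], trees[[3]])
    d23 <- rf_distance(trees[[2]], trees[[3]])
    expect_identical(d12, rf_distance(trees[[2]], trees[[1]]))
    expect_true(d13 <= d12 + d23)
    ph <- lapply(trees, ape::as.phylo)
    expect_equal(d12, as.integer(phangorn::RF.dist(ph[[1]], ph[[2]])))
  }
})

test_that("trees rebuild from their split sets (round-trip)", {
  expect_identical(write_newick(tree_from_splits(
    matrix(c(1L, 1L, 0L, 0L), 4, 1, dimnames = list(letters[1:4], NULL)),
    letters[1:4])), "(a,b,(c,d));")
  expect_identical(ncol(tree_from_splits(NULL, letters[1:5])$mat), 0L)
  cat5 <- tree_from_splits(cbind(c(1L, 1L, 0L, 0L, 0L),
                                 c(1L, 1L, 1L, 0L, 0L)), letters[1:5])
  expect_identical(tree_keys(cat5), c("11000", "11100"))
  expect_error(tree_from_splits(cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L)),
                                letters[1:4]), "compatible")
  # property: splits(tree_from_splits(X)) == X for random compatible X
  set.seed(3)
  for (rep in 1:20) {
    rooted <- rep %% 2 == 0
    n <- sample(5:8, 1L)
    full <- majplus:::random_binary_tree(letters[1:n], rooted)
    pick <- sort(sample(ncol(full$mat), sample(ncol(full$mat), 1L)))
    sub <- full$mat[, pick, drop = FALSE]
    rebuilt <- tree_from_splits(sub, full$taxa, rooted = rooted)
    expect_identical(tree_keys(rebuilt),
                     sort(majplus:::split_keys(sub)))
  }
})

test_that("restriction commutes with split restriction", {
  set.seed(5)
  for (rep in 1:15) {
    rooted <- rep %% 2 == 0
    n <- sample(6:8, 1L)
    t <- majplus:::random_binary_tree(letters[1:n], rooted)
    s <- sort(sample(t$taxa, sample(3:(n - 1L), 1L)))
    direct <- restrict_tree(t, s)
    # restrict each split by hand, drop degenerate, dedupe
    sub <- t$mat[match(s, t$taxa), , drop = FALSE]
    sub <- majplus:::canonicalize_cols(sub, rooted)
    keep <- majplus:::nontrivial_cols(sub, rooted)
    manual <- unique(sort(majplus:::split_keys(sub[, keep, drop = FALSE])))
    expect_identical(tree_keys(direct), manual)
  }
})
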