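# shared fixtures and small utilities for the test-suite; everything is
# built in code, no data files

rp <- function(..., rooted = FALSE) read_profile(c(...), rooted = rooted)

tree_keys <- function(t) sort(majplus:::split_keys(t$mat))

expect_same_tree <- function(a, b) {
  expect_identical(a$taxa, b$taxa)
  expect_identical(tree_keys(a), tree_keys(b))
}

# a random profile drawn from the generator under a fixed seed, skipped
# (returns NULL) when its matrix exceeds the enumeration budget
small_random_profile <- function(seed, rooted, u_max = 14L,
                                 n_range = 5:7, k_range = 2:4,
                                 perturb = 1L) {
  set.seed(seed)
  g <- generate_profile(n_taxa = sample(n_range, 1L),
                        k_trees = sample(k_range, 1L),
                        deletion_probability = 0.35,
                        perturbation_count = perturb,
                        rooted = rooted, seed = seed)
  mx <- build_matrix(g$profile)
  if (mx$U > u_max) return(NULL)
  g$profile
}
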