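test_that("pairwise ML distance handles the degenerate and calibrated cases", {
  s <- fixture_sim$sim$alignment[1, ]
  expect_equal(ml_pairwise_distance(s, s, LG, CATS12)$distance, 0)
  # simulator round trip: true separation 0.3, long alignment
  t2 <- ape::read.tree(text = "(a:0.15,b:0.15);")
  sim <- evolve_alignment(t2, LG, CATS12, 20000, seed = 105)
  d <- ml_pairwise_distance(sim$alignment[1, ], sim$alignment[2, ],
                            LG, CATS12)
  expect_equal(d$distance, 0.3, tolerance = 0.02 / 0.3)
  expect_false(d$saturated)
  # a pathological pair with every site different and one shared pattern
  # direction drives the optimum to the bound
  a <- rep("A", 500); b <- rep("R", 500)
  sat <- ml_pairwise_distance(a, b, LG, CATS12)
  expect_true(sat$saturated)
  expect_equal(sat$distance, 10)
  expect_error(ml_pairwise_distance(c("-", "A"), c("A", "-"), LG, CATS12),
               "no shared")
})

test_that("grid distances agree with the exact one-dimensional optimiser", {
  grid <- distance_grid(LG, CATS12)
  d <- distance_matrix(fixture_sim$codes, grid)
  expect_equal(d$distance, t(d$distance))
  expect_equal(diag(d$distance), rep(0, 20), ignore_attr = TRUE)
  set.seed(11)
  for (i in 1:10) {
    p <- sample.int(20, 2)
    exact <- ml_pairwise_distance(fixture_sim$codes[p[1], ],
                                  fixture_sim$codes[p[2], ], LG, CATS12)
    expect_equal(d$distance[p[1], p[2]], exact$distance, tolerance = 5e-3)
  }
  # column weights replicate column multiplicity exactly
  w <- rep(1, ncol(fixture_sim$codes)); w[3] <- 5
  dup <- cbind(fixture_sim$codes,
               fixture_sim$codes[, rep(3, 4)])
  expect_equal(distance_matrix(fixture_sim$codes, grid, weights = w)$distance,
               distance_matrix(dup, grid)$distance, tolerance = 1e-8)
})

test_that("neighbor joining recovers additive distances exactly", {
  set.seed(13)
  for (rep in 1:3) {
    true <- random_unrooted_tree(5, seed = 300 + rep)
    est <- nj_tree(cophenetic(true))
    expect_equal(rf_distance(true, est)$rf, 0)
    expect_equal(sort(est$edge.length), sort(true$edge.length),
                 tolerance = 1e-9)
  }
  # three taxa: closed-form star lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  star <- nj_tree(d3)
  expect_equal(sort(star$edge.length), c(1, 2, 3))   # (3+4-5)/2 etc.
  # label-order invariance
  true <- random_unrooted_tree(8, seed = 44)
  D <- cophenetic(true)
  perm <- sample(8)
  est1 <- nj_tree(D); est2 <- nj_tree(D[perm, perm])
  expect_equal(rf_distance(est1, est2)$rf, 0)
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2, 2)), "non-finite|3 taxa")
})

test_that("bootstrap trees are deterministic and recover strong signal", {
  # strong signal: every internal branch >= 0.3
  tr <- random_topology(50, seed = 71)
  tr$edge.length <- ifelse(tr$edge[, 2] > 50,
                           runif(nrow(tr$edge), 0.3, 0.5),
                           runif(nrow(tr$edge), 0.05, 0.15))
  sim <- evolve_alignment(tr, LG, CATS1, 2000, seed = 72)
  bt <- bootstrap_trees(sim$alignment, 20, LG, CATS1, seed = 73)
  tab <- compatible_reference_bipartitions(tr, bt, threshold = 0.95)
  expect_gte(mean(tab$recovered), 47 / 47)   # every true split recovered
  # determinism
  b1 <- bootstrap_trees(fixture_sim$sim$alignment, 1, LG, CATS12, seed = 5)
  b2 <- bootstrap_trees(fixture_sim$sim$alignment, 1, LG, CATS12, seed = 5)
  expect_equal(b1$trees[[1]], b2$trees[[1]])
  # an alignment of identical columns resamples to itself
  const_cols <- fixture_sim$sim$alignment[, rep(7, 30)]
  grid <- distance_grid(LG, CATS12)
  point <- nj_tree(distance_matrix(const_cols, grid))
  bc <- bootstrap_trees(const_cols, 5, LG, CATS12, seed = 6, grid = grid)
  for (b in bc$trees)
    expect_equal(rf_distance(b, point)$rf, 0)
})

test_that("tree samples round-trip through multi-tree Newick", {
  bt <- bootstrap_trees(fixture_sim$sim$alignment, 3, LG, CATS12, seed = 8)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_sample(bt, path)
  expect_length(readLines(path), 3)
  back <- read_tree_sample(path)
  expect_equal(back$n_replicates, 3)
  expect_equal(back$method, "external")
  for (i in 1:3)
    expect_equal(rf_distance(back$trees[[i]], bt$trees[[i]])$rf, 0)
})

test_that("fixed-tree model selection recovers the generating model", {
  tr <- assign_branch_lengths(random_topology(30, seed = 21),
                              branch_length_prior(), seed = 22)
  simL <- evolve_alignment(tr, LG, CATS1, 3000, seed = 23)
  tabL <- select_model(simL$alignment, tr)
  expect_equal(nrow(tabL), 8)
  expect_equal(attr(tabL, "best"), "LG")
  simD <- evolve_alignment(tr, load_model("Dayhoff"), CATS1, 3000,
                           seed = 24)
  expect_match(attr(select_model(simD$alignment, tr), "best"), "^Dayhoff")
  # nested property: empirical frequencies equal to the defaults give the
  # same likelihood but a 19-parameter BIC penalty
  base <- score_model(simL$alignment, tr, LG)
  forced <- rate_model("LG", LG$exchangeabilities, LG$frequencies)
  same <- score_model(simL$alignment, tr, forced, use_empirical_freqs = FALSE)
  expect_equal(base$log_likelihood, same$log_likelihood)
  emp <- score_model(simL$alignment, tr, LG, use_empirical_freqs = TRUE)
  expect_equal(emp$n_parameters, 19)
  expect_equal(emp$bic, -2 * emp$log_likelihood + 19 * log(3000))
})

test_that("taxon subsampling shortens mean branch lengths", {
  tr <- assign_branch_lengths(random_topology(80, seed = 91),
                              branch_length_prior(), seed = 92)
  sim <- evolve_alignment(tr, LG, CATS1, 400, seed = 93)
  grid <- distance_grid(LG, CATS1)
  prof <- subsample_branch_profile(sim$alignment,
                                   fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                                   n_reps = 4, model = LG, cats = CATS1,
                                   seed = 94, grid = grid)
  expect_equal(nrow(prof), 5)
  # fraction 1 equals the full-data tree
  full <- nj_tree(distance_matrix(sim$alignment, grid))
  expect_equal(prof$mean_branch_length[prof$fraction == 1],
               mean(full$edge.length))
  # downward trend in sampling fraction
  expect_lte(cor(prof$fraction, prof$mean_branch_length,
                 method = "spearman"), 0)
  prof2 <- subsample_branch_profile(sim$alignment,
                                    fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                                    n_reps = 4, model = LG, cats = CATS1,
                                    seed = 94, grid = grid)
  expect_identical(prof, prof2)
  expect_warning(
    subsample_branch_profile(sim$alignment, fractions = 0.02, n_reps = 1,
                             model = LG, cats = CATS1, seed = 1,
                             grid = grid),
    "skipped")
})
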