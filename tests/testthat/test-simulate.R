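test_that("random topologies are uniform over the three 4-leaf trees", {
  # sequential uniform-edge attachment gives each labelled unrooted binary
  # topology probability 1/(2n-5)!!; at n = 4 that is 1/3 per topology
  keys <- vapply(1:3000, function(s) {
    tr <- random_topology(4, seed = s)
    bipartitions(tr)$key
  }, character(1))
  freq <- table(keys) / 3000
  expect_length(freq, 3)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("topologies have the right shape and are reproducible", {
  tr <- random_topology(1000, seed = 9)
  expect_equal(length(tr$tip.label), 1000)
  expect_equal(tr$Nnode, 998)
  expect_equal(nrow(tr$edge), 2 * 1000 - 3)
  expect_equal(sum(tr$edge[, 2] > 1000), 1000 - 3)   # internal edges
  expect_identical(random_topology(10, seed = 4)$edge,
                   random_topology(10, seed = 4)$edge)
  expect_error(random_topology(3, seed = 1), ">= 4")
})

test_that("branch lengths follow the internal/terminal gamma priors", {
  prior <- branch_length_prior()
  topo <- random_topology(1000, seed = 10)
  # pool three independent draws so the Monte-Carlo error of the mean
  # (~2% at ~3000 internal branches) sits well inside the 5% band
  draws <- lapply(11:13, function(s) assign_branch_lengths(topo, prior,
                                                           seed = s))
  tr <- draws[[1]]
  ntip <- 1000
  internal <- unlist(lapply(draws, function(d)
    d$edge.length[d$edge[, 2] > ntip]))
  terminal <- unlist(lapply(draws, function(d)
    d$edge.length[d$edge[, 2] <= ntip]))
  expect_length(internal, 3 * 997)
  expect_equal(mean(internal),
               prior$internal_shape * prior$internal_scale,
               tolerance = 0.05)
  expect_equal(mean(terminal),
               prior$terminal_shape * prior$terminal_scale,
               tolerance = 0.05)
  # scale calibration: sample medians near the targets
  expect_equal(median(internal), 0.05, tolerance = 0.1)
  expect_equal(median(terminal), 0.10, tolerance = 0.1)
  # gamma-median oracle via the quantile function
  expect_equal(qgamma(0.5, prior$internal_shape,
                      scale = prior$internal_scale), 0.05,
               tolerance = 1e-10)
  tr2 <- assign_branch_lengths(topo, prior, seed = 11)
  expect_identical(tr$edge.length, tr2$edge.length)
})

test_that("evolution on a zero-length tree copies the root sequence", {
  t2 <- ape::read.tree(text = "(a:0,b:0);")
  sim <- evolve_alignment(t2, LG, CATS1, 2000, seed = 5)
  expect_identical(sim$alignment["a", ], sim$alignment["b", ])
  expect_false(any(sim$alignment == "-"))
})

test_that("simulated residue frequencies converge to the model equilibrium", {
  t2 <- ape::read.tree(text = "(a:0.1,b:0.1);")
  sim <- evolve_alignment(t2, LG, CATS1, 50000, seed = 6)
  freqs <- aa_frequencies(sim$alignment)$frequencies
  expect_true(all(abs(freqs - LG$frequencies) < 0.01))
})

test_that("per-category divergence matches the closed-form p-distance", {
  t2 <- ape::read.tree(text = "(a:0.15,b:0.15);")
  sim <- evolve_alignment(t2, LG, CATS12, 50000, seed = 7)
  codes <- encode_alignment(sim$alignment)
  pdist <- vapply(1:12, function(c) {
    s <- sim$true_categories == c
    mean(codes[1, s] != codes[2, s])
  }, numeric(1))
  # expected: 1 - sum_i pi_i P_ii(r_c * t), t = 0.3 total
  expected <- vapply(CATS12$rates, function(r)
    1 - sum(LG$frequencies * diag(transition_probabilities(LG, 0.3, r))),
    numeric(1))
  n_c <- tabulate(sim$true_categories, 12)
  expect_true(all(abs(pdist - expected) <
                    4 * sqrt(expected * (1 - expected) / n_c) + 1e-9))
  expect_true(all(diff(pdist) > -0.01))   # monotone up to Monte-Carlo noise
})

test_that("simulation is deterministic and serialisable", {
  s1 <- evolve_alignment(fixture_sim$tree, LG, CATS12, 100, seed = 12)
  s2 <- evolve_alignment(fixture_sim$tree, LG, CATS12, 100, seed = 12)
  expect_identical(s1$alignment, s2$alignment)
  expect_identical(s1$true_categories, s2$true_categories)
  dir <- withr::local_tempdir()
  paths <- write_simulation(s1, dir)
  expect_true(all(file.exists(paths)))
  back <- read_alignment(paths[1])
  expect_identical(back, s1$alignment)
  cats_tab <- read.table(paths[3], header = TRUE, sep = "\t")
  expect_identical(cats_tab$category, s1$true_categories)
  tre <- ape::read.tree(paths[2])
  expect_equal(sort(tre$tip.label), sort(fixture_sim$tree$tip.label))
})

test_that("saturation profile is tree length times category rate", {
  tl <- sum(fixture_sim$tree$edge.length)
  prof <- saturation_profile(fixture_sim$sim, CATS12)
  expect_equal(prof, tl * CATS12$rates)
  expect_true(all(diff(prof) > 0))
})
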