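test_that("bipartition extraction yields one canonical split per internal edge", {
  quartet <- ape::read.tree(text = "((A,B),(C,D));")
  b <- bipartitions(quartet)
  expect_equal(nrow(b), 1)
  expect_equal(b$key, "1,2")   # A,B vs C,D in sorted taxon order
  big <- random_unrooted_tree(30, seed = 51)
  expect_equal(nrow(bipartitions(big)), 27)   # n - 3
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  expect_equal(nrow(bipartitions(star)), 0)   # multifurcation contributes none
  expect_error(bipartitions(ape::read.tree(text = "(A,B,C);")), "4 leaves")
})

test_that("RF distance equals brute-force symmetric difference and behaves as a metric", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1)$rf, 0)
  expect_equal(rf_distance(t1, t2)$rf, 2)
  expect_equal(rf_distance(t1, t2)$normalized, 1)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "E")
  set.seed(19)
  trees <- lapply(1:6, function(i) random_unrooted_tree(8, seed = 500 + i))
  for (i in 1:5) for (j in (i + 1):6) {
    mine <- rf_distance(trees[[i]], trees[[j]])$rf
    expect_equal(mine, brute_force_rf(trees[[i]], trees[[j]]))
    expect_equal(mine, as.numeric(
      phangorn::RF.dist(trees[[i]], trees[[j]])))
    expect_equal(mine, rf_distance(trees[[j]], trees[[i]])$rf)  # symmetry
  }
  # triangle inequality over sampled triples
  for (trip in list(c(1, 2, 3), c(2, 4, 6), c(1, 5, 6))) {
    d12 <- rf_distance(trees[[trip[1]]], trees[[trip[2]]])$rf
    d13 <- rf_distance(trees[[trip[1]]], trees[[trip[3]]])$rf
    d23 <- rf_distance(trees[[trip[2]]], trees[[trip[3]]])$rf
    expect_lte(d13, d12 + d23)
  }
})

test_that("support frequencies count splits across the sample", {
  base <- random_unrooted_tree(8, seed = 61)
  other <- random_unrooted_tree(8, seed = 62)
  trees <- c(rep(list(base), 8), rep(list(other), 2))
  supp <- support_frequencies(trees)
  base_keys <- bipartitions(base)$key
  other_only <- setdiff(bipartitions(other)$key, base_keys)
  expect_true(all(supp[setdiff(base_keys, bipartitions(other)$key)] == 0.8))
  expect_true(all(supp[other_only] == 0.2))
  # double-counting identity: total support mass equals mean split count
  expect_equal(sum(supp) * length(trees),
               sum(vapply(trees, function(tr) nrow(bipartitions(tr)),
                          numeric(1))))
  # identical trees give support 1 everywhere
  supp1 <- support_frequencies(rep(list(base), 5))
  expect_true(all(supp1 == 1))
})

test_that("reference recovery respects the support threshold", {
  ref <- random_unrooted_tree(10, seed = 71)
  tab <- compatible_reference_bipartitions(ref, rep(list(ref), 7))
  expect_true(all(tab$recovered))
  expect_equal(tab$support, rep(1, 7))
  expect_equal(sort(tab$length),
               sort(bipartitions(ref)$length))
  deviant <- random_unrooted_tree(10, seed = 72)
  tab2 <- compatible_reference_bipartitions(
    ref, c(rep(list(ref), 9), list(deviant)), threshold = 1)
  missing_keys <- setdiff(bipartitions(ref)$key, bipartitions(deviant)$key)
  expect_true(all(!tab2$recovered[tab2$key %in% missing_keys]))
  expect_true(all(tab2$recovered[!tab2$key %in% missing_keys]))
})

test_that("recovery statistics summarise hand-built tables correctly", {
  # partition A recovers only the 2 longest of 4 splits, partition B all 4,
  # partition C all 4 (third partition needed for the correlation)
  lens <- c(0.1, 0.2, 0.3, 0.4)
  mk <- function(p, rate, rec) data.frame(
    partition = p, mean_rate = rate, key = paste0("k", 1:4),
    length = lens, support = ifelse(rec, 1, 0), recovered = rec)
  tables <- rbind(mk("A", 0.1, c(FALSE, FALSE, TRUE, TRUE)),
                  mk("B", 1.0, rep(TRUE, 4)),
                  mk("C", 2.0, rep(TRUE, 4)))
  st <- recovery_statistics(tables)
  per <- st$per_partition
  expect_equal(per$below_median_recovery[per$partition == "A"], 0)
  expect_equal(per$below_median_recovery[per$partition == "B"], 1)
  expect_equal(per$top_quartile_recovery, rep(1, 3))  # 0.4 recovered by all
  expect_equal(per$median_recovered_length[per$partition == "A"], 0.35)
  # all-recovered degenerate case: constant medians give missing rho
  all_rec <- rbind(mk("A", 0.1, rep(TRUE, 4)), mk("B", 1, rep(TRUE, 4)),
                   mk("C", 2, rep(TRUE, 4)))
  st2 <- recovery_statistics(all_rec)
  expect_true(is.na(st2$rho_median))
  expect_error(recovery_statistics(tables[tables$partition == "A", ]),
               "3 partitions")
})

test_that("OLS slope of RF on rate matches closed forms", {
  expect_equal(rf_slope(c(5, 5, 5), c(1, 2, 3)), 0)
  expect_equal(rf_slope(c(10, 20), c(1, 2)), 10)
  set.seed(23)
  x <- runif(6); y <- 3 - 7 * x + rnorm(6, 0, 0.1)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(rf_slope(y, x), beta, tolerance = 1e-12)
  expect_equal(rf_slope(y, x, category_range = 2:4),
               rf_slope(y[2:4], x[2:4]))
  expect_error(rf_slope(5, 1), "2 categories")
})

test_that("classical MDS embeds Euclidean metrics exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
  xy <- mds_embedding(d)
  expect_equal(as.matrix(dist(xy)), unname(as.matrix(d)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # duplicated point lands on identical coordinates
  d4 <- rbind(cbind(d, d[, 3]), c(d[3, ], 0))
  xy4 <- mds_embedding(d4)
  expect_equal(xy4[3, ], xy4[4, ], tolerance = 1e-9)
  expect_equal(mds_embedding(matrix(0, 4, 4)), matrix(0, 4, 2),
               ignore_attr = TRUE)
  # eigen-truncation: 2-D embedding never stretches Euclidean-embeddable
  # distances
  set.seed(29)
  pts <- matrix(rnorm(7 * 5), 7, 5)
  D <- as.matrix(dist(pts))
  emb <- as.matrix(dist(mds_embedding(D)))
  expect_true(all(emb <= D + 1e-9))
  expect_error(mds_embedding(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("BH q-values are monotone in p and bounded by one", {
  set.seed(31)
  p <- runif(40)^2
  q <- bh_qvalues(p)
  expect_true(all(q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_equal(bh_qvalues(p), p.adjust(p, "BH"))
})

test_that("pairwise RF matrices feed the MDS front end", {
  trees <- lapply(1:5, function(i) random_unrooted_tree(10, seed = 600 + i))
  m <- rf_matrix(trees)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 5))
  expect_equal(m[1, 2], rf_distance(trees[[1]], trees[[2]])$rf)
  mn <- rf_matrix(trees, normalized = TRUE)
  expect_true(all(mn >= 0 & mn <= 1))
  xy <- mds_embedding(m)
  expect_equal(dim(xy), c(5, 2))
})
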