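test_that("built-in models satisfy the reversible-CTMC invariants", {
  for (name in c("LG", "WAG", "Dayhoff", "JTT")) {
    m <- load_model(name)
    expect_equal(sum(m$frequencies), 1, tolerance = 1e-12)
    expect_true(all(m$frequencies >= 0))
    expect_lt(max(abs(rowSums(m$generator))), 1e-10)
    expect_equal(-sum(m$frequencies * diag(m$generator)), 1,
                 tolerance = 1e-10)
    flux <- m$frequencies * m$generator   # pi_i Q_ij
    expect_lt(max(abs(flux - t(flux))), 1e-10)
    expect_true(all(m$exchangeabilities >= 0))
    expect_equal(diag(m$exchangeabilities), rep(0, 20),
                 ignore_attr = TRUE)
  }
})

test_that("unknown model names are rejected", {
  expect_error(load_model("C60"), "unsupported")
  expect_error(load_model(42), "unsupported")
})

test_that("frequency override renormalises the generator to unit mean rate", {
  lg <- load_model("LG")
  uni <- load_model("LG", frequencies = rep(0.05, 20))
  expect_equal(-sum(uni$frequencies * diag(uni$generator)), 1,
               tolerance = 1e-10)
  # independent recomputation of the scaling constant from the
  # exchangeability table: mu = sum_i pi_i sum_{j != i} s_ij pi_j
  ex <- lg$exchangeabilities
  mu <- sum(0.05 * (ex %*% rep(0.05, 20)))
  Q_manual <- ex * 0.05
  diag(Q_manual) <- -rowSums(Q_manual)
  expect_equal(uni$generator, Q_manual / mu, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("PAML .dat files round-trip through the parser", {
  # synthetic exchangeabilities and frequencies, written in PAML layout
  # (19 lower-triangle rows then frequencies) by the test itself
  ex <- outer(1:20, 1:20, function(i, j) (i + j) / 10)
  diag(ex) <- 0
  freqs <- (1:20) / sum(1:20)
  lines <- vapply(2:20, function(i)
    paste(sprintf("%.6f", ex[i, 1:(i - 1)]), collapse = " "), character(1))
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(lines, "", paste(sprintf("%.8f", freqs), collapse = " ")),
             path)
  m <- read_paml_dat(path, name = "toy")
  expect_equal(unname(m$exchangeabilities), ex, tolerance = 1e-5)
  expect_equal(unname(m$frequencies), freqs, tolerance = 1e-6)
  expect_equal(-sum(m$frequencies * diag(m$generator)), 1, tolerance = 1e-10)
})

test_that("transition probabilities match a matrix-exponential oracle and CTMC limits", {
  lg <- load_model("LG")
  expect_equal(transition_probabilities(lg, 0, 1), diag(20),
               ignore_attr = TRUE, tolerance = 1e-12)
  # independent oracle: Matrix::expm of the generator
  for (t in c(0.05, 0.5, 2)) {
    P <- transition_probabilities(lg, t, 1.3)
    expect_equal(P, as.matrix(Matrix::expm(lg$generator * t * 1.3)),
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(rowSums(P), rep(1, 20), ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
  expect_equal(transition_probabilities(lg, 0.5, 2),
               transition_probabilities(lg, 1, 1), tolerance = 1e-12)
  Pinf <- transition_probabilities(lg, 1e6, 1)
  expect_lt(max(abs(t(Pinf) - lg$frequencies)), 1e-6)
  expect_error(transition_probabilities(lg, -1, 1), "non-negative")
  expect_error(transition_probabilities(lg, 1, 0), "positive")
})

test_that("gamma discretization matches closed forms and a numerical-integration oracle", {
  expect_equal(discretize_gamma(0.7, 1)$rates, 1)
  # unit exponential, two bins: conditional means 2 - (1 + log 2) and
  # 1 + log 2 - (1 - log 2) ... = closed-form tail integrals
  expect_equal(discretize_gamma(1, 2)$rates,
               c(2 * (1 - (1 + log(2)) / 2), 2 * ((1 + log(2)) / 2)),
               tolerance = 1e-12)
  numint <- function(alpha, k) {
    edges <- qgamma((0:k) / k, alpha, alpha)
    sapply(seq_len(k), function(i)
      integrate(function(x) x * dgamma(x, alpha, alpha),
                edges[i], edges[i + 1], rel.tol = 1e-10)$value * k)
  }
  for (a in c(0.25, 0.803, 1, 2, 5)) for (k in c(1, 2, 4, 12)) {
    g <- discretize_gamma(a, k)
    expect_equal(g$rates, numint(a, k), tolerance = 1e-6)
    expect_equal(mean(g$rates), 1, tolerance = 1e-9)
    expect_true(all(diff(g$rates) > 0) || k == 1)
    expect_true(all(g$rates > 0))
  }
  expect_error(discretize_gamma(-1, 4), "positive")
  expect_error(discretize_gamma(1, 0), "positive integer")
})

test_that("expected substitutions reproduce the short-branch worked arithmetic", {
  g <- discretize_gamma(0.803, 12)
  slow <- expected_substitutions(0.05, 2596, 12, g$rates[1])
  fast <- expected_substitutions(0.05, 2596, 12, g$rates[12])
  expect_equal(slow$total, 129.8)
  expect_equal(round(slow$count, 2), 0.25)
  expect_equal(round(fast$count, 2), 41.36)
  expect_equal(100 * slow$fraction, 0.194, tolerance = 0.005)
  expect_equal(100 * fast$fraction, 31.86, tolerance = 0.02)
  # fraction independent of branch length
  expect_equal(expected_substitutions(0.7, 2596, 12, g$rates[3])$fraction,
               expected_substitutions(0.001, 2596, 12, g$rates[3])$fraction)
  # a category at k times the mean carries all expected substitutions
  expect_equal(expected_substitutions(0.3, 1000, 8, 8)$fraction, 1)
  # conservation: summing over the k category rates gives N * L
  counts <- sapply(g$rates, function(r)
    expected_substitutions(0.12, 2596, 12, r)$count)
  expect_equal(sum(counts), 2596 * 0.12, tolerance = 1e-9)
  expect_error(expected_substitutions(-0.1, 10, 2, 1), "positive")
})
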