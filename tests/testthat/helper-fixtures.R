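# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; no data files.

LG <- load_model("LG")
CATS12 <- discretize_gamma(0.803, 12)
CATS1 <- discretize_gamma(1, 1)

# A mid-sized simulation reused across test files: 20 taxa, 600 sites.
fixture_sim <- local({
  tree <- assign_branch_lengths(random_topology(20, seed = 401),
                                branch_length_prior(), seed = 402)
  sim <- evolve_alignment(tree, LG, CATS12, 600, seed = 403)
  list(tree = tree, sim = sim, codes = encode_alignment(sim$alignment))
})

# Exhaustive-enumeration site likelihood: sums the CTMC probability over
# every assignment of states to internal nodes. Independent of the pruning
# code path (only transition_probabilities is shared).
brute_force_site_loglik <- function(tree, codes_site, model, rate = 1) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nn <- tr$Nnode
  Ps <- lapply(seq_len(nrow(tr$edge)), function(e)
    transition_probabilities(model, tr$edge.length[e], rate))
  root <- tr$edge[1, 1]
  internals <- ntip + seq_len(nn)
  grid <- do.call(expand.grid, rep(list(1:20), nn))
  x <- codes_site[tr$tip.label]
  tot <- 0
  for (gi in seq_len(nrow(grid))) {
    st <- rep(NA_integer_, ntip + nn)
    st[internals] <- as.integer(grid[gi, ])
    p <- unname(model$frequencies[st[root]])
    for (e in seq_len(nrow(tr$edge))) {
      a <- st[tr$edge[e, 1]]
      ch <- tr$edge[e, 2]
      p <- p * if (ch <= ntip) {
        if (is.na(x[ch])) 1 else Ps[[e]][a, x[ch]]
      } else Ps[[e]][a, st[ch]]
    }
    tot <- tot + p
  }
  log(tot)
}

# Brute-force RF: symmetric difference of bipartition sets enumerated
# directly from tip descendants of each internal edge, without the
# package's canonical-key machinery.
brute_force_rf <- function(t1, t2) {
  splits <- function(tr) {
    taxa <- sort(tr$tip.label)
    ntip <- length(tr$tip.label)
    out <- character(0)
    for (e in which(tr$edge[, 2] > ntip)) {
      tips <- ape::extract.clade(tr, tr$edge[e, 2])$tip.label
      side <- sort(match(tips, taxa))
      if (length(side) < 2 || length(side) > ntip - 2) next
      if (!(1 %in% side)) side <- setdiff(seq_len(ntip), side)
      out <- c(out, paste(sort(side), collapse = "-"))
    }
    unique(out)
  }
  s1 <- splits(t1); s2 <- splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

random_unrooted_tree <- function(n, seed) {
  tr <- random_topology(n, seed = seed)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr
}
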