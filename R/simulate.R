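# Seed fan-out: one master seed deterministically derives independent
# per-stage, per-index seeds so sub-experiments can be rerun in isolation.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((abs(master) + 10007 * stage + 7919 * index) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random unrooted binary topology by sequential attachment
#'
#' Starts from the unique 3-leaf unrooted tree and grafts each further leaf
#' onto a uniformly chosen existing edge. Every labelled unrooted binary
#' topology is generated with equal probability under this scheme.
#'
#' @param n_leaves number of leaves (>= 4).
#' @param seed RNG seed.
#' @param labels optional leaf labels (default `t1..tn`).
#' @return unrooted `ape::phylo` topology without branch lengths.
#' @export
random_topology <- function(n_leaves, seed = NULL, labels = NULL) {
  if (!is.numeric(n_leaves) || length(n_leaves) != 1L || n_leaves < 4 ||
      n_leaves != round(n_leaves))
    stop("n_leaves must be an integer >= 4")
  n <- as.integer(n_leaves)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))

  build <- function() {
    # Node numbering follows ape: tips 1..n, internals n+1 .. 2n-2.
    # Start with the star on leaves 1..3 around internal node n+1.
    n_edges <- 2L * n - 3L
    parent <- integer(n_edges)
    child <- integer(n_edges)
    parent[1:3] <- n + 1L
    child[1:3] <- 1:3
    m <- 3L                 # edges so far
    next_internal <- n + 2L
    for (leaf in 4:n) {
      e <- sample.int(m, 1L)
      v <- next_internal
      next_internal <- next_internal + 1L
      # split edge e: parent[e] -> v -> old child; attach leaf to v
      old_child <- child[e]
      child[e] <- v
      m <- m + 1L; parent[m] <- v; child[m] <- old_child
      m <- m + 1L; parent[m] <- v; child[m] <- leaf
    }
    structure(list(edge = cbind(parent, child, deparse.level = 0),
                   tip.label = labels, Nnode = n - 2L),
              class = "phylo")
  }
  tr <- if (is.null(seed)) build() else with_seed(seed, build())
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Gamma prior on internal and terminal branch lengths
#'
#' Shapes default to those of the package's reference simulation design
#' (internal 0.7581720, terminal 1.509421). Scales are calibrated from the
#' target medians (default 0.05 substitutions/site internal, 0.10 terminal)
#' via the gamma quantile function, unless given explicitly.
#'
#' @param internal_shape,terminal_shape gamma shapes (> 0).
#' @param internal_scale,terminal_scale gamma scales (substitutions/site);
#'   if `NULL`, derived from the medians.
#' @param internal_median,terminal_median target median branch lengths used
#'   to calibrate the scales.
#' @return list of class `branch_length_prior`.
#' @export
branch_length_prior <- function(internal_shape = 0.7581720,
                                terminal_shape = 1.509421,
                                internal_scale = NULL,
                                terminal_scale = NULL,
                                internal_median = 0.05,
                                terminal_median = 0.10) {
  if (is.null(internal_scale))
    internal_scale <- internal_median / stats::qgamma(0.5, internal_shape)
  if (is.null(terminal_scale))
    terminal_scale <- terminal_median / stats::qgamma(0.5, terminal_shape)
  p <- list(internal_shape = internal_shape, terminal_shape = terminal_shape,
            internal_scale = internal_scale, terminal_scale = terminal_scale)
  if (any(!vapply(p, function(x) is.numeric(x) && x > 0, logical(1))))
    stop("all branch-length prior parameters must be positive")
  structure(p, class = "branch_length_prior")
}

#' Assign gamma-distributed branch lengths to a tree
#'
#' Terminal (leaf-incident) and internal edges are drawn independently from
#' the prior's two gamma distributions.
#'
#' @param tree `phylo` topology; existing branch lengths are overwritten.
#' @param prior [branch_length_prior()].
#' @param seed RNG seed.
#' @return `phylo` with positive `edge.length`.
#' @export
assign_branch_lengths <- function(tree, prior = branch_length_prior(),
                                  seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(prior, "branch_length_prior"))
  ntip <- length(tree$tip.label)
  is_terminal <- tree$edge[, 2] <= ntip
  draw <- function() {
    el <- numeric(nrow(tree$edge))
    el[is_terminal] <- stats::rgamma(sum(is_terminal),
                                     shape = prior$terminal_shape,
                                     scale = prior$terminal_scale)
    el[!is_terminal] <- stats::rgamma(sum(!is_terminal),
                                      shape = prior$internal_shape,
                                      scale = prior$internal_scale)
    pmax(el, 1e-9)
  }
  tree$edge.length <- if (is.null(seed)) draw() else with_seed(seed, draw())
  tree
}

#' Evolve an amino-acid alignment along a tree
#'
#' Simulates sites independently under the reversible model with
#' discrete-gamma rate heterogeneity: each site draws a rate category
#' uniformly from the `k` equiprobable categories (the true category is
#' recorded), the root state is drawn from the model's equilibrium
#' frequencies, and states are propagated from the root to the tips with
#' the transition probabilities of each branch at the site's category rate.
#' No indels and no invariant class: the output alignment is gap-free,
#' though sites may happen to be constant by chance.
#'
#' @param tree `phylo` with branch lengths.
#' @param model `rate_model`.
#' @param cats `gamma_categories`.
#' @param n_sites number of sites (>= 1).
#' @param seed RNG seed.
#' @return object of class `simulation_result`: list with `tree`,
#'   `alignment` (character matrix), `true_categories` (integer vector),
#'   `seed`.
#' @export
evolve_alignment <- function(tree, model, cats, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "rate_model"),
            inherits(cats, "gamma_categories"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths on every edge")
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1)
    stop("n_sites must be >= 1")
  n_sites <- as.integer(n_sites)
  k <- cats$n_categories

  run <- function() {
    cat_idx <- sample.int(k, n_sites, replace = TRUE)
    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    tr <- ape::reorder.phylo(tree, "cladewise")  # parent precedes child
    root <- tr$edge[1, 1]
    states <- matrix(NA_integer_, ntip + nnode, n_sites)
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                                 prob = model$frequencies)
    sites_by_cat <- split(seq_len(n_sites), factor(cat_idx, levels = seq_len(k)))
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
      for (c in seq_len(k)) {
        sites <- sites_by_cat[[c]]
        if (!length(sites)) next
        P <- transition_probabilities(model, t, cats$rates[c])
        ps <- states[p, sites]
        for (a in unique(ps)) {
          ss <- sites[ps == a]
          states[ch, ss] <- sample.int(20L, length(ss), replace = TRUE,
                                       prob = P[a, ])
        }
      }
    }
    aln <- matrix(AA_ORDER[states[seq_len(ntip), , drop = FALSE]],
                  ntip, n_sites)
    rownames(aln) <- tr$tip.label
    list(alignment = aln, true_categories = cat_idx)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(tree = tree, alignment = out$alignment,
                 true_categories = out$true_categories,
                 model = model$name, alpha = cats$alpha,
                 k = k, seed = seed),
            class = "simulation_result")
}

#' Per-category saturation diagnostic of a simulation
#'
#' Expected substitutions per site accumulated tree-wide by each rate
#' category: total tree length times the category rate multiplier.
#'
#' @param result `simulation_result`.
#' @param cats `gamma_categories` used in the simulation.
#' @return numeric k-vector.
#' @export
saturation_profile <- function(result, cats) {
  stopifnot(inherits(result, "simulation_result"),
            inherits(cats, "gamma_categories"))
  sum(result$tree$edge.length) * cats$rates
}

#' Write a simulation to disk
#'
#' Writes the alignment (FASTA), the true tree (Newick, with branch
#' lengths), and the per-site true categories (TSV: `site`, `category`,
#' 1-based sites).
#'
#' @param result `simulation_result`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_simulation <- function(result, dir, prefix = "sim") {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".fasta", ".nwk", "_categories.tsv")))
  write_alignment(result$alignment, paths[1])
  ape::write.tree(result$tree, paths[2])
  write_tsv(data.frame(site = seq_along(result$true_categories),
                       category = result$true_categories), paths[3])
  invisible(paths)
}
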