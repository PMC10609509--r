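# Felsenstein pruning, vectorised over sites.
#
# Computes per-site log-likelihoods of an alignment under a fixed tree and a
# reversible model, at one or more rate multipliers. Gaps/ambiguities are
# missing data (all-ones tip partials). Underflow is handled by rescaling
# the partial-likelihood columns at every internal node and accumulating the
# log scale factors per site.

col_max20 <- function(m) {
  mx <- m[1, ]
  for (i in 2:20) mx <- pmax(mx, m[i, ])
  mx
}

#' Per-site log-likelihoods under a fixed tree
#'
#' @param alignment character matrix or coercible object; rows must cover
#'   all tree leaves (extra rows are ignored).
#' @param tree `phylo` with branch lengths; rooted or unrooted (the
#'   likelihood is root-invariant for reversible models).
#' @param model `rate_model`.
#' @param rates numeric vector of rate multipliers (> 0).
#' @return numeric matrix, `n_sites` x `length(rates)`, of per-site
#'   log-likelihoods.
#' @export
site_log_likelihoods <- function(alignment, tree, model, rates = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "rate_model"))
  if (any(rates <= 0)) stop("rates must be positive")
  codes <- if (is.matrix(alignment) && is.integer(alignment)) alignment
           else encode_alignment(alignment)
  miss <- setdiff(tree$tip.label, rownames(codes))
  if (length(miss))
    stop("tree leaves missing from alignment: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  if (ntip == 1L) {
    x <- codes[tree$tip.label[1], ]
    ll <- ifelse(is.na(x), 0, log(model$frequencies)[x])
    return(matrix(rep(ll, length(rates)), ncol = length(rates)))
  }
  codes <- codes[tree$tip.label, , drop = FALSE]
  S <- ncol(codes)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  n_children <- tabulate(tr$edge[, 1], nbins = ntip + nnode)

  out <- matrix(NA_real_, S, length(rates))
  for (ri in seq_along(rates)) {
    partial <- vector("list", ntip + nnode)
    scale_log <- numeric(S)
    remaining <- n_children
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      P <- transition_probabilities(model, tr$edge.length[e], rates[ri])
      if (ch <= ntip) {
        # contrib[a, s] = P[a, x_s] (prob. of the observed tip state given
        # parent state a); missing data -> ones
        contrib <- matrix(1, 20L, S)
        x <- codes[ch, ]
        ok <- which(!is.na(x))
        if (length(ok)) contrib[, ok] <- P[, x[ok], drop = FALSE]
      } else {
        contrib <- P %*% partial[[ch]]
        partial[ch] <- list(NULL)
      }
      partial[[p]] <- if (is.null(partial[[p]])) contrib
                      else partial[[p]] * contrib
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L && p != root) {
        mx <- col_max20(partial[[p]])
        mx[mx == 0] <- 1
        partial[[p]] <- partial[[p]] / rep(mx, each = 20L)
        scale_log <- scale_log + log(mx)
      }
    }
    lik <- colSums(model$frequencies * partial[[root]])
    out[, ri] <- log(lik) + scale_log
  }
  out
}

#' Log-likelihood of a single alignment site
#'
#' Convenience wrapper around [site_log_likelihoods()] for one site and one
#' rate multiplier.
#'
#' @param alignment character matrix or coercible object.
#' @param site 1-based column index.
#' @param tree `phylo` with branch lengths.
#' @param model `rate_model`.
#' @param rate rate multiplier (> 0).
#' @return scalar log-likelihood.
#' @export
site_log_likelihood <- function(alignment, site, tree, model, rate = 1) {
  alignment <- if (is.matrix(alignment) && is.integer(alignment)) alignment
               else encode_alignment(alignment)
  stopifnot(site >= 1, site <= ncol(alignment))
  site_log_likelihoods(alignment[, site, drop = FALSE], tree, model, rate)[1, 1]
}
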