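#' Reversible amino-acid substitution models
#'
#' A `rate_model` bundles a symmetric exchangeability matrix, equilibrium
#' frequencies, and the resulting generator Q, normalised so that the
#' expected number of substitutions per site per unit time is 1
#' (\eqn{-\sum_i \pi_i Q_{ii} = 1}). The eigendecomposition of the
#' symmetrised generator is precomputed and stored, so transition
#' probabilities at arbitrary times are two 20x20 products.
#'
#' @param name one of `"LG"`, `"WAG"`, `"Dayhoff"`, `"JTT"`.
#' @param frequencies optional 20-vector of equilibrium frequencies in PAML
#'   residue order, replacing the model's default frequencies (the `+F`
#'   behaviour); renormalised to sum to 1 and the generator rescaled to unit
#'   mean rate.
#' @return an object of class `rate_model` with elements `name`,
#'   `exchangeabilities` (20x20 symmetric, zero diagonal), `frequencies`,
#'   `generator`, and the cached spectral decomposition.
#' @examples
#' lg <- load_model("LG")
#' -sum(lg$frequencies * diag(lg$generator))  # 1
#' @export
load_model <- function(name, frequencies = NULL) {
  supported <- c("LG", "WAG", "Dayhoff", "JTT")
  if (!is.character(name) || length(name) != 1L || !(name %in% supported)) {
    stop("unsupported model '", paste(name, collapse = ","),
         "'; supported: ", paste(supported, collapse = ", "))
  }
  tab <- get(paste0(".", name), envir = asNamespace("phangorn"))
  ex <- lower_triangle_to_matrix(tab$Q)
  freqs <- if (is.null(frequencies)) unname(tab$bf) else frequencies
  rate_model(name, ex, freqs)
}

#' Construct a rate model from exchangeabilities and frequencies
#'
#' @param name model identifier (free-form for user models).
#' @param exchangeabilities symmetric 20x20 non-negative matrix, zero
#'   diagonal.
#' @param frequencies 20-vector of equilibrium frequencies (renormalised).
#' @return `rate_model` object; see [load_model()].
#' @export
rate_model <- function(name, exchangeabilities, frequencies) {
  ex <- as.matrix(exchangeabilities)
  if (!isTRUE(all.equal(dim(ex), c(20L, 20L))))
    stop("exchangeabilities must be 20x20")
  if (max(abs(ex - t(ex))) > 1e-10) stop("exchangeabilities must be symmetric")
  if (any(ex < 0)) stop("exchangeabilities must be non-negative")
  diag(ex) <- 0
  freqs <- as.numeric(frequencies)
  if (length(freqs) != 20L || any(freqs < 0))
    stop("frequencies must be a non-negative 20-vector")
  freqs <- freqs / sum(freqs)
  if (any(freqs <= 0))
    stop("zero equilibrium frequencies are not supported")

  Q <- ex * rep(freqs, each = 20L)   # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))        # expected substitutions per unit time
  Q <- Q / mu

  # Symmetrise: B = Pi^(1/2) Q Pi^(-1/2) is symmetric for reversible Q.
  sq <- sqrt(freqs)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  # P(t) = Pi^(-1/2) U exp(L t) U' Pi^(1/2)
  left <- es$vectors / sq            # Pi^(-1/2) U
  right <- t(es$vectors * sq)        # U' Pi^(1/2)

  dimnames(Q) <- dimnames(ex) <- list(AA_ORDER, AA_ORDER)
  names(freqs) <- AA_ORDER
  structure(
    list(name = name, exchangeabilities = ex, frequencies = freqs,
         generator = Q, eigenvalues = es$values, left = left, right = right),
    class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Reversible amino-acid substitution model:", x$name, "\n")
  cat("  unit mean rate: ", format(-sum(x$frequencies * diag(x$generator))),
      "\n", sep = "")
  invisible(x)
}

lower_triangle_to_matrix <- function(q) {
  # column-wise lower-triangle order: s(2,1), s(3,1), ..., s(20,1), s(3,2), ...
  m <- matrix(0, 20L, 20L)
  m[lower.tri(m)] <- q
  m + t(m)
}

#' Read a PAML-style amino-acid model file
#'
#' Parses the de facto standard `.dat` layout: 19 rows of a lower-triangular
#' exchangeability matrix followed by a row of 20 equilibrium frequencies.
#' Comment text after the numbers is ignored.
#'
#' @param path file path.
#' @param name identifier given to the resulting model (default: file name).
#' @return `rate_model` object.
#' @export
read_paml_dat <- function(path, name = sub("\\.dat$", "", basename(path))) {
  txt <- readLines(path, warn = FALSE)
  toks <- unlist(strsplit(paste(txt, collapse = " "), "[ \t]+"))
  nums <- suppressWarnings(as.numeric(toks))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 210L)
    stop("expected at least 210 numbers (190 exchangeabilities + 20 frequencies) in ", path)
  ex <- nums[1:190]
  freqs <- nums[191:210]
  # PAML lists row i's entries s(i, 1..i-1); reorder into column-wise
  # lower-triangle order used by lower_triangle_to_matrix().
  m <- matrix(0, 20L, 20L)
  idx <- 1L
  for (i in 2:20) for (j in 1:(i - 1L)) {
    m[j, i] <- ex[idx]   # upper triangle, column-wise when read back
    idx <- idx + 1L
  }
  m <- m + t(m)
  rate_model(name, m, freqs)
}

#' Transition probability matrix of a model
#'
#' Computes \eqn{P = \exp(Q \cdot r \cdot t)} for branch length `t`
#' (expected substitutions per site at the mean rate) and rate multiplier
#' `r`, via the cached spectral decomposition of the symmetrised generator.
#'
#' @param model `rate_model`.
#' @param branch_length non-negative branch length.
#' @param rate positive rate multiplier.
#' @return 20x20 row-stochastic matrix.
#' @export
transition_probabilities <- function(model, branch_length, rate = 1) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.numeric(branch_length) || length(branch_length) != 1L ||
      is.na(branch_length) || branch_length < 0)
    stop("branch_length must be a single non-negative number")
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0)
    stop("rate must be a single positive number")
  t <- branch_length * rate
  P <- model$left %*% (exp(model$eigenvalues * t) * model$right)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P
}

#' Discretize a gamma rate distribution into equiprobable categories
#'
#' Approximates mean-1 gamma rate heterogeneity (shape `alpha`, rate `alpha`)
#' by `k` equal-probability categories, each carrying the conditional mean of
#' its quantile bin, so the category rates average exactly 1. This is the
#' mean-per-bin variant of the discrete-gamma approximation.
#'
#' @param alpha gamma shape (> 0); small values mean strong rate
#'   heterogeneity.
#' @param k number of categories (>= 1).
#' @return object of class `gamma_categories`: list with `alpha`,
#'   `n_categories`, `rates` (ascending, mean 1), `category_probability`.
#' @examples
#' discretize_gamma(0.803, 12)$rates  # slowest ~ 0.023, fastest ~ 3.823
#' @export
discretize_gamma <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("alpha must be a single positive number")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    stop("k must be a positive integer")
  k <- as.integer(k)
  edges <- stats::qgamma(seq(0, 1, length.out = k + 1L),
                         shape = alpha, rate = alpha)
  # E[X | bin] * k: conditional means via the incomplete-gamma identity
  # integral x f(x) dx over a bin of Gamma(a, a) = P(a+1 bin) (mean 1).
  cum <- stats::pgamma(edges, shape = alpha + 1, rate = alpha)
  rates <- k * diff(cum)
  rates <- rates / mean(rates)  # remove residual floating-point drift
  structure(
    list(alpha = alpha, n_categories = k, rates = rates,
         category_probability = rep(1 / k, k)),
    class = "gamma_categories")
}

#' @export
print.gamma_categories <- function(x, ...) {
  cat("Discrete gamma rates: alpha =", x$alpha, ", k =", x$n_categories, "\n")
  print(signif(x$rates, 4))
  invisible(x)
}

#' Expected substitutions contributed by one rate category along a branch
#'
#' For an alignment of `alignment_length` sites split into `n_categories`
#' equiprobable rate categories, the sites of a category with rate multiplier
#' `category_rate` are expected to accumulate
#' `(alignment_length / n_categories) * branch_length * category_rate`
#' substitutions along a branch, out of an alignment-wide total of
#' `alignment_length * branch_length`. The fraction is computed from the
#' unrounded count and is independent of branch length.
#'
#' @param branch_length branch length in substitutions/site (> 0).
#' @param alignment_length number of sites (> 0).
#' @param n_categories number of equiprobable rate categories (> 0).
#' @param category_rate the category's rate multiplier (> 0).
#' @return list with `count`, `total`, and `fraction` (count / total).
#' @examples
#' expected_substitutions(0.05, 2596, 12, 0.0234)  # ~0.25 of 129.8 total
#' @export
expected_substitutions <- function(branch_length, alignment_length,
                                   n_categories, category_rate) {
  args <- c(branch_length = branch_length, alignment_length = alignment_length,
            n_categories = n_categories, category_rate = category_rate)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("all arguments must be positive finite numbers")
  count <- (alignment_length / n_categories) * branch_length * category_rate
  total <- alignment_length * branch_length
  list(count = count, total = total, fraction = count / total)
}
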