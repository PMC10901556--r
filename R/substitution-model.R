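#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Fixed residue alphabet, alphabetical one-letter codes. All matrices, state
# indices and argmax tie-breaks use this order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PAML/phangorn amino-acid ordering, used only when importing the JTT table.
AA_PAML <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' JTT exchangeabilities and equilibrium frequencies
#'
#' Returns the Jones-Taylor-Thornton empirical amino-acid model as a symmetric
#' 20 x 20 exchangeability matrix and equilibrium frequency vector, in the
#' package's fixed alphabetical residue order. The numeric table is the pinned
#' copy shipped with \pkg{phangorn}.
#'
#' @return A list with elements `S` (symmetric 20 x 20 matrix, zero diagonal)
#'   and `pi` (named frequency vector summing to 1).
#' @export
jtt_exchangeabilities <- function() {
  jtt <- get(".JTT", envir = environment(phangorn::pml))
  S <- matrix(0, 20, 20, dimnames = list(AA_PAML, AA_PAML))
  S[lower.tri(S)] <- jtt$Q
  S <- S + t(S)
  pi <- as.numeric(jtt$bf)
  names(pi) <- AA_PAML
  perm <- match(AA_ALPHABET, AA_PAML)
  list(S = S[perm, perm], pi = pi[perm] / sum(pi))
}

#' Construct an amino-acid substitution model
#'
#' Builds a `substitution_model` object of the JTT family with optional
#' discrete-gamma rate heterogeneity (`+G`), a proportion of invariant sites
#' (`+I`) and empirical equilibrium frequencies (`+F`).
#'
#' @param name Model name, one of `"JTT"`, `"JTT+G"`, `"JTT+I"`, `"JTT+G+I"`,
#'   `"JTT+G+I+F"` (any order of the `+` suffixes is accepted).
#' @param alpha Gamma shape parameter (> 0). Required when the name contains
#'   `+G`; ignored otherwise.
#' @param p_inv Proportion of invariant sites in `[0, 1)`. Required with
#'   `+I`; ignored otherwise.
#' @param n_categories Number of discrete gamma categories (default 5).
#' @param frequencies Optional length-20 frequency vector (alphabetical
#'   order) replacing the JTT frequencies; used by `+F` models, where it is
#'   normally obtained from [empirical_frequencies()].
#' @param gamma_method Discretization rule: mean (default) or median of the
#'   equal-probability gamma slices.
#' @return An object of class `substitution_model`.
#' @examples
#' m <- substitution_model("JTT+G+I", alpha = 1, p_inv = 0.1)
#' rate_mixture(m)
#' @export
substitution_model <- function(name = "JTT+G+I", alpha = NULL, p_inv = NULL,
                               n_categories = 5, frequencies = NULL,
                               gamma_method = c("mean", "median")) {
  gamma_method <- match.arg(gamma_method)
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  if (parts[1] != "JTT" || !all(parts[-1] %in% c("G", "I", "F"))) {
    abort(paste0("unknown model name: ", name))
  }
  has_g <- "G" %in% parts
  has_i <- "I" %in% parts
  has_f <- "F" %in% parts
  jtt <- jtt_exchangeabilities()
  pi <- jtt$pi
  if (!is.null(frequencies)) {
    if (length(frequencies) != 20 || any(frequencies < 0)) {
      abort("frequencies must be 20 nonnegative values")
    }
    pi <- frequencies / sum(frequencies)
    names(pi) <- AA_ALPHABET
  }
  if (has_g) {
    if (is.null(alpha)) abort("model with +G requires alpha")
    if (!is.numeric(alpha) || alpha <= 0) abort("alpha must be > 0")
  } else {
    alpha <- NULL
  }
  if (has_i) {
    if (is.null(p_inv)) abort("model with +I requires p_inv")
    if (!is.numeric(p_inv) || p_inv < 0 || p_inv >= 1) {
      abort("p_inv must lie in [0, 1)")
    }
  } else {
    p_inv <- NULL
  }
  structure(
    list(name = name, S = jtt$S, pi = pi,
         gamma_shape = alpha, n_categories = as.integer(n_categories),
         p_invariant = p_inv, use_empirical_freqs = has_f,
         gamma_method = gamma_method),
    class = "substitution_model"
  )
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model>", x$name, "\n")
  if (!is.null(x$gamma_shape)) {
    cat("  gamma shape:", format(x$gamma_shape),
        "(", x$n_categories, "categories,", x$gamma_method, "rule )\n")
  }
  if (!is.null(x$p_invariant)) {
    cat("  p_invariant:", format(x$p_invariant), "\n")
  }
  invisible(x)
}

#' Instantaneous rate matrix of a substitution model
#'
#' Assembles the GTR-form generator `Q` from the exchangeabilities and
#' equilibrium frequencies: `q_ij = S_ij * pi_j` off-diagonal, diagonal set so
#' rows sum to zero, and the whole matrix scaled so the mean substitution rate
#' at equilibrium, `-sum(pi_i q_ii)`, equals 1. Branch lengths applied to this
#' matrix are therefore expected numbers of substitutions per site.
#'
#' @param model A [substitution_model()].
#' @return A 20 x 20 matrix with rows summing to 0.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "substitution_model"))
  make_generator(model$S, model$pi)
}

# Generator from arbitrary (S, pi); also used by toy models in tests.
make_generator <- function(S, pi) {
  n <- length(pi)
  if (abs(sum(pi) - 1) > 1e-9 || any(pi < 0)) {
    abort("frequencies must be nonnegative and sum to 1")
  }
  Q <- S * rep(pi, each = n)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) abort("degenerate model: zero mean substitution rate")
  Q / mu
}

# Symmetric eigendecomposition of a reversible generator. Q = D^-1/2 B D^1/2
# with B symmetric, so P(t) = D^-1/2 U exp(L t) U' D^1/2 with guaranteed real
# eigenvalues; reused across branches by the pruning engine.
eigen_generator <- function(Q, pi) {
  d <- sqrt(pi)
  B <- Q * (d / rep(d, each = length(d)))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / d, V = t(e$vectors * d), lambda = e$values)
}

transition_from_eigen <- function(eg, t) {
  P <- eg$U %*% (exp(eg$lambda * t) * eg$V)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix over a branch
#'
#' Computes `P(rate * t) = expm(Q * rate * t)` for a reversible generator,
#' via symmetric eigendecomposition.
#'
#' @param Q Rate matrix from [build_rate_matrix()] (or any reversible
#'   generator with stationary distribution `pi`).
#' @param t Branch length (>= 0), in expected substitutions per site when `Q`
#'   is mean-rate-normalized.
#' @param rate Scalar rate multiplier (>= 0), e.g. a gamma category rate.
#' @param pi Stationary frequencies of `Q`. If `NULL` they are recovered
#'   numerically as the left null vector of `Q`; passing them explicitly is
#'   cheaper and exact.
#' @return A row-stochastic matrix of the same dimension as `Q`.
#' @export
transition_probs <- function(Q, t, rate = 1, pi = NULL) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    abort("branch length t must be a finite nonnegative scalar")
  }
  if (rate < 0) abort("rate must be >= 0")
  if (is.null(pi)) pi <- stationary_frequencies(Q)
  transition_from_eigen(eigen_generator(Q, pi), rate * t)
}

# Left null vector of Q, normalized: the stationary distribution.
stationary_frequencies <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Discretize a gamma distribution into equal-weight rate categories
#'
#' Splits the mean-1 gamma(shape = alpha, rate = alpha) distribution into `k`
#' equal-probability slices and represents each by its conditional mean
#' (default) or median. Rates are normalized to mean exactly 1.
#'
#' @param alpha Gamma shape (> 0); small values mean strong rate
#'   heterogeneity.
#' @param k Number of categories (>= 1).
#' @param method `"mean"` (conditional expectation of each slice, computed
#'   from the incomplete-gamma identity) or `"median"` of each slice.
#' @return Numeric vector of `k` nondecreasing rates with mean 1.
#' @export
discretize_gamma <- function(alpha, k, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0) abort("alpha must be > 0")
  if (k < 1) abort("k must be >= 1")
  k <- as.integer(k)
  if (k == 1L) return(1)
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                          rate = alpha)
  if (method == "mean") {
    # E[X | slice] via the identity E[X; X<q] = pgamma(q, a+1) for gamma(a, a).
    upper <- stats::pgamma(breaks[-1], shape = alpha + 1, rate = alpha)
    lower <- stats::pgamma(breaks[-(k + 1)], shape = alpha + 1, rate = alpha)
    rates <- (upper - lower) * k
  } else {
    mid <- (seq_len(k) - 0.5) / k
    rates <- stats::qgamma(mid, shape = alpha, rate = alpha)
  }
  rates / mean(rates)
}

#' Combine gamma categories with an invariant-site class
#'
#' Appends a rate-0 invariant category with weight `p_invariant` to a set of
#' equal-weight gamma rates, rescaling the nonzero rates so the mixture mean
#' stays 1 (branch lengths keep their substitutions-per-site meaning).
#'
#' @param rates Gamma category rates (mean 1), e.g. from
#'   [discretize_gamma()].
#' @param p_invariant Proportion of invariant sites in `[0, 1)`.
#' @return A tibble with columns `rate` and `weight`; the last row is the
#'   invariant class (rate 0) when `p_invariant > 0`.
#' @export
make_rate_mixture <- function(rates, p_invariant = 0) {
  if (!is.numeric(p_invariant) || p_invariant < 0 || p_invariant >= 1) {
    abort("p_invariant must lie in [0, 1)")
  }
  k <- length(rates)
  if (p_invariant == 0) {
    return(tibble(rate = rates / mean(rates), weight = rep(1 / k, k)))
  }
  w <- rep((1 - p_invariant) / k, k)
  r <- rates / sum(w * rates) * 1 # mixture mean (over nonzero part) -> 1
  tibble(rate = c(r, 0), weight = c(w, p_invariant))
}

#' Rate mixture of a substitution model
#'
#' The (k + 1)-category rate mixture implied by a model's `+G` and `+I`
#' components (a single rate-1 category for plain JTT).
#'
#' @param model A [substitution_model()].
#' @return A tibble with columns `rate` and `weight` whose mixture mean is 1.
#' @export
rate_mixture <- function(model) {
  stopifnot(inherits(model, "substitution_model"))
  rates <- if (is.null(model$gamma_shape)) 1 else {
    discretize_gamma(model$gamma_shape, model$n_categories,
                     method = model$gamma_method)
  }
  p_inv <- if (is.null(model$p_invariant)) 0 else model$p_invariant
  make_rate_mixture(rates, p_inv)
}

#' Empirical residue frequencies of an alignment (+F)
#'
#' Counts residues over all non-gap, non-ambiguous alignment cells and
#' normalizes to a frequency vector in alphabetical residue order.
#'
#' @param aln An alignment (see [as_alignment()]).
#' @return Named length-20 frequency vector summing to 1.
#' @export
empirical_frequencies <- function(aln) {
  m <- as_alignment(aln)
  cells <- m[m %in% AA_ALPHABET]
  if (length(cells) == 0) abort("alignment has no unambiguous residues")
  counts <- table(factor(cells, levels = AA_ALPHABET))
  f <- as.numeric(counts) / sum(counts)
  names(f) <- AA_ALPHABET
  f
}
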