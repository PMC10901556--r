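# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths: likelihoods by exhaustive enumeration of
# internal-state assignments, matrix exponentials by scaled Taylor series,
# gamma category means by adaptive quadrature.

# Taylor-series matrix exponential with scaling-and-squaring (30 terms).
series_expm <- function(A, n_terms = 30) {
  s <- max(0, ceiling(log2(max(1e-16, norm(A, "1")))))
  B <- A / 2^s
  X <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(n_terms)) {
    term <- term %*% B / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# Exhaustive-sum likelihood and marginal posteriors for small rooted trees.
# Sums over all 20^n_internal internal-state assignments per rate category.
enum_engine <- function(tree, aln, model, branch_scale = 1) {
  aln <- as_alignment(aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- tadevo:::alignment_states(aln)[tr$tip.label, , drop = FALSE]
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  stopifnot(nint <= 4)
  Q <- build_rate_matrix(model)
  mix <- rate_mixture(model)
  S <- ncol(states)
  combos <- as.matrix(expand.grid(rep(list(1:20), nint)))
  root <- ntip + 1L

  site_like <- numeric(S)
  post <- array(0, dim = c(nint, S, 20))
  for (ci in seq_len(nrow(mix))) {
    r <- mix$rate[ci]
    P <- lapply(seq_len(nrow(tr$edge)), function(e) {
      if (r == 0) diag(20) else
        transition_probs(Q, tr$edge.length[e] * branch_scale, rate = r,
                         pi = model$pi)
    })
    for (s_i in seq_len(S)) {
      obs <- states[, s_i]
      pr_combo <- numeric(nrow(combos))
      for (ca in seq_len(nrow(combos))) {
        full <- c(obs, combos[ca, ])
        pr <- model$pi[combos[ca, root - ntip]]
        for (e in seq_len(nrow(tr$edge))) {
          a <- full[tr$edge[e, 1]]
          b <- full[tr$edge[e, 2]]
          if (is.na(b)) next # missing tip: marginalized out
          pr <- pr * (if (is.na(a)) NA else P[[e]][a, b])
        }
        pr_combo[ca] <- pr
      }
      w <- mix$weight[ci]
      site_like[s_i] <- site_like[s_i] + w * sum(pr_combo)
      for (v in seq_len(nint)) {
        for (st in 1:20) {
          post[v, s_i, st] <- post[v, s_i, st] +
            w * sum(pr_combo[combos[, v] == st])
        }
      }
    }
  }
  norm <- apply(post, c(1, 2), sum)
  list(
    site_log_likelihoods = log(site_like),
    log_likelihood = sum(log(site_like)),
    post = post / array(norm, dim = dim(post))
  )
}

# Bisection solver for the competitive equilibrium: independent of the
# closed-form cubic used by the package.
bisect_competitive <- function(P_tot, L_tot, I_tot, K_D_L, K_D_I,
                               tol = 1e-13) {
  resid <- function(p) {
    p * (1 + L_tot / (K_D_L + p) + I_tot / (K_D_I + p)) - P_tot
  }
  lo <- 0
  hi <- P_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(1, P_tot)) break
  }
  p <- (lo + hi) / 2
  PL <- L_tot * p / (K_D_L + p)
  PI <- I_tot * p / (K_D_I + p)
  list(P_free = p, PL = PL, PI = PI,
       fraction_L_bound = if (L_tot > 0) PL / L_tot else 0)
}

random_chronogram <- function(n, height, seed) {
  simulate_chronogram(n, height = height, seed = seed)
}
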