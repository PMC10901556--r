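# Marginal ancestral reconstruction: for every internal node and site, the
# posterior over the 20 residues given all data, integrating over the other
# nodes (outside-partial "up" pass) and over rate categories (weighted by
# each category's per-site posterior, not its prior weight).

# Down pass variant that also stores per-edge child contributions,
# needed for sibling products in the up pass.
down_pass_full <- function(pp, rate) {
  res <- down_pass(pp, rate, keep = TRUE)
  edge <- pp$tree$edge
  contrib <- vector("list", nrow(edge))
  for (e in seq_len(nrow(edge))) {
    contrib[[e]] <- res$P[[e]] %*% res$partial[[edge[e, 2]]]
  }
  res$contrib <- contrib
  res
}

# Up (preorder) pass for one category: outside partials and their scalers.
up_pass <- function(pp, dp) {
  edge <- pp$tree$edge
  nn <- pp$ntip + pp$nnode
  S <- pp$nsites
  root <- pp$ntip + 1L
  up <- vector("list", nn)
  uplogsc <- matrix(0, nn, S)
  up[[root]] <- matrix(pp$pi, 20, S)
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in rev(seq_len(nrow(edge)))) { # reverse postorder = preorder
    u <- edge[e, 1]; v <- edge[e, 2]
    sib <- up[[u]]
    sc <- uplogsc[u, ]
    for (e2 in kids[[as.character(u)]]) {
      if (e2 == e) next
      sib <- sib * dp$contrib[[e2]]
      sc <- sc + dp$logsc[edge[e2, 2], ]
    }
    val <- crossprod(dp$P[[e]], sib)
    s <- apply(val, 2, max)
    s[s == 0] <- 1
    up[[v]] <- sweep(val, 2, s, "/")
    uplogsc[v, ] <- sc + log(s)
  }
  list(up = up, uplogsc = uplogsc)
}

#' Marginal ancestral posteriors at every internal node
#'
#' Computes, for each internal node and alignment column, the marginal
#' posterior distribution over the 20 residues under the fitted model,
#' mixing rate categories by their per-site posterior weight.
#'
#' @inheritParams log_likelihood
#' @return An `ancestral_posterior` object: a list with `post` (array
#'   `internal nodes x sites x 20`; node dimension named by ape node
#'   numbers), `site_log_likelihoods`, `log_likelihood`, `tree`, and the
#'   `model` used. Use [tidy.ancestral_posterior()] for a tibble view and
#'   [call_sequences()] for ML/AltAll sequences.
#' @export
marginal_posteriors <- function(tree, aln, model, branch_scale = 1) {
  pp <- prep_pruning(tree, aln, model, branch_scale)
  ncat <- nrow(pp$mix)
  S <- pp$nsites
  internal <- pp$ntip + seq_len(pp$nnode)

  # pass 1: per-category site log-likelihoods (for the cross-category shift)
  cat_ll <- matrix(0, S, ncat)
  for (c_i in seq_len(ncat)) {
    cat_ll[, c_i] <- down_pass(pp, pp$mix$rate[c_i], keep = FALSE)$site_ll
  }
  m <- apply(cat_ll, 1, max)
  site_ll <- log(as.vector(exp(cat_ll - m) %*% pp$mix$weight)) + m

  # pass 2: accumulate posterior numerators category by category
  numer <- array(0, dim = c(pp$nnode, S, 20))
  for (c_i in seq_len(ncat)) {
    dp <- down_pass_full(pp, pp$mix$rate[c_i])
    upr <- up_pass(pp, dp)
    w <- pp$mix$weight[c_i]
    for (v in internal) {
      j <- dp$partial[[v]] * upr$up[[v]] # 20 x S
      esc <- exp(dp$logsc[v, ] + upr$uplogsc[v, ] - m)
      numer[v - pp$ntip, , ] <- numer[v - pp$ntip, , ] +
        t(j) * (w * esc)
    }
  }
  denom <- apply(numer, c(1, 2), sum)
  post <- numer / array(denom, dim = dim(numer))
  dimnames(post) <- list(as.character(internal), NULL, AA_ALPHABET)

  structure(
    list(post = post, site_log_likelihoods = site_ll,
         log_likelihood = sum(site_ll),
         tree = pp$tree, model = model, branch_scale = branch_scale,
         node_ids = internal),
    class = "ancestral_posterior"
  )
}

#' @export
print.ancestral_posterior <- function(x, ...) {
  d <- dim(x$post)
  cat("<ancestral_posterior> ", d[1], " internal nodes x ", d[2],
      " sites (model ", x$model$name, ")\n", sep = "")
  cat("  total log-likelihood: ", format(x$log_likelihood), "\n", sep = "")
  invisible(x)
}

#' Tidy an ancestral posterior into a tibble
#'
#' @param x An `ancestral_posterior`.
#' @param ... Unused.
#' @return A tibble with one row per (node, site): `node`, `site`, the 20
#'   probability columns `p_A` ... `p_Y`, and the `ml` and `altall` residue
#'   calls at the default cutoffs.
#' @method tidy ancestral_posterior
#' @export
tidy.ancestral_posterior <- function(x, ...) {
  d <- dim(x$post)
  nodes <- as.integer(dimnames(x$post)[[1]])
  flat <- matrix(x$post, nrow = d[1] * d[2], ncol = 20)
  colnames(flat) <- paste0("p_", AA_ALPHABET)
  calls <- call_matrix(x$post)
  tibble(
    node = rep(nodes, times = d[2]),
    site = rep(seq_len(d[2]), each = d[1])
  ) |>
    dplyr::bind_cols(as_tibble(flat)) |>
    dplyr::mutate(ml = as.vector(calls$ml), altall = as.vector(calls$altall)) |>
    dplyr::arrange(.data$node, .data$site)
}

# ML and AltAll residue matrices (nodes x sites) from a posterior array.
call_matrix <- function(post, primary_cutoff = 0.90, secondary_min = 0.10) {
  d <- dim(post)
  ml <- matrix("", d[1], d[2])
  altall <- matrix("", d[1], d[2])
  for (i in seq_len(d[1])) {
    p <- matrix(post[i, , ], nrow = d[2], ncol = 20)
    best <- max.col(p, ties.method = "first")
    p2 <- p
    p2[cbind(seq_len(d[2]), best)] <- -Inf
    second <- max.col(p2, ties.method = "first")
    pb <- p[cbind(seq_len(d[2]), best)]
    ps <- p[cbind(seq_len(d[2]), second)]
    ml[i, ] <- AA_ALPHABET[best]
    swap <- pb < primary_cutoff & ps >= secondary_min
    altall[i, ] <- ifelse(swap, AA_ALPHABET[second], AA_ALPHABET[best])
  }
  list(ml = ml, altall = altall)
}

#' ML and AltAll ancestral sequences
#'
#' The maximum-likelihood sequence takes the highest-posterior residue at
#' every site (ties broken in fixed alphabetical order). The AltAll sequence
#' replaces a site by its second most likely residue exactly when the best
#' posterior is below `primary_cutoff` and the runner-up reaches at least
#' `secondary_min` — the "all plausible alternatives at once" variant used to
#' probe reconstruction robustness.
#'
#' @param post An `ancestral_posterior` from [marginal_posteriors()].
#' @param primary_cutoff Posterior below which a site counts as ambiguous
#'   (default 0.90).
#' @param secondary_min Minimum posterior of the runner-up residue for a swap
#'   (default 0.10).
#' @return A tibble with columns `node`, `ml_sequence`, `altall_sequence`,
#'   and `n_ambiguous` (number of swapped sites).
#' @export
call_sequences <- function(post, primary_cutoff = 0.90, secondary_min = 0.10) {
  stopifnot(inherits(post, "ancestral_posterior"))
  if (primary_cutoff <= 0 || primary_cutoff > 1 ||
      secondary_min < 0 || secondary_min > 1) {
    abort("cutoffs must lie in (0, 1]")
  }
  calls <- call_matrix(post$post, primary_cutoff, secondary_min)
  tibble(
    node = as.integer(dimnames(post$post)[[1]]),
    ml_sequence = apply(calls$ml, 1, paste, collapse = ""),
    altall_sequence = apply(calls$altall, 1, paste, collapse = ""),
    n_ambiguous = rowSums(calls$ml != calls$altall)
  )
}

#' Information criteria for a fitted model
#'
#' Small-sample-corrected AIC, `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`, and
#' `BIC = -2 lnL + k ln n`.
#'
#' @param log_lik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (alignment columns, by convention here).
#' @return A list with `AICc` and `BIC`; `AICc` is `NA` when `n <= k + 1`.
#' @export
information_criteria <- function(log_lik, k, n) {
  aicc <- if (n > k + 1) -2 * log_lik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
          else NA_real_
  list(AICc = aicc, BIC = -2 * log_lik + k * log(n))
}

#' Substitution-model selection by AICc
#'
#' Fits each candidate model (gamma shape, invariant fraction and rate
#' scalar as applicable; `+F` models use the alignment's empirical
#' frequencies) and ranks them by small-sample-corrected AIC. Akaike weights
#' are `exp(-delta_i/2)` normalized over the candidates, with `delta`
#' relative to the smallest AICc.
#'
#' @param tree Rooted `phylo` tree.
#' @param aln Alignment.
#' @param models Character vector of candidate model names (JTT family).
#' @param alpha0,p_inv0 Starting values for the gamma shape and invariant
#'   fraction.
#' @param n_categories Gamma categories per model.
#' @param sample_size AICc/BIC sample size; defaults to the number of
#'   alignment columns.
#' @return A tibble ranked by AICc with columns `model`, `log_likelihood`,
#'   `k`, `n`, `AICc`, `delta_AICc`, `akaike_weight`, `BIC`, and the fitted
#'   `alpha`, `p_inv`, `branch_scale`.
#' @export
model_selection_table <- function(tree, aln,
                                  models = c("JTT", "JTT+G", "JTT+I",
                                             "JTT+G+I", "JTT+G+I+F"),
                                  alpha0 = 1, p_inv0 = 0.1,
                                  n_categories = 5, sample_size = NULL) {
  if (length(models) < 1) abort("at least one candidate model is required")
  aln <- as_alignment(aln)
  n <- if (is.null(sample_size)) ncol(aln) else sample_size
  rows <- purrr::map(models, function(nm) {
    has_g <- grepl("\\+G", nm)
    has_i <- grepl("\\+I", nm)
    has_f <- grepl("\\+F", nm)
    template <- substitution_model(
      nm,
      alpha = if (has_g) alpha0,
      p_inv = if (has_i) p_inv0,
      n_categories = n_categories,
      frequencies = if (has_f) empirical_frequencies(aln)
    )
    fit <- fit_model_parameters(tree, aln, template)
    k <- 1L + has_g + has_i + 19L * has_f # rate scalar + shape + pinv (+F)
    ic <- information_criteria(fit$log_likelihood, k, n)
    if (is.na(ic$AICc)) {
      warn(paste0("AICc undefined for ", nm, ": n <= k + 1"))
    }
    tibble(model = nm, log_likelihood = fit$log_likelihood,
           k = k, n = n, AICc = ic$AICc, BIC = ic$BIC,
           alpha = fit$model$gamma_shape %||% NA_real_,
           p_inv = fit$model$p_invariant %||% NA_real_,
           branch_scale = fit$branch_scale)
  })
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$AICc))) {
    return(dplyr::mutate(tab, delta_AICc = NA_real_,
                         akaike_weight = NA_real_) |>
             dplyr::relocate("delta_AICc", "akaike_weight",
                             .after = "AICc"))
  }
  dmin <- min(tab$AICc, na.rm = TRUE)
  tab |>
    dplyr::mutate(
      delta_AICc = .data$AICc - dmin,
      akaike_weight = exp(-.data$delta_AICc / 2) /
        sum(exp(-(.data$AICc - dmin) / 2), na.rm = TRUE)
    ) |>
    dplyr::relocate("delta_AICc", "akaike_weight", .after = "AICc") |>
    dplyr::arrange(.data$AICc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
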