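# Felsenstein pruning over a (k+1)-category rate mixture.
#
# All engines work on a postorder-sorted edge list with per-edge expected
# substitution counts (chronogram length in My x global rate scalar, or free
# per-edge lengths), and a shared eigendecomposition of the mean-rate-1
# generator, so per-category transition matrices are cheap.

prep_pruning <- function(tree, aln, model, branch_scale = 1,
                         edge_subst = NULL) {
  aln <- as_alignment(aln)
  if (!setequal(rownames(aln), tree$tip.label)) {
    miss <- c(setdiff(tree$tip.label, rownames(aln)),
              setdiff(rownames(aln), tree$tip.label))
    abort(paste0("alignment/tree label mismatch: ",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  if (branch_scale <= 0) abort("branch_scale must be > 0")
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- alignment_states(aln)[tr$tip.label, , drop = FALSE]
  mix <- rate_mixture(model)
  Q <- build_rate_matrix(model)
  list(
    tree = tr,
    ntip = length(tr$tip.label),
    nnode = tr$Nnode,
    states = states,
    nsites = ncol(states),
    mix = mix,
    pi = unname(model$pi),
    eig = eigen_generator(Q, model$pi),
    edge_subst = if (is.null(edge_subst)) tr$edge.length * branch_scale
                 else edge_subst
  )
}

# Tip conditional-likelihood matrix (20 x S): indicator for observed
# residues, ones for gaps/ambiguity (missing data).
tip_partial <- function(states_row, nsites) {
  L <- matrix(0, 20, nsites)
  obs <- !is.na(states_row)
  L[, !obs] <- 1
  L[cbind(states_row[obs], which(obs))] <- 1
  L
}

# Down (postorder) pass for one rate category. Returns per-node partials
# (20 x S), per-node accumulated log-scalers (length S), and site
# log-likelihoods for this category.
down_pass <- function(pp, rate, keep = TRUE) {
  nn <- pp$ntip + pp$nnode
  S <- pp$nsites
  P <- vector("list", nrow(pp$tree$edge)) # per-edge transition matrix
  for (e in seq_len(nrow(pp$tree$edge))) {
    P[[e]] <- if (rate == 0) diag(20) else
      transition_from_eigen(pp$eig, rate * pp$edge_subst[e])
  }
  partial <- vector("list", nn)
  logsc <- matrix(0, nn, S)
  for (i in seq_len(pp$ntip)) {
    partial[[i]] <- tip_partial(pp$states[i, ], S)
  }
  edge <- pp$tree$edge
  rescale <- function(v) {
    s <- apply(partial[[v]], 2, max)
    s[s == 0] <- 1
    partial[[v]] <<- sweep(partial[[v]], 2, s, "/")
    logsc[v, ] <<- logsc[v, ] + log(s)
  }
  for (e in seq_len(nrow(edge))) { # postorder: children before parents
    par <- edge[e, 1]; child <- edge[e, 2]
    # internal child is complete here (appears once on the child side);
    # rescale before it propagates upward
    if (child > pp$ntip) rescale(child)
    contrib <- P[[e]] %*% partial[[child]]
    if (is.null(partial[[par]])) {
      partial[[par]] <- contrib
      logsc[par, ] <- logsc[child, ]
    } else {
      partial[[par]] <- partial[[par]] * contrib
      logsc[par, ] <- logsc[par, ] + logsc[child, ]
    }
  }
  root <- pp$ntip + 1L
  rescale(root)
  site_ll <- log(as.vector(pp$pi %*% partial[[root]])) + logsc[root, ]
  if (keep) {
    list(partial = partial, logsc = logsc, site_ll = site_ll, P = P)
  } else {
    list(site_ll = site_ll)
  }
}

mixture_site_ll <- function(cat_ll, weights) {
  # cat_ll: S x ncat matrix of per-category site log-likelihoods
  m <- apply(cat_ll, 1, max)
  m[!is.finite(m)] <- 0
  log(as.vector(exp(cat_ll - m) %*% weights)) + m
}

#' Log-likelihood of an alignment on a time tree
#'
#' Felsenstein pruning under a reversible amino-acid model with a
#' discrete-gamma + invariant-sites rate mixture. Gaps and `X` are treated
#' as missing data. Branch lengths are `branch_scale` times the tree's
#' lengths, so with a chronogram in My the scalar is a rate in substitutions
#' per site per My.
#'
#' @param tree Rooted `phylo` tree whose tip labels match the alignment.
#' @param aln Alignment (see [as_alignment()]).
#' @param model A [substitution_model()].
#' @param branch_scale Global rate scalar (> 0).
#' @return A list with `log_likelihood` (total) and `site_log_likelihoods`.
#' @export
log_likelihood <- function(tree, aln, model, branch_scale = 1) {
  pp <- prep_pruning(tree, aln, model, branch_scale)
  cat_ll <- vapply(pp$mix$rate,
                   function(r) down_pass(pp, r, keep = FALSE)$site_ll,
                   numeric(pp$nsites))
  if (pp$nsites == 1) cat_ll <- matrix(cat_ll, nrow = 1)
  site_ll <- mixture_site_ll(cat_ll, pp$mix$weight)
  list(log_likelihood = sum(site_ll), site_log_likelihoods = site_ll)
}

#' Fit substitution-model parameters by maximum likelihood
#'
#' Optimizes any subset of the gamma shape, invariant fraction and global
#' branch-rate scalar on a fixed topology; optionally re-optimizes each
#' branch length (coordinate descent) instead of the single scalar.
#'
#' @param tree Rooted `phylo` tree.
#' @param aln Alignment.
#' @param model Template [substitution_model()]; its values seed the
#'   optimizer and fix whichever parameters are not optimized.
#' @param optimize Character vector among `"alpha"`, `"p_inv"`,
#'   `"branch_scale"` (those present in the model are used by default).
#' @param branch_mode `"scale"` (default): chronogram lengths times one
#'   fitted rate scalar. `"branch_lengths"`: free per-edge substitution
#'   lengths, refined by coordinate descent (intended for small trees).
#' @param branch_scale Starting value for the rate scalar.
#' @param control Passed to [stats::optim()] (method `L-BFGS-B` on
#'   transformed parameters).
#' @return A list with the fitted `model`, `branch_scale` (or `edge_subst`
#'   for per-branch mode), `log_likelihood`, the best-so-far optimization
#'   `trace`, and `convergence`.
#' @export
fit_model_parameters <- function(tree, aln, model,
                                 optimize = NULL,
                                 branch_mode = c("scale", "branch_lengths"),
                                 branch_scale = NULL,
                                 control = list()) {
  branch_mode <- match.arg(branch_mode)
  if (is.null(optimize)) {
    optimize <- c(if (!is.null(model$gamma_shape)) "alpha",
                  if (!is.null(model$p_invariant)) "p_inv",
                  "branch_scale")
  }
  bad <- setdiff(optimize, c("alpha", "p_inv", "branch_scale"))
  if (length(bad)) abort(paste0("unknown parameter(s): ",
                                paste(bad, collapse = ", ")))
  if ("alpha" %in% optimize && is.null(model$gamma_shape)) {
    abort("model has no gamma component; cannot optimize alpha")
  }
  if ("p_inv" %in% optimize && is.null(model$p_invariant)) {
    abort("model has no invariant component; cannot optimize p_inv")
  }
  aln <- as_alignment(aln)
  states <- alignment_states(aln)
  n_var <- sum(apply(states, 2, function(s) {
    u <- unique(s[!is.na(s)]); length(u) > 1
  }))
  if (n_var == 0 && "alpha" %in% optimize) {
    warn("no variable sites; rate parameters are not identifiable")
  }
  if (is.null(branch_scale)) {
    # crude starting rate: one substitution per site over the tree height
    branch_scale <- 1 / max(ape::node.depth.edgelength(tree))
  }

  trace <- numeric(0)
  best <- -Inf
  eval_ll <- function(alpha, p_inv, scale) {
    m <- model
    if (!is.null(m$gamma_shape)) m$gamma_shape <- alpha
    if (!is.null(m$p_invariant)) m$p_invariant <- p_inv
    ll <- log_likelihood(tree, aln, m, branch_scale = scale)$log_likelihood
    best <<- max(best, ll)
    trace <<- c(trace, best)
    ll
  }

  par0 <- numeric(0)
  if ("alpha" %in% optimize) par0["log_alpha"] <- log(model$gamma_shape)
  if ("p_inv" %in% optimize) {
    par0["logit_pinv"] <- stats::qlogis(max(model$p_invariant, 1e-4))
  }
  if ("branch_scale" %in% optimize) par0["log_scale"] <- log(branch_scale)
  unpack <- function(par) {
    a <- if ("alpha" %in% optimize) exp(par[["log_alpha"]]) else
      model$gamma_shape
    p <- if ("p_inv" %in% optimize) stats::plogis(par[["logit_pinv"]]) else
      model$p_invariant
    s <- if ("branch_scale" %in% optimize) exp(par[["log_scale"]]) else
      branch_scale
    list(alpha = a, p_inv = p, scale = s)
  }

  if (length(par0) > 0) {
    ctl <- utils::modifyList(list(fnscale = -1, maxit = 200), control)
    opt <- stats::optim(par0, function(par) {
      th <- unpack(par)
      eval_ll(th$alpha, th$p_inv, th$scale)
    }, method = "L-BFGS-B",
    lower = rep(-12, length(par0)), upper = rep(12, length(par0)),
    control = ctl)
    th <- unpack(opt$par)
    convergence <- opt$convergence
  } else {
    th <- list(alpha = model$gamma_shape, p_inv = model$p_invariant,
               scale = branch_scale)
    convergence <- 0L
  }

  fitted <- model
  if (!is.null(fitted$gamma_shape)) fitted$gamma_shape <- th$alpha
  if (!is.null(fitted$p_invariant)) fitted$p_invariant <- th$p_inv

  out <- list(model = fitted, branch_scale = th$scale,
              trace = trace, convergence = convergence)

  if (branch_mode == "branch_lengths") {
    ed <- tree$edge.length * th$scale
    tr_post <- ape::reorder.phylo(tree, "postorder")
    # coordinate descent over edges on the postorder tree
    map <- match(paste(tr_post$edge[, 1], tr_post$edge[, 2]),
                 paste(tree$edge[, 1], tree$edge[, 2]))
    ed_post <- ed[map]
    ll_edges <- function(ev) {
      pp <- prep_pruning(tr_post, aln, model = fitted, edge_subst = ev)
      cat_ll <- vapply(pp$mix$rate,
                       function(r) down_pass(pp, r, keep = FALSE)$site_ll,
                       numeric(pp$nsites))
      if (pp$nsites == 1) cat_ll <- matrix(cat_ll, nrow = 1)
      sum(mixture_site_ll(cat_ll, pp$mix$weight))
    }
    for (sweep_i in 1:2) {
      for (e in seq_along(ed_post)) {
        f <- function(x) { v <- ed_post; v[e] <- x; ll_edges(v) }
        o <- stats::optimize(f, c(1e-8, max(ed_post[e] * 10, 1)),
                             maximum = TRUE, tol = 1e-4)
        if (o$objective > ll_edges(ed_post)) ed_post[e] <- o$maximum
      }
    }
    out$edge_subst <- ed_post
    out$tree_postorder <- tr_post
    out$log_likelihood <- ll_edges(ed_post)
  } else {
    out$log_likelihood <-
      log_likelihood(tree, aln, fitted, th$scale)$log_likelihood
  }
  out
}
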