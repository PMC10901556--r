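#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an affinity estimate
#'
#' @param x An `affinity_estimate` from [fit_fp_saturation()] or
#'   [fit_fp_competition()].
#' @param ... Unused.
#' @return A tibble with one row per reported route: `method`, `K_D`
#'   (uM), `std_error`, and `IC50` where applicable.
#' @method tidy affinity_estimate
#' @export
tidy.affinity_estimate <- function(x, ...) {
  out <- tibble(method = x$method, K_D = x$K_D, std_error = x$se,
                IC50 = x$IC50 %||% NA_real_)
  if (!is.null(x$K_D_direct) && x$method != "competition-direct") {
    out <- dplyr::bind_rows(out, tibble(
      method = "competition-direct", K_D = x$K_D_direct,
      std_error = x$se_direct, IC50 = NA_real_))
  }
  out
}

#' Glance at an affinity estimate
#'
#' @inheritParams tidy.affinity_estimate
#' @return A one-row tibble with fit diagnostics: residual standard error,
#'   number of points, convergence flag, and whether only a lower bound is
#'   supported.
#' @method glance affinity_estimate
#' @export
glance.affinity_estimate <- function(x, ...) {
  tibble(
    sigma = stats::sd(stats::residuals(x$fit)),
    n_points = nrow(x$data),
    converged = x$fit$convInfo$isConv %||% TRUE,
    lower_bound_only = isTRUE(x$lower_bound_only)
  )
}

#' Tidy an ITC fit
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return A tibble of parameter estimates and standard errors.
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble(
    term = c("n", "K_D_uM", "dH_kcal", "dG_kcal", "dS_kcal_per_K"),
    estimate = c(x$n, x$K_D, x$dH, x$dG, x$dS),
    std_error = c(x$se_n, x$se_K_D, x$se_dH, NA_real_, NA_real_)
  )
}

#' Glance at an ITC fit
#'
#' @inheritParams tidy.itc_fit
#' @return A one-row tibble: `K_D_uM`, `c_value`, residual sigma,
#'   injections.
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(
    K_D_uM = x$K_D, c_value = x$c_value,
    sigma = stats::sd(stats::residuals(x$fit)),
    n_injections = nrow(x$data)
  )
}

#' Glance at an ancestral posterior
#'
#' @param x An `ancestral_posterior`.
#' @param ... Unused.
#' @return A one-row tibble: total log-likelihood, node and site counts,
#'   model name, and the fraction of (node, site) posteriors whose best
#'   residue reaches 0.95.
#' @method glance ancestral_posterior
#' @export
glance.ancestral_posterior <- function(x, ...) {
  best <- apply(x$post, c(1, 2), max)
  tibble(
    log_likelihood = x$log_likelihood,
    n_nodes = dim(x$post)[1], n_sites = dim(x$post)[2],
    model = x$model$name,
    frac_confident = mean(best >= 0.95)
  )
}
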