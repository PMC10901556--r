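#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
#'   scale_x_log10 scale_y_log10 theme_minimal geom_abline geom_hline
#' @export
ggplot2::autoplot

#' Plot an FP fit (saturation or competition) with its fitted curve
#'
#' @param object An `affinity_estimate`.
#' @param n_curve Points along the fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot affinity_estimate
#' @export
autoplot.affinity_estimate <- function(object, n_curve = 200, ...) {
  d <- object$data
  xcol <- if ("competitor_uM" %in% names(d)) "competitor_uM" else
    "protein_uM"
  xs <- d[[xcol]]
  pos <- xs[xs > 0]
  grid <- tibble(!!xcol := 10^seq(log10(min(pos) / 3), log10(max(pos) * 3),
                                  length.out = n_curve))
  grid$mP <- stats::predict(object$fit, newdata = grid)
  ggplot(d, aes(x = .data[[xcol]], y = .data$mP)) +
    geom_line(data = grid, colour = "grey40") +
    geom_point() +
    scale_x_log10() +
    labs(
      x = if (xcol == "competitor_uM") "competitor (uM)" else "protein (uM)",
      y = "polarization (mP)",
      title = sprintf("%s: K_D = %.3g uM", object$method, object$K_D)
    ) +
    theme_minimal()
}

#' Plot an ITC fit: per-injection heats and fitted isotherm
#'
#' @param object An `itc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- stats::fitted(object$fit)
  ggplot(d, aes(x = .data$injection)) +
    geom_hline(yintercept = 0, colour = "grey80") +
    geom_line(aes(y = .data$fitted), colour = "grey40") +
    geom_point(aes(y = .data$heat_ucal)) +
    labs(x = "injection", y = "heat (ucal)",
         title = sprintf("1:1 isotherm: n = %.2f, K_D = %.3g uM",
                         object$n, object$K_D)) +
    theme_minimal()
}

#' Plot per-site reconstruction confidence at one node
#'
#' Shows the posterior of the best and second-best residue along the
#' sequence, with the AltAll swap rule marked.
#'
#' @param object An `ancestral_posterior`.
#' @param node Internal node (ape number); default the root.
#' @param primary_cutoff,secondary_min AltAll thresholds to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ancestral_posterior
#' @export
autoplot.ancestral_posterior <- function(object, node = NULL,
                                         primary_cutoff = 0.90,
                                         secondary_min = 0.10, ...) {
  nodes <- as.integer(dimnames(object$post)[[1]])
  if (is.null(node)) node <- nodes[1]
  p <- matrix(object$post[as.character(node), , ], ncol = 20)
  best_i <- max.col(p, ties.method = "first")
  S <- nrow(p)
  best <- p[cbind(seq_len(S), best_i)]
  p2 <- p
  p2[cbind(seq_len(S), best_i)] <- -Inf
  second_i <- max.col(p2, ties.method = "first")
  second <- p[cbind(seq_len(S), second_i)]
  d <- tibble(
    site = rep(seq_len(S), 2),
    posterior = c(best, second),
    which = rep(c("best", "second"), each = S),
    residue = AA_ALPHABET[c(best_i, second_i)],
    swapped = rep(best < primary_cutoff & second >= secondary_min, 2)
  )
  ggplot(d, aes(x = .data$site, y = .data$posterior,
                colour = .data$which)) +
    geom_hline(yintercept = primary_cutoff, linetype = 2,
               colour = "grey60") +
    geom_point(aes(shape = .data$swapped)) +
    geom_line(alpha = 0.4) +
    labs(x = "alignment site", y = "posterior probability",
         title = paste0("node ", node, ": ML vs runner-up residue"),
         colour = NULL, shape = "AltAll swap") +
    theme_minimal()
}

#' Motif versus full-length affinity scatter
#'
#' Log-log scatter of motif K_D against full-length K_D with the identity
#' line; points below the line are interactions whose flanking regions
#' tighten binding.
#'
#' @param table An affinity table (see [table1_fixture()]).
#' @param motif_col,fulllength_col Column names.
#' @return A ggplot.
#' @export
plot_affinity_comparison <- function(table,
                                     motif_col = "kd_native_motif_uM",
                                     fulllength_col = "kd_fulllength_uM") {
  d <- table[!is.na(table[[motif_col]]) & !is.na(table[[fulllength_col]]), ]
  ggplot(d, aes(x = .data[[motif_col]], y = .data[[fulllength_col]])) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point() +
    ggplot2::geom_text(aes(label = .data$label), size = 2.7, vjust = -0.8) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "motif K_D (uM)", y = "full-length K_D (uM)") +
    theme_minimal()
}
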