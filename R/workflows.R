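# End-to-end workflows: reconstruction arc and affinity arc. Each run
# writes into a fresh directory (write-once), never mutates its inputs, and
# dumps a manifest of every effective parameter so a run can be reproduced
# exactly from the manifest alone.

prepare_run_dir <- function(outdir, overwrite = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !overwrite) {
    abort(paste0("output directory is not empty: ", outdir,
                 " (runs are write-once; use overwrite = TRUE)"))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outdir
}

write_manifest <- function(outdir, params) {
  params$package_version <- as.character(utils::packageVersion("tadevo"))
  jsonlite::write_json(params, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the ancestral-reconstruction workflow
#'
#' Fits the requested substitution model on the fixed tree, computes
#' marginal ancestral posteriors at every internal node, calls ML and
#' AltAll sequences, and (optionally) a substitution-model selection table.
#' Outputs: `posteriors.tsv` (node, site, 20 probability columns, ml,
#' altall), `ancestors_ml.fasta`, `ancestors_altall.fasta`, optional
#' `model_selection.tsv`, and `manifest.json` with every effective
#' parameter.
#'
#' @param alignment Alignment object or FASTA path.
#' @param tree `phylo` tree or Newick path.
#' @param outdir Output directory (must be empty or absent).
#' @param model_name JTT-family model name.
#' @param alpha,p_inv,n_categories Starting model parameters.
#' @param primary_cutoff,secondary_min AltAll thresholds.
#' @param branch_mode Passed to [fit_model_parameters()].
#' @param model_selection If `TRUE`, also rank the JTT family variants.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the fitted model, the
#'   `ancestral_posterior`, the sequence calls, and the model-selection
#'   table (if requested).
#' @export
run_asr_workflow <- function(alignment, tree, outdir,
                             model_name = "JTT+G+I",
                             alpha = 1, p_inv = 0.1, n_categories = 5,
                             primary_cutoff = 0.9, secondary_min = 0.1,
                             branch_mode = "scale",
                             model_selection = FALSE,
                             overwrite = FALSE) {
  if (is.character(alignment) && !is.matrix(alignment) &&
      length(alignment) == 1) {
    alignment <- read_fasta_alignment(alignment)
  }
  alignment <- as_alignment(alignment)
  if (is.character(tree)) tree <- parse_newick(path = tree)
  if (!(primary_cutoff > 0 && primary_cutoff < 1 &&
        secondary_min > 0 && secondary_min < 1)) {
    abort("cutoffs must lie in (0, 1)")
  }
  prepare_run_dir(outdir, overwrite)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("workflow stage '", name, "' failed: ",
                   conditionMessage(e),
                   " — check the stage inputs listed in manifest.json"))
    })
  }

  has_g <- grepl("\\+G", model_name)
  has_i <- grepl("\\+I", model_name)
  template <- substitution_model(
    model_name,
    alpha = if (has_g) alpha, p_inv = if (has_i) p_inv,
    n_categories = n_categories,
    frequencies = if (grepl("\\+F", model_name))
      empirical_frequencies(alignment))
  fit <- step("fit_model", fit_model_parameters(tree, alignment, template,
                                                branch_mode = branch_mode))
  post <- step("marginal_posteriors",
               marginal_posteriors(tree, alignment, fit$model,
                                   branch_scale = fit$branch_scale))
  calls <- call_sequences(post, primary_cutoff, secondary_min)

  readr::write_tsv(tidy(post), file.path(outdir, "posteriors.tsv"))
  write_fasta(stats::setNames(calls$ml_sequence,
                              paste0("node_", calls$node)),
              file.path(outdir, "ancestors_ml.fasta"))
  write_fasta(stats::setNames(calls$altall_sequence,
                              paste0("node_", calls$node, "_altall")),
              file.path(outdir, "ancestors_altall.fasta"))

  sel <- NULL
  if (model_selection) {
    sel <- step("model_selection",
                model_selection_table(tree, alignment,
                                      alpha0 = alpha, p_inv0 = p_inv,
                                      n_categories = n_categories))
    readr::write_tsv(sel, file.path(outdir, "model_selection.tsv"))
  }

  write_manifest(outdir, list(
    workflow = "asr", model_name = model_name,
    alpha_start = alpha, p_inv_start = p_inv,
    alpha_fitted = fit$model$gamma_shape,
    p_inv_fitted = fit$model$p_invariant,
    branch_scale_fitted = fit$branch_scale,
    n_categories = n_categories, branch_mode = branch_mode,
    primary_cutoff = primary_cutoff, secondary_min = secondary_min,
    n_sequences = nrow(alignment), n_sites = ncol(alignment),
    n_tips = length(tree$tip.label),
    log_likelihood = post$log_likelihood,
    model_selection = model_selection
  ))
  invisible(list(fit = fit, posterior = post, calls = calls,
                 model_selection = sel))
}

#' Run the binding-affinity workflow
#'
#' Fits every titration experiment in a table (grouped by `experiment_id`):
#' saturation experiments directly, competition experiments using the probe
#' K_D — taken from a saturation experiment in the same run when present,
#' else from `probe_kd`. Writes `affinity_estimates.tsv`. When an affinity
#' table is supplied (e.g. [table1_fixture()]), also writes
#' `affinity_report.tsv` with fold-change, range-count and improvement
#' summaries.
#'
#' @param titrations Titration tibble or CSV path (columns `experiment_id`,
#'   `mode`, `probe_nM`, `protein_uM`, `competitor_uM`, `mP`, `replicate`),
#'   or `NULL` to run analytics only.
#' @param outdir Output directory (must be empty or absent).
#' @param probe_kd Probe K_D (uM) used for competition fits when no
#'   saturation experiment is present.
#' @param affinity_table Optional affinity table for summary analytics.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the per-experiment estimates tibble and
#'   the analytics summary (or `NULL`).
#' @export
run_binding_workflow <- function(titrations = NULL, outdir,
                                 probe_kd = NULL, affinity_table = NULL,
                                 overwrite = FALSE) {
  if (is.null(titrations) && is.null(affinity_table)) {
    abort("nothing to do: supply titrations and/or an affinity table")
  }
  prepare_run_dir(outdir, overwrite)

  estimates <- NULL
  if (!is.null(titrations)) {
    if (is.character(titrations)) {
      titrations <- readr::read_csv(titrations, show_col_types = FALSE)
    }
    need <- c("experiment_id", "mode", "probe_nM", "protein_uM",
              "competitor_uM", "mP")
    if (!all(need %in% names(titrations))) {
      abort(paste0("titration table must have columns: ",
                   paste(need, collapse = ", ")))
    }
    groups <- split(titrations, titrations$experiment_id)
    sat <- purrr::keep(groups, ~ .x$mode[1] == "saturation")
    comp <- purrr::keep(groups, ~ .x$mode[1] == "competition")

    sat_fits <- purrr::imap(sat, function(d, id) {
      fit_fp_saturation(d, probe_nM = d$probe_nM[1])
    })
    if (is.null(probe_kd)) {
      if (length(sat_fits) == 0 && length(comp) > 0) {
        abort(paste0(
          "competition experiments need a probe calibration: supply ",
          "probe_kd or include a saturation experiment for the probe"))
      }
      if (length(sat_fits) > 0) probe_kd <- sat_fits[[1]]$K_D
    }
    comp_fits <- purrr::imap(comp, function(d, id) {
      fit_fp_competition(d, K_D_probe = probe_kd,
                         probe_nM = d$probe_nM[1],
                         protein_uM = d$protein_uM[1])
    })
    all_fits <- c(sat_fits, comp_fits)
    estimates <- purrr::imap(all_fits, function(f, id) {
      dplyr::mutate(tidy(f), experiment_id = id, .before = 1)
    }) |> dplyr::bind_rows()
    readr::write_tsv(estimates, file.path(outdir, "affinity_estimates.tsv"))
  }

  summary_tbl <- NULL
  if (!is.null(affinity_table)) {
    fc <- fold_change(affinity_table)
    imp <- count_improved(affinity_table,
                          subset = species != "Homo sapiens")
    summary_tbl <- tibble(
      quantity = c("max_fold_change", "human_fold_change",
                   "n_improved_fulllength", "n_compared",
                   "n_motif_kd_in_0.6_4.5",
                   "exceptions"),
      value = c(
        as.character(max(fc$fold_change, na.rm = TRUE)),
        as.character(fc$fold_change[
          affinity_table$species == "Homo sapiens"][1]),
        as.character(imp$n_improved), as.character(imp$n_compared),
        as.character(count_in_range(affinity_table, "kd_native_motif_uM",
                                    0.6, 4.5,
                                    subset = species != "Homo sapiens")),
        imp$exceptions)
    )
    readr::write_tsv(summary_tbl, file.path(outdir, "affinity_report.tsv"))
  }

  write_manifest(outdir, list(
    workflow = "binding",
    probe_kd = probe_kd,
    n_experiments = if (is.null(estimates)) 0L
                    else length(unique(estimates$experiment_id)),
    analytics = !is.null(affinity_table)
  ))
  invisible(list(estimates = estimates, summary = summary_tbl))
}
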