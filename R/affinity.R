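# Analytics over the measured affinity table: motif vs full-length p53TAD
# dissociation constants for the human reference interaction and 12 fish
# p53TAD/MDM2 pairs.

#' The packaged affinity table (13 p53TAD/MDM2 interactions)
#'
#' Transcription of the published affinity measurements: for each species /
#' paralog, the canonical-motif peptide sequence (human numbering 15–27) and
#' dissociation constants (uM, with their reported uncertainties as separate
#' columns) for the native motif interaction, the motif versus human MDM2,
#' the human motif versus the native MDM2, and the full-length native
#' p53TAD. The human row carries two printed full-length values: the value
#' measured in the same study (default) and an earlier kinetics-based value
#' (`kd_fulllength_prior_uM`).
#'
#' @return A 13-row tibble (human reference + 12 fish interactions).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_affinities.csv", package = "tadevo",
                      mustWork = TRUE)
  read_affinity_table(path)
}

#' Read an affinity table from CSV
#'
#' @param path CSV with the columns of [table1_fixture()].
#' @return A tibble.
#' @export
read_affinity_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           species = "c", common_name = "c", paralog = "c",
                           label = "c", motif_sequence = "c",
                           .default = "d"))
  kd_cols <- grep("^kd_.*_uM$", names(tab), value = TRUE)
  for (col in kd_cols) {
    if (any(!is.na(tab[[col]]) & tab[[col]] <= 0)) {
      abort(paste0("non-positive K_D in column ", col))
    }
  }
  tab
}

#' Fold change between two affinity columns
#'
#' `K_D(from) / K_D(to)`: values above 1 mean the `to` interaction is
#' tighter. Rows with either value missing get `NA`.
#'
#' @param table An affinity table.
#' @param from_col,to_col Column names (default: native motif vs full-length
#'   native K_D).
#' @return The input rows with `kd_from`, `kd_to`, `fold_change` appended.
#' @export
fold_change <- function(table, from_col = "kd_native_motif_uM",
                        to_col = "kd_fulllength_uM") {
  if (!all(c(from_col, to_col) %in% names(table))) {
    abort("unknown column name(s)")
  }
  table |>
    dplyr::mutate(
      kd_from = .data[[from_col]],
      kd_to = .data[[to_col]],
      fold_change = .data$kd_from / .data$kd_to
    ) |>
    dplyr::select(dplyr::any_of(c("species", "paralog", "label")),
                  "kd_from", "kd_to", "fold_change")
}

#' Count affinities inside a closed K_D interval
#'
#' @param table An affinity table.
#' @param column K_D column to test.
#' @param lo,hi Closed interval bounds (uM), `lo <= hi`.
#' @param subset Optional filter expression evaluated in the table (e.g.
#'   `species != "Homo sapiens"`); default all rows.
#' @return Integer count of subset rows with `lo <= value <= hi`
#'   (missing values never count).
#' @export
count_in_range <- function(table, column = "kd_native_motif_uM",
                           lo = 0.6, hi = 4.5, subset = NULL) {
  if (!column %in% names(table)) abort(paste0("unknown column: ", column))
  if (lo > hi) abort("lo must be <= hi")
  expr <- rlang::enquo(subset)
  if (!rlang::quo_is_null(expr)) {
    table <- dplyr::filter(table, !!expr)
  }
  v <- table[[column]]
  sum(!is.na(v) & v >= lo & v <= hi)
}

#' Count interactions whose full-length affinity improves on the motif
#'
#' Counts rows where the full-length K_D is strictly smaller (tighter) than
#' the motif K_D, and names the exceptions.
#'
#' @param table An affinity table.
#' @param motif_col,fulllength_col Column names.
#' @param subset Optional filter expression (see [count_in_range()]).
#' @return A one-row tibble: `n_improved`, `n_compared`, and `exceptions`
#'   (comma-separated labels of non-improved rows).
#' @export
count_improved <- function(table, motif_col = "kd_native_motif_uM",
                           fulllength_col = "kd_fulllength_uM",
                           subset = NULL) {
  expr <- rlang::enquo(subset)
  if (!rlang::quo_is_null(expr)) table <- dplyr::filter(table, !!expr)
  both <- !is.na(table[[motif_col]]) & !is.na(table[[fulllength_col]])
  t2 <- table[both, ]
  improved <- t2[[fulllength_col]] < t2[[motif_col]]
  lab <- if ("label" %in% names(t2)) t2$label else t2$species
  tibble(
    n_improved = sum(improved),
    n_compared = nrow(t2),
    exceptions = paste(lab[!improved], collapse = ", ")
  )
}

#' Correlation between motif and full-length affinities
#'
#' Squared Pearson correlation of the two K_D columns on the linear or log
#' scale, over rows with both values.
#'
#' @param table An affinity table.
#' @param scale `"linear"` or `"log"` (natural log of K_D).
#' @param subset Optional filter expression.
#' @param motif_col,fulllength_col Column names.
#' @return A one-row tibble: `r_squared`, `n`, `scale`.
#' @export
motif_vs_fulllength_correlation <- function(table,
                                            scale = c("linear", "log"),
                                            subset = NULL,
                                            motif_col = "kd_native_motif_uM",
                                            fulllength_col =
                                              "kd_fulllength_uM") {
  scale <- match.arg(scale)
  expr <- rlang::enquo(subset)
  if (!rlang::quo_is_null(expr)) table <- dplyr::filter(table, !!expr)
  x <- table[[motif_col]]
  y <- table[[fulllength_col]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 paired rows")
  if (scale == "log") { x <- log(x); y <- log(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance in one column; correlation undefined")
    return(tibble(r_squared = NA_real_, n = length(x), scale = scale))
  }
  tibble(r_squared = stats::cor(x, y)^2, n = length(x), scale = scale)
}
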