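# Isothermal titration calorimetry: single-site (1:1) isotherm with
# per-injection displacement dilution.
#
# Cell contents are diluted by (1 - dV/V0) at each injection (displaced
# volume leaves the sensed cell); the syringe ligand tops the cell up. The
# same forward model is used by the simulator, and heats are in ucal with
# dH in kcal/mol.

itc_forward_heats <- function(volumes_uL, cell_uM, syringe_uM, n, K_D_uM,
                              dH_kcal, cell_volume_uL = 200) {
  V0 <- cell_volume_uL
  M <- cell_uM
  X <- 0
  C_prev <- 0
  heats <- numeric(length(volumes_uL))
  for (i in seq_along(volumes_uL)) {
    f <- 1 - volumes_uL[i] / V0
    M <- M * f
    X <- X * f + syringe_uM * volumes_uL[i] / V0
    sites <- n * M
    b <- sites + X + K_D_uM
    C <- (b - sqrt(b^2 - 4 * sites * X)) / 2
    heats[i] <- dH_kcal * (C - C_prev * f) * V0 * 1e-3 # ucal
    C_prev <- C
  }
  heats
}

#' Fit a single-site ITC isotherm
#'
#' Least-squares fit of the 1:1 binding isotherm to per-injection heats,
#' with cell dilution handled per injection. Thermodynamics follow from the
#' fitted association constant: `dG = -RT ln K_a`, `dS = (dH - dG)/T`,
#' `K_D = 1/K_a`.
#'
#' @param data A data frame with columns `injection`, `volume_uL`,
#'   `heat_ucal` (rows may be in any order; they are sorted by `injection`).
#' @param cell_uM Protein concentration in the cell at the start (uM); 11 uM
#'   in the experiments this models.
#' @param syringe_uM Ligand concentration in the syringe (uM; 116–118 uM in
#'   the modelled experiments).
#' @param cell_volume_uL Calorimeter cell volume (uL; 200 for an iTC200).
#' @param temperature Kelvin (default 298.15).
#' @return An `itc_fit` object with `n`, `K_D` (uM), `K_a` (1/M), `dH`,
#'   `dG`, `dS_T` (all kcal/mol; `dS_T = T * dS`), the `nls` fit, and the
#'   data; supports [tidy()]/[glance()]/[ggplot2::autoplot()].
#' @export
fit_itc_isotherm <- function(data, cell_uM = 11, syringe_uM = 118,
                             cell_volume_uL = 200, temperature = 298.15) {
  stopifnot(all(c("injection", "volume_uL", "heat_ucal") %in% names(data)))
  if (nrow(data) < 10) abort("need at least 10 injections")
  if (cell_uM <= 0 || syringe_uM <= 0) abort("concentrations must be > 0")
  d <- tibble::as_tibble(data[c("injection", "volume_uL", "heat_ucal")])
  d <- dplyr::arrange(d, .data$injection)

  dh0 <- sum(d$heat_ucal) / (cell_uM * cell_volume_uL * 1e-3) # rough dH
  if (dh0 == 0) dh0 <- -1
  grid <- 10^seq(-3, 1.5, length.out = 10)
  fit <- multistart_fit(function(kd0) {
    minpack.lm::nlsLM(
      heat_ucal ~ itc_forward_heats(volume_uL, cell_uM, syringe_uM,
                                    n, exp(lkd), dH, cell_volume_uL),
      data = d,
      start = list(n = 1, lkd = log(kd0), dH = dh0),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }, grid)
  co <- summary(fit)$coefficients
  kd <- exp(co["lkd", "Estimate"])
  n_fit <- co["n", "Estimate"]
  dH <- co["dH", "Estimate"]
  Ka <- 1 / (kd * 1e-6) # 1/M
  R <- 1.9872041e-3     # kcal / mol / K
  dG <- -R * temperature * log(Ka)
  dS <- (dH - dG) / temperature
  c_value <- n_fit * cell_uM * 1e-6 * Ka
  if (c_value < 1) {
    warn(sprintf(
      "c-value %.2g < 1: isotherm is shallow, expect wide confidence limits",
      c_value))
  }
  structure(
    list(n = n_fit, K_D = kd, K_a = Ka, dH = dH, dG = dG, dS = dS,
         dS_T = temperature * dS, temperature = temperature,
         se_K_D = kd * co["lkd", "Std. Error"],
         se_n = co["n", "Std. Error"], se_dH = co["dH", "Std. Error"],
         c_value = c_value, fit = fit, data = d,
         cell_uM = cell_uM, syringe_uM = syringe_uM,
         cell_volume_uL = cell_volume_uL),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("<itc_fit>\n")
  cat(sprintf("  n    = %.3f\n  K_D  = %.4g uM (K_a = %.3g /M)\n", x$n,
              x$K_D, x$K_a))
  cat(sprintf("  dH   = %.3f kcal/mol\n  dG   = %.3f kcal/mol\n", x$dH, x$dG))
  cat(sprintf("  -TdS = %.3f kcal/mol (T = %.2f K)\n", -x$dS_T,
              x$temperature))
  invisible(x)
}
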