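# Equilibrium binding models for fluorescence-polarization (FP) titrations.
#
# Concentration conventions follow the experiments being modelled: probe
# (labelled peptide) totals in the same unit as protein and competitor
# totals (micromolar throughout the package), K_D in micromolar, signals in
# millipolarization (mP), treated as linear in the bound fraction of probe.

#' Bound fraction of a ligand in a 1:1 equilibrium
#'
#' Exact quadratic solution of `P + L <-> PL` mass balance — no trace-ligand
#' approximation, so probe depletion is handled exactly.
#'
#' @param P_tot Total protein concentration (>= 0).
#' @param L_tot Total ligand (probe) concentration (>= 0).
#' @param K_D Dissociation constant (> 0), same units.
#' @return Fraction of ligand bound, in `[0, 1]` (0 when `L_tot = 0`).
#' @export
bound_fraction_single <- function(P_tot, L_tot, K_D) {
  if (any(P_tot < 0) || any(L_tot < 0)) abort("concentrations must be >= 0")
  if (any(K_D <= 0)) abort("K_D must be > 0")
  n <- max(length(P_tot), length(L_tot), length(K_D))
  P_tot <- rep_len(P_tot, n); L_tot <- rep_len(L_tot, n)
  K_D <- rep_len(K_D, n)
  b <- P_tot + L_tot + K_D
  pl <- (b - sqrt(b^2 - 4 * P_tot * L_tot)) / 2
  ifelse(L_tot > 0, pl / L_tot, 0)
}

#' Exact competitive binding equilibrium (probe + competitor for one protein)
#'
#' Solves the ternary system `P + L <-> PL`, `P + I <-> PI` exactly: free
#' protein is the unique physical root of a cubic (solved in closed
#' trigonometric form), from which all species follow.
#'
#' @param P_tot,L_tot,I_tot Total protein, probe and competitor
#'   concentrations (>= 0).
#' @param K_D_L Probe dissociation constant (> 0).
#' @param K_D_I Competitor dissociation constant (> 0).
#' @return A tibble with free and complexed concentrations `P_free`,
#'   `L_free`, `I_free`, `PL`, `PI`, and `fraction_L_bound`.
#' @export
solve_competitive_equilibrium <- function(P_tot, L_tot, I_tot, K_D_L, K_D_I) {
  n <- max(length(P_tot), length(L_tot), length(I_tot))
  P_tot <- rep_len(P_tot, n); L_tot <- rep_len(L_tot, n)
  I_tot <- rep_len(I_tot, n)
  if (any(c(P_tot, L_tot, I_tot) < 0)) abort("totals must be >= 0")
  if (K_D_L <= 0 || K_D_I <= 0) abort("dissociation constants must be > 0")

  # cubic in free protein p: p^3 + a p^2 + b p + c = 0 (Wang 1995 form)
  a <- K_D_L + K_D_I + L_tot + I_tot - P_tot
  b <- K_D_I * (L_tot - P_tot) + K_D_L * (I_tot - P_tot) + K_D_L * K_D_I
  c <- -K_D_L * K_D_I * P_tot
  q <- a^2 - 3 * b
  arg <- (-2 * a^3 + 9 * a * b - 27 * c) / (2 * sqrt(pmax(q, 0)^3))
  theta <- acos(pmin(pmax(arg, -1), 1))
  p <- -a / 3 + (2 / 3) * sqrt(pmax(q, 0)) * cos(theta / 3)
  p <- pmin(pmax(p, 0), P_tot)
  # polish with Newton steps on the monotone mass-balance residual
  f <- function(p) p * (1 + L_tot / (K_D_L + p) + I_tot / (K_D_I + p)) - P_tot
  fp <- function(p) 1 + L_tot * K_D_L / (K_D_L + p)^2 +
    I_tot * K_D_I / (K_D_I + p)^2
  for (i in 1:4) p <- pmin(pmax(p - f(p) / fp(p), 0), P_tot)

  PL <- L_tot * p / (K_D_L + p)
  PI <- I_tot * p / (K_D_I + p)
  tibble(
    P_free = p, L_free = L_tot - PL, I_free = I_tot - PI,
    PL = PL, PI = PI,
    fraction_L_bound = ifelse(L_tot > 0, PL / L_tot, 0)
  )
}

# Plain-vector wrapper used inside nls formulas (nls would misread a `$`
# extraction as a model parameter).
competition_fraction_bound <- function(P_tot, L_tot, I_tot, K_D_L, K_D_I) {
  solve_competitive_equilibrium(P_tot, L_tot, I_tot, K_D_L,
                                K_D_I)$fraction_L_bound
}

# Multi-start nonlinear least squares over a log-spaced K_D grid; returns
# the best converged nlsLM fit. Deterministic (no RNG).
multistart_fit <- function(make_formula_fit, kd_grid) {
  fits <- purrr::map(kd_grid, function(kd0) {
    tryCatch(make_formula_fit(kd0), error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("all fit starts failed", class = "tadevo_fit_error")
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  fits[[which.min(rss)]]
}

new_affinity_estimate <- function(K_D, se, method, fit, data, extra = list()) {
  structure(
    c(list(K_D = K_D, se = se, method = method, fit = fit, data = data),
      extra),
    class = "affinity_estimate"
  )
}

#' @export
print.affinity_estimate <- function(x, ...) {
  cat("<affinity_estimate> K_D = ", format(x$K_D, digits = 3),
      " +/- ", format(x$se, digits = 2), " uM  (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Fit a 1-site saturation binding curve (FP)
#'
#' Least-squares fit of `mP = mP_free + (mP_bound - mP_free) * f_bound`
#' where `f_bound` is the exact 1:1 bound fraction of the probe
#' ([bound_fraction_single()]), over parameters `(K_D, mP_free, mP_bound)`.
#' Starting `K_D` values are taken from a log-spaced grid to avoid local
#' minima.
#'
#' @param data A data frame with columns `protein_uM` (titrated protein
#'   totals) and `mP` (polarization readings).
#' @param probe_nM Total probe concentration in nM (15 nM in the assay this
#'   models).
#' @return An `affinity_estimate` (K_D in uM) with the underlying `nls` fit;
#'   supports [tidy()]/[glance()]/[ggplot2::autoplot()].
#' @export
fit_fp_saturation <- function(data, probe_nM = 15) {
  stopifnot(all(c("protein_uM", "mP") %in% names(data)))
  if (nrow(data) < 6) abort("need at least 6 titration points")
  if (any(data$protein_uM < 0)) abort("concentrations must be >= 0")
  L <- probe_nM / 1000
  if (diff(range(data$mP)) == 0) {
    abort("flat signal: binding amplitude is not identifiable",
          class = "tadevo_fit_error")
  }
  grid <- 10^seq(-4, 2, length.out = 13)
  fit <- multistart_fit(function(kd0) {
    minpack.lm::nlsLM(
      mP ~ f0 + (f1 - f0) * bound_fraction_single(protein_uM, L, exp(lkd)),
      data = data,
      start = list(f0 = min(data$mP), f1 = max(data$mP), lkd = log(kd0)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, grid)
  co <- summary(fit)$coefficients
  kd <- exp(co["lkd", "Estimate"])
  se <- kd * co["lkd", "Std. Error"] # delta method on log scale
  amp <- abs(co["f1", "Estimate"] - co["f0", "Estimate"])
  noise <- stats::sd(stats::residuals(fit))
  if (amp < 3 * noise) {
    abort("flat signal: amplitude below noise floor; K_D unidentifiable",
          class = "tadevo_fit_error")
  }
  new_affinity_estimate(kd, se, "saturation-fit", fit,
                        tibble::as_tibble(data[c("protein_uM", "mP")]),
                        list(probe_nM = probe_nM))
}

#' Convert an IC50 to a competitor K_D (exact competition correction)
#'
#' Implements the exact conversion used for competitive FP displacement
#' data: from the 50%-displacement point, the free concentrations of probe,
#' protein and competitor are recovered from mass balance (no trace
#' approximations) and `K_D = P_free * I_free / PI` evaluated there. In the
#' trace-probe, trace-protein limit this reduces to the Cheng-Prusoff form
#' `K_D = IC50 / (1 + L_free / K_D_probe)`.
#'
#' @param IC50 Total competitor concentration at half-maximal displacement
#'   (uM).
#' @param K_D_probe Probe dissociation constant (uM).
#' @param probe_total Total probe concentration (uM).
#' @param protein_total Total protein concentration (uM).
#' @return Competitor `K_D` (uM).
#' @export
kd_from_ic50 <- function(IC50, K_D_probe, probe_total, protein_total) {
  if (any(c(IC50, K_D_probe, probe_total, protein_total) <= 0)) {
    abort("all inputs must be > 0")
  }
  PL0 <- bound_fraction_single(protein_total, probe_total, K_D_probe) *
    probe_total
  PL50 <- PL0 / 2
  L50 <- probe_total - PL50
  P50 <- K_D_probe * PL50 / L50
  PI50 <- protein_total - P50 - PL50
  I50 <- IC50 - PI50
  if (any(PI50 <= 0) || any(I50 <= 0)) {
    abort(paste0("IC50 below the tight-binding floor (~protein_total/2): ",
                 "competitor K_D not recoverable from this IC50"),
          class = "tadevo_infeasible")
  }
  P50 * I50 / PI50
}

#' Fit an FP displacement (competition) curve by two routes
#'
#' Route A (primary, mirroring common practice with competition FP data):
#' a four-parameter logistic is fitted to `mP` versus log competitor
#' concentration to extract the IC50, which is converted to the competitor
#' `K_D` by the exact competition correction of [kd_from_ic50()]. Route B:
#' direct least-squares fit of the exact ternary equilibrium
#' ([solve_competitive_equilibrium()]) to the same curve. Both are reported.
#'
#' @param data A data frame with columns `competitor_uM` and `mP`.
#' @param K_D_probe Probe K_D (uM), from a saturation experiment.
#' @param probe_nM Total probe (nM).
#' @param protein_uM Total protein (uM).
#' @return An `affinity_estimate` whose `K_D`/`se` are the route-A values,
#'   with `K_D_direct`/`se_direct` (route B), `IC50`, and both fits
#'   attached. If the curve shows < 10% displacement the estimate is
#'   returned as a lower bound (`lower_bound_only = TRUE`) with a warning.
#' @export
fit_fp_competition <- function(data, K_D_probe, probe_nM = 15,
                               protein_uM = 1) {
  stopifnot(all(c("competitor_uM", "mP") %in% names(data)))
  if (nrow(data) < 6) abort("need at least 6 titration points")
  if (K_D_probe <= 0) abort("K_D_probe must be > 0")
  L <- probe_nM / 1000
  d <- tibble::as_tibble(data[c("competitor_uM", "mP")])

  f_bound0 <- bound_fraction_single(protein_uM, L, K_D_probe)
  span <- max(d$mP) - min(d$mP)
  rel_change <- span / max(abs(d$mP))
  lower_bound_only <- FALSE
  if (span < 1e-10 || rel_change < 0.10) {
    warn("less than 10% displacement: reporting a lower bound on K_D")
    lower_bound_only <- TRUE
  }

  # Route A: 4PL logistic in log-concentration
  grid <- 10^seq(-4, 2, length.out = 13)
  fitA <- multistart_fit(function(kd0) {
    minpack.lm::nlsLM(
      mP ~ bottom + (top - bottom) /
        (1 + (competitor_uM / exp(lic))^h),
      data = d,
      start = list(top = max(d$mP), bottom = min(d$mP),
                   lic = log(kd0), h = 1),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }, grid)
  coA <- summary(fitA)$coefficients
  ic50 <- exp(coA["lic", "Estimate"])
  # The 4PL inflection is a biased IC50 estimate when the displacement
  # curve is asymmetric (tight binders near the stoichiometric regime).
  # Refine it to the concentration where the replicate-averaged curve
  # crosses the half-signal point between the fitted plateaus.
  mid_mP <- (coA["top", "Estimate"] + coA["bottom", "Estimate"]) / 2
  avg <- d |>
    dplyr::filter(.data$competitor_uM > 0) |>
    dplyr::summarise(mP = mean(.data$mP), .by = "competitor_uM") |>
    dplyr::arrange(.data$competitor_uM)
  cross <- which(diff(sign(avg$mP - mid_mP)) != 0)
  if (length(cross) > 0) {
    i <- cross[which.min(abs(log(avg$competitor_uM[cross]) - log(ic50)))]
    x1 <- log(avg$competitor_uM[i]); x2 <- log(avg$competitor_uM[i + 1])
    y1 <- avg$mP[i]; y2 <- avg$mP[i + 1]
    dif <- diff(avg$mP)
    if (all(dif <= 0) || all(dif >= 0)) {
      # monotone curve: shape-preserving spline inversion
      sf <- stats::splinefun(log(avg$competitor_uM), avg$mP,
                             method = "hyman")
      ic50 <- exp(stats::uniroot(function(x) sf(x) - mid_mP,
                                 c(x1, x2), tol = 1e-12)$root)
    } else {
      ic50 <- exp(x1 + (mid_mP - y1) / (y2 - y1) * (x2 - x1))
    }
  }
  kdA <- tryCatch(
    kd_from_ic50(ic50, K_D_probe, L, protein_uM),
    tadevo_infeasible = function(e) NA_real_)
  seA <- if (is.na(kdA)) NA_real_ else {
    # propagate the log-IC50 SE through the conversion numerically
    dk <- function(x) kd_from_ic50(x, K_D_probe, L, protein_uM)
    h <- ic50 * 1e-4
    grad <- (dk(ic50 + h) - dk(ic50 - h)) / (2 * h)
    abs(grad) * ic50 * coA["lic", "Std. Error"]
  }

  # Route B: exact ternary model
  fitB <- multistart_fit(function(kd0) {
    minpack.lm::nlsLM(
      mP ~ f0 + (f1 - f0) * competition_fraction_bound(
        protein_uM, L, competitor_uM, K_D_probe, exp(lkd)),
      data = d,
      start = list(f1 = max(d$mP), f0 = min(d$mP), lkd = log(kd0)),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }, grid)
  coB <- summary(fitB)$coefficients
  kdB <- exp(coB["lkd", "Estimate"])
  seB <- kdB * coB["lkd", "Std. Error"]

  primary_kd <- if (is.na(kdA)) kdB else kdA
  primary_se <- if (is.na(kdA)) seB else seA
  new_affinity_estimate(
    primary_kd, primary_se,
    if (is.na(kdA)) "competition-direct" else "competition-conversion",
    fitA, d,
    list(K_D_direct = kdB, se_direct = seB, IC50 = ic50,
         fit_direct = fitB, K_D_probe = K_D_probe,
         probe_nM = probe_nM, protein_uM = protein_uM,
         fraction_bound_0 = f_bound0,
         lower_bound_only = lower_bound_only))
}
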