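test_that("single-site bound fraction solves the quadratic exactly", {
  expect_equal(bound_fraction_single(0, 0.015, 1), 0)
  expect_equal(bound_fraction_single(1, 1, 1), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  # stoichiometric limit
  expect_equal(bound_fraction_single(0.4, 1, 1e-12), 0.4,
               tolerance = 1e-6)
  expect_equal(bound_fraction_single(2, 1, 1e-12), 1, tolerance = 1e-6)
  expect_error(bound_fraction_single(-1, 1, 1), ">= 0")
  expect_error(bound_fraction_single(1, 1, 0), "> 0")
})

test_that("competitive equilibrium conserves mass and matches bisection", {
  # degenerate case: no competitor reduces to the single-site solution
  eq0 <- solve_competitive_equilibrium(1, 0.015, 0, 0.1, 3.6)
  expect_equal(eq0$fraction_L_bound,
               bound_fraction_single(1, 0.015, 0.1), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:25) {
    P <- runif(1, 0.01, 5); L <- runif(1, 0.001, 1)
    I <- runif(1, 0, 100)
    kL <- 10^runif(1, -3, 1); kI <- 10^runif(1, -3, 1.5)
    eq <- solve_competitive_equilibrium(P, L, I, kL, kI)
    expect_equal(eq$P_free + eq$PL + eq$PI, P, tolerance = 1e-9 * max(1, P))
    expect_equal(eq$L_free + eq$PL, L, tolerance = 1e-9)
    expect_equal(eq$I_free + eq$PI, I, tolerance = 1e-9 * max(1, I))
    oracle <- bisect_competitive(P, L, I, kL, kI)
    expect_equal(eq$fraction_L_bound, oracle$fraction_L_bound,
                 tolerance = 1e-6)
  }
})

test_that("displacement signal is monotone in competitor concentration", {
  series <- c(0, 10^seq(-2, 3, length.out = 30))
  fb <- solve_competitive_equilibrium(1, 0.015, series, 0.1,
                                      2)$fraction_L_bound
  expect_true(all(diff(fb) <= 1e-12))
})

test_that("noiseless saturation data are refit exactly", {
  d <- simulate_fp_dataset("saturation", K_D = 0.1, noise_sd = 0, seed = 7)
  est <- fit_fp_saturation(d)
  expect_equal(est$K_D, 0.1, tolerance = 1e-6)
  expect_equal(est$method, "saturation-fit")

  flat <- d
  flat$mP <- 100
  expect_error(fit_fp_saturation(flat), "flat signal")
})

test_that("saturation confidence intervals are calibrated", {
  hits <- 0
  for (seed in 1:100) {
    d <- simulate_fp_dataset("saturation", K_D = 0.1, noise_sd = 2,
                             seed = seed)
    est <- fit_fp_saturation(d)
    ci <- est$K_D * exp(c(-1, 1) * 1.96 * est$se / est$K_D)
    if (ci[1] <= 0.1 && 0.1 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("noiseless competition data are refit exactly by the direct route", {
  d <- simulate_fp_dataset("competition", K_D = 3.6, K_D_probe = 0.1,
                           protein_uM = 1, noise_sd = 0, seed = 3)
  est <- fit_fp_competition(d, K_D_probe = 0.1, protein_uM = 1)
  expect_equal(est$K_D_direct, 3.6, tolerance = 1e-4)
  # both routes reported, conversion route primary
  expect_equal(est$method, "competition-conversion")
  expect_equal(tidy(est)$method,
               c("competition-conversion", "competition-direct"))
})

test_that("IC50 conversion inverts the forward competition model", {
  # across the assay's concentration regimes
  grid <- expand.grid(protein = c(0.2, 0.5, 1, 2),
                      kd_true = c(0.05, 0.5, 3.6, 10))
  for (r in seq_len(nrow(grid))) {
    P <- grid$protein[r]; kd_true <- grid$kd_true[r]
    L <- 0.015; kdL <- 0.1
    f <- function(i) solve_competitive_equilibrium(P, L, i, kdL,
                                                   kd_true)$fraction_L_bound
    f0 <- f(0)
    ic50 <- uniroot(function(i) f(i) - f0 / 2, c(1e-8, 1e6),
                    tol = 1e-13)$root
    expect_equal(kd_from_ic50(ic50, kdL, L, P), kd_true,
                 tolerance = 0.02 * kd_true)
  }
})

test_that("IC50 conversion has the right limits", {
  # Cheng-Prusoff in the trace-probe, trace-protein limit
  L <- 1e-6; P <- 1e-6; kdL <- 0.5
  ic50 <- 4
  Lfree <- L # effectively all free
  expect_equal(kd_from_ic50(ic50, kdL, L, P),
               ic50 / (1 + Lfree / kdL), tolerance = 1e-4)
  # tight-binding floor: IC50 at protein/2 with a trace probe is infeasible
  expect_error(kd_from_ic50(0.5, 0.1, 1e-4, 1), class = "tadevo_infeasible")
  expect_error(kd_from_ic50(-1, 0.1, 0.015, 1), "> 0")
})

test_that("conversion and direct routes agree in the assay regime", {
  # probe far below protein (15 nM vs 0.2-2 uM), as in the experiments
  for (cfg in list(list(P = 0.2, kd = 0.26), list(P = 1, kd = 3.6),
                   list(P = 2, kd = 1.6), list(P = 1, kd = 0.049))) {
    d <- simulate_fp_dataset("competition", K_D = cfg$kd,
                             K_D_probe = 0.1, protein_uM = cfg$P,
                             noise_sd = 0, seed = 17)
    est <- fit_fp_competition(d, K_D_probe = 0.1, protein_uM = cfg$P)
    expect_equal(est$K_D, est$K_D_direct, tolerance = 0.05)
  }
})

test_that("competition K_D is recovered under realistic noise", {
  d <- simulate_fp_dataset("competition", K_D = 3.6, K_D_probe = 0.1,
                           protein_uM = 1, noise_sd = 2, seed = 41,
                           n_replicates = 2)
  est <- fit_fp_competition(d, K_D_probe = 0.1, protein_uM = 1)
  expect_equal(est$K_D, 3.6, tolerance = 0.15)
})

test_that("a probe competing against itself gives consistent routes", {
  d <- simulate_fp_dataset("competition", K_D = 0.1, K_D_probe = 0.1,
                           protein_uM = 0.5, noise_sd = 0, seed = 23)
  est <- fit_fp_competition(d, K_D_probe = 0.1, protein_uM = 0.5)
  expect_equal(est$K_D, est$K_D_direct, tolerance = 0.05)
  expect_equal(est$K_D_direct, 0.1, tolerance = 1e-3)
})

test_that("undisplaceable curves are flagged as lower bounds", {
  series <- c(0, 10^seq(-2, 1, length.out = 11))
  d <- tibble::tibble(competitor_uM = series,
                      mP = 200 + rep(0.01, 12) * seq_len(12))
  expect_warning(
    est <- fit_fp_competition(d, K_D_probe = 0.1, protein_uM = 1),
    "lower bound")
  expect_true(glance(est)$lower_bound_only)
})

test_that("noiseless ITC isotherms are refit within 1%", {
  d <- simulate_itc_dataset(n = 1, K_D_uM = 0.3, dH_kcal = -8,
                            cell_uM = 11, syringe_uM = 118, noise_sd = 0)
  fit <- fit_itc_isotherm(d, cell_uM = 11, syringe_uM = 118)
  expect_equal(fit$n, 1, tolerance = 0.01)
  expect_equal(fit$K_D, 0.3, tolerance = 0.01)
  expect_equal(fit$dH, -8, tolerance = 0.01)
  # thermodynamic identities hold by construction
  expect_equal(fit$dG, fit$dH - fit$temperature * fit$dS,
               tolerance = 1e-10)
  expect_equal(fit$K_D, 1 / fit$K_a * 1e6, tolerance = 1e-10)
})

test_that("ITC fits are invariant to data row order", {
  d <- simulate_itc_dataset(noise_sd = 0.05, seed = 9)
  shuffled <- d[sample(nrow(d)), ]
  f1 <- fit_itc_isotherm(d)
  f2 <- fit_itc_isotherm(shuffled)
  expect_equal(f1$K_D, f2$K_D, tolerance = 1e-10)
  expect_equal(f1$dH, f2$dH, tolerance = 1e-10)
})

test_that("shallow isotherms trigger a c-value warning", {
  d <- simulate_itc_dataset(K_D_uM = 300, dH_kcal = -8, noise_sd = 0)
  expect_warning(fit_itc_isotherm(d), "c-value")
})
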