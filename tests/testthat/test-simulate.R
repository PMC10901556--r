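test_that("generators are deterministic given the seed", {
  tr <- simulate_chronogram(6, height = 100, seed = 2)
  m <- substitution_model("JTT+G+I", alpha = 1, p_inv = 0.2)
  a1 <- simulate_alignment(tr, m, 50, seed = 5, branch_scale = 0.01)
  a2 <- simulate_alignment(tr, m, 50, seed = 5, branch_scale = 0.01)
  expect_identical(a1$alignment, a2$alignment)
  expect_identical(a1$truth$node_states, a2$truth$node_states)

  d1 <- simulate_fp_dataset(seed = 3)
  d2 <- simulate_fp_dataset(seed = 3)
  expect_identical(d1$mP, d2$mP)
  expect_false(identical(d1$mP, simulate_fp_dataset(seed = 4)$mP))

  i1 <- simulate_itc_dataset(seed = 8)
  i2 <- simulate_itc_dataset(seed = 8)
  expect_identical(i1$heat_ucal, i2$heat_ucal)
})

test_that("zero-length branches copy the root everywhere", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  tr$edge.length[] <- 0
  m <- substitution_model("JTT")
  sim <- simulate_alignment(tr, m, 30, seed = 1)
  aln <- unclass(sim$alignment)
  expect_true(all(aln[1, ] == aln[2, ]) && all(aln[1, ] == aln[3, ]))
})

test_that("invariant-category sites never change along the tree", {
  tr <- simulate_chronogram(8, height = 300, seed = 6)
  m <- substitution_model("JTT+G+I", alpha = 1, p_inv = 0.4)
  sim <- simulate_alignment(tr, m, 200, seed = 9, branch_scale = 0.01)
  mix <- sim$truth$mixture
  inv_sites <- which(mix$rate[sim$truth$site_category] == 0)
  expect_gt(length(inv_sites), 0)
  st <- sim$truth$node_states[, inv_sites, drop = FALSE]
  expect_true(all(apply(st, 2, function(col) all(col == col[1]))))
})

test_that("long branches decorrelate ends to joint stationarity", {
  # rate*t = 50 on both branches: tip states should be independent draws
  # from the equilibrium frequencies
  tr <- parse_newick("(A:25,B:25);")
  m <- substitution_model("JTT")
  sim <- simulate_alignment(tr, m, 20000, seed = 31, branch_scale = 2)
  aln <- unclass(sim$alignment)
  counts <- table(factor(aln["A", ], levels = tadevo:::AA_ALPHABET))
  chi <- suppressWarnings(
    chisq.test(counts, p = unname(m$pi)))
  expect_gt(chi$p.value, 1e-3)
  # joint frequency of a common pair approximates the product
  pA <- mean(aln["A", ] == "L")
  pB <- mean(aln["B", ] == "A")
  pAB <- mean(aln["A", ] == "L" & aln["B", ] == "A")
  se <- sqrt(pA * pB * (1 - pA * pB) / 20000)
  expect_lt(abs(pAB - pA * pB), 4 * se + 1e-12)
})

test_that("simulated composition tracks +F frequencies", {
  tr <- simulate_chronogram(4, height = 100, seed = 3)
  freqs <- rep(1 / 20, 20)
  m <- substitution_model("JTT+G+I+F", alpha = 1, p_inv = 0.1,
                          frequencies = freqs)
  sim <- simulate_alignment(tr, m, 5000, seed = 12, branch_scale = 0.01)
  comp <- empirical_frequencies(sim$alignment)
  expect_lt(max(abs(comp - 0.05)), 0.02)
})

test_that("generator outputs pass the fitters' input validation", {
  sat <- simulate_fp_dataset("saturation", noise_sd = 1, seed = 2)
  expect_s3_class(fit_fp_saturation(sat), "affinity_estimate")
  comp <- simulate_fp_dataset("competition", noise_sd = 1, seed = 2)
  expect_s3_class(fit_fp_competition(comp, K_D_probe = 0.1),
                  "affinity_estimate")
  itc <- simulate_itc_dataset(seed = 2)
  expect_s3_class(fit_itc_isotherm(itc), "itc_fit")
})

test_that("FP generator edge cases behave", {
  expect_error(simulate_fp_dataset(noise_sd = -1), "noise_sd")
  noiseless <- simulate_fp_dataset("competition", K_D = 2, noise_sd = 0,
                                   seed = 1)
  truth <- attr(noiseless, "truth")
  frac <- solve_competitive_equilibrium(
    1, 0.015, noiseless$competitor_uM, truth$K_D_probe,
    2)$fraction_L_bound
  expect_equal(noiseless$mP,
               truth$mP_free + (truth$mP_bound - truth$mP_free) * frac,
               tolerance = 1e-12)
  # zero competitor everywhere: flat at the bound-plateau level
  flat <- simulate_fp_dataset("competition", K_D = 2, noise_sd = 0,
                              series = rep(0, 8) + c(0, 1e-12 * 1:7),
                              seed = 1)
  expect_lt(diff(range(flat$mP)), 1e-6)
})

test_that("ITC generator matches its forward model and limits", {
  d0 <- simulate_itc_dataset(noise_sd = 0)
  expect_equal(d0$heat_ucal,
               tadevo:::itc_forward_heats(d0$volume_uL, 11, 118, 1, 0.3, -8),
               tolerance = 1e-12)
  dz <- simulate_itc_dataset(dH_kcal = 0, noise_sd = 0)
  expect_true(all(dz$heat_ucal == 0))
  # doubling the syringe concentration halves the saturation midpoint
  h1 <- simulate_itc_dataset(K_D_uM = 0.05, syringe_uM = 118,
                             n_injections = 40, noise_sd = 0)
  h2 <- simulate_itc_dataset(K_D_uM = 0.05, syringe_uM = 236,
                             n_injections = 40, noise_sd = 0)
  mid <- function(d) which.max(abs(diff(d$heat_ucal)))
  expect_equal(mid(h2), ceiling(mid(h1) / 2), tolerance = 1)
})

test_that("the WGD chronogram has the advertised structure", {
  tr <- simulate_wgd_chronogram(seed = 11)
  expect_equal(length(tr$tip.label), 62)
  expect_true(is_chronogram(tr))
  expect_equal(max(node_ages(tr)), 430, tolerance = 1e-6)
  wgd <- length(tr$tip.label) + match("wgd", tr$node.label)
  expect_equal(node_ages(tr)[wgd], 303, tolerance = 1e-6)
  expect_equal(sum(grepl("_P1$", tr$tip.label)), 20)
  expect_equal(sum(grepl("_P2$", tr$tip.label)), 20)
  expect_error(simulate_wgd_chronogram(clade_age = 310), "clade_age")
})
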