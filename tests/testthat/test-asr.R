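toy_model <- function() substitution_model("JTT+G+I", alpha = 0.7,
                                           p_inv = 0.15)

test_that("single observed sequence gives the stationary log-frequency", {
  # second taxon is all-gap, so the data reduce to one observed residue;
  # by stationarity the site likelihood is exactly pi_a
  tr <- parse_newick("(A:0.3,B:0.7);")
  m <- toy_model()
  for (res in c("A", "W", "L")) {
    ll <- log_likelihood(tr, c(A = res, B = "-"), m)
    expect_equal(ll$log_likelihood, log(unname(m$pi[res])),
                 tolerance = 1e-12)
  }
})

test_that("an all-gap taxon does not change the likelihood", {
  tr <- parse_newick("((A:0.3,B:0.5):0.2,(C:0.4,D:0.1):0.3);")
  tr5 <- parse_newick(
    "((A:0.3,B:0.5):0.2,((C:0.2,E:0.2):0.2,D:0.1):0.3);")
  m <- toy_model()
  base <- log_likelihood(tr, c(A = "FSDL", B = "FSDM", C = "YSDL",
                               D = "FTDL"), m)
  with_gap <- log_likelihood(tr5, c(A = "FSDL", B = "FSDM", C = "YSDL",
                                    D = "FTDL", E = "----"), m)
  expect_equal(with_gap$log_likelihood, base$log_likelihood,
               tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  m <- toy_model()
  set.seed(42)
  for (seed in 1:3) {
    n <- sample(3:5, 1)
    tr <- random_chronogram(n, height = 150, seed = seed)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c(tadevo:::AA_ALPHABET, "-"), 2, replace = TRUE,
                   prob = c(rep(1, 20), 2)), collapse = "")
    }, character(1))
    names(seqs) <- tr$tip.label
    scale <- 0.004
    mine <- log_likelihood(tr, seqs, m, branch_scale = scale)
    oracle <- enum_engine(tr, seqs, m, branch_scale = scale)
    expect_equal(mine$site_log_likelihoods, oracle$site_log_likelihoods,
                 tolerance = 1e-9)

    post <- marginal_posteriors(tr, seqs, m, branch_scale = scale)
    expect_equal(max(abs(post$post - oracle$post)), 0, tolerance = 1e-8)
    sums <- apply(post$post, c(1, 2), sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-8)
  }
})

test_that("plain JTT agrees with an independent pruning implementation", {
  tr <- parse_newick("((A:0.3,B:0.5):0.2,(C:0.4,D:0.1):0.3);")
  seqs <- c(A = "FSDL", B = "FSDM", C = "YSDL", D = "FTDL")
  mine <- log_likelihood(tr, seqs, substitution_model("JTT"))
  pd <- phangorn::phyDat(do.call(rbind, strsplit(unname(seqs), "")) |>
                           `rownames<-`(names(seqs)), type = "AA")
  ref <- phangorn::pml(tr, pd, model = "JTT")
  expect_equal(mine$log_likelihood, as.numeric(ref$logLik),
               tolerance = 1e-8)
})

test_that("likelihood is invariant to root placement", {
  tr <- random_chronogram(6, height = 100, seed = 9)
  seqs <- c("FSDLA", "FSDMA", "YSDLC", "FTDLA", "FSELA", "WSDLA")
  names(seqs) <- tr$tip.label
  m <- toy_model()
  base <- log_likelihood(tr, seqs, m, branch_scale = 0.005)$log_likelihood
  for (og in tr$tip.label[c(2, 5)]) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og,
                          resolve.root = TRUE)
    ll <- log_likelihood(rerooted, seqs, m,
                         branch_scale = 0.005)$log_likelihood
    expect_equal(ll, base, tolerance = 1e-9)
  }
})

test_that("a zero-length branch pins the nodal posterior to the leaf", {
  tr <- parse_newick("((A:0,B:1):1,C:2);")
  m <- toy_model()
  post <- marginal_posteriors(tr, c(A = "W", B = "F", C = "L"), m,
                              branch_scale = 0.01)
  node_above_A <- as.character(
    tr$edge[tr$edge[, 2] == match("A", tr$tip.label), 1])
  expect_equal(unname(post$post[node_above_A, 1, "W"]), 1,
               tolerance = 1e-9)
})

test_that("parameter fitting is a local optimum and idempotent", {
  tr <- random_chronogram(6, height = 100, seed = 4)
  m_true <- substitution_model("JTT+G+I", alpha = 0.8, p_inv = 0.2)
  sim <- simulate_alignment(tr, m_true, 150, seed = 21,
                            branch_scale = 0.01)
  start <- substitution_model("JTT+G+I", alpha = 2, p_inv = 0.05)
  ll_start <- log_likelihood(tr, sim$alignment, start,
                             branch_scale = 0.005)$log_likelihood
  fit <- fit_model_parameters(tr, sim$alignment, start,
                              branch_scale = 0.005)
  expect_gte(fit$log_likelihood, ll_start)
  expect_true(all(diff(fit$trace) >= 0)) # best-so-far trace is monotone

  # local optimum: +-1% perturbations do not improve the likelihood
  for (delta in c(0.99, 1.01)) {
    m_pert <- fit$model
    m_pert$gamma_shape <- fit$model$gamma_shape * delta
    expect_lte(
      log_likelihood(tr, sim$alignment, m_pert,
                     fit$branch_scale)$log_likelihood,
      fit$log_likelihood + 1e-6)
    expect_lte(
      log_likelihood(tr, sim$alignment, fit$model,
                     fit$branch_scale * delta)$log_likelihood,
      fit$log_likelihood + 1e-6)
  }

  refit <- fit_model_parameters(tr, sim$alignment, fit$model,
                                branch_scale = fit$branch_scale)
  expect_equal(refit$log_likelihood, fit$log_likelihood, tolerance = 1e-6)
})

test_that("per-branch optimization improves on the clock scaling", {
  tr <- random_chronogram(4, height = 100, seed = 13)
  m <- substitution_model("JTT")
  sim <- simulate_alignment(tr, m, 60, seed = 5, branch_scale = 0.01)
  fit_scale <- fit_model_parameters(tr, sim$alignment, m,
                                    optimize = "branch_scale")
  fit_bl <- fit_model_parameters(tr, sim$alignment, m,
                                 optimize = "branch_scale",
                                 branch_mode = "branch_lengths")
  expect_gte(fit_bl$log_likelihood, fit_scale$log_likelihood - 1e-6)
})

test_that("AltAll calls follow the two-threshold rule exactly", {
  p <- array(0, dim = c(1, 3, 20),
             dimnames = list("7", NULL, tadevo:::AA_ALPHABET))
  # site 1: confident (0.95); site 2: ambiguous (0.85/0.12);
  # site 3: weak runner-up (0.89/0.08)
  p[1, 1, c("A", "C")] <- c(0.95, 0.05)
  p[1, 2, c("L", "M")] <- c(0.85, 0.12); p[1, 2, "A"] <- 0.03
  p[1, 3, c("W", "F")] <- c(0.89, 0.08); p[1, 3, "A"] <- 0.03
  fake <- structure(list(post = p), class = "ancestral_posterior")
  calls <- call_sequences(fake)
  expect_equal(calls$ml_sequence, "ALW")
  expect_equal(calls$altall_sequence, "AMW")
  expect_equal(calls$n_ambiguous, 1)
  expect_error(call_sequences(fake, primary_cutoff = 0), "cutoffs")
})

test_that("AltAll differs from ML exactly at rule sites (random tables)", {
  set.seed(7)
  for (rep_i in 1:5) {
    nsite <- 40
    raw <- matrix(rexp(nsite * 20)^3, nsite, 20)
    raw <- raw / rowSums(raw)
    p <- array(raw, dim = c(1, nsite, 20),
               dimnames = list("9", NULL, tadevo:::AA_ALPHABET))
    fake <- structure(list(post = p), class = "ancestral_posterior")
    calls <- call_sequences(fake)
    ml <- strsplit(calls$ml_sequence, "")[[1]]
    alt <- strsplit(calls$altall_sequence, "")[[1]]
    best <- apply(raw, 1, max)
    second <- apply(raw, 1, function(x) sort(x, decreasing = TRUE)[2])
    rule <- best < 0.90 & second >= 0.10
    expect_identical(which(ml != alt), which(rule))
  }
})

test_that("AICc/BIC arithmetic matches hand computation", {
  ic <- information_criteria(-3000, 10, 500)
  expect_equal(ic$AICc, 6000 + 20 + 2 * 10 * 11 / 489, tolerance = 1e-12)
  expect_equal(ic$AICc, 6020.449897750, tolerance = 1e-9)
  expect_equal(ic$BIC, 6000 + 10 * log(500), tolerance = 1e-12)
  expect_true(is.na(information_criteria(-10, 5, 6)$AICc))
})

test_that("model selection table ranks, weighs and degrades sanely", {
  tr <- random_chronogram(6, height = 100, seed = 2)
  m <- substitution_model("JTT+G", alpha = 0.5)
  sim <- simulate_alignment(tr, m, 120, seed = 3, branch_scale = 0.01)

  single <- model_selection_table(tr, sim$alignment, models = "JTT")
  expect_equal(single$akaike_weight, 1, tolerance = 1e-10)

  twin <- model_selection_table(tr, sim$alignment,
                                models = c("JTT", "JTT"))
  expect_equal(twin$akaike_weight, c(0.5, 0.5), tolerance = 1e-10)

  tab <- model_selection_table(tr, sim$alignment,
                               models = c("JTT", "JTT+G"))
  expect_equal(sum(tab$akaike_weight), 1, tolerance = 1e-10)
  expect_false(is.unsorted(tab$AICc))
  expect_equal(tab$k[tab$model == "JTT"], 1)
  expect_equal(tab$k[tab$model == "JTT+G"], 2)

  expect_warning(
    model_selection_table(tr, sim$alignment, models = "JTT+G+I+F",
                          sample_size = 20),
    "AICc undefined")
})
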