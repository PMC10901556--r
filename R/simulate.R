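# Synthetic-data generators. Each takes an explicit integer seed and is
# deterministic given (inputs, seed); RNG state is restored afterwards.

#' Simulate a random chronogram
#'
#' Coalescent topology rescaled to a given height — a convenient stand-in
#' for a time-calibrated species tree in tests and recovery studies.
#'
#' @param n_tips Number of leaves.
#' @param height Root age (My).
#' @param seed Integer seed.
#' @param labels Optional tip labels (default `t1..tn`).
#' @return An ultrametric `phylo` tree of the given height.
#' @export
simulate_chronogram <- function(n_tips, height = 430, seed = 1,
                                labels = NULL) {
  if (n_tips < 2) abort("need at least 2 tips")
  tr <- withr::with_seed(seed, ape::rcoal(n_tips, tip.label = labels))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) *
    height
  tr
}

#' Simulate a chronogram with a duplicated (WGD) clade
#'
#' Builds a species chronogram shaped like the reconstruction problem this
#' package targets: a recent clade of `n_clade` species (random coalescent
#' topology), a ladder of `n_outgroup` successively deeper outgroups, and a
#' whole-genome duplication represented by duplicating the clade at
#' `wgd_age`, which doubles its leaves into `_P1`/`_P2` paralog copies. The
#' defaults give 20 + 22 species and 62 leaves after duplication at 303 My,
#' the leaf count of the p53TAD reconstruction this emulates.
#'
#' @param n_clade Species in the duplicated clade.
#' @param n_outgroup Outgroup species on the backbone ladder.
#' @param clade_age Age (My) of the clade root; must be below `wgd_age`.
#' @param height Root age (My) of the whole tree; must exceed `wgd_age`.
#' @param wgd_age Age (My) of the duplication (default 303).
#' @param seed Integer seed (clade topology).
#' @param suffixes Paralog suffixes for the duplicated leaves.
#' @return An ultrametric `phylo` tree with `n_outgroup + 2 * n_clade`
#'   leaves; the duplication node carries the label `"wgd"`.
#' @export
simulate_wgd_chronogram <- function(n_clade = 20, n_outgroup = 22,
                                    clade_age = 280, height = 430,
                                    wgd_age = 303, seed = 1,
                                    suffixes = c("_P1", "_P2")) {
  if (!(clade_age < wgd_age && wgd_age < height)) {
    abort("need clade_age < wgd_age < height")
  }
  clade <- simulate_chronogram(n_clade, height = clade_age, seed = seed,
                               labels = paste0("sp", seq_len(n_clade)))
  s <- sub(";$", "", ape::write.tree(clade, digits = 12))
  ages <- seq(wgd_age + (height - wgd_age) / n_outgroup, height,
              length.out = n_outgroup)
  prev_age <- clade_age
  for (i in seq_len(n_outgroup)) {
    s <- sprintf("(%s:%.10g,out%d:%.10g)", s, ages[i] - prev_age, i, ages[i])
    prev_age <- ages[i]
  }
  tr <- parse_newick(text = paste0(s, ";"))
  duplicate_clade(tr, paste0("sp", seq_len(n_clade)), wgd_age,
                  suffixes = suffixes, node_label = "wgd")
}

#' Simulate amino-acid sequence evolution along a chronogram
#'
#' Generates an alignment under the model the reconstruction assumes: root
#' residues drawn from the equilibrium frequencies; one rate category drawn
#' per site (invariant with probability `p_inv`, else one of the equal-weight
#' gamma categories) and applied on every branch; residues evolved edge by
#' edge via the transition probabilities. All internal-node states are
#' recorded as ground truth.
#'
#' @param tree Rooted `phylo` tree (branch lengths in My when used with
#'   `branch_scale` rates per My).
#' @param model A [substitution_model()].
#' @param n_sites Number of alignment columns (> 0).
#' @param seed Integer seed.
#' @param branch_scale Substitutions per site per unit branch length.
#' @return A list with `alignment` (tip sequences, `aa_alignment`) and
#'   `truth`: `node_states` (character matrix, all nodes x sites, rows named
#'   by ape node number), `site_category` (row index into `mixture`),
#'   `mixture`, the generating parameters and the seed.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1,
                               branch_scale = 1) {
  if (n_sites <= 0) abort("n_sites must be > 0")
  n_sites <- as.integer(n_sites)
  mix <- rate_mixture(model)
  Q <- build_rate_matrix(model)
  eig <- eigen_generator(Q, model$pi)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  root <- ntip + 1L

  sim <- withr::with_seed(seed, {
    cat_i <- sample.int(nrow(mix), n_sites, replace = TRUE,
                        prob = mix$weight)
    states <- matrix(NA_integer_, nn, n_sites)
    states[root, ] <- sample.int(20, n_sites, replace = TRUE,
                                 prob = model$pi)
    edges <- rev(seq_len(nrow(tr$edge))) # preorder: parents before children
    for (e in edges) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      t_e <- tr$edge.length[e] * branch_scale
      child_states <- states[par, ]
      for (ci in unique(cat_i)) {
        r <- mix$rate[ci]
        sel <- which(cat_i == ci)
        if (r == 0 || t_e == 0) next
        P <- transition_from_eigen(eig, r * t_e)
        for (s in 1:20) {
          grp <- sel[states[par, sel] == s]
          if (length(grp) == 0) next
          child_states[grp] <- sample.int(20, length(grp), replace = TRUE,
                                          prob = P[s, ])
        }
      }
      states[child, ] <- child_states
    }
    list(states = states, cat_i = cat_i)
  })

  res <- matrix(AA_ALPHABET[sim$states], nn, n_sites)
  rownames(res) <- c(tr$tip.label,
                     as.character(ntip + seq_len(tr$Nnode)))
  aln <- as_alignment(res[seq_len(ntip), , drop = FALSE])
  list(
    alignment = aln,
    truth = list(node_states = res, site_category = sim$cat_i,
                 mixture = mix, model = model$name,
                 alpha = model$gamma_shape, p_inv = model$p_invariant,
                 branch_scale = branch_scale, seed = seed)
  )
}

#' Simulate a fluorescence-polarization titration
#'
#' Saturation mode titrates protein against a fixed labelled probe;
#' competition mode displaces a preformed probe/protein complex with
#' increasing competitor. Mean signals come from the exact equilibrium
#' solvers, mapped linearly between the free and bound mP plateaus, with
#' additive Gaussian noise. Defaults mirror the modelled assay: 15 nM probe,
#' protein in the 0.2–2 uM range, 12-point competitor series, 2 mP noise.
#'
#' @param mode `"saturation"` or `"competition"`.
#' @param K_D Dissociation constant of the probed interaction (uM): the
#'   probe's own K_D in saturation mode, the competitor's in competition
#'   mode.
#' @param probe_nM Total probe (nM).
#' @param protein_uM Fixed protein total (uM; competition mode), ignored in
#'   saturation mode.
#' @param K_D_probe Probe K_D (uM), needed in competition mode.
#' @param series Concentration series (uM): protein totals (saturation) or
#'   competitor totals (competition).
#' @param mP_free,mP_bound Signal plateaus for free and fully bound probe.
#' @param noise_sd Gaussian noise SD in mP (>= 0).
#' @param n_replicates Independent replicates.
#' @param seed Integer seed.
#' @param experiment_id Label stored with the rows.
#' @return A tibble in the package's titration layout: `experiment_id`,
#'   `mode`, `probe_nM`, `protein_uM`, `competitor_uM`, `mP`, `replicate`,
#'   with the generating truth attached as attribute `"truth"`.
#' @export
simulate_fp_dataset <- function(mode = c("competition", "saturation"),
                                K_D = 3.6, probe_nM = 15, protein_uM = 1,
                                K_D_probe = 0.1,
                                series = NULL,
                                mP_free = 80, mP_bound = 200,
                                noise_sd = 2, n_replicates = 1, seed = 1,
                                experiment_id = "sim") {
  mode <- match.arg(mode)
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  L <- probe_nM / 1000
  if (is.null(series)) {
    # default designs cover the full transition: saturation spans ~4 decades
    # of protein around sub-uM K_Ds; the displacement series runs to 1 mM so
    # both plateaus are reached even for ~5 uM competitors at 1-2 uM protein
    series <- if (mode == "saturation") {
      10^seq(-2.5, 1.5, length.out = 12)
    } else {
      c(0, 10^seq(-1.5, 3, length.out = 11))
    }
  }
  if (is.unsorted(series)) abort("concentration series must be increasing")
  mean_frac <- if (mode == "saturation") {
    bound_fraction_single(series, L, K_D)
  } else {
    solve_competitive_equilibrium(protein_uM, L, series, K_D_probe,
                                  K_D)$fraction_L_bound
  }
  mean_mP <- mP_free + (mP_bound - mP_free) * mean_frac
  prot_col <- if (mode == "saturation") series else protein_uM
  comp_col <- if (mode == "competition") series else 0
  out <- withr::with_seed(seed, {
    purrr::map(seq_len(n_replicates), function(rep_i) {
      tibble(
        experiment_id = experiment_id, mode = mode, probe_nM = probe_nM,
        protein_uM = prot_col,
        competitor_uM = comp_col,
        mP = mean_mP + stats::rnorm(length(series), 0, noise_sd),
        replicate = rep_i
      )
    }) |> dplyr::bind_rows()
  })
  attr(out, "truth") <- list(K_D = K_D, K_D_probe = K_D_probe,
                             mP_free = mP_free, mP_bound = mP_bound,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate an ITC titration
#'
#' Per-injection heats from the single-site isotherm with per-injection
#' cell dilution (the same forward model [fit_itc_isotherm()] fits), plus
#' Gaussian noise. Defaults mirror the modelled experiment: 11 uM cell,
#' 118 uM syringe, 2 uL injections.
#'
#' @param n Stoichiometry.
#' @param K_D_uM Dissociation constant (uM).
#' @param dH_kcal Binding enthalpy (kcal/mol).
#' @param cell_uM,syringe_uM,cell_volume_uL Instrument setup.
#' @param n_injections,injection_uL Injection schedule.
#' @param noise_sd Gaussian noise SD on heats (ucal).
#' @param seed Integer seed.
#' @return A tibble with `injection`, `volume_uL`, `heat_ucal` and the truth
#'   attached as attribute `"truth"`.
#' @export
simulate_itc_dataset <- function(n = 1, K_D_uM = 0.3, dH_kcal = -8,
                                 cell_uM = 11, syringe_uM = 118,
                                 cell_volume_uL = 200,
                                 n_injections = 20, injection_uL = 2,
                                 noise_sd = 0.1, seed = 1) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (cell_uM <= 0 || syringe_uM <= 0) abort("concentrations must be > 0")
  vols <- rep(injection_uL, n_injections)
  heats <- itc_forward_heats(vols, cell_uM, syringe_uM, n, K_D_uM, dH_kcal,
                             cell_volume_uL)
  out <- withr::with_seed(seed, tibble(
    injection = seq_len(n_injections),
    volume_uL = vols,
    heat_ucal = heats + stats::rnorm(n_injections, 0, noise_sd)
  ))
  attr(out, "truth") <- list(n = n, K_D_uM = K_D_uM, dH_kcal = dH_kcal,
                             cell_uM = cell_uM, syringe_uM = syringe_uM,
                             noise_sd = noise_sd, seed = seed)
  out
}
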