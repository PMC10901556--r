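---
title: "Models and methods behind tadevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tadevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadevo)
```

`tadevo` couples two analysis arcs that are usually run in separate tools:
(i) maximum-likelihood ancestral sequence reconstruction (ASR) of a short
protein region — the MDM2-binding motif of the p53 transactivation domain
(p53TAD) — on a time-calibrated species tree that carries a duplicated
teleost clade, and (ii) inference of equilibrium dissociation constants
(K~D~) from fluorescence-polarization (FP) and isothermal titration
calorimetry (ITC) experiments, with summary analytics over a table of
motif versus full-length affinities. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

## The evolutionary model

Sequences evolve by a reversible continuous-time Markov chain on the 20
amino acids. The generator is assembled in GTR form from the empirical JTT
exchangeability matrix $S$ and equilibrium frequencies $\pi$:

$$q_{ij} = S_{ij}\,\pi_j \ (i \neq j), \qquad
  q_{ii} = -\sum_{j \neq i} q_{ij},$$

scaled so that the mean substitution rate at equilibrium,
$-\sum_i \pi_i q_{ii}$, is exactly 1. Branch lengths multiplied into this
generator are therefore expected substitutions per site, and a chronogram
in million years (My) enters the likelihood through a single rate scalar
in substitutions/site/My. The JTT numbers are the pinned table shipped
with **phangorn**; `tadevo` re-indexes them into a fixed alphabetical
residue order that also serves as the deterministic tie-break for all
argmax operations.

Rate heterogeneity across sites uses the standard discrete-gamma
approximation plus an invariant class:

* `alpha` — gamma shape; smaller means stronger heterogeneity. Default
  in examples: 1.
* `n_categories` — number of equal-probability gamma classes; default 5,
  matching the analysis this package re-implements.
* `p_inv` — proportion of invariant (rate 0) sites, in $[0, 1)$.

Each gamma class is represented by the *mean* of its equal-probability
slice, computed from the incomplete-gamma identity (a median rule is
available via `gamma_method = "median"`; the choice moves posteriors in
the third decimal, and the mean rule is the package default because it
preserves the mixture mean exactly). After appending the invariant class,
all rates are rescaled so the mixture mean is 1 — without this, branch
lengths would change meaning between `JTT+G` and `JTT+G+I` fits.

## Likelihood, reconstruction, AltAll

`log_likelihood()` implements Felsenstein pruning over the $(k+1)$-category
mixture, with per-node column rescaling to avoid underflow on deep trees.
Gaps and `X` are missing data (partial-likelihood vectors of ones): the
region being reconstructed is indel-rich, and no indel process is modelled
— only residues at alignable columns are inferred.

`marginal_posteriors()` adds the standard outside ("up") pass, giving for
every internal node and site the posterior over the 20 residues,
marginalized over all other nodes *and* over rate categories. Categories
are mixed by their per-site posterior weight (prior weight times the
category's site likelihood), not by the prior weight alone; the
alternative is visibly wrong for sites that are clearly fast or clearly
invariant.

`call_sequences()` produces the two sequences used downstream:

* **ML**: the argmax residue per site (alphabetical tie-break);
* **AltAll**: the second-most-likely residue at exactly those sites where
  the best posterior is below 0.90 *and* the runner-up reaches at least
  0.10, else the ML residue. A reconstruction is considered robust when
  the ML and AltAll proteins behave the same in binding experiments.

`fit_model_parameters()` maximizes the likelihood over any subset of
(`alpha`, `p_inv`, rate scalar) with L-BFGS-B on log/logit-transformed
parameters. Two branch-length policies exist. The default, `"scale"`,
keeps the chronogram's relative branch lengths and fits one global rate —
the chronogram is the analysis's stated input, and a single scalar
preserves its clock interpretation while adding one parameter.
`"branch_lengths"` releases every edge (coordinate descent with Brent
steps); it is provided for small problems and for checking that
conclusions do not hinge on the clock assumption, not as the default,
since with ~120 edges it is both slow and unidentifiable for the short
alignments this domain offers.

`model_selection_table()` ranks JTT-family variants by
$\mathrm{AICc} = -2\ln L + 2k + 2k(k+1)/(n-k-1)$ with $n$ = alignment
columns (a convention, recorded in the output, since tools differ here)
and $k$ counting the fitted scalar, shape, invariant fraction, and 19 free
frequencies for `+F`. Akaike weights are normalized over the candidate
set. Reproducing any particular published AICc number additionally
requires that tool's gamma-discretization and sample-size conventions;
the package guarantees its own arithmetic (tested against hand
computation) and the *ranking* behaviour on data of known provenance.

## Tree surgery in age space

Chronogram edits are specified in node ages (My), not branch lengths, so
ultrametricity is preserved by construction:

* `prune_taxa()` removes leaves and merges unary nodes (pairwise distances
  among survivors are unchanged);
* `graft_leaf()` inserts a present-day leaf on an edge at a stated
  divergence age (strictly inside the edge's age span);
* `duplicate_clade()` replaces a clade with a bifurcation at a stated age
  whose two children are copies of the clade, leaf labels suffixed
  `_P1`/`_P2`. This represents a whole-genome duplication on a species
  tree — for the teleost WGD the age is 303 My — and afterwards each
  paralog evolves on its own copy.

The attachment ages for grafted species are user inputs: the original
analysis took them from published fish timetrees, and no single default
would be right.

`classify_paralog()` encodes the synteny rule used to assign p53 copies to
paralog classes: Class II copies sit downstream of *gps2* (sense,
upstream side) with an antisense E3-ubiquitin-ligase gene followed by a
*capga* homolog downstream; Class I copies have *slc2a4* antisense
upstream. Conflicting neighborhoods return `unknown` with a conflict
flag rather than a guess.

## Binding models

All FP signals are treated as linear in the bound fraction of the labelled
probe (no anisotropy/total-intensity correction — a documented limitation;
the experiments this models report mP and fit directly).

* `bound_fraction_single()`: exact quadratic solution of the 1:1 mass
  balance. Probe depletion is handled exactly; there is no trace-ligand
  approximation anywhere in the package.
* `solve_competitive_equilibrium()`: the ternary system (probe and
  competitor sharing one protein) reduced to a cubic in free protein,
  solved in closed trigonometric form and polished with a few Newton
  steps on the monotone mass-balance residual (the closed form alone
  loses digits when the three roots nearly collide; the residual after
  polishing is at machine precision).
* `fit_fp_saturation()`: least squares over (K~D~, two plateaus) with
  multi-start from a log-spaced K~D~ grid (13 starts over
  10^-4^–10^2^ µM); the grid removes the classic local minimum where the
  amplitude collapses. Flat curves (amplitude under 3 residual SDs) are
  rejected as unidentifiable rather than fitted.
* `fit_fp_competition()` reports two routes. Route A (primary, matching
  common practice for displacement data): a four-parameter logistic in
  log concentration pins the two plateaus, the IC50 is read off as the
  concentration where the replicate-averaged curve crosses the
  half-signal point (shape-preserving spline inversion — the 4PL
  inflection itself is a biased IC50 estimate on the asymmetric curves
  of tight binders), and `kd_from_ic50()` converts it to K~D~. Route B:
  direct least squares of the exact ternary model. Route A is primary
  because published displacement K~D~s are typically IC50-derived;
  route B is the internal control — the two must agree whenever the
  probe is sub-stoichiometric to protein (15 nM probe versus 0.2–2 µM
  protein in the modelled assay), and the tests enforce agreement
  within 5% there.
* `kd_from_ic50()` is the exact free-concentration conversion: at the
  50%-displacement point the probe complex is half its competitor-free
  value, all free species follow from mass balance, and
  $K_D = P_\mathrm{free} I_\mathrm{free} / PI$ evaluated there. It
  reduces to Cheng–Prusoff in the trace limit and refuses IC50s at or
  below the tight-binding floor (≈ protein/2 with a trace probe), where
  the conversion's sensitivity diverges.
* `fit_itc_isotherm()`: single-site isotherm with per-injection
  displacement dilution — each injection dilutes the cell contents by
  $(1 - \Delta V / V_0)$ before the syringe ligand is added, and the heat
  of injection $i$ is $\Delta H \cdot V_0$ times the newly formed complex.
  Instrument vendors differ in their exact dilution correction and the
  original analysis used the instrument software; this package pins one
  self-consistent convention, uses it in both simulator and fitter, and
  documents it here. Derived quantities: $\Delta G = -RT\ln K_a$,
  $\Delta S = (\Delta H - \Delta G)/T$, $K_D = 1/K_a$.

Uncertainties on fitted K~D~s come from the fit covariance on the log
scale (delta method). Published replicate-based uncertainties in the
packaged affinity table are stored as separate columns, never recomputed.

## The affinity table and its analytics

`table1_fixture()` returns the packaged transcription of the measured
affinities: 13 interactions (human reference + 12 fish p53TAD/MDM2
pairs), motif peptide sequences, and four K~D~ columns with separate
uncertainty columns. The human full-length entry has two printed values
(same-study FP measurement, default; an earlier kinetics-derived value
kept in `kd_fulllength_prior_uM`). A checksum test pins every numeric
cell.

`fold_change()`, `count_in_range()` (closed intervals — the published
count includes both endpoints, which forces this choice),
`count_improved()` (strict inequality, exceptions named) and
`motif_vs_fulllength_correlation()` reproduce the headline summaries:
the largest motif→full-length gain is 73-fold (zebrafish), the human
gain is 4-fold, 11 of 12 fish interactions improve (the European eel P1
motif is the exception), and 10 of 12 extant fish motifs fall in the
0.6–4.5 µM band. The published motif/full-length R² (0.014) is defined by
a supplementary point set whose exact membership and scale are not
restated in the text, so the correlation operation parameterizes subset
and scale instead of hard-coding that value.

## Synthetic data: what it shows and what it cannot

The generators exist so that every pipeline stage has a ground-truth
test without downloads:

* `simulate_alignment()` draws root residues from $\pi$, assigns each
  site one rate category for the whole tree (the gamma-sites assumption
  the likelihood makes), and evolves residues edge by edge, recording all
  internal states. It deliberately matches the inference model: recovery
  tests therefore demonstrate *correctness of the implementation*, not
  robustness to model violation. Real p53TAD alignments contain indels,
  alignment error and composition drift that no test here exercises.
* `simulate_wgd_chronogram()` builds the reconstruction problem at its
  true size: a 20-species clade duplicated at 303 My under 22 ladder
  outgroups, 62 leaves, root age 430 My — the leaf count of the p53TAD
  analysis. Rate 0.002 subst/site/My gives root-to-tip path lengths
  under one substitution per site, the regime of a conserved protein
  motif.
* `simulate_fp_dataset()` / `simulate_itc_dataset()` use the exact
  forward models with additive Gaussian noise (defaults: 2 mP; 0.1 µcal)
  at the modelled assay conditions (15 nM probe, 0.2–2 µM protein,
  12-point series to 1 mM — chosen so displacement curves reach both
  plateaus; 11 µM cell, ~118 µM syringe). Instrument drift,
  pipetting error correlated across a dilution series, and fluorescence
  artifacts are not simulated.

All generators take an explicit integer seed, restore the RNG state, and
are bit-reproducible given (inputs, seed).

## Problem sizes used in the shipped checks

The packaged checks run the reconstruction recovery at 62 leaves × 2000
sites (model refit plus posteriors), enumeration cross-checks on trees of
up to 5 taxa (the largest size where summing over all internal-state
assignments is exact and affordable), model-selection ranking at 16 taxa
× 400 sites, and binding round-trips at the assay design sizes. These
sizes were chosen to exercise the full-scale reconstruction problem while
keeping the whole suite runnable on a laptop in minutes.

## Known limitations

* Joint (max-sum) ancestral reconstruction is not implemented — the
  downstream use is per-site posteriors and AltAll variants, both
  marginal notions.
* No indel model; columns with gaps contribute only through their
  observed residues.
* The node-number ↔ biology mapping (e.g. "the ancestral teleost node")
  belongs to a specific published tree; on user trees, nodes are
  addressed by ape numbers or node labels.
* The FP model assumes a single binding site and a 1:1 competitor; ITC
  assumes a single-site isotherm (`n` absorbs concentration error).
* Exact reproduction of third-party AICc tables is out of scope (their
  discretization and sample-size conventions are not printed); the
  package's own arithmetic and ranking behaviour are what is guaranteed.
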