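# tadevo

Ancestral sequence reconstruction and binding-affinity inference for the
p53TAD/MDM2 interaction in ray-finned fishes — and for any short protein
motif whose evolution you want to trace on a time-calibrated tree and
tie to measured equilibrium constants.

The interaction between the disordered transactivation domain of p53
(p53TAD) and the SWIB domain of its ubiquitin ligase MDM2 is mediated by a
~13-residue motif. Across fishes this motif repeatedly lost affinity
(K_D drifting into the 0.6–4.5 µM band), while flanking disordered
regions compensated: full-length p53TAD binds 4- to 73-fold tighter than
the bare motif in 11 of 12 measured fish interactions. `tadevo`
re-implements the computational machinery behind that kind of analysis as
a tested R package:

* **Evolutionary models** — JTT with discrete-gamma (+G), invariant-site
  (+I) and empirical-frequency (+F) extensions; mean-rate-1 generators so
  branch lengths are substitutions per site.
* **Likelihood & reconstruction** — Felsenstein pruning over the rate
  mixture, marginal posteriors at every internal node (`20` states ×
  sites), ML and AltAll ancestral sequence calls (AltAll: swap in the
  runner-up residue wherever the best posterior < 0.90 and the runner-up
  ≥ 0.10), and AICc/BIC model selection with Akaike weights.
* **Chronogram surgery** — prune, graft-at-age, and clade duplication at
  a stated age (the teleost whole-genome duplication at 303 My), all in
  node-age space so trees stay ultrametric; plus the gps2/slc2a4 synteny
  rule for classifying p53 paralogs.
* **Binding inference** — exact 1:1 and competitive equilibria (closed-form
  cubic), FP saturation and displacement fitting (IC50 route with exact
  free-concentration conversion, plus a direct ternary fit as control),
  and single-site ITC isotherm fitting with full thermodynamics.
* **Affinity analytics** — the packaged 13-interaction affinity table and
  the fold-change / range-count / improvement / correlation summaries.
* **Synthetic data** — seeded generators for sequence evolution along a
  chronogram, FP titrations and ITC isotherms, so the whole pipeline is
  testable offline with known ground truth.

Tabular results are tibbles; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

Affinity analytics over the packaged table:

```r
library(tadevo)

tab <- table1_fixture()
fc  <- fold_change(tab)          # K_D(motif) / K_D(full-length)
max(fc$fold_change, na.rm = TRUE)
#> [1] 73.46939
fc$fold_change[fc$label == "H. sapiens"]
#> [1] 4.262295
count_improved(tab, subset = species != "Homo sapiens")
#> # A tibble: 1 x 3
#>   n_improved n_compared exceptions
#>        <int>      <int> <chr>
#> 1         11         12 A. anguilla p53TAD_P1
count_in_range(tab, "kd_native_motif_uM", 0.6, 4.5,
               subset = species != "Homo sapiens")
#> [1] 10
```

The zebrafish full-length p53TAD binds its MDM2 73-fold tighter than its
bare motif; the human gain is 4-fold; 11 of 12 fish interactions improve
(the European eel paralog-1 motif, already tight at 0.19 µM, is the
exception); 10 of 12 extant fish motifs sit in the 0.6–4.5 µM band.

Reconstruction on synthetic data with known truth:

```r
tree <- simulate_wgd_chronogram(seed = 11)   # 62 leaves, WGD at 303 My
model <- substitution_model("JTT+G+I", alpha = 1, p_inv = 0.1)
sim  <- simulate_alignment(tree, model, n_sites = 300, seed = 12,
                           branch_scale = 0.002)
fit  <- fit_model_parameters(tree, sim$alignment, model,
                             branch_scale = 0.002)
post <- marginal_posteriors(tree, sim$alignment, fit$model,
                            fit$branch_scale)
calls <- call_sequences(post)                 # ML + AltAll per node
```

Binding inference from a displacement titration:

```r
d <- simulate_fp_dataset("competition", K_D = 3.6, K_D_probe = 0.1,
                         protein_uM = 1, noise_sd = 2, seed = 33,
                         n_replicates = 2)
est <- fit_fp_competition(d, K_D_probe = 0.1, protein_uM = 1)
tidy(est)
#> # A tibble: 2 x 4
#>   method                   K_D std_error  IC50
#>   <chr>                  <dbl>     <dbl> <dbl>
#> 1 competition-conversion  3.53     0.166  39.6
#> 2 competition-direct      3.51     0.146  NA
```

Both K_D routes (IC50 conversion and direct ternary fit) agree with the
generating value of 3.6 µM within the noise.

See `vignettes/tadevo-methods.Rmd` for the models, conventions and
numerical choices, and `run_asr_workflow()` / `run_binding_workflow()`
for the end-to-end bundles (posterior TSVs, ancestor FASTAs,
model-selection tables, affinity reports, reproducibility manifests).

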