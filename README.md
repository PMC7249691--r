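# il12rewire

Quantitative models of non-canonical Interleukin-12 (IL-12) signaling in
melanoma, for systems biologists studying how tumor cells rewire cytokine
responses. B16F0 melanoma cells overexpress one IL-12 receptor subunit,
IL12RB2, while barely expressing its partner IL12RB1. This package
implements the analysis pipeline for asking what that skew does:

1. **Dose-response inference** — does IL-12 rescue melanoma cells from
   imatinib cytotoxicity? Viability is modeled as

   ```
   Live(%) = 100 * [ 1 - C_Im / (C_Im + EC50 * (1 + a * C_IL12/(C_IL12 + Kd))) ]
   ```

   where the rescue effect `a` rescales the drug EC50 by up to `(1 + a)`
   at saturating IL-12 (`Kd` fixed at 40 ng/mL). Posteriors for
   `(EC50, a)` come from a Metropolis-Hastings sampler with
   SSE-marginalized likelihood `P(Y|θ) ∝ SSE^(-N/2)`, proposal scales
   tuned to a 0.2 acceptance fraction, three over-disperse chains, and
   Gelman-Rubin convergence diagnostics (PSRF < 1.2). The rescue is
   significant when `P(a < 0) < 0.05`.

2. **Receptor-mechanism selection** — is phospho-Akt/phospho-STAT4
   signaling ligand-driven, receptor-density-driven, or both? Three
   equilibrium mechanisms generate activated receptor complexes from the
   total pool `TOTRC` (canonical `ARC = TOTRC·IL12/(K_C + IL12)`,
   non-canonical `ARC = TOTRC/(K_N + 1)`, and a hybrid that nests both),
   feeding a saturable phosphorylation stage
   `pS = TOTS·ARC/(K_D + ARC)`. Mechanisms are fit by minimum SSE
   (optionally with `K_C` shared across readouts of a cell line) and
   compared with Bayes factors `B_ij = (SSE_i/SSE_j)^(-N/2)`, graded
   weak/positive/strong/very strong at 3/20/150.

3. **Surface-density analysis** — receptor complexes per um^2 of
   membrane from the stoichiometry rule (heterodimer: complexes =
   IL12RB2 copies; homodimer: half), cell-line areas (104/344 um^2) and
   a forward-scatter size normalization, plus the linear total-Akt
   correction `Total Akt = 0.352·density + 382`.

4. **Single-cell receptor skew** — per-cell-type classification of
   scRNA-seq cells by non-zero IL12RB1/IL12RB2 TPM, IL12RB2:IL12RB1
   ratio distributions over both-expressing cells, Pearson chi-squared
   (or Fisher) contingency tests, and rank-based ratio comparisons. The
   reference human dataset is GEO accession GSE115978 (downloaded
   separately); seeded generators emulate every assay so the entire
   pipeline runs and is tested offline.

## Worked example

```r
library(il12rewire)

# simulate the 16-point factorial viability assay (truth: EC50 = 10, a = 1)
d <- gen_viability(viability_design(truth = dose_response_params(10, 1),
                                    noise_sd = 3, seed = 1))
fit <- fit_viability_mcmc(d, n_steps = 50000, seed = 1)
fit
#> IL-12 rescue model fit (Metropolis-Hastings)
#>   16 obs, 3 chains x 50000 steps, tuned acceptance 0.158
#> Posterior summary (75000 pooled samples)
#>   ec50     median 10.36  95% CI [8.772, 12.15]  P(< 0) = 0 *  PSRF 1.001
#>   alpha    median 0.9855  95% CI [0.5719, 1.518]  P(< 0) = 0 *  PSRF 1.001
```

The posterior median EC50 (10.36 uM) and rescue effect (0.99) recover
the generating values; PSRF ~1.00 for both parameters says the three
chains converged, and `P(a < 0) = 0` flags the IL-12 rescue as
significant. A rescue effect of 1 means saturating IL-12 doubles the
imatinib EC50.

```r
# stratified phospho data generated by the hybrid mechanism, then refit
b16 <- receptor_context("B16F0")       # homodimer complexes, 344 um^2
ph  <- gen_phospho(phospho_design(seed = 1), b16)
select_mechanism(ph, b16)
#> Mechanism selection by Bayes factors (rows = model i, cols = model j)
#>   n_obs = 96; ranking by SSE: hybrid > noncanonical > canonical
#>   SSE canonical     5.76197e+06
#>   SSE noncanonical  2.57639e+06
#>   SSE hybrid        79414.6
#>              canonical noncanonical   hybrid
#> canonical     1.00e+00     1.66e-17 4.87e-90
#> noncanonical  6.01e+16     1.00e+00 2.93e-73
#> hybrid        2.05e+89     3.41e+72 1.00e+00
```

The hybrid row dominates both alternatives with Bayes factors far above
150 (very strong evidence): the data carry both a ligand-dose effect and
a receptor-density effect, and only the hybrid mechanism captures both.

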