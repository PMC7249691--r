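---
title: "Modeling non-canonical IL-12 signaling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling non-canonical IL-12 signaling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(il12rewire)
```

## The biological question

Interleukin-12 (IL-12) is a heterodimeric cytokine that drives type-1
anti-tumor immunity through a receptor composed of two subunits, IL12RB1
and IL12RB2, and the canonical JAK-STAT4 pathway. Melanoma cells of the
B16F0 model overexpress IL12RB2 while expressing almost no IL12RB1. This
package implements the quantitative machinery to ask what that skew buys
the tumor cell: whether IL-12 blunts the cytotoxicity of a drug challenge
(imatinib), and whether the phospho-signaling response (pAkt vs pSTAT4)
across cells stratified by IL12RB2 copy number is best explained by
ligand-driven, receptor-density-driven, or mixed activation of the
receptor complex. A final stage asks whether the IL12RB2:IL12RB1 skew is
also visible in human melanoma single-cell RNA-seq.

## The viability rescue model

Percent live cells after co-treatment with drug at concentration
$C_{Im}$ and IL-12 at $C_{IL12}$ is modeled as

$$\mathrm{Live}(\%) = 100\left[1 -
  \frac{C_{Im}}{C_{Im} + EC_{50}\left(1 + \alpha
  \frac{C_{IL12}}{C_{IL12} + K_d}\right)}\right]$$

IL-12 enters only by rescaling the drug's $EC_{50}$: occupancy of the
IL-12 receptor (binding constant $K_d$, fixed at 40 ng/mL and exposed as
a configuration override rather than inferred) multiplies it by up to
$(1+\alpha)$. A rescue effect $\alpha = 1$ therefore doubles the
effective $EC_{50}$ at saturating IL-12 — a 100% right-shift of the
dose-response curve. $\alpha$ is constrained to $(-1, \infty)$ so the
effective $EC_{50}$ stays positive; negative values would mean IL-12
sensitizes rather than rescues.

### Likelihood and priors

No explicit noise model is imposed. The likelihood is the
SSE-marginalized form $P(Y \mid \theta) \propto \mathrm{SSE}^{-N/2}$, so
the negative log-likelihood is $(N/2)\log \mathrm{SSE}$ and no noise
standard deviation is sampled. Observed viabilities above 100% (assay
noise) enter the residuals unmodified: clipping would bias the SSE. The
prior is improper uniform on the valid domain; parameters are sampled on
the natural scale, and proposals outside the domain are rejected. A
perfect fit (SSE = 0) is degenerate under this likelihood and is
signaled by a $-\infty$ return rather than silently maximized.

## The sampler

`fit_viability_mcmc()` wraps a random-walk Metropolis-Hastings sampler:

* **Proposals** are independent zero-mean normals per parameter.
* **Tuning**: proposal standard deviations are rescaled by
  $\exp(2(a - 0.2))$ after each 500-step pilot block until the block
  acceptance $a$ lies in $0.2 \pm 0.05$. Pilot samples are discarded and
  the tuned scales are frozen before inference, preserving chain
  validity. If acceptance stays near 1 even after a 100-fold scale
  increase (a flat target), the initial scales are returned unchanged.
* **Initialization**: 3 chains (2 minimum for diagnostics) start from
  uniform draws over a declared box — by default $EC_{50}$ in 0.05-5
  times the maximum drug dose and $\alpha$ in $(-0.9, 5)$, at least an
  order of magnitude wider than the posterior for a well-designed assay.
* **Convergence** is assessed by the classic (non-rank-normalized)
  Gelman-Rubin potential scale reduction factor,
  $\widehat{R} = \sqrt{\left(\frac{n-1}{n}W + \frac{B}{n}\right)/W}$,
  declared converged when all values are below 1.2. The era-appropriate
  classic formula is used deliberately (no rank normalization, no
  degrees-of-freedom correction) and is pinned by an independently coded
  oracle test.
* **Burn-in** defaults to the first 50% of each chain. The converged
  segment is not detected automatically; the fraction is configuration.
* **Summaries**: posterior medians, central 95% intervals, the tail
  probability $P(\alpha < 0)$ (significant rescue when below 0.05), and
  the maximum-likelihood value taken as the highest-posterior sample
  visited anywhere in the run — no separate optimizer, matching how an
  ML value is read off a sampled posterior.

Every run is bit-reproducible given its seed: tuning, initialization and
sampling use seeds derived from the single root seed.

## Receptor-activation mechanisms

All three mechanisms act on the total receptor-complex pool TOTRC, which
is derived from measured IL12RB2 copies by a stoichiometry rule: in T
cells (2D6 model) the complex is the IL12RB1:IL12RB2 heterodimer and
complexes equal IL12RB2 copies; in B16F0 melanoma the complex is the
IL12RB2 homodimer and complexes equal half the copies. At equilibrium:

* **Canonical** (ligand-dependent):
  $ARC = TOTRC \cdot IL12 / (K_C + IL12)$.
* **Non-canonical** (spontaneous, density-driven):
  $ARC = TOTRC / (K_N + 1)$, independent of ligand. The state is
  reported with `arc1 = 0` by convention so the activation state has a
  uniform shape across mechanisms.
* **Hybrid**: both routes drain the shared free pool, giving
  $ARC_1 = TOTRC\, f(1-g) / (1 - fg)$ with
  $f = IL12/(K_C+IL12)$, $g = 1/(K_N+1)$, and
  $ARC_2 = (TOTRC - ARC_1)/(K_N + 1)$. The hybrid nests the canonical
  model as $K_N \to \infty$ and the non-canonical model as
  $IL12 \to 0$ (or $K_C \to \infty$).

A single saturable phosphorylation stage converts activated complexes to
the measured signal, $pS = TOTS\,(ARC_1 + ARC_2)/(K_D + ARC_1 + ARC_2)$,
with identical kinetics for both activated forms. MFI is modeled
directly, without background subtraction; background is absorbed by the
fitted TOTS/$K_D$ scale. The equilibrium solutions are cross-checked in
the test suite against brute-force ODE relaxation of the underlying
mass-action schemes (deSolve), which exists solely as a test oracle —
the user-facing pipeline is equilibrium-only.

### Surface density and the total-Akt correction

`complex_density()` divides complexes by the membrane area (104 um^2 for
2D6, 344 um^2 for B16F0) scaled by `fsc_scale`, a dimensionless
forward-scatter size normalization defined here as subset mean FSC-A
over the cell-line reference mean FSC-A (default 1 when no FSC data are
available — the simplest reading of size normalization by forward
scatter). Total Akt rises with receptor density following
`Total Akt (MFI) = 0.352 * density + 382`; when the correction is
enabled (`tots_correction = TRUE`) this per-subset value replaces the
fitted TOTS so the ratio pS/TOTS can be examined. The correction is
per-readout and off by default: the supporting serum-stimulation data
cover Akt, and there is no analogous evidence for STAT4, so applying it
to STAT4 is left to the caller.

## Model selection

Each mechanism is fit by minimizing the SSE between observed and
predicted MFI. The optimizer is derivative-free Nelder-Mead from a
deterministic grid of multi-starts on log-scaled parameters (positivity
by construction; log scaling suits constants spanning decades), followed
by BFGS and Nelder-Mead polish passes of the best start. Fits are
deterministic given the data. The hybrid fit additionally starts from
the best canonical solution (with $K_N$ large) and the best
non-canonical solution (with $K_C$ large), so the nesting inequality
$\mathrm{SSE}_{hybrid} \le \min(\mathrm{SSE}_{can},
\mathrm{SSE}_{non})$ holds up to optimizer tolerance by construction.
Bayes factors are computed as
$B_{ij} = (\mathrm{SSE}_i/\mathrm{SSE}_j)^{-N_{obs}/2}$ and graded on
the standard scale (1-3 weak, 3-20 positive, 20-150 strong, >150 very
strong; reciprocal grades for $B < 1$). Raw values are reported without
clamping — a nested comparison can dip below 1 only through optimizer
noise, and transparency is preferred to cosmetic monotonicity. The SSE
is unweighted; weighting subsets by flow event count would be a natural
extension but is not part of the implemented method. Unstimulated
observations enter ligand-dependent models at exactly `il12 = 0`, with
no vehicle offset. The ligand binding constant $K_C$ reflects
extracellular affinity, so `fit_shared_kc()` can constrain it to be
equal across the Akt and STAT4 readouts of one cell line while all other
parameters stay per-readout.

## Single-cell receptor skew

`classify_cells()` classifies each annotated cell by strictly positive
TPM of each receptor gene — "expressed" means TPM > 0 exactly, with no
minimum-expression threshold, which makes the classification invariant
to any positive rescaling of the matrix. Ratios IL12RB2:IL12RB1 are
computed only over the both-expressing subset; zero denominators are
excluded, never imputed. Differences in the class distribution across
cell types are tested on the cells expressing at least one gene, by
Pearson chi-squared without continuity correction by default; a Fisher
exact test is also provided because both tests appear in practice for
this comparison, and the method used is recorded in the result. Ratio
distributions are compared by a Wilcoxon rank-sum test on log ratios — a
declared configuration choice of a robust location test for right-skewed
positive ratios, checked in the tests against a permutation oracle for
order-of-magnitude agreement only. The reference human dataset is the
deposited melanoma single-cell study (GEO accession GSE115978); it must
be downloaded separately, and all desk-scale testing runs on the
synthetic cohort described next.

## What the generators emulate — and what they do not

The generators' defaults are the study conditions, not tuning knobs.

* `gen_viability()`: full-factorial imatinib {0, 5, 10, 20} uM by IL-12
  {0, 40, 100, 200} ng/mL grid — 16 observations per replicate, matching
  the design under which the rescue model is identifiable (16 points for
  2 free parameters). Noise is additive Gaussian in percent-viability
  units (default sd 3, a typical flow-assay replicate scatter), not
  clipped at 100.
* `gen_phospho()`: per-cell IL12RB2 copies are log-normal with median
  $10^{4.5}$ and log-sd 1.15, spanning roughly $10^3$-$10^6$ copies to
  cover the measured range of both cell-line models (19,500-330,000
  copies); cells are binned at half-decade edges into 8 subsets, each
  represented by the geometric mean of its bin edges (bin edges are
  configuration, since the published stratification is shown but not
  tabulated); doses are {0, 7, 100, 300} ng/mL; 3 replicate experiments
  of 2,000 cells give ~96 subset-dose rows, comfortably above the 69
  observations the identifiability argument requires. Noise is
  multiplicative log-normal with sdlog equal to `noise_frac` (default
  0.05), so the absolute noise sd at the top of the response range is
  about 5% of the dynamic range — MFI is positive and right-skewed, so
  multiplicative noise is the natural error model. Default truth is the
  hybrid mechanism with $K_C = 60.7$ ng/mL (the melanoma-line estimate),
  $K_N = 4$, TOTS = 2000 MFI and $K_D = 5\times10^4$ complexes, placing
  unstimulated activation and ligand response both within the observable
  range.
* `gen_scrna()`: zero-inflated two-gene expression. Per-type class
  probabilities and cell counts default to the published skew in human
  melanoma (malignant 20.7% both / 55.9% RB1-only / 5.2% RB2-only over
  2018 cells; NK 23.9/65.2/2.2 over 92; CD4 T 21.8/72.7/0.8 over 856;
  CD8 T 10.3/81.6/0.3 over 1759), and expressed TPM is log-normal with
  per-type meanlog offsets chosen so ratio medians fall near 2
  (malignant), 0.3 (NK, CD4) and 0.085 (CD8), with sdlog 1.5.

The generators do **not** emulate: fluorescence spillover or gating of
raw flow events (the pipeline starts from per-subset summary tables),
correlated biological replicate effects, mRNA dropout that depends on
expression level, library-size variation, or cell-type misannotation.
Passing tests therefore demonstrate correctness of the inference
machinery under the stated statistical structure, not robustness to
every artifact of real cytometry or scRNA-seq data.

## Numerical choices and degenerate inputs

* Out-of-domain proposals are rejected (equivalent to a flat prior on
  the domain); all-infinite initialization raises an error.
* Tuning failure past the round cap raises a `tuning_failure` condition
  carrying the last acceptance fraction.
* Gelman-Rubin requires >= 2 chains with >= 10 post-burn-in samples and
  errors on zero within-chain variance rather than returning NaN.
* SSE = 0 in the viability likelihood returns $-\infty$ (degenerate
  perfect fit); a zero SSE in a Bayes-factor denominator raises a
  degenerate-comparison error.
* Empty copy-number bins in `gen_phospho()` are dropped with a message.
* Ties in classification are impossible by construction (strict > 0);
  types with no both-expressing cells report an `NA` median ratio.

## Problem sizes

Default analyses use 3 chains of 50,000 steps (the scale at which the
chains converge well before the end of the run); the coverage study in
the test suite uses 50 replicates at 3 x 4,000 steps, and selection
consistency uses 20 replicates of the ~96-row default phospho design.
These sizes were chosen to make the full suite run in well under a
minute per stage on a single core while keeping Monte-Carlo error far
smaller than the tolerances being checked.

## Known limitations

* The equilibrium treatment has no kinetics; transient overshoot or slow
  receptor turnover would be invisible.
* Individual rate constants ($k_{f1}$, $k_{r1}$, ...) are structurally
  unidentifiable; only their ratios ($K_C$, $K_N$, $K_D$) are fit.
* The SSE-based Bayes factor is a maximum-likelihood approximation to
  the marginal likelihood; it does not penalize the hybrid model's extra
  parameter, which is why nested comparisons gravitate to $B \approx 1$
  rather than below it. Information criteria are deliberately out of
  scope.
* The $EC_{50}$ unit is whatever unit the input table declares for the
  drug column; the package does not hard-code a published point value.
* The shared-$K_C$ fit couples readouts within one cell line only;
  nothing is shared across cell lines.
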