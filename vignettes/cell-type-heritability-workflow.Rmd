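---
title: "From cell-type specificity to regional heritability and connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cell-type specificity to regional heritability and connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellherit)
```

# Overview

`cellherit` implements a chain of analyses that connects cell-type-resolved
gene expression to GWAS SNP-heritability, extrapolates cell-type results to
anatomical regions through composition weights, and closes the loop with a
case/control classifier on functional-connectivity matrices. Every stage is
exercised end-to-end on synthetic data with planted ground truth, so the
statistical behaviour of each component (calibration under the null, power
under planted signal) is testable without any private datasets.

The pipeline has five analytic stages over one synthetic-data layer:

1. **Expression specificity (TDEP).** Counts per gene and cell type are
   depth-normalized to transcripts per million,
   $\mathrm{TPM}_{g,c} = 10^6 \, \mathrm{Raw}_{g,c} / \sum_g \mathrm{Raw}_{g,c}$,
   and converted to expression proportions
   $\mathrm{EP}_{g,c} = \mathrm{TPM}_{g,c} / \sum_c \mathrm{TPM}_{g,c}$,
   a relative specificity measure in $[0,1]$. A gene is TDEP (top-decile
   expression proportion) for a cell type if its EP is in the top 10% of
   the background genes for that cell type *and* its expression exceeds
   1 TPM there.
2. **SNP-heritability enrichment.** TDEP gene sets, expanded by ±100 kb,
   define SNP annotations. A compact stratified LD score regression
   regresses GWAS $\chi^2$ statistics on annotation-stratified LD scores,
   $E[\chi^2_j] = a + N \sum_c \tau_c \ell(j, c)$, with a free intercept,
   weighted least squares, a delete-a-block jackknife SE for the target
   coefficient, and a one-sided p-value in the enrichment direction.
3. **Regional aggregation.** Cluster-level enrichment Z-scores are carried
   to anatomical dissections as the neuronal-composition-weighted sum
   $Z_d = \sum_k \mathrm{pct}_{k,d} Z_k$, converted to one-sided p-values
   and BH-adjusted across dissections.
4. **Gene sets and genomic co-occurrence.** Over-representation is tested
   with upper-tail hypergeometric tests against the fixed background. The
   genome is tiled into 100 kb bins; per cell type, TDEP TSS counts are
   regressed on total TSS counts and bins with internally studentized
   residuals above 3 are flagged as co-occurrence hotspots.
5. **Connectivity classification.** Per-subject ROI time series become
   Pearson connectivity matrices; a cross-entropy-trained classifier with
   held-out AUC evaluation drives recursive ROI elimination, where each
   connection's importance is the gated permutation ratio
   $\mathrm{FI} = \bar e_{\mathrm{perm}} / e_{\mathrm{orig}}$ and the ROI
   with the smallest summed importance is removed each run.

# The synthetic-data layer

The generators in `sim_config()` / `generate_*()` define the study
conditions; their defaults were fixed once, at values a simulation study in
this field would call realistic at desk scale, and parameter-recovery tests
override single effect-size fields only.

* **Atlas.** 2,000 genes by 20 clusters in 5 superclusters (three of them
  neuronal). Counts are negative binomial with dispersion 2 around
  log-normal gene means and cluster library factors in [0.5, 1.5]; 20% of
  genes are markers whose mean is multiplied by `marker_fold` in their home
  cluster. Only the relative-expression structure matters downstream, so no
  attempt is made to model droplet-level properties of UMI data.
* **Genome.** 22 autosomes of 50 Mb; gene lengths log-normal around 20 kb;
  5% of genes placed inside a reserved high-LD ("extended MHC") interval
  and flagged; 10% labelled lncRNA so the biotype filter has work to do.
* **GWAS.** Genotypes are standardized Gaussian scores with block-diagonal
  LD: within contiguous blocks of `ld_block_size` SNPs every pair has
  correlation `block_rho`. Causal effects have per-SNP variance
  proportional to 1 (background) or `enrich_tau` (annotated), scaled to a
  total SNP-heritability `h2`; the phenotype adds Gaussian noise and
  marginal z-scores come from single-SNP regression. The equicorrelated
  blocks give the closed-form expected LD score $1 + (B-1)\rho^2$ used as
  an oracle. Replicate loops may hold the genotype matrix fixed and redraw
  effects and noise — the fixed-genotype, random-effect Monte Carlo design
  standard in statistical genetics.
* **Dissections.** Cluster-by-dissection cell counts use Dirichlet weights
  with concentration 0.25 for neuronal clusters (dissection-biased, sparse)
  and 5 for non-neuronal clusters (spread), multinomial totals of
  3,000–6,000 cells.
* **Connectivity.** Controls draw multivariate normal time series from a
  mildly correlated positive-definite base covariance; cases add `delta`
  to the covariance of the configured ROI pairs and the matrix is projected
  back to positive definite by eigenvalue clipping — the simplest
  controllable effect size. No haemodynamic model is attempted.

What passing tests on these data do and do not show: they demonstrate that
the estimators are calibrated and can recover planted signal under the
generative assumptions above (independent subjects, Gaussian signals,
block LD). They do not certify behaviour under real LD panels, UMI
sampling artefacts, scanner confounds, or case/control motion differences,
all of which are upstream of this package's scope.

# Numerical and design choices

**Decile threshold and ties.** The TDEP threshold for a cell type is the
`ceiling(0.1 * n)`-th largest EP over the `n` background genes; genes *at*
the threshold are included. With continuous EPs the pre-filter set size is
exactly the decile cap; the TPM > 1 filter then acts, which is why TDEP
sets can be smaller than a tenth of the background. Under degenerate ties
(many genes sharing the threshold EP) the inclusive rule can exceed the
cap; this cannot occur on the continuous synthetic data.

**Zero-expression genes.** Genes with zero total expression get EP 0 in
every cell type rather than NaN, and remain in the background only if the
expression filter kept them (it does not).

**Supercluster-level specificity** re-aggregates raw counts to
superclusters and recomputes TPM and EP, rather than averaging
cluster-level EPs: the normalizations are defined per cell type at
whichever level is analysed.

**LD scores** sum bias-adjusted squared correlations
$\hat r^2 - (1-\hat r^2)/(n-2)$, floored at zero, over a window counted in
SNP index positions (the synthetic map has no recombination coordinates);
the window should cover at least one LD block. Monomorphic panel SNPs
contribute zero with a warning.

**Regression weights.** The fit is two-step: a first pass weighted by
$1/\max(\ell_{\mathrm{base}}, 1)$, a second pass additionally downweighted
by $2\max(\hat\mu_j, 1)^2$ from the first-pass fitted values — the standard
heteroskedasticity approximation for $\chi^2$ regression. The intercept is
free. Standard errors come from a delete-a-block jackknife over 200
contiguous SNP blocks, implemented by downdating the normal equations.

**A known identifiability caveat.** With equicorrelated blocks of constant
size, the base LD score is nearly constant across SNPs, so the intercept
and the base-annotation coefficient are jointly weakly identified. The
target coefficient, its jackknife SE and the one-sided p-value are
unaffected (the null-calibration and power suites verify this), but the
derived enrichment *ratio* — which needs the base coefficient — is noisy
under this LD design and should be read qualitatively.

**eMHC exclusion.** SNPs inside the reserved high-LD interval can be
excluded before fitting (`emhc_snps()`), mirroring the standard practice of
dropping the extended MHC.

**Conditional scans** add the conditioning annotation to the model and
report the target's conditional p. An all-zero conditioning annotation is
dropped with a warning (reproducing the unconditional fit); a conditioning
annotation identical to the target is a singular-design error; a target
conditioned on itself is rejected outright. FDR is Benjamini–Hochberg
within trait — the plain step-up procedure, chosen over
Benjamini–Yekutieli absent any stated dependence correction.

**Regional p-values** treat the weighted sum $Z_d$ as standard normal,
following the direct conversion convention for the cluster Z-scores
themselves. Because $\sum_k \mathrm{pct}_{k,d}^2 < 1$, the weighted sum of
independent standard normals has variance below 1 (conservative), while
positive correlation between cluster Z-scores pushes the other way; the
convention is applied as stated and this caveat is the reason regional
FDR flags should be read jointly with the cluster-level results. The
decile scaling of composition entries is display-only and never enters
$Z_d$. Curated dissection exclusions are an explicit argument, not
hard-coded names.

**Co-occurrence residuals** are internally studentized (leverage-adjusted,
`rstandard`), which gives mean approximately — not identically — zero and
unit scale; a perfect fit (zero residual variance) returns all-zero
residuals rather than 0/0. The random-placement expectation for empty-bin
fractions is uniform multinomial placement of TSS into bins, whose mean has
the closed form $(1 - 1/n_{\mathrm{bins}})^{n_{\mathrm{tss}}}$ used as the
simulation oracle.

**Classifier.** The classification contract is cross-entropy training plus
ROC-AUC evaluation on held-out subjects, with features standardized on
training statistics only (leakage control). Two backends satisfy it: a
single-hidden-layer feed-forward network (`nnet`, weight decay) and a
ridge-penalized logistic regression (`glmnet`), the latter the default for
permutation-heavy simulation because shuffling one feature of a linear
model permits incremental logit updates, evaluating all permutations as
one matrix operation.

**Permutation gate.** One connection is shuffled across the subjects of
the evaluation split; if the original error falls outside the central 95%
interval of the permuted errors the connection is "contributing" and its
importance is the mean permuted error over the original error, otherwise
zero. Under a null feature the original error is exchangeable with the
permuted ones, so the gate fires with probability about 0.05 — a property
the acceptance suite measures directly. The choice to permute within the
evaluation split (rather than the training split) keeps the reference
error and the permuted errors on the same data.

**Recursive elimination** removes the ROI with the smallest summed
importance over its connections, ties broken by the lowest ROI index, down
to a configurable floor (default 2 ROIs). Every run's full-size FI matrix,
held-out AUC, and eliminated ROI are recorded, so any preserved-run
summary convention can be computed from the trace. Aggregation scales each
run's FI matrix by its own maximum, weights by the run's AUC, and sums —
making the aggregate invariant to run order and skipping all-zero
matrices with a warning.

**Top-n enrichment** ranks all $R^2$ matrix entries (diagonal zero and
both symmetric copies included) so that the n-grid of even numbers reaches
$R^2$ — the convention under which 76 ROIs give 2,888 tests — with ties
broken by linear index, and tests flagged-endpoint over-representation by
upper-tail hypergeometric tests.

# Problem sizes

The test and acceptance suites run at sizes chosen to make every claim
measurable on a single CPU: null calibration uses 500 GWAS replicates at
5,000 SNPs and N = 2,000; power uses 100 replicates at 20,000 SNPs and
N = 5,000 with a tenfold enriched annotation at $h^2 = 0.5$; marker
recovery uses a fiftyfold marker atlas; the connectivity study uses 20
ROIs, 3 folds, 100 permutations, and ten independently seeded dataset
pairs. The analysis scripts under `analysis/` run a single seeded instance
of each stage and narrate the numbers they find.

# Known limitations

* The S-LDSC model here is the reduced form {base + target
  (+ conditionals)}, not a full multi-annotation baseline; with real GWAS
  this omission biases coefficients, but on synthetic data whose generative
  model matches the reduced form it is exact.
* The regional null treats dissection Z-scores as standard normal (see
  above).
* LD is synthetic and block-structured; nothing here handles real
  reference panels, allele frequencies, or QC of real summary statistics.
* The connectivity generator plants covariance differences directly at the
  ROI level; it does not emulate haemodynamics, motion, or preprocessing.
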