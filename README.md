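# cellherit

Genome-wide association studies of psychiatric disorders implicate hundreds
of loci of individually tiny effect; connecting that diffuse signal to
physical brain structures requires an intermediate readout. `cellherit`
implements one such chain for R users who work at the interface of
statistical genetics, single-cell transcriptomics, and neuroimaging:

1. **Cell-type specificity.** From an aggregated gene-by-cell-type count
   matrix, compute TPM
   (`Exp_{g,c} = Raw_{g,c} · 10^6 / Σ_g Raw_{g,c}`), expression proportion
   (`EP_{g,c} = Exp_{g,c} / Σ_c Exp_{g,c}`), and per cell type the TDEP set
   — genes in the top decile of EP with expression above 1 TPM — over a
   background of protein-coding, autosomal, non-eMHC, expressed genes.
2. **SNP-heritability enrichment.** TDEP genes ± 100 kb define SNP
   annotations; a compact stratified LD score regression fits
   `E[χ²_j] = a + N Σ_c τ_c ℓ(j,c)` by two-step weighted least squares
   with a delete-a-block jackknife SE, a one-sided enrichment p-value from
   the coefficient z-score, Benjamini–Hochberg FDR per trait, and pairwise
   conditional models for overlapping cell types.
3. **Regional aggregation.** Cluster-level Z-scores are extrapolated to
   anatomical dissections as the neuronal-composition-weighted sum
   `Z_d = Σ_k pct_{k,d} · Z_k`.
4. **Gene sets and genomic co-occurrence.** Upper-tail hypergeometric
   tests against the fixed background; 100 kb genome bins with
   `nTdep ~ nTss` regressions whose studentized residuals flag bins where
   specificity genes co-occur beyond baseline gene clumping.
5. **Connectivity classification.** Pearson connectivity from ROI time
   series, a cross-entropy classifier evaluated by held-out AUC, gated
   permutation feature importance (`FI = mean_e_perm / e_orig`), recursive
   ROI elimination, AUC-weighted FI aggregation, and top-n enrichment of
   flagged ROI connections.

A first-class synthetic-data layer (`sim_config()`, `generate_atlas()`,
`generate_gwas()`, `generate_fmri()`, `generate_gene_annotation()`) plants
known marker genes, enriched SNP annotations, and differential
connections, so each stage has parameter-recovery and calibration tests.
The methods vignette (`vignettes/cell-type-heritability-workflow.Rmd`)
documents the models, defaults, and numerical choices.

## Worked example

The numbered scripts under `analysis/` run one seeded instance of the full
chain and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # atlas, genome, GWAS inputs, fMRI data
Rscript analysis/02_tdep.R        # specificity scoring
Rscript analysis/03_enrichment.R  # stratified LD score regression
Rscript analysis/04_regions.R     # dissection-level aggregation
Rscript analysis/05_genesets.R    # hypergeometric + co-occurrence
Rscript analysis/06_fmri.R        # connectivity RFE in two datasets
```

Output of the run above (seed 20260924, 2,000 genes × 20 clusters, planted
eightfold markers, tenfold enriched annotation on cluster `cl001`,
covariance shift on ROI pair 3–7):

```
background: 1703 genes; TDEP sets: 171-171 genes per cluster
planted marker recovery: 85.5%; median pairwise Jaccard: 0.046
planted annotation: cl001  (tau z = 4.10, p = 2.1e-05, fdr = 0.00042)
FDR<=0.05 clusters: 1 of 20
top dissection: d01 (Z = 2.13, fdr = 0.2); 0 of 12 at FDR<=0.05
gene-set tests: 20; min FDR 1.8e-12
empty 100 kb bins: observed 85.6%, random expectation 85.7% (closed form 85.7%)
dataset 1: mean AUC 0.89, top connections: ROI03-ROI07, ROI06-ROI15
dataset 2: mean AUC 0.90, top connections: ROI03-ROI07, ROI03-ROI18
preserved-run correlation between datasets: r = 0.60 (p = 0.005)
```

Reading these numbers: the TDEP stage recovers most planted markers and
cluster TDEP sets overlap little (median Jaccard 0.046); the regression
singles out exactly the cluster whose annotation carries extra per-SNP
variance; the regional stage ranks the dissection where that cluster
concentrates first (at this effect size without surviving FDR — the
composition weights dilute a single-cluster signal); the planted ROI pair
tops the aggregated importance ranking in both independently simulated
connectivity datasets, and preserved-run counts replicate across them.

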