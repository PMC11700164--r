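#' Simulation configuration for the synthetic brain pipeline
#'
#' Bundles every knob of the synthetic-data layer: the gene/cell-type atlas,
#' the GWAS generative model, and the case/control connectivity datasets.
#' Defaults are desk-scale study conditions chosen once for the whole
#' package; parameter-recovery tests override single fields (for example
#' `marker_fold` or `enrich_tau`) but never the structure.
#'
#' @param seed integer seed; each generator derives its own stream from it
#'   via a fixed counter offset so stages are independently re-runnable.
#' @param n_genes number of genes in the synthetic genome.
#' @param n_clusters number of fine cell clusters.
#' @param n_superclusters number of coarse superclusters (
#'   `n_clusters >= n_superclusters`).
#' @param n_dissections number of anatomical dissections.
#' @param frac_neuronal fraction of superclusters labelled neuronal.
#' @param marker_frac fraction of genes planted as cluster-specific markers.
#' @param marker_fold fold-change applied to a marker gene's mean expression
#'   in its home cluster (1 = null, no planted specificity).
#' @param nb_dispersion negative-binomial size parameter shared by all genes.
#' @param emhc_frac fraction of genes placed inside the synthetic extended
#'   MHC interval (and flagged `emhc`).
#' @param lnc_frac fraction of genes given the `lncRNA` biotype (the rest are
#'   `protein_coding`).
#' @param n_chrom number of autosomes used (1..22).
#' @param chrom_length length in bp of each synthetic autosome.
#' @param clumped_frac fraction of genes placed in clumps (several TSS per
#'   100 kb) rather than uniformly; 0 disables clumping.
#' @param n_snps number of SNPs.
#' @param n_individuals GWAS sample size.
#' @param n_panel LD reference panel sample size.
#' @param ld_block_size SNPs per independent equicorrelated LD block.
#' @param block_rho within-block haplotype correlation in `[0, 1)`.
#' @param h2 trait SNP-heritability in `(0, 1)`.
#' @param enrich_tau per-SNP variance multiplier for annotated SNPs (>= 0;
#'   1 = null).
#' @param n_rois number of fMRI regions of interest.
#' @param ts_length time points per subject.
#' @param n_cases,n_controls group sizes of the connectivity dataset.
#' @param delta_pairs list of `c(i, j, delta)` triplets: ROI pairs whose
#'   case-group covariance is shifted by `delta` (then projected back to
#'   positive definite).
#' @param dirichlet_neuronal,dirichlet_nonneuronal Dirichlet concentration
#'   for dissection compositions; neuronal clusters get the sparse value so
#'   they concentrate in few dissections, non-neuronal clusters spread.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_clusters = 20L,
                       n_superclusters = 5L,
                       n_dissections = 12L,
                       frac_neuronal = 0.6,
                       marker_frac = 0.2,
                       marker_fold = 8,
                       nb_dispersion = 2,
                       emhc_frac = 0.05,
                       lnc_frac = 0.1,
                       n_chrom = 22L,
                       chrom_length = 5e7,
                       clumped_frac = 0,
                       n_snps = 10000L,
                       n_individuals = 2000L,
                       n_panel = 500L,
                       ld_block_size = 50L,
                       block_rho = 0.3,
                       h2 = 0.3,
                       enrich_tau = 5,
                       n_rois = 20L,
                       ts_length = 150L,
                       n_cases = 30L,
                       n_controls = 30L,
                       delta_pairs = list(c(1L, 2L, 0.35)),
                       dirichlet_neuronal = 0.25,
                       dirichlet_nonneuronal = 5) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_clusters = as.integer(n_clusters),
    n_superclusters = as.integer(n_superclusters),
    n_dissections = as.integer(n_dissections),
    frac_neuronal = frac_neuronal,
    marker_frac = marker_frac, marker_fold = marker_fold,
    nb_dispersion = nb_dispersion, emhc_frac = emhc_frac,
    lnc_frac = lnc_frac, n_chrom = as.integer(n_chrom),
    chrom_length = chrom_length, clumped_frac = clumped_frac,
    n_snps = as.integer(n_snps), n_individuals = as.integer(n_individuals),
    n_panel = as.integer(n_panel), ld_block_size = as.integer(ld_block_size),
    block_rho = block_rho, h2 = h2, enrich_tau = enrich_tau,
    n_rois = as.integer(n_rois), ts_length = as.integer(ts_length),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    delta_pairs = delta_pairs,
    dirichlet_neuronal = dirichlet_neuronal,
    dirichlet_nonneuronal = dirichlet_nonneuronal
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks count positivity, probability ranges, and the cross-field
#' constraints the generators rely on. Called by [sim_config()]; exported so
#' externally assembled configs can be checked too.
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly, or an error describing every violated field.
#' @export
validate_sim_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)

  counts <- c("n_genes", "n_clusters", "n_superclusters", "n_dissections",
              "n_snps", "n_individuals", "n_panel", "ld_block_size",
              "n_rois", "ts_length", "n_cases", "n_controls", "n_chrom")
  for (f in counts) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L && cfg[[f]] > 0,
        sprintf("%s must be a positive count", f))
  }
  chk(cfg$n_clusters >= cfg$n_superclusters,
      "n_clusters must be >= n_superclusters")
  chk(cfg$n_chrom >= 1L && cfg$n_chrom <= 22L,
      "n_chrom must be between 1 and 22 (canonical autosomes)")
  for (f in c("marker_frac", "emhc_frac", "lnc_frac", "frac_neuronal",
              "clumped_frac")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, sprintf("%s must be in [0, 1]", f))
  }
  chk(cfg$block_rho >= 0 && cfg$block_rho < 1, "block_rho must be in [0, 1)")
  chk(cfg$h2 > 0 && cfg$h2 < 1, "h2 must be in (0, 1)")
  chk(cfg$enrich_tau >= 0, "enrich_tau must be >= 0")
  chk(cfg$marker_frac * cfg$n_genes >= cfg$n_clusters,
      "marker_frac * n_genes must be >= n_clusters (one marker per cluster)")
  chk(cfg$nb_dispersion > 0, "nb_dispersion must be > 0")
  chk(is.list(cfg$delta_pairs), "delta_pairs must be a list of triplets")
  if (is.list(cfg$delta_pairs)) {
    for (dp in cfg$delta_pairs) {
      chk(length(dp) == 3L && all(is.finite(dp)) &&
            dp[1] >= 1 && dp[2] >= 1 &&
            dp[1] <= cfg$n_rois && dp[2] <= cfg$n_rois && dp[1] != dp[2],
          "each delta_pairs entry must be c(roi_i, roi_j, delta) with valid, distinct ROI indices")
    }
  }
  if (length(bad)) {
    stop("invalid sim_config:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cfg)
}

# Per-stage seed fan-out: one global seed, fixed documented offsets, so each
# generator is independently re-runnable. Kept well below 2^31.
stage_seed <- function(cfg, stage) {
  offsets <- c(annotation = 101L, atlas = 202L, gwas = 303L, fmri = 404L,
               pipeline = 505L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (cfg$seed %% 1000000L) * 1000L + offsets[[stage]]
}
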