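test_that("sim_config validates counts, fractions, and cross-field rules", {
  expect_s3_class(tiny_config(), "sim_config")
  expect_error(tiny_config(h2 = 1.5), "h2")
  expect_error(tiny_config(block_rho = 1), "block_rho")
  expect_error(tiny_config(n_chrom = 30L), "n_chrom")
  expect_error(tiny_config(n_individuals = 0L), "n_individuals")
  expect_error(tiny_config(enrich_tau = -1), "enrich_tau")
  expect_error(tiny_config(marker_frac = 0.001), "marker_frac")
  expect_error(tiny_config(delta_pairs = list(c(1L, 99L, 0.3))),
               "delta_pairs")
})

test_that("gene annotation has the contracted shape and is deterministic", {
  cfg <- tiny_config()
  ann <- generate_gene_annotation(cfg)
  expect_equal(nrow(ann), cfg$n_genes)
  expect_true(all(ann$start < ann$end))
  expect_true(all(ann$tss >= ann$start & ann$tss <= ann$end))
  expect_true(all(ann$chrom %in% paste0("chr", 1:22)))
  expect_true(all(ann$strand %in% c("+", "-")))
  expect_identical(ann, generate_gene_annotation(cfg))
  reg <- emhc_region(cfg)
  inside <- ann$chrom == reg$chrom & ann$start >= reg$start &
    ann$end <= reg$end
  expect_true(all(inside[ann$emhc]))
})

test_that("clumped gene placement leaves more empty 100 kb bins than uniform", {
  cfg <- tiny_config(clumped_frac = 0.8, n_chrom = 2L)
  ann <- generate_gene_annotation(cfg)
  bin <- paste(ann$chrom, ann$tss %/% 1e5)
  n_bins <- 2 * ceiling(cfg$chrom_length / 1e5)
  observed_empty <- 1 - length(unique(bin)) / n_bins
  # oracle: empty-bin fraction under 1000 uniform placements of the same
  # number of TSS
  set.seed(99)
  null_empty <- replicate(1000, {
    1 - length(unique(sample.int(n_bins, cfg$n_genes, replace = TRUE))) / n_bins
  })
  expect_gt(observed_empty, stats::quantile(null_empty, 0.99))
})

test_that("atlas plants markers, is deterministic, and null fold is null", {
  cfg <- tiny_config(marker_fold = 50)
  atlas <- generate_atlas(cfg)
  expect_identical(atlas$expr, generate_atlas(cfg)$expr)
  expect_equal(dim(atlas$expr), c(cfg$n_genes, cfg$n_clusters))
  expect_equal(nrow(atlas$composition), cfg$n_clusters)

  # markers attain their maximum expression proportion in the home cluster
  ep <- expression_proportion(normalize_tpm(atlas$expr))
  hits <- unlist(lapply(names(atlas$truth$marker_genes), function(k) {
    mk <- atlas$truth$marker_genes[[k]]
    apply(ep[mk, , drop = FALSE], 1, which.max) == match(k, colnames(ep))
  }))
  expect_gt(mean(hits), 0.95)

  # marker_fold = 1: TDEP sets show no excess overlap vs random same-size
  # sets (permutation oracle)
  cfg0 <- tiny_config(marker_fold = 1)
  atlas0 <- generate_atlas(cfg0)
  ann0 <- generate_gene_annotation(cfg0)
  bg0 <- filter_background(atlas0$expr, ann0)
  sets0 <- specificity_table(atlas0$expr, bg0)$tdep_sets
  jm <- jaccard_matrix(sets0)
  obs <- stats::median(jm[upper.tri(jm)])
  set.seed(5)
  null_med <- replicate(200, {
    rnd <- lapply(lengths(sets0), function(k) sample(bg0, k))
    jr <- jaccard_matrix(rnd)
    stats::median(jr[upper.tri(jr)])
  })
  expect_lte(obs, stats::quantile(null_med, 0.99))
})

test_that("gwas simulator matches its stratified-heritability contract", {
  cfg <- tiny_config(enrich_tau = 1, n_snps = 2000L, n_individuals = 500L)
  member <- as.numeric(seq_len(cfg$n_snps) %% 4 == 0)
  g0 <- generate_gwas(cfg, member, seed = 1)
  expect_equal(nrow(g0$sumstats), cfg$n_snps)
  expect_true(all(is.finite(g0$sumstats$z)))
  expect_identical(g0$sumstats,
                   generate_gwas(cfg, member, seed = 1)$sumstats)

  # null symmetry: tau = 1 gives equal expected chi2 for annotated vs
  # background SNPs (difference within Monte-Carlo error over 200 reps)
  diffs <- vapply(1:200, function(i) {
    g <- generate_gwas(cfg, member, seed = 100 + i,
                       genotypes = g0$genotypes, make_panel = FALSE)
    chi2 <- g$sumstats$z^2
    mean(chi2[member == 1]) - mean(chi2[member == 0])
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se)

  # strong enrichment: annotated SNPs carry visibly larger chi2
  cfg2 <- tiny_config(enrich_tau = 10, h2 = 0.5, n_snps = 4000L,
                      n_individuals = 2000L)
  member2 <- as.numeric(seq_len(cfg2$n_snps) %% 4 == 0)
  g2 <- generate_gwas(cfg2, member2, seed = 7)
  chi2 <- g2$sumstats$z^2
  expect_gt(mean(chi2[member2 == 1]), mean(chi2[member2 == 0]))

  bad <- tiny_config()
  bad$n_individuals <- 0L
  expect_error(generate_gwas(bad, member), "n_individuals")
})

test_that("fmri generator plants covariance differences deterministically", {
  cfg <- tiny_config()
  fm <- generate_fmri(cfg)
  expect_length(fm$ts, cfg$n_cases + cfg$n_controls)
  expect_equal(sum(fm$labels), cfg$n_cases)
  expect_identical(fm$ts[[1]], generate_fmri(cfg)$ts[[1]])
  # case covariance carries the planted shift, still positive definite
  dp <- fm$truth$differential_pairs
  expect_gt(fm$cov_case[dp[1, "i"], dp[1, "j"]],
            fm$cov_control[dp[1, "i"], dp[1, "j"]])
  expect_true(all(eigen(fm$cov_case, only.values = TRUE)$values > 0))
  expect_setequal(fm$roi_meta$group[c(dp[, "i"], dp[, "j"])], "limbic")
})

test_that("null fmri data yield chance-level held-out AUC", {
  cfg <- tiny_config(delta_pairs = list(c(1L, 2L, 0)), n_cases = 24L,
                     n_controls = 24L, n_rois = 6L)
  fm <- generate_fmri(cfg)
  conn <- lapply(fm$ts, compute_connectivity)
  folds <- make_folds(fm$labels, vapply(fm$ts, nrow, 1L), n_folds = 4,
                      seed = 3)
  feats <- connectivity_features(conn)
  aucs <- vapply(1:4, function(f) {
    te <- folds == f
    train_eval(feats[!te, ], fm$labels[!te], feats[te, ], fm$labels[te],
               fmri_config("logistic"))$auc
  }, numeric(1))
  # binomial noise around 0.5 with 12 held-out subjects per fold
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})
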