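test_that("gene-window annotation follows the half-open convention", {
  ann <- data.frame(gene = "gA", chrom = "chr1", start = 1000, end = 2000,
                    strand = "+", tss = 1000, biotype = "protein_coding",
                    emhc = FALSE)
  snps <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                     pos = c(500, 101999, 102000, 1500))
  m <- build_annotation("gA", ann, snps, window_kb = 100)$member
  expect_equal(m, c(1L, 1L, 0L, 0L))

  # window 0: SNP exactly at the gene start is a member, end is not
  snps0 <- data.frame(chrom = "chr1", pos = c(999, 1000, 1999, 2000))
  expect_equal(build_annotation("gA", ann, snps0, window_kb = 0)$member,
               c(0L, 1L, 1L, 0L))

  expect_error(build_annotation(character(0), ann, snps), "empty")
  expect_error(build_annotation("gZ", ann, snps), "gZ")
})

test_that("gene-window annotation agrees with a brute-force interval scan", {
  cfg <- tiny_config()
  ann <- generate_gene_annotation(cfg)
  snps <- snp_map(cfg)
  genes <- sample(ann$gene, 60)
  fast <- build_annotation(genes, ann, snps, window_kb = 100)$member
  slow <- brute_annotation(genes, ann, snps, window_kb = 100)
  expect_identical(fast, slow)
})

test_that("LD scores match closed forms for the block-equicorrelated panel", {
  cfg <- tiny_config(block_rho = 0, n_snps = 1000L, n_panel = 300L)
  panel <- local({
    set.seed(21)
    simulate_genotypes(cfg$n_panel, cfg$n_snps, cfg$ld_block_size, 0)
  })
  base <- rep(1, cfg$n_snps)
  ld0 <- compute_ld_scores(panel, list(base = base), window_snps = 25)
  expect_lt(abs(mean(ld0$scores[, "base"]) - 1), 0.1)

  rho <- 0.5
  b <- 20L
  set.seed(22)
  panel2 <- simulate_genotypes(300, 1000, b, rho)
  ld2 <- compute_ld_scores(panel2, list(base = base), window_snps = b)
  expect_lt(abs(mean(ld2$scores[, "base"]) - (1 + (b - 1) * rho^2)), 0.3)

  # an all-zero annotation has all-zero LD scores
  ldz <- compute_ld_scores(panel2, list(base = base, none = rep(0, 1000)),
                           window_snps = b)
  expect_equal(unname(ldz$scores[, "none"]), rep(0, 1000))

  # monomorphic SNP: terms zeroed with a warning
  panel3 <- panel2
  panel3[, 5] <- 1
  expect_warning(ld3 <- compute_ld_scores(panel3, list(base = base),
                                          window_snps = b), "monomorphic")
  expect_equal(unname(ld3$scores[5, "base"]), 0)
  expect_error(compute_ld_scores(panel2[1:2, ], list(base = base), b), ">= 3")
})

test_that("sldsc recovers a strongly enriched annotation and rejects bad designs", {
  cfg <- tiny_config(enrich_tau = 10, h2 = 0.5, n_snps = 6000L,
                     n_individuals = 3000L, n_panel = 300L)
  member <- as.numeric(seq_len(cfg$n_snps) %% 5 == 0)
  ann <- list(base = rep(1, cfg$n_snps), target = member)
  g <- generate_gwas(cfg, member, seed = 31)
  ld <- compute_ld_scores(g$panel, ann, window_snps = cfg$ld_block_size)
  fit <- sldsc_fit(g$sumstats, ld, ann, "target", n_blocks = 100)
  expect_lt(fit$p, 0.05)
  expect_gt(fit$tau, 0)
  # under block-equicorrelated LD the base LD score is near-constant, so
  # the h2-share ratio is weakly identified; only finiteness is contracted
  expect_true(is.finite(fit$enrichment))
  expect_equal(fit$prop_snps, 0.2)

  # duplicated annotation -> singular design naming the column
  ann_dup <- list(base = rep(1, cfg$n_snps), target = member, twin = member)
  ld_dup <- compute_ld_scores(g$panel, ann_dup,
                              window_snps = cfg$ld_block_size)
  expect_error(
    sldsc_fit(g$sumstats, ld_dup, ann_dup, "target", conditional = "twin",
              n_blocks = 100),
    "collinear.*twin|twin.*collinear"
  )
  expect_error(sldsc_fit(g$sumstats[1:150, ], ld$scores[1:150, ], ann,
                         "target", n_blocks = 100), "2 \\* n_blocks")
})

test_that("jackknife SE tracks the empirical spread of tau", {
  cfg <- tiny_config(enrich_tau = 1, n_snps = 3000L, n_individuals = 800L,
                     n_panel = 250L)
  member <- as.numeric(seq_len(cfg$n_snps) %% 5 == 0)
  ann <- list(base = rep(1, cfg$n_snps), target = member)
  g0 <- generate_gwas(cfg, member, seed = 41)
  ld <- compute_ld_scores(g0$panel, ann, window_snps = cfg$ld_block_size)
  res <- t(vapply(1:60, function(i) {
    g <- generate_gwas(cfg, member, seed = 400 + i,
                       genotypes = g0$genotypes, make_panel = FALSE)
    f <- sldsc_fit(g$sumstats, ld, ann, "target", n_blocks = 150)
    c(tau = f$tau, se = f$se)
  }, c(tau = 0, se = 0)))
  ratio <- mean(res[, "se"]) / stats::sd(res[, "tau"])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("tau estimates increase with the planted enrichment", {
  taus <- vapply(c(1, 5, 15), function(tau_plant) {
    cfg <- tiny_config(enrich_tau = tau_plant, n_snps = 3000L,
                       n_individuals = 1500L, n_panel = 250L)
    member <- as.numeric(seq_len(cfg$n_snps) %% 5 == 0)
    ann <- list(base = rep(1, cfg$n_snps), target = member)
    g <- generate_gwas(cfg, member, seed = 51)
    ld <- compute_ld_scores(g$panel, ann, window_snps = cfg$ld_block_size)
    sldsc_fit(g$sumstats, ld, ann, "target", n_blocks = 150)$tau
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("BH adjustment within trait matches hand computation", {
  res <- data.frame(trait = "t1", p = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(fdr_adjust(res)$fdr, rep(0.04, 4))
  one <- data.frame(trait = "t1", p = 0.2)
  expect_equal(fdr_adjust(one)$fdr, 0.2)
  ones <- data.frame(trait = rep(c("a", "b"), 3), p = rep(1, 6))
  expect_equal(fdr_adjust(ones)$fdr, rep(1, 6))
  # grouping: adjustment is independent per trait
  two <- data.frame(trait = c("a", "a", "b"), p = c(0.01, 0.04, 0.01))
  expect_equal(fdr_adjust(two)$fdr, c(0.02, 0.04, 0.01))
})

test_that("conditional scan handles null, overlapping, and self conditions", {
  cfg <- tiny_config(enrich_tau = 12, h2 = 0.5, n_snps = 6000L,
                     n_individuals = 3000L, n_panel = 300L)
  causal <- as.numeric(seq_len(cfg$n_snps) %% 5 == 0)
  # a shadow annotation overlapping the causal one on 90% of its SNPs
  set.seed(8)
  shadow <- causal
  on_idx <- which(causal == 1)
  swap <- sample(on_idx, round(0.1 * length(on_idx)))
  shadow[swap] <- 0
  shadow[sample(which(causal == 0), length(swap))] <- 1
  ann <- list(base = rep(1, cfg$n_snps), causal = causal, shadow = shadow,
              zero = rep(0, cfg$n_snps))
  g <- generate_gwas(cfg, causal, seed = 61)
  ld <- compute_ld_scores(g$panel, ann, window_snps = cfg$ld_block_size)

  uncond <- sldsc_fit(g$sumstats, ld, ann, "shadow", n_blocks = 100)
  cond_zero <- suppressWarnings(
    sldsc_fit(g$sumstats, ld, ann, "shadow", conditional = "zero",
              n_blocks = 100)
  )
  expect_equal(cond_zero$p, uncond$p) # all-zero condition changes nothing

  cond <- sldsc_fit(g$sumstats, ld, ann, "shadow", conditional = "causal",
                    n_blocks = 100)
  expect_lt(uncond$p, 0.05)  # shadow looks enriched marginally
  expect_gt(cond$p, uncond$p) # but loses signal given the causal set

  expect_error(
    conditional_scan(g$sumstats, ld, ann,
                     data.frame(target = "causal", condition = "causal"),
                     n_blocks = 100),
    "itself"
  )
  grid <- conditional_scan(
    g$sumstats, ld, ann,
    data.frame(target = c("causal", "causal"),
               condition = c(NA, "shadow"), stringsAsFactors = FALSE),
    n_blocks = 100
  )
  expect_equal(nrow(grid), 2)
  expect_lt(grid$p[2], 0.05) # the causal set survives conditioning
})
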