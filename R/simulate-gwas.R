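#' Simulate genotypes with block-diagonal equicorrelated LD
#'
#' Genotypes are standardized Gaussian scores: within each contiguous block
#' of `block_size` SNPs, every pair of SNPs has correlation `rho`; SNPs in
#' different blocks are independent. The equicorrelated-block structure has
#' closed-form expected LD scores (`1 + (B - 1) * rho^2` for a full block),
#' which the LD score estimator is tested against.
#'
#' @param n samples, `p` SNPs, `block_size` SNPs per block, `rho`
#'   within-block correlation in `[0, 1)`.
#' @param p,block_size,rho see above.
#' @return `n x p` matrix.
#' @export
simulate_genotypes <- function(n, p, block_size, rho) {
  stopifnot(n > 0, p > 0, block_size > 0, rho >= 0, rho < 1)
  e <- matrix(stats::rnorm(n * p), n, p)
  if (rho == 0) return(e)
  n_blocks <- ceiling(p / block_size)
  f <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(p)]
  sqrt(1 - rho) * e + sqrt(rho) * f[, block_of, drop = FALSE]
}

#' Build the synthetic SNP map
#'
#' Assigns SNPs to chromosomes in contiguous index order (so LD blocks never
#' straddle chromosomes) with sorted uniform positions per chromosome.
#'
#' @param cfg a [sim_config()].
#' @return data.frame `snp`, `chrom`, `pos`, `a1`, `a2`.
#' @export
snp_map <- function(cfg) {
  set.seed(stage_seed(cfg, "gwas"))
  p <- cfg$n_snps
  per_chrom <- diff(round(seq(0, p, length.out = cfg$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(floor(stats::runif(k, 0, cfg$chrom_length)))
  }), use.names = FALSE)
  alle <- c("A", "C", "G", "T")
  a1 <- sample(alle, p, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(alle, a), 1), "")
  data.frame(snp = sprintf("rs%06d", seq_len(p)), chrom = chrom, pos = pos,
             a1 = a1, a2 = unname(a2), stringsAsFactors = FALSE)
}

#' Simulate GWAS summary statistics under a stratified heritability model
#'
#' Draws per-SNP causal effects with variance proportional to 1 for
#' background SNPs and `enrich_tau` for SNPs in the supplied annotation,
#' scaled so the total genetic variance equals `h2`. The phenotype is the
#' genetic value plus Gaussian noise; marginal per-SNP z-scores come from
#' single-SNP regression on the simulated genotypes. An independent LD
#' reference panel with the same block structure is returned alongside.
#'
#' Replicate loops can pass a fixed `genotypes` matrix (and reuse the
#' returned `panel`) so only effects, noise, and marginal statistics are
#' redrawn — the fixed-genotype, random-effect design standard in
#' statistical genetics simulation.
#'
#' @param cfg a [sim_config()].
#' @param annotation_snps 0/1 membership vector over SNPs `1..n_snps` (or a
#'   list with a `member` field, as returned by [build_annotation()]).
#' @param seed optional override of the stage seed.
#' @param genotypes optional pre-simulated `n_individuals x n_snps` matrix.
#' @param make_panel set `FALSE` to skip panel simulation (reusing an
#'   earlier one).
#' @param geno_stats optional [genotype_col_stats()] of `genotypes`;
#'   precomputing it once avoids re-scanning a large fixed genotype matrix
#'   on every replicate.
#' @return list with `sumstats` (data.frame `snp`, `chrom`, `pos`, `a1`,
#'   `a2`, `z`, `n`), `panel` (`n_panel x n_snps` matrix or NULL),
#'   `genotypes`, and `truth` (`enriched_annotation`, planted `tau`).
#' @export
generate_gwas <- function(cfg, annotation_snps, seed = NULL,
                          genotypes = NULL, make_panel = TRUE,
                          geno_stats = NULL) {
  validate_sim_config(cfg)
  member <- if (is.list(annotation_snps)) annotation_snps$member else annotation_snps
  ann_name <- if (is.list(annotation_snps) && !is.null(annotation_snps$name)) {
    annotation_snps$name
  } else "annotated"
  if (length(member) != cfg$n_snps) {
    stop("annotation_snps must index SNPs 1..n_snps (length ", cfg$n_snps, ")")
  }
  member <- as.numeric(member != 0)

  map <- snp_map(cfg) # consumes the deterministic map stream first
  set.seed(if (is.null(seed)) stage_seed(cfg, "gwas") + 1L else seed)

  n <- cfg$n_individuals
  p <- cfg$n_snps
  if (is.null(genotypes)) {
    genotypes <- simulate_genotypes(n, p, cfg$ld_block_size, cfg$block_rho)
  } else {
    stopifnot(nrow(genotypes) == n, ncol(genotypes) == p)
  }

  s <- ifelse(member > 0, cfg$enrich_tau, 1)
  s <- s / sum(s) * cfg$h2
  beta <- stats::rnorm(p, 0, sqrt(s))
  g <- drop(genotypes %*% beta)
  y <- g + stats::rnorm(n, 0, sqrt(1 - cfg$h2))

  z <- marginal_z(genotypes, y, geno_stats)

  panel <- if (make_panel) {
    simulate_genotypes(cfg$n_panel, p, cfg$ld_block_size, cfg$block_rho)
  }

  sumstats <- data.frame(map, z = z, n = n, stringsAsFactors = FALSE)
  list(sumstats = sumstats, panel = panel, genotypes = genotypes,
       truth = list(enriched_annotation = ann_name, tau = cfg$enrich_tau,
                    member = member))
}

#' Per-column means and centred sums of squares of a genotype matrix
#'
#' @param x genotype matrix.
#' @return list with `mean` and `ss` per SNP.
#' @export
genotype_col_stats <- function(x) {
  n <- nrow(x)
  xm <- colMeans(x)
  list(mean = xm, ss = colSums(x^2) - n * xm^2)
}

# Marginal single-SNP regression z-scores, vectorized over SNPs.
marginal_z <- function(x, y, stats_x = NULL) {
  n <- length(y)
  yc <- y - mean(y)
  num <- drop(crossprod(x, yc))
  if (is.null(stats_x)) stats_x <- genotype_col_stats(x)
  r <- num / sqrt(stats_x$ss * sum(yc^2))
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  r * sqrt((n - 2) / (1 - r^2))
}
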