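#' Synthetic extended-MHC interval
#'
#' The synthetic genome reserves one interval as the extended MHC (eMHC):
#' chr6:25-34 Mb when the synthetic chromosomes are long enough to contain
#' it, otherwise the central third of the last available chromosome. Genes
#' flagged `emhc` are placed inside it and SNPs inside it can be excluded
#' before LD score regression, mirroring standard practice of dropping this
#' high-LD region.
#'
#' @param cfg a [sim_config()].
#' @return list with `chrom`, `start`, `end` (0-based half-open).
#' @export
emhc_region <- function(cfg) {
  chrom <- paste0("chr", min(6L, cfg$n_chrom))
  if (cfg$chrom_length >= 34e6) {
    list(chrom = chrom, start = 25e6, end = 34e6)
  } else {
    list(chrom = chrom, start = cfg$chrom_length / 3,
         end = 2 * cfg$chrom_length / 3)
  }
}

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` genes on `n_chrom` synthetic autosomes. Coordinates are
#' 0-based half-open; the TSS is the strand-appropriate gene boundary. A
#' configurable fraction of genes is placed inside the synthetic eMHC
#' interval (and flagged), and an optional fraction is placed in clumps of
#' several TSS per 100 kb to exercise the genomic co-occurrence analysis.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of the stage seed.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `biotype`, `emhc`.
#' @export
generate_gene_annotation <- function(cfg, seed = NULL) {
  validate_sim_config(cfg)
  set.seed(if (is.null(seed)) stage_seed(cfg, "annotation") else seed)

  n <- cfg$n_genes
  gene <- sprintf("g%05d", seq_len(n))
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  chrom <- sample(chroms, n, replace = TRUE)

  len <- pmin(pmax(round(stats::rlnorm(n, log(2e4), 0.8)), 200),
              floor(cfg$chrom_length / 10))
  start <- floor(stats::runif(n, 0, cfg$chrom_length - len))

  # clumped placement: several TSS per 100 kb, same chromosome
  n_clumped <- round(cfg$clumped_frac * n)
  if (n_clumped > 0) {
    idx <- sample.int(n, n_clumped)
    n_clumps <- max(1L, ceiling(n_clumped / 5))
    centers <- floor(stats::runif(n_clumps, 0, cfg$chrom_length - 2e5))
    assign_clump <- sample.int(n_clumps, n_clumped, replace = TRUE)
    chrom[idx] <- sample(chroms, n_clumps, replace = TRUE)[assign_clump]
    start[idx] <- centers[assign_clump] +
      floor(stats::runif(n_clumped, 0, 5e4))
  }

  # eMHC genes are physically placed inside the reserved interval
  emhc <- rep(FALSE, n)
  n_emhc <- round(cfg$emhc_frac * n)
  if (n_emhc > 0) {
    reg <- emhc_region(cfg)
    idx <- sample.int(n, n_emhc)
    emhc[idx] <- TRUE
    chrom[idx] <- reg$chrom
    span <- reg$end - reg$start
    len[idx] <- pmin(len[idx], floor(span / 4))
    start[idx] <- floor(stats::runif(n_emhc, reg$start,
                                     reg$end - len[idx]))
  }

  end <- start + len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start, end)
  biotype <- ifelse(seq_len(n) %in% sample.int(n, round(cfg$lnc_frac * n)),
                    "lncRNA", "protein_coding")

  data.frame(gene = gene, chrom = chrom, start = start, end = end,
             strand = strand, tss = tss, biotype = biotype, emhc = emhc,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cell-type atlas
#'
#' Draws a gene-by-cluster count matrix from a negative-binomial model with
#' shared dispersion. A fraction of genes are planted markers: their mean is
#' multiplied by `marker_fold` in their home cluster only. Clusters are
#' assigned to superclusters and labelled neuronal/non-neuronal, and a
#' cluster-by-dissection cell-count table is drawn with sparse Dirichlet
#' weights for neuronal clusters (dissection-biased) and diffuse weights for
#' non-neuronal clusters.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of the stage seed.
#' @return list with `expr` (genes x clusters count matrix), `hierarchy`
#'   (data.frame cluster / supercluster / neuronal), `composition`
#'   (clusters x dissections cell counts), and `truth` (planted marker gene
#'   map, cluster -> gene ids).
#' @export
generate_atlas <- function(cfg, seed = NULL) {
  validate_sim_config(cfg)
  set.seed(if (is.null(seed)) stage_seed(cfg, "atlas") else seed)

  n_g <- cfg$n_genes
  n_k <- cfg$n_clusters
  genes <- sprintf("g%05d", seq_len(n_g))
  clusters <- sprintf("cl%03d", seq_len(n_k))

  n_markers <- round(cfg$marker_frac * n_g)
  marker_idx <- sample.int(n_g, n_markers)
  marker_home <- rep_len(seq_len(n_k), n_markers)
  marker_genes <- split(genes[marker_idx], clusters[marker_home])
  marker_genes <- marker_genes[clusters] # cluster order, empty sets kept
  names(marker_genes) <- clusters

  base_mean <- stats::rlnorm(n_g, meanlog = log(5), sdlog = 1.2)
  lib_factor <- stats::runif(n_k, 0.5, 1.5)
  mu <- outer(base_mean, lib_factor)
  mu[cbind(marker_idx, marker_home)] <-
    mu[cbind(marker_idx, marker_home)] * cfg$marker_fold

  counts <- matrix(
    stats::rnbinom(n_g * n_k, mu = as.vector(mu), size = cfg$nb_dispersion),
    nrow = n_g, dimnames = list(genes, clusters)
  )

  n_sc <- cfg$n_superclusters
  supercluster_of <- sort(rep_len(seq_len(n_sc), n_k))
  n_neu_sc <- max(1L, round(cfg$frac_neuronal * n_sc))
  sc_neuronal <- seq_len(n_sc) <= n_neu_sc
  hierarchy <- data.frame(
    cluster = clusters,
    supercluster = sprintf("sc%02d", supercluster_of),
    neuronal = sc_neuronal[supercluster_of],
    stringsAsFactors = FALSE
  )

  n_d <- cfg$n_dissections
  rdirichlet <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(x) == 0) x <- rep(1, length(alpha))
    x / sum(x)
  }
  composition <- matrix(0L, nrow = n_k, ncol = n_d,
                        dimnames = list(clusters,
                                        sprintf("d%02d", seq_len(n_d))))
  neu_k <- hierarchy$neuronal
  cells_per_dissection <- round(stats::runif(n_d, 3000, 6000))
  for (d in seq_len(n_d)) {
    n_cells <- cells_per_dissection[d]
    n_neu <- round(n_cells * 0.65)
    if (any(neu_k)) {
      w <- rdirichlet(rep(cfg$dirichlet_neuronal, sum(neu_k)))
      composition[neu_k, d] <- stats::rmultinom(1, n_neu, w)
    }
    if (any(!neu_k)) {
      w <- rdirichlet(rep(cfg$dirichlet_nonneuronal, sum(!neu_k)))
      composition[!neu_k, d] <- stats::rmultinom(1, n_cells - n_neu, w)
    }
  }

  list(expr = counts, hierarchy = hierarchy, composition = composition,
       truth = list(marker_genes = marker_genes))
}
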