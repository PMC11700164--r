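# Shared desk-scale fixtures, regenerated in code at test time.

tiny_config <- function(...) {
  defaults <- list(seed = 11L, n_genes = 600L, n_clusters = 6L,
                   n_superclusters = 3L, n_dissections = 5L,
                   marker_frac = 0.2, marker_fold = 50, n_snps = 1500L,
                   n_individuals = 400L, n_panel = 200L,
                   ld_block_size = 25L, block_rho = 0.3, h2 = 0.3,
                   enrich_tau = 5, n_rois = 8L, ts_length = 80L,
                   n_cases = 12L, n_controls = 12L,
                   delta_pairs = list(c(1L, 2L, 0.4)))
  args <- list(...)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# A hand-built annotation table for filter tests: every gene expressed,
# coordinates trivial.
toy_annotation <- function(genes, chrom = "chr1", biotype = "protein_coding",
                           emhc = FALSE) {
  n <- length(genes)
  start <- seq(0, by = 10000, length.out = n)
  data.frame(gene = genes, chrom = rep_len(chrom, n), start = start,
             end = start + 5000, strand = "+", tss = start,
             biotype = rep_len(biotype, n), emhc = rep_len(emhc, n),
             stringsAsFactors = FALSE)
}

# Brute-force oracle for SNP membership in gene windows (interval scan).
brute_annotation <- function(genes, annotation, snps, window_kb) {
  ann <- annotation[annotation$gene %in% genes, ]
  w <- window_kb * 1000
  vapply(seq_len(nrow(snps)), function(i) {
    any(ann$chrom == snps$chrom[i] &
          snps$pos[i] >= pmax(ann$start - w, 0) &
          snps$pos[i] < ann$end + w)
  }, logical(1)) * 1L
}

# Exhaustive hypergeometric oracle by enumeration of all draws.
enumerate_hyper_p <- function(overlap, set_size, bg_size, query_size) {
  draws <- utils::combn(bg_size, query_size)
  inset <- colSums(draws <= set_size) # wlog the target is genes 1..set_size
  mean(inset >= overlap)
}
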