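#' Hypergeometric over-representation tests against a fixed background
#'
#' Upper-tail hypergeometric p-value for the overlap of the query with each
#' target set, every set first intersected with the background, followed by
#' BH adjustment across targets.
#'
#' @param query character vector of gene ids (must lie in the background).
#' @param targets named list of character vectors.
#' @param background character vector of background gene ids (nonempty).
#' @return data.frame: `set`, `overlap`, `set_size`, `query_size`,
#'   `background_size`, `p`, `fdr`.
#' @export
hypergeometric_enrichment <- function(query, targets, background) {
  if (length(background) == 0) stop("empty background")
  if (!all(query %in% background)) {
    stop("query genes outside the background: ",
         paste(utils::head(setdiff(query, background), 5), collapse = ", "))
  }
  nb <- length(background)
  nq <- length(query)
  in_query <- background %in% query
  names(in_query) <- background
  set_size <- integer(length(targets))
  overlap <- integer(length(targets))
  for (i in seq_along(targets)) {
    tg <- targets[[i]][targets[[i]] %in% background]
    set_size[i] <- length(tg)
    overlap[i] <- sum(in_query[tg])
  }
  # P(X >= overlap), X ~ Hypergeom(|target| white, nb - |target| black, nq draws)
  p <- stats::phyper(overlap - 1, set_size, nb - set_size, nq,
                     lower.tail = FALSE)
  out <- data.frame(set = names(targets), overlap = overlap,
                    set_size = set_size, query_size = nq,
                    background_size = nb, p = p, stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Tile the genome into fixed-width bins and count TSS per bin
#'
#' Bins start at position 0 on each chromosome; a TSS at position x lands
#' in bin `floor(x / bin_size)` (half-open bins). Counts the background
#' protein-coding TSS per bin (`n_tss`) and, per cell type, the TDEP TSS
#' (`n_tdep_<cell type>`). Only bins spanning the declared chromosome
#' lengths exist; a TSS beyond its chromosome is an error. An optional
#' exclusion mask removes bins (e.g. all-N assembly gaps).
#'
#' @param annotation gene annotation restricted to the background (columns
#'   `gene`, `chrom`, `tss`).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param tdep_sets named list, cell type -> gene ids.
#' @param bin_kb bin width in kb (default 100).
#' @param exclude_bins optional data.frame (`chrom`, `bin`) of bins to drop.
#' @return data.frame: `chrom`, `bin`, `bin_start`, `n_tss`, then one
#'   `n_tdep_*` column per cell type. Bins without any TSS are included.
#' @export
bin_genome <- function(annotation, chrom_lengths, tdep_sets, bin_kb = 100,
                       exclude_bins = NULL) {
  bin_size <- bin_kb * 1000
  if (anyNA(annotation$tss)) stop("TSS required for all background genes")
  over <- annotation$tss >= chrom_lengths[annotation$chrom]
  if (any(over, na.rm = TRUE) || anyNA(over)) {
    stop("TSS beyond declared chromosome length: ",
         paste(utils::head(annotation$gene[which(over | is.na(over))], 5),
               collapse = ", "))
  }
  grid <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_size)
    data.frame(chrom = ch, bin = seq_len(nb) - 1L, stringsAsFactors = FALSE)
  }))
  grid$bin_start <- grid$bin * bin_size
  key <- paste(grid$chrom, grid$bin)

  gene_bin <- paste(annotation$chrom, annotation$tss %/% bin_size)
  grid$n_tss <- as.integer(table(factor(gene_bin, levels = key)))
  for (ct in names(tdep_sets)) {
    sel <- annotation$gene %in% tdep_sets[[ct]]
    grid[[paste0("n_tdep_", ct)]] <-
      as.integer(table(factor(gene_bin[sel], levels = key)))
  }
  if (!is.null(exclude_bins)) {
    drop_key <- paste(exclude_bins$chrom, exclude_bins$bin)
    grid <- grid[!key %in% drop_key, , drop = FALSE]
  }
  rownames(grid) <- NULL
  grid
}

#' Random-placement expectation for the empty-bin fraction
#'
#' Repeatedly drops `n_tss` TSS into `n_bins` bins uniformly with
#' replacement and records the fraction of bins receiving none, giving the
#' null distribution that observed TSS clumping is compared against. The
#' closed-form mean is `(1 - 1/n_bins)^n_tss`.
#'
#' @param n_bins,n_tss counts (> 0 bins; `n_tss = 0` gives fraction 1).
#' @param n_trials Monte Carlo trials (default 1000).
#' @param seed RNG seed.
#' @return list with `fraction` (trial vector), `mean`, and
#'   `expected_closed_form`.
#' @export
random_tss_expectation <- function(n_bins, n_tss, n_trials = 1000,
                                   seed = 1L) {
  stopifnot(n_bins > 0, n_tss >= 0, n_trials > 0)
  set.seed(seed)
  frac <- vapply(seq_len(n_trials), function(i) {
    if (n_tss == 0) return(1)
    hit <- unique(sample.int(n_bins, n_tss, replace = TRUE))
    1 - length(hit) / n_bins
  }, numeric(1))
  list(fraction = frac, mean = mean(frac),
       expected_closed_form = (1 - 1 / n_bins)^n_tss)
}

#' Genomic co-occurrence of TDEP genes beyond baseline gene clumping
#'
#' Restricted to bins containing at least one background TSS, fits one OLS
#' regression of the TDEP TSS count on the total TSS count per cell type,
#' keeps the internally studentized residuals, flags bins whose residual
#' exceeds 3 (far more TDEP TSS than the gene density predicts), and
#' returns the Spearman correlation matrix of the residual vectors across
#' cell types.
#'
#' @param bins output of [bin_genome()].
#' @return list with `residuals` (bins x cell types), `spearman`
#'   (cell types x cell types), `flags` (logical, residual > 3), and
#'   `bins` (the retained bin table).
#' @export
cooccurrence_residuals <- function(bins) {
  keep <- bins$n_tss >= 1
  b <- bins[keep, , drop = FALSE]
  if (length(unique(b$n_tss)) < 2) {
    stop("degenerate regression: n_tss constant across bins")
  }
  ct_cols <- grep("^n_tdep_", names(b), value = TRUE)
  if (!length(ct_cols)) stop("no TDEP count columns in the bin table")
  res <- vapply(ct_cols, function(cc) {
    fit <- stats::lm(b[[cc]] ~ b$n_tss)
    # a perfect fit has no residual scale to studentize against
    if (summary(fit)$sigma < 1e-10) return(numeric(nrow(b)))
    stats::rstandard(fit)
  }, numeric(nrow(b)))
  colnames(res) <- sub("^n_tdep_", "", ct_cols)
  sp <- stats::cor(res, method = "spearman")
  list(residuals = res, spearman = sp, flags = res > 3, bins = b)
}
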