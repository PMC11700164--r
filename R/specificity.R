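#' Normalize a count matrix to transcripts per million
#'
#' Depth-normalizes each cell type (column) so its expression values sum to
#' one million: `tpm[g, c] = counts[g, c] * 1e6 / sum_g counts[g, c]`.
#'
#' @param counts nonnegative genes x cell types matrix with dimnames.
#' @return matrix of the same shape whose columns each sum to 1e6.
#' @export
normalize_tpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- colSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    stop("cell type(s) with zero total count: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Expression proportion per gene across cell types
#'
#' Divides each gene's TPM in a cell type by the gene's summed TPM across
#' all cell types, giving a relative specificity measure in `[0, 1]` that
#' sums to 1 per expressed gene. Genes with zero total expression get 0
#' everywhere (not NaN).
#'
#' @param tpm matrix from [normalize_tpm()].
#' @return matrix of expression proportions, same shape.
#' @export
expression_proportion <- function(tpm) {
  tot <- rowSums(tpm)
  ep <- tpm / ifelse(tot > 0, tot, 1)
  ep[tot == 0, ] <- 0
  ep
}

#' Background gene set for all downstream gene-set mathematics
#'
#' Keeps genes that are protein-coding, autosomal (chr1..chr22), outside the
#' extended MHC, and expressed (> 1 TPM) in at least one cluster-level cell
#' type. Every expression gene must have an annotation record.
#'
#' @param counts genes x clusters count matrix (cluster level).
#' @param annotation data.frame as from [generate_gene_annotation()]
#'   (columns `gene`, `chrom`, `biotype`, `emhc`).
#' @return character vector of retained gene ids, in matrix order.
#' @export
filter_background <- function(counts, annotation) {
  genes <- rownames(counts)
  if (is.null(genes)) stop("counts must have gene rownames")
  missing <- setdiff(genes, annotation$gene)
  if (length(missing)) {
    stop("genes missing from the annotation: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  ann <- annotation[match(genes, annotation$gene), ]
  autosomal <- ann$chrom %in% paste0("chr", 1:22)
  tpm <- normalize_tpm(counts)
  expressed <- rowSums(tpm > 1) >= 1
  keep <- ann$biotype == "protein_coding" & autosomal & !ann$emhc & expressed
  genes[keep]
}

#' Build the per-gene, per-cell-type specificity table
#'
#' Combines TPM, expression proportion, and the TDEP flag into one long
#' table. TDEP selection is delegated to [select_tdep()].
#'
#' @param counts genes x cell types count matrix.
#' @param background character vector of background gene ids.
#' @return list with matrices `tpm`, `ep`, logical `tdep`, and
#'   `tdep_sets` (cell type -> gene id vector).
#' @export
specificity_table <- function(counts, background) {
  tpm <- normalize_tpm(counts)
  ep <- expression_proportion(tpm)
  sel <- select_tdep(tpm, ep, background)
  list(tpm = tpm, ep = ep, tdep = sel$flags, tdep_sets = sel$sets)
}

#' Select top-decile expression proportion (TDEP) genes per cell type
#'
#' For each cell type the decile threshold is the 90th percentile of EP over
#' all background genes (the value of the `ceil(0.1 * n)`-th largest EP);
#' genes at or above the threshold (ties included) that also exceed 1 TPM
#' are TDEP. The TPM filter acts after decile ranking, so TDEP sets can be
#' smaller than the decile cap.
#'
#' @param tpm,ep matrices over the same genes and cell types.
#' @param background character vector of background gene ids (>= 10 genes).
#' @return list with `flags` (background genes x cell types logical matrix)
#'   and `sets` (named list, cell type -> TDEP gene ids).
#' @export
select_tdep <- function(tpm, ep, background) {
  if (length(background) < 10) {
    stop("background must contain at least 10 genes")
  }
  missing <- setdiff(background, rownames(ep))
  if (length(missing)) {
    stop("background genes absent from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  ep_bg <- ep[background, , drop = FALSE]
  tpm_bg <- tpm[background, , drop = FALSE]
  cap <- ceiling(0.1 * length(background))
  flags <- matrix(FALSE, nrow(ep_bg), ncol(ep_bg),
                  dimnames = dimnames(ep_bg))
  for (ct in seq_len(ncol(ep_bg))) {
    thr <- sort(ep_bg[, ct], decreasing = TRUE)[cap]
    flags[, ct] <- ep_bg[, ct] >= thr & tpm_bg[, ct] > 1
  }
  sets <- lapply(seq_len(ncol(flags)), function(ct) {
    rownames(flags)[flags[, ct]]
  })
  names(sets) <- colnames(flags)
  list(flags = flags, sets = sets)
}

#' Aggregate cluster counts to the supercluster level
#'
#' Supercluster specificity is computed on counts summed over the member
#' clusters and then re-normalized, i.e. TPM is applied per cell type at
#' each level of the hierarchy rather than averaging cluster-level EPs.
#'
#' @param counts genes x clusters matrix.
#' @param hierarchy data.frame with `cluster`, `supercluster`.
#' @return genes x superclusters count matrix.
#' @export
aggregate_superclusters <- function(counts, hierarchy) {
  idx <- match(colnames(counts), hierarchy$cluster)
  if (anyNA(idx)) stop("clusters missing from the hierarchy")
  sc <- factor(hierarchy$supercluster[idx])
  agg <- vapply(levels(sc), function(s) {
    rowSums(counts[, sc == s, drop = FALSE])
  }, numeric(nrow(counts)))
  rownames(agg) <- rownames(counts)
  agg
}

#' Pairwise Jaccard indices of gene sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`; two empty sets get 0 by
#' convention, the diagonal is 1.
#'
#' @param sets named list of >= 2 character vectors.
#' @return symmetric matrix of Jaccard indices.
#' @export
jaccard_matrix <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  k <- length(sets)
  jm <- diag(1, k)
  dimnames(jm) <- list(names(sets), names(sets))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      u <- length(union(sets[[a]], sets[[b]]))
      jm[a, b] <- jm[b, a] <-
        if (u == 0) 0 else length(intersect(sets[[a]], sets[[b]])) / u
    }
  }
  jm
}
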