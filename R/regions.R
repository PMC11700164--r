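#' Cluster proportions per anatomical dissection
#'
#' Converts a cluster-by-dissection cell-count table into proportions over
#' the retained clusters (neuronal only, by default, since the cell-type
#' signal for psychiatric traits is neuronal and neuron/glia composition
#' ratios vary by dissection). Dissections with zero retained cells are
#' excluded with a warning. A rank-based decile scaling of the proportions
#' (1-10 over all cluster-dissection entries) is attached for display only;
#' it never enters the weighted Z.
#'
#' @param composition clusters x dissections count matrix.
#' @param hierarchy data.frame with `cluster` and logical `neuronal`.
#' @param neuronal_only keep only neuronal clusters (default TRUE).
#' @param exclude optional character vector of dissection names dropped
#'   before computing proportions (curated exclusions).
#' @return list with `pct` (retained clusters x dissections, columns sum to
#'   1) and `decile` (same shape, integers 1-10).
#' @export
cluster_proportions <- function(composition, hierarchy,
                                neuronal_only = TRUE, exclude = NULL) {
  if (any(composition < 0)) stop("cell counts must be nonnegative")
  if (!is.null(exclude)) {
    composition <- composition[, !colnames(composition) %in% exclude,
                               drop = FALSE]
  }
  idx <- match(rownames(composition), hierarchy$cluster)
  if (anyNA(idx)) stop("cluster(s) missing from the hierarchy")
  keep <- if (neuronal_only) hierarchy$neuronal[idx] else rep(TRUE, nrow(composition))
  m <- composition[keep, , drop = FALSE]
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("excluding dissection(s) with zero retained cells: ",
            paste(colnames(m)[tot == 0], collapse = ", "))
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  pct <- sweep(m, 2, tot, "/")
  decile <- matrix(
    as.integer(cut(rank(pct, ties.method = "average"),
                   breaks = 10, labels = FALSE)),
    nrow(pct), dimnames = dimnames(pct)
  )
  list(pct = pct, decile = decile)
}

#' Composition-weighted regional enrichment
#'
#' Extrapolates cluster-level enrichment Z-scores to dissections as the
#' composition-weighted sum `Z_d = sum_k pct[k, d] * Z_k`, converts it with
#' the upper tail of the standard normal (the convention used for the
#' cluster Z-scores themselves; see the methods vignette for the variance
#' caveat), and BH-adjusts across dissections.
#'
#' @param proportions `pct` matrix from [cluster_proportions()].
#' @param cluster_z named numeric vector of cluster enrichment Z-scores;
#'   every retained cluster must have one.
#' @return data.frame per dissection: `dissection`, `z`, `p`, `fdr`.
#' @export
dissection_enrichment <- function(proportions, cluster_z) {
  pct <- if (is.list(proportions) && !is.null(proportions$pct)) {
    proportions$pct
  } else proportions
  missing <- setdiff(rownames(pct), names(cluster_z))
  if (length(missing)) {
    stop("cluster(s) without a Z-score: ", paste(missing, collapse = ", "))
  }
  zk <- cluster_z[rownames(pct)]
  zd <- drop(crossprod(pct, zk))
  p <- stats::pnorm(zd, lower.tail = FALSE)
  data.frame(dissection = colnames(pct), z = unname(zd), p = unname(p),
             fdr = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
}
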