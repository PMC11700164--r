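#' SNP annotation from gene windows
#'
#' Marks SNP j as a member iff its position falls in
#' `[start - window, end + window)` (0-based half-open, clipped at 0) of any
#' listed gene on the same chromosome.
#'
#' @param genes character vector of gene ids (nonempty).
#' @param annotation gene annotation data.frame (`gene`, `chrom`, `start`,
#'   `end`).
#' @param snps data.frame with `chrom` and `pos` (one row per SNP, in SNP
#'   order).
#' @param window_kb symmetric window in kb added to each gene (default 100).
#' @param name annotation label.
#' @return list with `name` and 0/1 `member` vector over the SNPs.
#' @export
build_annotation <- function(genes, annotation, snps, window_kb = 100,
                             name = "annot") {
  if (length(genes) == 0) stop("empty gene set")
  if (window_kb < 0) stop("window_kb must be >= 0")
  missing <- setdiff(genes, annotation$gene)
  if (length(missing)) {
    stop("genes absent from the annotation: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  ann <- annotation[annotation$gene %in% genes, ]
  w <- window_kb * 1000
  # half-open [start - w, end + w) on the integer line -> 1-based closed
  # [start - w + 1, end + w] for IRanges, query at pos + 1
  subj <- GenomicRanges::GRanges(
    ann$chrom,
    IRanges::IRanges(start = pmax(ann$start - w, 0) + 1, end = ann$end + w)
  )
  qry <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(snps$pos + 1, width = 1))
  member <- as.integer(IRanges::overlapsAny(qry, subj))
  list(name = name, member = member)
}

#' Stratified LD scores from a reference panel
#'
#' For each SNP j and annotation c, sums the bias-adjusted squared
#' correlation `r2 - (1 - r2) / (n - 2)` (floored at 0) over annotated SNPs
#' within `window_snps` index positions of j, including j itself. The
#' window is counted in SNPs because the synthetic maps carry no
#' recombination coordinates.
#'
#' @param panel `n x p` reference genotype matrix, `n >= 3`.
#' @param annotations named list of 0/1 membership vectors of length p
#'   (include a base annotation of all ones for model fitting).
#' @param window_snps one-sided window size in SNP index units.
#' @return list with `scores` (p x annotations matrix), `n_panel`, and
#'   `n_monomorphic` (SNPs with zero panel variance, whose r2 terms were
#'   set to 0 with a warning).
#' @export
compute_ld_scores <- function(panel, annotations, window_snps) {
  n <- nrow(panel)
  p <- ncol(panel)
  if (n < 3) stop("panel sample size must be >= 3")
  stopifnot(is.list(annotations), length(annotations) >= 1)
  amat <- vapply(annotations, function(a) {
    m <- if (is.list(a)) a$member else a
    if (length(m) != p) stop("annotation length must equal SNP count")
    as.numeric(m != 0)
  }, numeric(p))

  sds <- apply(panel, 2, stats::sd)
  mono <- sds == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s): their r2 terms set to 0")
    sds[mono] <- 1
  }
  xs <- scale(panel, center = TRUE, scale = sds)
  xs[, mono] <- 0

  scores <- amat # self term: r2 = 1, adjusted value 1, for polymorphic SNPs
  scores[mono, ] <- 0
  for (d in seq_len(min(window_snps, p - 1))) {
    lo <- seq_len(p - d)
    hi <- lo + d
    r <- colSums(xs[, lo, drop = FALSE] * xs[, hi, drop = FALSE]) / (n - 1)
    r2 <- pmax(r^2 - (1 - r^2) / (n - 2), 0)
    scores[lo, ] <- scores[lo, ] + r2 * amat[hi, , drop = FALSE]
    scores[hi, ] <- scores[hi, ] + r2 * amat[lo, , drop = FALSE]
  }
  colnames(scores) <- names(annotations)
  list(scores = scores, n_panel = n, n_monomorphic = sum(mono))
}

#' Fit the stratified LD score regression for one target annotation
#'
#' Regresses GWAS chi-square statistics on annotation-stratified LD scores:
#' `E[chi2_j] = intercept + N * sum_c tau_c * l(j, c)` with a free
#' intercept, the base annotation always included, weighted least squares
#' with LD weights `1 / max(l_base, 1)` times heteroskedasticity weights
#' from a first-pass fit (two-step, standard LDSC practice). The standard
#' error of the target coefficient comes from a delete-a-block jackknife
#' over contiguous SNP blocks, the one-sided p-value from the upper normal
#' tail of `z = tau / se` (enrichment direction), and the enrichment ratio
#' from the fitted per-annotation heritability shares.
#'
#' @param sumstats data.frame with `z` and `n` per SNP (SNP order must match
#'   the LD score rows).
#' @param ld result of [compute_ld_scores()] (or a bare score matrix).
#' @param annotations the named membership list used for the LD scores
#'   (must contain `base` plus the target and any conditionals).
#' @param target annotation name to test.
#' @param conditional optional character vector of annotation names added to
#'   the model.
#' @param n_blocks jackknife blocks (default 200).
#' @param exclude optional logical/integer vector of SNPs to drop before
#'   fitting (e.g. the extended MHC).
#' @return one-row data.frame: `annotation`, `tau`, `se`, `z`, `p`,
#'   `enrichment`, `prop_snps`, `prop_h2`, `conditioned_on`, `n_snps_fit`.
#' @export
sldsc_fit <- function(sumstats, ld, annotations, target,
                      conditional = NULL, n_blocks = 200, exclude = NULL) {
  scores <- if (is.list(ld) && !is.null(ld$scores)) ld$scores else ld
  stopifnot(nrow(scores) == nrow(sumstats))
  if (!"base" %in% colnames(scores)) stop("LD scores must include 'base'")
  if (!target %in% colnames(scores)) stop("target annotation not in LD scores")
  if (target == "base") stop("target must differ from the base annotation")
  bad_cond <- setdiff(conditional, colnames(scores))
  if (length(bad_cond)) {
    stop("conditional annotation(s) not in LD scores: ",
         paste(bad_cond, collapse = ", "))
  }

  keep <- rep(TRUE, nrow(sumstats))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) keep <- !exclude else keep[exclude] <- FALSE
  }
  chi2 <- sumstats$z[keep]^2
  nn <- sumstats$n[keep]
  sc <- scores[keep, , drop = FALSE]

  use <- unique(c("base", target, conditional))
  # conditionals whose LD scores are identically zero cannot enter the
  # design (all-zero column); dropping them reproduces the unconditional fit
  zero_cols <- use[colSums(abs(sc[, use, drop = FALSE])) == 0]
  if (target %in% zero_cols) stop("target annotation has all-zero LD scores")
  if (length(zero_cols)) {
    warning("dropping all-zero annotation(s): ",
            paste(zero_cols, collapse = ", "))
    use <- setdiff(use, zero_cols)
  }
  x <- cbind(intercept = 1, sc[, use, drop = FALSE] * nn)

  p_fit <- length(chi2)
  if (p_fit < 2 * n_blocks) {
    stop("need at least 2 * n_blocks = ", 2 * n_blocks, " SNPs, have ", p_fit)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("singular design; collinear annotation(s): ",
         paste(dropped, collapse = ", "))
  }

  w1 <- 1 / pmax(sc[, "base"], 1)
  beta1 <- wls_solve(x, chi2, w1)$beta
  fitted1 <- drop(x %*% beta1)
  w2 <- w1 / (2 * pmax(fitted1, 1)^2)

  blocks <- cut(seq_len(p_fit), breaks = n_blocks, labels = FALSE)
  fit <- wls_jackknife(x, chi2, w2, blocks)
  names(fit$beta) <- colnames(x)
  names(fit$se) <- colnames(x)

  tau <- fit$beta[target]
  se <- fit$se[target]
  zsc <- tau / se
  p_one <- stats::pnorm(zsc, lower.tail = FALSE)

  # enrichment ratio: share of fitted h2 in the target vs share of SNPs
  amat <- vapply(use, function(a) {
    m <- annotations[[a]]
    as.numeric((if (is.list(m)) m$member else m) != 0)[keep]
  }, numeric(p_fit))
  h_per_snp <- drop(amat %*% fit$beta[use])
  total_h2 <- sum(h_per_snp)
  in_target <- amat[, target] > 0
  prop_h2 <- if (total_h2 != 0) sum(h_per_snp[in_target]) / total_h2 else NA_real_
  prop_snps <- mean(in_target)
  enrichment <- if (!is.na(prop_h2) && prop_snps > 0) prop_h2 / prop_snps else NA_real_

  data.frame(
    annotation = target, tau = unname(tau), se = unname(se),
    z = unname(zsc), p = unname(p_one), enrichment = enrichment,
    prop_snps = prop_snps, prop_h2 = prop_h2,
    conditioned_on = if (length(setdiff(conditional, zero_cols))) {
      paste(setdiff(conditional, zero_cols), collapse = ",")
    } else NA_character_,
    n_snps_fit = p_fit, stringsAsFactors = FALSE
  )
}

# Weighted least squares via the normal equations on pre-weighted blocks.
wls_solve <- function(x, y, w) {
  xw <- x * w
  a <- crossprod(xw, x)
  b <- crossprod(xw, y)
  list(beta = drop(solve(a, b)), a = a, b = b)
}

# Delete-a-block jackknife for WLS coefficients: accumulate per-block
# normal-equation contributions and re-solve with each block removed.
wls_jackknife <- function(x, y, w, blocks) {
  full <- wls_solve(x, y, w)
  ids <- sort(unique(blocks))
  b <- length(ids)
  k <- ncol(x)
  thetas <- matrix(0, b, k)
  for (i in seq_len(b)) {
    sel <- blocks == ids[i]
    xw <- x[sel, , drop = FALSE] * w[sel]
    a_b <- crossprod(xw, x[sel, , drop = FALSE])
    c_b <- crossprod(xw, y[sel])
    thetas[i, ] <- drop(solve(full$a - a_b, full$b - c_b))
  }
  centred <- sweep(thetas, 2, colMeans(thetas))
  se <- sqrt((b - 1) / b * colSums(centred^2))
  list(beta = full$beta, se = se, jackknife = thetas)
}

#' Benjamini-Hochberg FDR within trait
#'
#' Adjusts the one-sided enrichment p-values for multiple comparisons with
#' the monotone step-up BH procedure, independently within each trait.
#'
#' @param results data.frame with columns `p` and `trait`.
#' @param group_by grouping column name (default `"trait"`).
#' @return `results` with an `fdr` column.
#' @export
fdr_adjust <- function(results, group_by = "trait") {
  stopifnot("p" %in% names(results))
  g <- if (group_by %in% names(results)) results[[group_by]] else rep(1, nrow(results))
  results$fdr <- stats::ave(results$p, g,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  results
}

#' Pairwise conditional enrichment scan
#'
#' For each (target, condition) pair refits the model with the condition's
#' annotation added and reports the target's conditional statistics;
#' `target == condition` pairs are rejected. Self-pairs in a full grid are
#' conventionally shown as the unconditional fit on the diagonal — pass
#' them as `condition = NA`.
#'
#' @param sumstats,ld,annotations as for [sldsc_fit()].
#' @param pairs data.frame (or 2-column matrix) with columns `target` and
#'   `condition` (`NA` condition = unconditional).
#' @param ... passed on to [sldsc_fit()] (e.g. `n_blocks`, `exclude`).
#' @return data.frame of one row per pair.
#' @export
conditional_scan <- function(sumstats, ld, annotations, pairs, ...) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    tg <- pairs$target[i]
    cd <- pairs$condition[i]
    if (!is.na(cd) && identical(tg, cd)) {
      stop("target conditioned on itself: ", tg)
    }
    res <- sldsc_fit(sumstats, ld, annotations, target = tg,
                     conditional = if (is.na(cd)) NULL else cd, ...)
    res$target <- tg
    res$condition <- cd
    res
  })
  do.call(rbind, out)
}
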