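#' Simulate case/control ROI time series
#'
#' Controls draw multivariate normal time series from a base
#' positive-definite covariance; cases draw from the base covariance shifted
#' additively on the configured ROI pairs, projected back to positive
#' definite by eigenvalue clipping. ROIs touched by a planted pair carry the
#' group tag `"limbic"` in the metadata, the rest `"other"`, so downstream
#' top-n enrichment has a flagged set to test.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of the stage seed.
#' @return list with `ts` (list of `ts_length x n_rois` matrices), `labels`
#'   (integer 0 control / 1 case), `roi_meta` (data.frame `roi`, `group`,
#'   `hemisphere`), `cov_control`, `cov_case`, and `truth`
#'   (`differential_pairs` matrix with columns i, j, delta).
#' @export
generate_fmri <- function(cfg, seed = NULL) {
  validate_sim_config(cfg)
  set.seed(if (is.null(seed)) stage_seed(cfg, "fmri") else seed)

  r <- cfg$n_rois
  w <- matrix(stats::rnorm(r * r), r, r)
  s <- tcrossprod(w) / r
  d <- diag(1 / sqrt(diag(s)))
  base <- 0.3 * (d %*% s %*% d) + 0.7 * diag(r) # mild base correlations

  case_cov <- base
  pairs <- do.call(rbind, lapply(cfg$delta_pairs, function(dp) {
    i <- as.integer(dp[1]); j <- as.integer(dp[2]); delta <- dp[3]
    case_cov[i, j] <<- case_cov[i, j] + delta
    case_cov[j, i] <<- case_cov[j, i] + delta
    c(i = i, j = j, delta = delta)
  }))
  case_cov <- psd_project(case_cov)
  if (inherits(try(chol(case_cov), silent = TRUE), "try-error")) {
    stop("case covariance not positive definite after projection")
  }

  n <- cfg$n_cases + cfg$n_controls
  labels <- c(rep(1L, cfg$n_cases), rep(0L, cfg$n_controls))
  ts <- lapply(labels, function(lab) {
    MASS::mvrnorm(cfg$ts_length, rep(0, r),
                  if (lab == 1L) case_cov else base)
  })

  flagged <- sort(unique(c(pairs[, "i"], pairs[, "j"])))
  roi_meta <- data.frame(
    roi = sprintf("ROI%02d", seq_len(r)),
    group = ifelse(seq_len(r) %in% flagged, "limbic", "other"),
    hemisphere = rep_len(c("L", "R"), r),
    stringsAsFactors = FALSE
  )

  list(ts = ts, labels = labels, roi_meta = roi_meta,
       cov_control = base, cov_case = case_cov,
       truth = list(differential_pairs = pairs))
}

# Project a symmetric matrix onto the positive-definite cone by clipping
# eigenvalues at a small floor.
psd_project <- function(m, floor_ev = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor_ev)
  e$vectors %*% (v * t(e$vectors))
}
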