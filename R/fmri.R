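#' Pearson connectivity matrix of an ROI time-series
#'
#' @param ts `time x ROI` matrix with >= 3 time points.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
compute_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points")
  v <- apply(ts, 2, stats::var)
  if (any(v == 0)) {
    nm <- colnames(ts)[v == 0]
    if (is.null(nm)) nm <- which(v == 0)
    stop("zero-variance ROI(s): ", paste(nm, collapse = ", "))
  }
  stats::cor(ts)
}

# Upper-triangle connection order shared by feature vectorization and FI
# matrix reconstruction: (1,2), (1,3), (2,3), (1,4), ...
conn_index <- function(n_roi) {
  m <- matrix(seq_len(n_roi^2), n_roi)
  which(upper.tri(m), arr.ind = TRUE)
}

#' Vectorize per-subject connectivity into a feature matrix
#'
#' @param conn_list list of full `R x R` connectivity matrices, one per
#'   subject.
#' @param rois integer indices of retained ROIs.
#' @return `subjects x choose(|rois|, 2)` matrix of upper-triangle
#'   connections.
#' @export
connectivity_features <- function(conn_list, rois = NULL) {
  if (is.null(rois)) rois <- seq_len(nrow(conn_list[[1]]))
  ut <- upper.tri(matrix(0, length(rois), length(rois)))
  t(vapply(conn_list, function(cm) cm[rois, rois, drop = FALSE][ut],
           numeric(sum(ut))))
}

#' Stratified cross-validation folds balanced by class and series length
#'
#' Splits subjects into `n_folds` near-equal portions with cases and
#' controls balanced within each, stratifying by time-series length: within
#' each class, subjects are ordered by length (random tie-break under the
#' seed) and dealt to folds cyclically, so each portion spans the length
#' distribution. With 46 cases and 46 controls and 5 folds the portion
#' sizes per class are 10, 9, 9, 9, 9.
#'
#' @param labels 0/1 vector.
#' @param ts_lengths numeric vector of time points per subject.
#' @param n_folds number of portions (>= 2).
#' @param seed RNG seed for tie-breaking.
#' @return integer fold assignment per subject.
#' @export
make_folds <- function(labels, ts_lengths, n_folds = 5, seed = 1L) {
  if (n_folds < 2) stop("n_folds must be >= 2 (no held-out data otherwise)")
  stopifnot(length(labels) == length(ts_lengths))
  if (min(table(labels)) < n_folds) {
    stop("each class needs at least n_folds subjects")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    ord <- idx[order(ts_lengths[idx], stats::runif(length(idx)))]
    fold[ord] <- rep_len(seq_len(n_folds), length(ord))
  }
  fold
}

#' Classifier configuration
#'
#' The classification contract is cross-entropy training plus ROC-AUC
#' evaluation; two interchangeable backends satisfy it: a feed-forward
#' neural network (`nnet`, one hidden layer, weight decay) and a
#' ridge-penalized logistic regression (`glmnet`), the latter cheap enough
#' for permutation-heavy simulation studies.
#'
#' @param backend `"mlp"` or `"logistic"`.
#' @param hidden hidden units for the mlp backend.
#' @param decay weight decay for the mlp backend.
#' @param maxit training iterations for the mlp backend.
#' @param lambda ridge penalty for the logistic backend.
#' @return list of class `fmri_config`.
#' @export
fmri_config <- function(backend = c("logistic", "mlp"), hidden = 8,
                        decay = 0.5, maxit = 300, lambda = 0.05) {
  backend <- match.arg(backend)
  structure(list(backend = backend, hidden = hidden, decay = decay,
                 maxit = maxit, lambda = lambda), class = "fmri_config")
}

#' Train the case/control classifier and evaluate it on held-out subjects
#'
#' Standardizes features on training statistics only, trains the configured
#' backend with a cross-entropy objective, and returns the held-out ROC AUC
#' together with the converged cross-entropy `e_orig` on the evaluation
#' split (the reference point of the permutation importance gate).
#'
#' @param train_x,train_y training features and 0/1 labels.
#' @param test_x,test_y evaluation features and labels.
#' @param config an [fmri_config()].
#' @return list with `predict` (closure on raw features), `auc`, `e_orig`,
#'   `prob_test`.
#' @export
train_eval <- function(train_x, train_y, test_x, test_y,
                       config = fmri_config()) {
  mu <- colMeans(train_x)
  sdv <- pmax(apply(train_x, 2, stats::sd), 1e-8)
  std <- function(x) sweep(sweep(x, 2, mu), 2, sdv, "/")
  xs <- std(train_x)

  linear <- NULL
  if (config$backend == "logistic") {
    if (ncol(xs) == 1) {
      # glmnet needs >= 2 columns; a single-feature model is plain logistic
      fit1 <- suppressWarnings(
        stats::glm(train_y ~ xs[, 1], family = stats::binomial())
      )
      b0 <- unname(stats::coef(fit1)[1])
      w <- unname(stats::coef(fit1)[2])
    } else {
      fit <- glmnet::glmnet(xs, factor(train_y, levels = c(0, 1)),
                            family = "binomial", alpha = 0,
                            lambda = config$lambda, standardize = FALSE)
      b0 <- as.numeric(fit$a0)
      w <- as.numeric(fit$beta[, 1])
    }
    # coefficients on the raw feature scale, so permutation importance can
    # update logits incrementally when a single column is shuffled
    w_raw <- w / sdv
    linear <- list(intercept = b0 - sum(w_raw * mu), w = w_raw)
    predict_prob <- function(x) {
      stats::plogis(drop(x %*% linear$w) + linear$intercept)
    }
  } else {
    fit <- nnet::nnet(xs, train_y, size = config$hidden, entropy = TRUE,
                      decay = config$decay, maxit = config$maxit,
                      trace = FALSE, MaxNWts = 100000)
    predict_prob <- function(x) drop(stats::predict(fit, std(x)))
  }

  prob <- predict_prob(test_x)
  e_orig <- cross_entropy(test_y, prob)
  if (!is.finite(e_orig)) stop("non-finite classifier loss")
  auc <- as.numeric(pROC::auc(response = test_y, predictor = prob,
                              levels = c(0, 1), direction = "<",
                              quiet = TRUE))
  list(predict = predict_prob, auc = auc, e_orig = e_orig,
       prob_test = prob, linear = linear)
}

cross_entropy <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Permutation feature importance with a 95% gate
#'
#' Shuffles one connection's values across the subjects of the evaluation
#' split `n_perm` times and recomputes the model's cross-entropy. If the
#' unpermuted error lies outside the central 95% interval of the permuted
#' errors, the connection is considered contributing and its importance is
#' `mean(permuted errors) / e_orig`; otherwise 0. Under a feature that
#' carries no signal the original error is exchangeable with the permuted
#' ones, so the gate passes with probability about 0.05.
#'
#' @param model result of [train_eval()].
#' @param features evaluation-split feature matrix (subjects x connections).
#' @param labels evaluation-split 0/1 labels.
#' @param n_roi number of ROIs the features were vectorized from.
#' @param n_perm permutations per connection (>= 2; default 1000).
#' @param seed RNG seed.
#' @param e_orig original error; defaults to the model's.
#' @return symmetric `n_roi x n_roi` feature-importance matrix, diagonal 0.
#' @export
permutation_fi <- function(model, features, labels, n_roi, n_perm = 1000,
                           seed = 1L, e_orig = model$e_orig) {
  idx <- conn_index(n_roi)
  stopifnot(nrow(idx) == ncol(features))
  fi_vec <- permutation_importance(model, features, labels, n_perm = n_perm,
                                   seed = seed, e_orig = e_orig)
  fi <- matrix(0, n_roi, n_roi)
  fi[idx] <- fi_vec
  fi + t(fi)
}

#' Gated permutation importance per feature
#'
#' The per-feature machinery behind [permutation_fi()], usable on any
#' feature matrix (not only vectorized connectivity): returns one
#' importance value per column, zero where the permutation gate does not
#' pass.
#'
#' @inheritParams permutation_fi
#' @return numeric vector of importances, one per feature column.
#' @export
permutation_importance <- function(model, features, labels, n_perm = 1000,
                                   seed = 1L, e_orig = model$e_orig) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  set.seed(seed)
  n <- nrow(features)
  n_feat <- ncol(features)

  fi_vec <- numeric(n_feat)
  base_logit <- if (!is.null(model$linear)) {
    drop(features %*% model$linear$w) + model$linear$intercept
  }
  for (j in seq_len(n_feat)) {
    errs <- numeric(n_perm)
    if (!is.null(base_logit)) {
      # linear model: shuffling column j only shifts the logit by
      # w_j * (x_perm - x_orig); all permutations evaluated as one matrix
      wj <- model$linear$w[j]
      contrib <- features[, j] * wj
      perms <- vapply(seq_len(n_perm), function(b) sample.int(n),
                      integer(n))
      pr <- stats::plogis((base_logit - contrib) +
                            matrix(contrib[perms], n, n_perm))
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      errs <- -colMeans(labels * log(pr) + (1 - labels) * log(1 - pr))
    } else {
      xp <- features
      for (b in seq_len(n_perm)) {
        xp[, j] <- features[sample.int(n), j]
        errs[b] <- cross_entropy(labels, model$predict(xp))
      }
    }
    ci <- stats::quantile(errs, c(0.025, 0.975), names = FALSE)
    if (e_orig < ci[1] || e_orig > ci[2]) {
      fi_vec[j] <- mean(errs) / e_orig
    }
  }
  fi_vec
}

#' Recursive ROI elimination within one cross-validation fold
#'
#' Alternates training/evaluation, permutation feature importance, and
#' removal of the ROI with the smallest summed importance over its
#' connections (ties broken by the lowest ROI index), until `min_rois`
#' remain. Each run's eliminated ROI, held-out AUC, and full-size FI matrix
#' (zeros on eliminated ROIs) are recorded, along with the number of runs
#' each ROI participated in ("preserved runs").
#'
#' @param conn_list per-subject full connectivity matrices.
#' @param labels 0/1 labels per subject.
#' @param fold_assign integer fold assignment from [make_folds()].
#' @param fold the fold used as the evaluation portion.
#' @param config an [fmri_config()].
#' @param min_rois stop when this many ROIs remain (default 2).
#' @param n_perm permutations per connection.
#' @param seed RNG seed.
#' @return list of class `rfe_trace`: `runs` (list of per-run records),
#'   `preserved` (named counts), `fold`, `n_runs`.
#' @export
rfe <- function(conn_list, labels, fold_assign, fold,
                config = fmri_config(), min_rois = 2, n_perm = 100,
                seed = 1L) {
  n_roi <- nrow(conn_list[[1]])
  if (n_roi < 3) stop("need at least 3 ROIs to start elimination")
  roi_names <- rownames(conn_list[[1]])
  if (is.null(roi_names)) roi_names <- sprintf("ROI%02d", seq_len(n_roi))

  test <- fold_assign == fold
  active <- seq_len(n_roi)
  preserved <- stats::setNames(integer(n_roi), roi_names)
  runs <- list()
  run_id <- 0L

  while (length(active) > min_rois) {
    run_id <- run_id + 1L
    preserved[active] <- preserved[active] + 1L

    feats <- connectivity_features(conn_list, active)
    model <- train_eval(feats[!test, , drop = FALSE], labels[!test],
                        feats[test, , drop = FALSE], labels[test], config)
    fi_sub <- permutation_fi(model, feats[test, , drop = FALSE],
                             labels[test], n_roi = length(active),
                             n_perm = n_perm, seed = seed + run_id)
    contribution <- rowSums(fi_sub)
    drop_local <- which.min(contribution) # ties -> lowest ROI index
    eliminated <- active[drop_local]

    fi_full <- matrix(0, n_roi, n_roi,
                      dimnames = list(roi_names, roi_names))
    fi_full[active, active] <- fi_sub
    runs[[run_id]] <- list(run = run_id, eliminated = roi_names[eliminated],
                           auc = model$auc, fi = fi_full,
                           active = roi_names[active])
    active <- setdiff(active, eliminated)
  }
  structure(list(runs = runs, preserved = preserved, fold = fold,
                 n_runs = run_id), class = "rfe_trace")
}

#' Aggregate feature-importance matrices across models
#'
#' Scales each run's FI matrix by its own maximum, weights it by the run's
#' held-out AUC, and sums elementwise across all selected runs of all
#' traces. Runs whose FI matrix is identically zero are skipped with a
#' warning.
#'
#' @param traces list of `rfe_trace` objects.
#' @param run_selector optional predicate `function(run)` choosing which
#'   runs enter the aggregate (default: all).
#' @return aggregated FI matrix.
#' @export
aggregate_fi <- function(traces, run_selector = NULL) {
  runs <- unlist(lapply(traces, `[[`, "runs"), recursive = FALSE)
  if (!is.null(run_selector)) runs <- Filter(run_selector, runs)
  if (!length(runs)) stop("no runs to aggregate")
  agg <- NULL
  skipped <- 0L
  for (r in runs) {
    m <- max(r$fi)
    if (m == 0) { skipped <- skipped + 1L; next }
    scaled <- r$fi / m * r$auc
    agg <- if (is.null(agg)) scaled else agg + scaled
  }
  if (skipped > 0) warning(skipped, " all-zero FI matrix/matrices skipped")
  if (is.null(agg)) stop("every FI matrix was zero")
  agg
}

#' Top-n enrichment of flagged-ROI connections
#'
#' Ranks all `R^2` matrix entries by aggregated importance (diagonal 0 and
#' both symmetric copies included; ties broken by linear index) and, for
#' each n in the grid, tests whether connections touching a flagged ROI are
#' over-represented among the top n with an upper-tail hypergeometric test.
#' The default grid is the even numbers 2..R^2 (2888 tests for R = 76).
#'
#' @param agg aggregated FI matrix.
#' @param flagged_rois character or integer set of flagged ROIs (nonempty).
#' @param n_grid vector of n values (default even numbers up to R^2).
#' @return data.frame `n`, `overlap`, `p`.
#' @export
topn_enrichment <- function(agg, flagged_rois, n_grid = NULL) {
  r <- nrow(agg)
  if (length(flagged_rois) == 0) stop("flagged_rois must be nonempty")
  roi_names <- rownames(agg)
  flagged_idx <- if (is.character(flagged_rois)) {
    match(flagged_rois, roi_names)
  } else as.integer(flagged_rois)
  if (anyNA(flagged_idx)) stop("unknown flagged ROI(s)")

  if (is.null(n_grid)) n_grid <- seq(2L, r^2, by = 2L)
  fi_vec <- as.vector(agg)
  pair_i <- rep(seq_len(r), times = r)
  pair_j <- rep(seq_len(r), each = r)
  is_flagged <- pair_i %in% flagged_idx | pair_j %in% flagged_idx
  ord <- order(-fi_vec, seq_along(fi_vec))
  cum_flagged <- cumsum(is_flagged[ord])

  n_pop <- r^2
  n_white <- sum(is_flagged)
  ov <- cum_flagged[n_grid]
  p <- stats::phyper(ov - 1, n_white, n_pop - n_white, n_grid,
                     lower.tail = FALSE)
  data.frame(n = n_grid, overlap = ov, p = p)
}

#' Correlation of preserved-run counts between two datasets
#'
#' Pearson product-moment correlation of mean preserved-run counts across
#' the shared ROI universe, optionally restricted to a subset (for example
#' the amygdalar/hippocampal regions).
#'
#' @param preserved_a,preserved_b named numeric vectors over the same ROIs
#'   (e.g. means over folds of `rfe_trace$preserved`).
#' @param roi_subset optional ROI names to restrict to (>= 3).
#' @return list with `r` and two-sided `p`.
#' @export
preserved_run_correlation <- function(preserved_a, preserved_b,
                                      roi_subset = NULL) {
  common <- intersect(names(preserved_a), names(preserved_b))
  if (!is.null(roi_subset)) common <- intersect(common, roi_subset)
  if (length(common) < 3) stop("need at least 3 ROIs for the correlation")
  ct <- stats::cor.test(preserved_a[common], preserved_b[common],
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_roi = length(common))
}
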