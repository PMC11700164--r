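test_that("connectivity matrices follow the Pearson contract", {
  set.seed(10)
  ts <- matrix(rnorm(600), 100, 6)
  cm <- compute_connectivity(ts)
  expect_equal(diag(cm), rep(1, 6))
  expect_equal(cm, t(cm))
  expect_true(all(eigen(cm, only.values = TRUE)$values > -1e-10))

  # duplicated ROI -> off-diagonal 1; anti-correlated pair -> -1
  ts2 <- cbind(ts[, 1], ts[, 1], -ts[, 1])
  cm2 <- compute_connectivity(ts2)
  expect_equal(cm2[1, 2], 1)
  expect_equal(cm2[1, 3], -1)

  # independent long series: |r| below 3/sqrt(T)
  set.seed(11)
  ts3 <- matrix(rnorm(4000 * 4), 4000, 4)
  cm3 <- compute_connectivity(ts3)
  expect_true(all(abs(cm3[upper.tri(cm3)]) < 3 / sqrt(4000)))

  ts_bad <- ts
  ts_bad[, 2] <- 5
  colnames(ts_bad) <- paste0("R", 1:6)
  expect_error(compute_connectivity(ts_bad), "R2")
  expect_error(compute_connectivity(ts[1:2, ]), "3 time points")
})

test_that("folds are class-balanced, length-stratified, and sized as published", {
  labels <- rep(c(1, 0), each = 46)
  lens <- rep(seq(120, 210, length.out = 46), 2)
  f <- make_folds(labels, lens, n_folds = 5, seed = 2)
  per_class <- table(f[labels == 1])
  expect_equal(sort(as.integer(per_class), decreasing = TRUE),
               c(10, 9, 9, 9, 9))
  expect_equal(sort(as.integer(table(f[labels == 0])), decreasing = TRUE),
               c(10, 9, 9, 9, 9))
  # stratification: mean series length similar across folds
  mu <- tapply(lens, f, mean)
  expect_lt(max(mu) - min(mu), 10)
  expect_identical(f, make_folds(labels, lens, 5, seed = 2))
  expect_error(make_folds(labels, lens, n_folds = 1), "n_folds")
  expect_error(make_folds(c(rep(1, 3), rep(0, 20)), rep(100, 23), 5),
               "class")
})

test_that("the classifier separates a linearly separable toy perfectly", {
  x <- matrix(c(seq(-2, -0.5, length.out = 10),
                seq(0.5, 2, length.out = 10)), ncol = 1)
  y <- rep(c(0, 1), each = 10)
  m <- train_eval(x, y, x, y, fmri_config("logistic", lambda = 1e-4))
  expect_equal(m$auc, 1)
  m2 <- train_eval(x, y, x, y, fmri_config("mlp", hidden = 2, decay = 1e-3))
  expect_equal(m2$auc, 1)
})

test_that("shuffled labels give chance AUC", {
  set.seed(12)
  aucs <- replicate(10, {
    x <- matrix(rnorm(60 * 10), 60)
    y <- sample(rep(0:1, 30))
    xt <- matrix(rnorm(40 * 10), 40)
    yt <- rep(0:1, 20)
    train_eval(x, y, xt, yt, fmri_config("logistic"))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("permutation importance reproduces the error-ratio formula", {
  set.seed(13)
  n <- 40
  x <- cbind(sig = rep(c(-1, 1), each = n / 2) + rnorm(n, 0, 0.3),
             noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rep(0:1, each = n / 2)
  m <- train_eval(x, y, x, y, fmri_config("logistic", lambda = 1e-3))
  fi <- permutation_importance(m, x, y, n_perm = 200, seed = 14)

  # independent oracle for the signal feature with the same RNG stream
  set.seed(14)
  errs <- replicate(200, {
    xp <- x
    xp[, 1] <- x[sample.int(n), 1]
    p <- m$predict(xp)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  })
  expect_equal(fi[1], mean(errs) / m$e_orig, tolerance = 1e-12)
  expect_gt(fi[1], 1) # shuffling a real signal inflates the error
})

test_that("linear fast path and generic path agree", {
  set.seed(15)
  n <- 30
  x <- matrix(rnorm(n * 4), n)
  y <- rep(0:1, each = n / 2)
  m <- train_eval(x, y, x, y, fmri_config("logistic"))
  fi_fast <- permutation_importance(m, x, y, n_perm = 50, seed = 16)
  m_slow <- m
  m_slow$linear <- NULL # force the generic predict route
  fi_slow <- permutation_importance(m_slow, x, y, n_perm = 50, seed = 16)
  expect_equal(fi_fast, fi_slow, tolerance = 1e-10)
})

test_that("rfe eliminates noise ROIs first and counts runs correctly", {
  cfg <- tiny_config(n_rois = 8L, delta_pairs = list(c(1L, 2L, 0.5)),
                     n_cases = 20L, n_controls = 20L, ts_length = 120L)
  fm <- generate_fmri(cfg)
  conn <- lapply(fm$ts, compute_connectivity)
  folds <- make_folds(fm$labels, vapply(fm$ts, nrow, 1L), 4, seed = 3)
  tr <- rfe(conn, fm$labels, folds, 1, fmri_config("logistic"),
            min_rois = 2, n_perm = 60, seed = 17)
  expect_equal(tr$n_runs, 6) # 8 ROIs down to 2
  expect_true(all(vapply(tr$runs, function(r) length(r$eliminated), 1L) == 1))
  expect_true(all(tr$preserved <= tr$n_runs))
  # the planted ROIs survive the longest
  expect_setequal(names(sort(tr$preserved, decreasing = TRUE))[1:2],
                  c("ROI01", "ROI02"))

  # 3 ROIs with min_rois = 2: exactly one elimination run
  conn3 <- lapply(conn, function(cm) cm[1:3, 1:3])
  tr3 <- rfe(conn3, fm$labels, folds, 1, fmri_config("logistic"),
             min_rois = 2, n_perm = 30, seed = 18)
  expect_equal(tr3$n_runs, 1)
  expect_error(rfe(lapply(conn, function(cm) cm[1:2, 1:2]), fm$labels,
                   folds, 1), "3 ROIs")
})

test_that("FI aggregation scales by max, weights by AUC, and is additive", {
  fi <- matrix(0, 4, 4)
  fi[1, 2] <- fi[2, 1] <- 4
  fi[3, 4] <- fi[4, 3] <- 1
  run <- list(run = 1, eliminated = "x", auc = 0.5, fi = fi)
  tr <- structure(list(runs = list(run)), class = "rfe_trace")
  agg1 <- aggregate_fi(list(tr))
  expect_equal(agg1[1, 2], 0.5)       # 4/4 * 0.5
  expect_equal(agg1[3, 4], 0.125)     # 1/4 * 0.5 = FI/8
  # two identical models double the aggregate; order does not matter
  agg2 <- aggregate_fi(list(tr, tr))
  expect_equal(agg2, 2 * agg1)
  zero_run <- list(run = 2, eliminated = "y", auc = 0.9,
                   fi = matrix(0, 4, 4))
  trz <- structure(list(runs = list(run, zero_run)), class = "rfe_trace")
  expect_warning(aggz <- aggregate_fi(list(trz)), "all-zero")
  expect_equal(aggz, agg1)
})

test_that("top-n enrichment enumerates R^2 entries and flags endpoints", {
  set.seed(19)
  r <- 20
  agg <- matrix(0, r, r, dimnames = list(sprintf("R%02d", 1:r),
                                         sprintf("R%02d", 1:r)))
  v <- runif(choose(r, 2))
  agg[upper.tri(agg)] <- v
  agg <- agg + t(agg)
  agg[1, 2] <- agg[2, 1] <- 2 # planted top connection

  res <- topn_enrichment(agg, flagged_rois = c("R01", "R02"))
  expect_equal(nrow(res), r^2 / 2)
  expect_lt(res$p[1], 0.05) # the top-2 entries are the planted pair
  expect_equal(res$overlap[1], 2)

  all_fl <- topn_enrichment(agg, flagged_rois = sprintf("R%02d", 1:r))
  expect_equal(all_fl$p, rep(1, nrow(all_fl)))
  expect_error(topn_enrichment(agg, character(0)), "nonempty")
})

test_that("preserved-run correlation behaves at the identities", {
  a <- setNames(as.numeric(1:10), paste0("R", 1:10))
  expect_equal(preserved_run_correlation(a, a)$r, 1)
  expect_equal(preserved_run_correlation(a, max(a) + min(a) - a)$r, -1)
  set.seed(20)
  b <- setNames(rnorm(10), names(a))
  out <- preserved_run_correlation(a, b, roi_subset = paste0("R", 1:5))
  expect_equal(out$n_roi, 5)
  expect_error(preserved_run_correlation(a, b, roi_subset = paste0("R", 1:2)),
               "3 ROIs")
})
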