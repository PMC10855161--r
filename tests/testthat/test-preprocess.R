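test_that("filter_low_signal drops zero-mean and low-variance features", {
  set.seed(2)
  v <- matrix(rnorm(50 * 100, mean = 2), 50, 100)
  v[, 1:5] <- 0                       # no signal (mean exactly 0)
  v[, 6:10] <- 3                      # constant non-zero (SD = 0)
  X <- omics_matrix(v, omics_name = "mrna")
  out <- filter_low_signal(X, sd_threshold = 0)
  expect_equal(ncol(out$values), 90)
  expect_false(any(feature_names(out) %in% feature_names(X)[1:10]))
  # threshold is inclusive: SD <= threshold goes
  v2 <- cbind(v[, 11:100], rnorm(50, mean = 1, sd = 0.01))
  colnames(v2) <- c(sprintf("g%02d", 1:90), "small")
  out2 <- filter_low_signal(omics_matrix(v2), sd_threshold = 0.1)
  expect_false("small" %in% feature_names(out2))
  expect_error(filter_low_signal(omics_matrix(matrix(0, 5, 3))), "every feature")
})

test_that("anova_preselect keeps top-F features with deterministic ties", {
  X <- tiny_omics(n = 60, d = 10, seed = 4)
  y <- rep(1:2, each = 30)
  # identical class distributions, k = d: everything kept in input order
  all_kept <- anova_preselect(X, y, k = 10)
  expect_identical(feature_names(all_kept), feature_names(X))
  expect_error(anova_preselect(X, y, k = 0), "k must lie")
  expect_error(anova_preselect(X, y, k = 11), "k must lie")
  expect_error(anova_preselect(X, rep(1, 60), k = 2), "2 classes")
  # F statistics agree with stats::oneway.test
  f_ours <- trustfuse:::anova_f_stats(X$values, y)
  f_ref <- apply(X$values, 2, function(col)
    oneway.test(col ~ factor(y), var.equal = TRUE)$statistic)
  expect_equal(unname(f_ours), unname(f_ref), tolerance = 1e-10)
})

test_that("anova_preselect recovers planted features", {
  hits <- vapply(1:20, function(s) {
    sp <- sim_spec(n_subjects = 300, n_classes = 3,
                   n_features = c(a = 50), module_sizes = list(rep(10, 5)),
                   informative_fraction = 0.1, effect_size = 1.5, seed = s)
    co <- generate_cohort(sp)
    sel <- anova_preselect(co$omics$a, co$labels, k = 5)
    planted <- feature_names(co$omics$a)[informative_features(sp)$a]
    all(feature_names(sel) %in% planted)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pca_variance_check flags a dominant direction and passes isotropy", {
  set.seed(9)
  iso <- omics_matrix(matrix(rnorm(500 * 50), 500, 50))
  res <- pca_variance_check(iso)
  expect_true(res$pass)
  expect_lt(res$fraction, 0.1)
  dup <- matrix(rnorm(100), 100, 1)[, rep(1, 50)] +
    matrix(rnorm(100 * 50, sd = 0.01), 100, 50)
  res2 <- pca_variance_check(omics_matrix(dup))
  expect_false(res2$pass)
  expect_gt(res2$fraction, 0.5)
  expect_error(pca_variance_check(omics_matrix(matrix(rnorm(10), 10, 1))),
               "2 features")
})

test_that("minmax_scale maps the fit range to [0,1] and reuses the transform", {
  X <- omics_matrix(cbind(a = c(2, 4, 6), b = c(1, 1, 2)),
                    subject_ids = c("s1", "s2", "s3"))
  sc <- minmax_scale(X)
  expect_equal(unname(sc$x$values[, "a"]), c(0, 0.5, 1))
  # constant feature maps to 0 with a warning
  Xc <- omics_matrix(cbind(a = c(2, 4, 6), flat = c(5, 5, 5)))
  expect_warning(scc <- minmax_scale(Xc), "constant")
  expect_true(all(scc$x$values[, "flat"] == 0))
  # held-out values above the training max exceed 1 and are preserved
  Xtr <- omics_matrix(cbind(a = c(0, 1, 2, 10)),
                      subject_ids = paste0("s", 1:4))
  fit <- minmax_scale(Xtr, fit_ids = c("s1", "s2", "s3"))
  expect_gt(fit$x$values["s4", "a"], 1)
  held <- apply_scaler(fit$scaler, Xtr)
  expect_identical(held$values, fit$x$values)
})

test_that("the chain fits on training subjects only and is idempotent", {
  sp <- sim_spec(n_subjects = 80, n_classes = 2,
                 n_features = c(a = 30), module_sizes = list(rep(10, 3)),
                 seed = 11)
  co <- generate_cohort(sp)
  ids <- names(co$labels)
  train <- ids[1:56]
  pp <- preprocess_omics(co$omics$a, co$labels, k = 20, train_ids = train)
  expect_true(all(diff(pp$report$retained) <= 0))
  # scaled training subjects span exactly [0, 1]
  tr <- pp$x$values[train, ]
  expect_equal(unname(apply(tr, 2, min)), rep(0, ncol(tr)))
  expect_equal(unname(apply(tr, 2, max)), rep(1, ncol(tr)))
  # perturbing test subjects does not change fitted outputs on train rows
  raw2 <- co$omics$a
  raw2$values[setdiff(ids, train), ] <- raw2$values[setdiff(ids, train), ] + 5
  pp2 <- preprocess_omics(raw2, co$labels, k = 20, train_ids = train)
  expect_identical(pp$x$values[train, ], pp2$x$values[train, ])
  # idempotent on its own output (same feature set, scaling a no-op)
  pp3 <- preprocess_omics(pp$x, co$labels, k = 20, train_ids = train)
  expect_equal(pp3$x$values, pp$x$values, tolerance = 1e-12)
})
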