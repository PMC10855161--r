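#' Drop no-signal and low-variance features
#'
#' Removes features whose raw mean is exactly zero (no signal) and features
#' whose standard deviation is at or below \code{sd_threshold}. Conventional
#' per-omics thresholds: 0.1 for mRNA expression, 0.001 for DNA methylation
#' beta values, 0 for miRNA.
#'
#' @param X An \code{omics_matrix} (raw, unscaled).
#' @param sd_threshold Non-negative SD cutoff; features with SD <= threshold
#'   are dropped.
#' @return The filtered \code{omics_matrix}.
#' @export
filter_low_signal <- function(X, sd_threshold = 0) {
  stopifnot(inherits(X, "omics_matrix"))
  if (ncol(X$values) == 0) stop("filter_low_signal: empty omics matrix")
  if (sd_threshold < 0) stop("sd_threshold must be non-negative")
  mu <- colMeans(X$values)
  sdv <- apply(X$values, 2, stats::sd)
  keep <- (mu != 0) & (sdv > sd_threshold)
  if (!any(keep))
    stop(sprintf("filter_low_signal removed every feature of '%s'",
                 X$omics_name))
  subset_omics(X, features = which(keep))
}

# internal: vectorized one-way ANOVA F statistics, one per feature column.
# Equivalent to stats::oneway.test(var.equal = TRUE) per column (checked in
# the test suite) but computed in closed form for the whole matrix at once.
anova_f_stats <- function(values, labels) {
  labels <- as.factor(labels)
  K <- nlevels(labels)
  n <- nrow(values)
  if (K < 2) stop("ANOVA preselection needs at least 2 classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 subjects")
  G <- stats::model.matrix(~ labels - 1)          # n x K indicator
  ng <- colSums(G)
  group_means <- (t(G) %*% values) / ng           # K x d
  grand <- colMeans(values)
  ssb <- colSums(ng * (sweep(group_means, 2, grand))^2)
  sst <- colSums(sweep(values, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (K - 1)) / (ssw / (n - K))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- 0
  f
}

#' Preselect features by one-way ANOVA F statistic
#'
#' Keeps the \code{k} features with the largest one-way ANOVA F statistic for
#' the class labels, computed on the supplied (training) subjects only. Ties
#' are broken by original column order so the selection is deterministic.
#'
#' @param X An \code{omics_matrix}.
#' @param labels Class labels aligned with the rows of \code{X} (or named by
#'   subject ID).
#' @param k Number of features to keep (1 <= k <= ncol).
#' @return The \code{omics_matrix} restricted to the selected features, in
#'   their original order.
#' @export
anova_preselect <- function(X, labels, k) {
  stopifnot(inherits(X, "omics_matrix"))
  d <- ncol(X$values)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > d)
    stop(sprintf("k must lie in 1..%d", d))
  labels <- align_labels(labels, subject_ids(X))
  f <- anova_f_stats(X$values, labels)
  ord <- order(-f, seq_len(d))        # descending F, ties by input order
  keep <- sort(ord[seq_len(k)])
  subset_omics(X, features = keep)
}

#' First-principal-component variance check
#'
#' Diagnostic gate on feature redundancy: computes the fraction of total
#' variance carried by the first principal component of the standardized
#' matrix and passes when that fraction is below \code{limit} (default 0.5),
#' i.e. when no single direction dominates the retained features. The input
#' is never modified.
#'
#' @param X An \code{omics_matrix} with >= 2 features and >= 2 subjects.
#' @param limit Pass threshold on the first-PC variance fraction.
#' @return List with \code{pass} (logical) and \code{fraction} (numeric).
#' @export
pca_variance_check <- function(X, limit = 0.5) {
  stopifnot(inherits(X, "omics_matrix"))
  v <- X$values
  if (ncol(v) < 2) stop("pca_variance_check needs at least 2 features")
  if (nrow(v) < 2) stop("pca_variance_check needs at least 2 subjects")
  sdv <- apply(v, 2, stats::sd)
  if (all(sdv == 0)) stop("pca_variance_check: zero total variance")
  if (any(sdv == 0))
    stop("pca_variance_check: zero-variance feature; run filter_low_signal first")
  pc <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  fraction <- pc$sdev[1]^2 / sum(pc$sdev^2)
  list(pass = fraction < limit, fraction = fraction)
}

#' Fit and apply per-feature min-max scaling
#'
#' Linearly maps every feature to [0, 1] using minima and maxima estimated on
#' the fitting subjects only (the training split); the fitted transform is
#' then applied to all subjects, so held-out values may fall outside [0, 1].
#' A feature constant on the fitting subjects is mapped to 0 with a warning.
#'
#' @param X An \code{omics_matrix}.
#' @param fit_ids Subject IDs used to estimate minima/maxima; default all.
#' @return List with the scaled \code{omics_matrix} (\code{x}) and the fitted
#'   \code{scaler} (reusable via [apply_scaler()]).
#' @export
minmax_scale <- function(X, fit_ids = subject_ids(X)) {
  stopifnot(inherits(X, "omics_matrix"))
  fit_ids <- intersect(fit_ids, subject_ids(X))
  if (length(fit_ids) == 0) stop("minmax_scale: no fitting subjects")
  vfit <- X$values[fit_ids, , drop = FALSE]
  mins <- apply(vfit, 2, min)
  maxs <- apply(vfit, 2, max)
  rng <- maxs - mins
  if (any(rng == 0)) {
    warning(sprintf("minmax_scale: %d constant feature(s) in '%s' mapped to 0",
                    sum(rng == 0), X$omics_name))
  }
  scaler <- structure(list(mins = mins, rng = rng,
                           feature_names = feature_names(X),
                           omics_name = X$omics_name),
                      class = "minmax_scaler")
  list(x = apply_scaler(scaler, X), scaler = scaler)
}

#' Apply a fitted min-max scaler to new subjects
#' @param scaler A \code{minmax_scaler} from [minmax_scale()].
#' @param X An \code{omics_matrix} with the scaler's features.
#' @return The scaled \code{omics_matrix}.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmax_scaler"), inherits(X, "omics_matrix"))
  if (!identical(feature_names(X), scaler$feature_names))
    X <- subset_omics(X, features = scaler$feature_names)
  v <- sweep(X$values, 2, scaler$mins, "-")
  safe_rng <- ifelse(scaler$rng == 0, 1, scaler$rng)
  v <- sweep(v, 2, safe_rng, "/")
  v[, scaler$rng == 0] <- 0
  omics_matrix(v, omics_name = X$omics_name)
}

#' Run the full preprocessing chain on one omics block
#'
#' Chains [filter_low_signal()], [anova_preselect()], [pca_variance_check()]
#' and [minmax_scale()], fitting every statistic (SDs, F values, PCA,
#' minima/maxima) on the training subjects only and applying the fitted
#' transforms to all subjects. The PCA criterion is a diagnostic gate:
#' \code{on_pca_fail = "warn"} (default) records the failure, \code{"reduce_k"}
#' shrinks the ANOVA selection by 10\% steps until the gate passes, and
#' \code{"abort"} raises an error.
#'
#' @param X Raw \code{omics_matrix}.
#' @param labels Class labels (named by subject ID or aligned with rows).
#' @param k Number of features to keep at the ANOVA stage; capped at the
#'   post-filter feature count.
#' @param train_ids Subject IDs of the training split; default all subjects.
#' @param sd_threshold SD cutoff for [filter_low_signal()].
#' @param pca_limit First-PC variance-fraction limit.
#' @param on_pca_fail One of \code{"warn"}, \code{"reduce_k"}, \code{"abort"}.
#' @return List with \code{x} (processed \code{omics_matrix}, all subjects),
#'   \code{scaler}, and \code{report} (per-stage retained counts, SD
#'   threshold, k used, first-PC fraction, PCA pass flag).
#' @export
preprocess_omics <- function(X, labels, k, train_ids = subject_ids(X),
                             sd_threshold = 0, pca_limit = 0.5,
                             on_pca_fail = c("warn", "reduce_k", "abort")) {
  on_pca_fail <- match.arg(on_pca_fail)
  stopifnot(inherits(X, "omics_matrix"))
  labels <- align_labels(labels, subject_ids(X))
  train_ids <- intersect(train_ids, subject_ids(X))
  d0 <- ncol(X$values)
  Xtr <- subset_omics(X, subjects = train_ids)
  ytr <- labels[train_ids]

  filt_tr <- filter_low_signal(Xtr, sd_threshold)
  X <- subset_omics(X, features = feature_names(filt_tr))
  d1 <- ncol(X$values)

  k <- min(k, d1)
  repeat {
    sel_tr <- anova_preselect(subset_omics(X, subjects = train_ids), ytr, k)
    pca <- pca_variance_check(sel_tr, pca_limit)
    if (pca$pass || on_pca_fail != "reduce_k") break
    k_new <- max(2L, floor(k * 0.9))
    if (k_new == k) break
    k <- k_new
  }
  if (!pca$pass) {
    msg <- sprintf(
      "first PC of '%s' carries %.1f%% of variance (limit %.0f%%)",
      X$omics_name, 100 * pca$fraction, 100 * pca_limit)
    if (on_pca_fail == "abort") stop(msg) else warning(msg)
  }
  X <- subset_omics(X, features = feature_names(sel_tr))
  d2 <- ncol(X$values)

  sc <- minmax_scale(subset_omics(X, subjects = train_ids))
  Xs <- apply_scaler(sc$scaler, X)
  report <- list(
    omics_name = X$omics_name,
    retained = c(input = d0, low_signal_filter = d1, anova = d2,
                 scaled = d2),
    sd_threshold = sd_threshold, k = k,
    first_pc_fraction = pca$fraction, pca_pass = pca$pass)
  list(x = Xs, scaler = sc$scaler, report = report)
}

# internal: reorder labels to a subject-ID order, with sanity checks
align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels)))
      stop("labels are missing some subject IDs")
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels length does not match subject count")
  }
  stats::setNames(labels, ids)
}
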