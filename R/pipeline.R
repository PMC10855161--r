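#' Stratified train/validation/test split
#'
#' @param labels Class labels (named by subject ID if available).
#' @param fractions Named fractions summing to 1.
#' @param seed Integer seed.
#' @return List of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
split_subjects <- function(labels, fractions = c(train = 0.7, val = 0.15,
                                                 test = 0.15), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(seed)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in unique(labels)) {
    members <- sample(which(labels == cl))
    n <- length(members)
    n_tr <- round(fractions[["train"]] * n)
    n_va <- round(fractions[["val"]] * n)
    idx$train <- c(idx$train, members[seq_len(n_tr)])
    idx$val <- c(idx$val, members[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, members[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  lapply(idx, sort)
}

# internal: multi-class F1 family from labels
f1_family <- function(truth, pred, class_levels) {
  f1 <- prec <- rec <- numeric(length(class_levels))
  support <- numeric(length(class_levels))
  for (i in seq_along(class_levels)) {
    cl <- class_levels[i]
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    support[i] <- sum(truth == cl)
  }
  list(per_class = f1, macro = mean(f1),
       weighted = sum(f1 * support) / sum(support))
}

#' Classification metrics for a set of predictions
#'
#' Binary tasks report ACC, F1 (of the positive class, taken as the larger
#' class level) and AUC of the positive-class probability; multi-class tasks
#' report ACC, weighted-average F1 and macro-average F1.
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param prob Optional n x K probability matrix (needed for AUC).
#' @param class_levels Class dictionary; defaults to sorted unique truth.
#' @return Named list of metrics in [0, 1]; AUC is \code{NA} when undefined
#'   (single-class truth or missing probabilities).
#' @export
evaluate_predictions <- function(truth, pred, prob = NULL,
                                 class_levels = sort(unique(truth))) {
  acc <- mean(pred == truth)
  K <- length(class_levels)
  f1s <- f1_family(truth, pred, class_levels)
  if (K == 2) {
    auc <- NA_real_
    if (!is.null(prob) && length(unique(truth)) == 2) {
      pos <- class_levels[2]
      score <- prob[, 2]
      # rank-based AUC (Mann-Whitney)
      r <- rank(score)
      n1 <- sum(truth == pos)
      n0 <- sum(truth != pos)
      auc <- (sum(r[truth == pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    list(acc = acc, f1 = f1s$per_class[2], auc = auc,
         f1_weighted = f1s$weighted, f1_macro = f1s$macro)
  } else {
    list(acc = acc, f1_weighted = f1s$weighted, f1_macro = f1s$macro)
  }
}

#' Evaluate a fitted model on a test set
#'
#' @param model Fitted \code{trustfuse_model}.
#' @param omics Named list of processed test \code{omics_matrix} objects.
#' @param labels True labels of the test subjects.
#' @return Metric list from [evaluate_predictions()].
#' @export
evaluate_model <- function(model, omics, labels) {
  if (!isTRUE(model$fitted)) stop("model is not fitted")
  pred <- predict_subjects(model, omics)
  evaluate_predictions(labels, pred$label, pred$probabilities,
                       model$class_levels)
}

#' Fit the full pipeline on a cohort
#'
#' Splits subjects (stratified), runs the preprocessing chain per omics
#' block (filters, ANOVA preselection, PCA gate, [0,1] scaling — every
#' statistic fitted on the training split only), builds the co-expression
#' network per block on training subjects, and trains the evidential model
#' with early stopping on validation accuracy.
#'
#' @param omics Named list of raw \code{omics_matrix} objects.
#' @param labels Class labels (aligned with subjects).
#' @param k ANOVA preselection size per omics (scalar or vector); defaults
#'   to all post-filter features.
#' @param sd_threshold Per-omics SD filter cutoffs (scalar or vector).
#' @param beta,threshold Network construction controls (see
#'   [build_network()]).
#' @param fractions Split fractions.
#' @param seed Seed for split and training.
#' @param ... Passed to [train_model()].
#' @return List with \code{model}, \code{split}, processed matrices
#'   (\code{omics_all}, covering all subjects), \code{labels},
#'   \code{networks}, \code{reports}, \code{metrics} (test metrics).
#' @export
fit_pipeline <- function(omics, labels, k = Inf, sd_threshold = 0,
                         beta = 6, threshold = 0.08,
                         fractions = c(train = 0.7, val = 0.15, test = 0.15),
                         seed = 1, ...) {
  M <- length(omics)
  k <- rep_len(k, M)
  sd_threshold <- rep_len(sd_threshold, M)
  labels <- align_labels(labels, subject_ids(omics[[1]]))
  split <- split_subjects(labels, fractions, seed)
  ids <- subject_ids(omics[[1]])
  train_ids <- ids[split$train]

  processed <- vector("list", M)
  reports <- vector("list", M)
  networks <- vector("list", M)
  for (m in seq_len(M)) {
    pp <- preprocess_omics(omics[[m]], labels, k = min(k[m], 1e9),
                           train_ids = train_ids,
                           sd_threshold = sd_threshold[m])
    processed[[m]] <- pp$x
    reports[[m]] <- pp$report
    networks[[m]] <- build_network(
      subset_omics(pp$x, subjects = train_ids), beta = beta,
      threshold = threshold)
  }
  names(processed) <- names(networks) <- names(omics)

  take <- function(idx) lapply(processed, function(X)
    subset_omics(X, subjects = ids[idx]))
  model <- train_model(take(split$train), labels[split$train], networks,
                       val_omics = take(split$val),
                       val_labels = labels[split$val],
                       seed = seed, ...)
  metrics <- evaluate_model(model, take(split$test), labels[split$test])
  list(model = model, split = split, omics_all = processed, labels = labels,
       networks = networks, reports = reports, metrics = metrics,
       take = take)
}

#' Masking-robustness protocol
#'
#' For each masked ratio, suppresses a random subset of one modality's test
#' features (via [mask_modality()]), re-runs inference, and reports the
#' accuracy-reduction ratio \code{(acc_full - acc_masked) / acc_full}
#' together with the masked modality's mean subjective-logic uncertainty,
#' averaged over mask draws.
#'
#' @param model Fitted model.
#' @param omics Processed test \code{omics_matrix} list.
#' @param labels Test labels.
#' @param mask_omics Name or index of the modality to mask.
#' @param ratios Masked ratios in [0, 1].
#' @param seeds Seeds for the random column draws (one inference per seed and
#'   ratio; results are averaged).
#' @return Data frame with columns \code{ratio}, \code{acc},
#'   \code{reduction}, \code{mean_u_masked}, \code{mean_u_fused}.
#' @export
robustness_curve <- function(model, omics, labels, mask_omics = 1,
                             ratios = c(0, 0.2, 0.4, 0.6, 0.8),
                             seeds = 1:3) {
  if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0, 1]")
  if (is.character(mask_omics)) mask_omics <- match(mask_omics, names(omics))
  base <- predict_subjects(model, omics)
  acc_full <- mean(base$label == labels)
  rows <- lapply(ratios, function(r) {
    accs <- us <- uf <- numeric(length(seeds))
    for (si in seq_along(seeds)) {
      om <- omics
      om[[mask_omics]] <- mask_modality(om[[mask_omics]], r, seed = seeds[si])
      pr <- predict_subjects(model, om)
      accs[si] <- mean(pr$label == labels)
      us[si] <- mean(pr$per_omics[[mask_omics]]$u)
      uf[si] <- mean(pr$fused$u)
    }
    data.frame(ratio = r, acc = mean(accs),
               reduction = (acc_full - mean(accs)) / acc_full,
               mean_u_masked = mean(us), mean_u_fused = mean(uf))
  })
  do.call(rbind, rows)
}

#' Run a configured end-to-end experiment
#'
#' Generates (or loads) a cohort, fits the pipeline, evaluates the test
#' split, optionally runs the robustness protocol and feature-ablation
#' importance, and archives everything under \code{out_dir}: `metrics.json`,
#' `training_log.csv`, `uncertainty.json`, and optionally `robustness.tsv`
#' and `importance.tsv`, plus a copy of the configuration. Reruns of the
#' same configuration reproduce the metrics bit for bit.
#'
#' @param config Named list; recognized fields: \code{spec} (a [sim_spec()];
#'   or supply \code{omics} + \code{labels}), \code{seeds} (one experiment
#'   per seed; mean and SD are reported), pipeline controls (\code{k},
#'   \code{beta}, \code{threshold}, \code{fractions}) and any
#'   [train_model()] argument, \code{robustness} (list with
#'   \code{mask_omics}, \code{ratios}, \code{seeds}), \code{importance}
#'   (logical).
#' @param out_dir Output directory (created); \code{NULL} skips writing.
#' @return List with per-seed results and aggregate metrics, invisibly when
#'   writing.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  seeds <- config$seeds %||% 1
  pipe_args <- config[intersect(names(config),
                                c("k", "sd_threshold", "beta", "threshold",
                                  "fractions"))]
  train_args <- config[intersect(names(config), setdiff(
    names(formals(train_model)),
    c("omics", "labels", "networks", "val_omics", "val_labels", "seed")))]
  runs <- lapply(seeds, function(sd) {
    cohort <- if (!is.null(config$spec)) {
      sp <- config$spec; sp$seed <- sp$seed + sd
      generate_cohort(sp)
    } else list(omics = config$omics, labels = config$labels)
    om <- cohort$omics
    if (!is.null(config$omics_subset)) om <- om[config$omics_subset]
    fit <- do.call(fit_pipeline, c(
      list(omics = om, labels = cohort$labels, seed = sd), pipe_args,
      train_args))
    out <- list(seed = sd, fit = fit, metrics = fit$metrics)
    ids <- subject_ids(om[[1]])
    test_om <- fit$take(fit$split$test)
    test_y <- fit$labels[fit$split$test]
    if (!is.null(config$robustness)) {
      rb <- config$robustness
      out$robustness <- robustness_curve(
        fit$model, test_om, test_y,
        mask_omics = rb$mask_omics %||% 1,
        ratios = rb$ratios %||% c(0, 0.2, 0.4, 0.6, 0.8),
        seeds = rb$seeds %||% 1:3)
    }
    if (isTRUE(config$importance))
      out$importance <- feature_importance(fit$model, test_om, test_y)
    out
  })
  metric_names <- names(runs[[1]]$metrics)
  tab <- sapply(metric_names, function(mn)
    vapply(runs, function(r) r$metrics[[mn]] %||% NA_real_, numeric(1)))
  tab <- rbind(tab)
  agg <- list(mean = apply(tab, 2, mean), sd = apply(tab, 2, stats::sd))
  result <- list(runs = runs, metrics_per_seed = tab, aggregate = agg,
                 seeds = seeds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(per_seed = as.data.frame(tab), mean = agg$mean, sd = agg$sd),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(runs[[1]]$fit$model$history,
                     file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
    last <- runs[[length(runs)]]
    test_om <- last$fit$take(last$fit$split$test)
    pr <- predict_subjects(last$fit$model, test_om)
    jsonlite::write_json(
      list(fused_u = pr$fused$u, conflict = pr$fused$conflict,
           per_omics_u = lapply(pr$per_omics, `[[`, "u")),
      file.path(out_dir, "uncertainty.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(last$robustness))
      utils::write.table(last$robustness,
                         file.path(out_dir, "robustness.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    if (!is.null(last$importance))
      utils::write.table(last$importance,
                         file.path(out_dir, "importance.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    save_model(last$fit$model, file.path(out_dir, "checkpoint.rds"))
    cfg_copy <- config[setdiff(names(config), c("omics", "labels"))]
    cfg_copy$spec <- unclass(cfg_copy$spec)
    jsonlite::write_json(cfg_copy, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(result))
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
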