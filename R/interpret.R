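#' Feature-ablation importance
#'
#' Global interpretation by ablation: each feature of each omics block is
#' suppressed in turn (its scaled value set to 0 across all test subjects;
#' the graph topology is untouched), inference is re-run with the fitted
#' model, and the importance is the signed drop in the reference metric —
#' F1 for binary tasks, macro-averaged F1 for multi-class. The model is
#' never refit. Equal drops share a rank.
#'
#' @param model Fitted \code{trustfuse_model}.
#' @param omics Named list of processed test \code{omics_matrix} objects.
#' @param labels Test labels.
#' @param metric \code{"auto"} (F1 if binary, F1-macro otherwise),
#'   \code{"f1"}, \code{"f1_macro"} or \code{"acc"}.
#' @return An \code{importance_table} data frame with columns
#'   \code{omics_name}, \code{feature_name}, \code{importance} (metric
#'   drop), \code{rank} (ties share the min rank).
#' @export
feature_importance <- function(model, omics, labels,
                               metric = c("auto", "f1", "f1_macro", "acc")) {
  metric <- match.arg(metric)
  if (!isTRUE(model$fitted)) stop("feature_importance needs a fitted model")
  if (metric == "auto") metric <- if (model$K == 2) "f1" else "f1_macro"
  score <- function(om) {
    pred <- predict_subjects(model, om)
    ev <- evaluate_predictions(labels, pred$label, pred$probabilities,
                               model$class_levels)
    ev[[metric]]
  }
  base <- score(omics)
  rows <- list()
  for (m in seq_along(omics)) {
    X <- omics[[m]]
    for (j in seq_len(ncol(X$values))) {
      om <- omics
      v <- X$values
      v[, j] <- 0
      om[[m]] <- omics_matrix(v, omics_name = X$omics_name)
      rows[[length(rows) + 1]] <- data.frame(
        omics_name = X$omics_name,
        feature_name = feature_names(X)[j],
        importance = base - score(om))
    }
  }
  tab <- do.call(rbind, rows)
  tab$rank <- rank(-tab$importance, ties.method = "min")
  attr(tab, "baseline") <- base
  attr(tab, "metric") <- metric
  class(tab) <- c("importance_table", class(tab))
  tab
}

#' Report the top-ranked biomarkers
#'
#' Returns the features occupying the top \code{k} distinct ranks of an
#' importance table. If a tie group straddles the reporting boundary, a
#' random subset of the tied group is drawn (reproducibly, with
#' \code{seed}) to fill the remaining slots — mirroring the convention of
#' reporting a fixed number of top biomarkers when ranks tie.
#'
#' @param table An \code{importance_table} from [feature_importance()].
#' @param k Number of distinct ranks to report (default 5).
#' @param seed Seed for down-sampling oversized tie groups.
#' @param per_omics Report the top k within each omics block separately?
#' @return Data frame of reported rows (subset of \code{table}), ordered by
#'   rank.
#' @export
top_k_report <- function(table, k = 5, seed = 1, per_omics = FALSE) {
  if (k < 1) stop("k must be >= 1")
  pick <- function(tab) {
    tab <- tab[order(tab$rank, tab$omics_name, tab$feature_name), ]
    ranks <- sort(unique(tab$rank))[seq_len(min(k, length(unique(tab$rank))))]
    kept <- tab[tab$rank %in% ranks, ]
    # cap the report at k rows: down-sample the last (tied) group if needed
    if (nrow(kept) > k) {
      last_rank <- max(kept$rank)
      head_rows <- kept[kept$rank < last_rank, ]
      tied <- kept[kept$rank == last_rank, ]
      room <- k - nrow(head_rows)
      set.seed(seed)
      tied <- tied[sort(sample(nrow(tied), room)), ]
      kept <- rbind(head_rows, tied)
    }
    kept
  }
  if (per_omics) {
    out <- do.call(rbind, lapply(split(table, table$omics_name), pick))
    rownames(out) <- NULL
    out
  } else {
    out <- pick(table)
    rownames(out) <- NULL
    out
  }
}
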