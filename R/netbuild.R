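#' Signed weighted co-expression adjacency
#'
#' Computes the cohort-level soft adjacency between features,
#' \eqn{A_{ij} = ((1 + r_{ij}) / 2)^\beta}, where \eqn{r_{ij}} is the Pearson
#' correlation of features i and j across the (training) subjects — the
#' signed WGCNA adjacency with soft-thresholding power \eqn{\beta}. The
#' diagonal is set to 1.
#'
#' @param X An \code{omics_matrix} of training subjects (n >= 3).
#' @param beta Soft-thresholding power (> 0).
#' @return A d x d numeric adjacency matrix with entries in [0, 1].
#' @export
compute_adjacency <- function(X, beta) {
  stopifnot(inherits(X, "omics_matrix"))
  if (nrow(X$values) < 3) stop("compute_adjacency needs at least 3 subjects")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be positive")
  sdv <- apply(X$values, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance feature(s); run filter_low_signal before network construction")
  r <- stats::cor(X$values)
  A <- ((1 + r) / 2)^beta
  diag(A) <- 1
  A
}

# internal: scale-free topology fit index R^2 of a soft adjacency, following
# the standard WGCNA recipe — bin the connectivity k_i, regress log10
# frequency on log10 mean connectivity per bin.
scale_free_fit <- function(A, n_breaks = 10) {
  k <- colSums(A) - 1   # soft connectivity, excluding the self term
  if (max(k) - min(k) < .Machine$double.eps^0.5) return(0)
  bins <- cut(k, breaks = n_breaks)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  ok <- !is.na(dk) & dk > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  summary(fit)$r.squared
}

#' Select the soft-thresholding power
#'
#' Standard WGCNA-style pick: returns the smallest candidate \eqn{\beta} whose
#' soft-connectivity distribution reaches a scale-free topology fit
#' \eqn{R^2 \ge} \code{fit_target}; if none does, returns the candidate with
#' the largest fit and warns.
#'
#' @param X An \code{omics_matrix} of training subjects.
#' @param candidates Candidate powers (default 1..12).
#' @param fit_target Required scale-free fit R^2 (default 0.8).
#' @return The selected power (numeric scalar).
#' @export
select_beta <- function(X, candidates = 1:12, fit_target = 0.8) {
  if (length(candidates) == 0) stop("candidates must be non-empty")
  fits <- vapply(candidates, function(b) scale_free_fit(compute_adjacency(X, b)),
                 numeric(1))
  hit <- which(fits >= fit_target)
  if (length(hit) > 0) return(candidates[hit[1]])
  warning(sprintf(
    "no candidate beta reached scale-free fit R^2 >= %.2f; using beta = %g (R^2 = %.2f)",
    fit_target, candidates[which.max(fits)], max(fits)))
  candidates[which.max(fits)]
}

#' Binarize a soft adjacency into an edge matrix
#'
#' \eqn{E_{ij} = 1} iff \eqn{A_{ij} \ge} \code{threshold} and \eqn{i \ne j};
#' the result is symmetric with a zero diagonal.
#'
#' @param A Soft adjacency matrix in [0, 1].
#' @param threshold Edge threshold in (0, 1).
#' @return Binary (0/1) edge matrix.
#' @export
binarize <- function(A, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  E <- (A >= threshold) * 1
  diag(E) <- 0
  E
}

#' Grid search for the binarization threshold
#'
#' Evaluates a criterion over a grid of candidate thresholds (conventional
#' range 0.05 to 0.5) and returns the argmax; ties go to the smallest
#' threshold. Two criteria are built in: \code{"density"} scores a candidate
#' by closeness of the resulting edge density to a target band (1 inside the
#' band, minus the distance to it outside), which is cheap and
#' training-free; alternatively pass a function \code{f(threshold, E) ->
#' score} (e.g. downstream validation accuracy).
#'
#' @param A Soft adjacency matrix.
#' @param grid Candidate thresholds in (0, 1); default
#'   \code{seq(0.05, 0.5, by = 0.05)}.
#' @param criterion \code{"density"} or a scoring function.
#' @param density_band Target edge-density interval for the built-in
#'   criterion.
#' @return The selected threshold.
#' @export
threshold_grid_search <- function(A, grid = seq(0.05, 0.5, by = 0.05),
                                  criterion = "density",
                                  density_band = c(0.05, 0.3)) {
  if (length(grid) == 0 || any(grid <= 0 | grid >= 1))
    stop("grid must be non-empty within (0, 1)")
  score_fn <- if (is.function(criterion)) {
    criterion
  } else if (identical(criterion, "density")) {
    function(thr, E) {
      d <- nrow(E)
      dens <- sum(E) / (d * (d - 1))
      if (dens >= density_band[1] && dens <= density_band[2]) 1
      else 1 - min(abs(dens - density_band), na.rm = TRUE) -
        abs(dens - mean(density_band)) * 1e-6   # deterministic tie-break
    }
  } else stop("criterion must be 'density' or a function")
  grid <- sort(grid)
  scores <- vapply(grid, function(thr) score_fn(thr, binarize(A, thr)),
                   numeric(1))
  grid[which.max(scores)]   # which.max takes the first (smallest) on ties
}

#' Build a cohort-level co-expression network
#'
#' Convenience wrapper: computes the signed adjacency on training subjects,
#' optionally selects \eqn{\beta} and/or the binarization threshold, and
#' packages the result. The edge set is fitted on training subjects only and
#' then frozen for held-out subjects.
#'
#' @param X An \code{omics_matrix} of training subjects.
#' @param beta Soft power, or \code{"auto"} for [select_beta()].
#' @param threshold Edge threshold in (0, 1) (conventional default 0.08), or
#'   \code{"auto"} for [threshold_grid_search()].
#' @param ... Passed on to [select_beta()] / [threshold_grid_search()].
#' @return An object of class \code{coexpression_network} with fields
#'   \code{adjacency}, \code{edges}, \code{beta}, \code{threshold},
#'   \code{feature_names}, \code{omics_name}.
#' @export
build_network <- function(X, beta = "auto", threshold = 0.08, ...) {
  if (identical(beta, "auto")) beta <- select_beta(X, ...)
  A <- compute_adjacency(X, beta)
  if (identical(threshold, "auto")) threshold <- threshold_grid_search(A, ...)
  E <- binarize(A, threshold)
  structure(list(adjacency = A, edges = E, beta = beta, threshold = threshold,
                 feature_names = feature_names(X), omics_name = X$omics_name),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  d <- nrow(x$edges)
  cat(sprintf(
    "<coexpression_network '%s': %d nodes, %d edges, beta=%g, threshold=%g>\n",
    x$omics_name, d, sum(x$edges) / 2, x$beta, x$threshold))
  invisible(x)
}

#' Assemble per-subject graphs
#'
#' One graph per subject: all subjects share the cohort-level edge matrix,
#' and node i of a subject's graph carries that subject's value for feature
#' i as its (scalar) node feature.
#'
#' @param X An \code{omics_matrix} (any subjects; typically scaled).
#' @param network A \code{coexpression_network} or a binary edge matrix whose
#'   dimension matches the feature count.
#' @return List of \code{subject_graph} objects (fields \code{subject_id},
#'   \code{node_features}, \code{edges}).
#' @export
build_subject_graphs <- function(X, network) {
  stopifnot(inherits(X, "omics_matrix"))
  E <- if (inherits(network, "coexpression_network")) network$edges else network
  if (ncol(X$values) != nrow(E))
    stop("feature count does not match the network dimension")
  ids <- subject_ids(X)
  lapply(seq_along(ids), function(s) {
    structure(list(subject_id = ids[s],
                   node_features = X$values[s, ],
                   edges = E),
              class = "subject_graph")
  })
}

# internal: directed edge index (messages j -> i) with self-loops added,
# shared by every subject of an omics block. Columns: i (target), j (source).
edge_index <- function(E, add_self_loops = TRUE) {
  d <- nrow(E)
  idx <- which(E != 0, arr.ind = TRUE)
  ei <- idx[, 1]; ej <- idx[, 2]
  if (add_self_loops) {
    ei <- c(ei, seq_len(d)); ej <- c(ej, seq_len(d))
  }
  ord <- order(ei, ej)
  list(i = ei[ord], j = ej[ord], d = d, n_edges = length(ei))
}
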