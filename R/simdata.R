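#' Specify a synthetic multi-omics cohort
#'
#' Defines the generative model used by [generate_cohort()]: per omics block,
#' features are drawn as block-correlated Gaussians (an equicorrelated factor
#' model within each module, independence across modules), and a subset of
#' "informative" features receives a class-conditional mean shift. The block
#' correlation makes thresholded co-expression graphs non-trivial; the mean
#' shifts plant a recoverable class signal. Defaults emulate a three-block
#' cohort (mRNA-, methylation- and miRNA-like) with three balanced classes.
#'
#' Informative features are the leading features of each block (so they fall
#' inside the leading correlated modules) and are assigned a favoured class
#' cyclically over \code{informative_classes}: a feature favouring class k is
#' shifted upward by \code{effect_size * noise_sd} in subjects of class k.
#' Restricting \code{informative_classes} for an omics makes that omics
#' informative only about the listed classes, which is how complementary
#' modalities are simulated.
#'
#' @param n_subjects Number of subjects.
#' @param n_classes Number of classes K (>= 2); labels are balanced up to the
#'   remainder.
#' @param n_features Named integer vector, features per omics block.
#' @param module_sizes List (one element per omics) of integer partitions of
#'   the block's feature count into correlated modules; default splits each
#'   block into modules of 10.
#' @param within_module_rho Pairwise correlation inside a module, in [0, 1).
#' @param informative_fraction Fraction of each block's features that carry a
#'   class signal; scalar or one value per omics.
#' @param effect_size Class mean shift in units of \code{noise_sd} (>= 0).
#' @param noise_sd Residual standard deviation (> 0).
#' @param informative_classes Optional list (per omics) of class indices the
#'   block can discriminate; default all classes for every block.
#' @param seed Integer seed; each omics block uses an independent substream
#'   derived from it, so adding a block never perturbs earlier ones.
#' @return An object of class \code{sim_spec}.
#' @export
sim_spec <- function(n_subjects = 300,
                     n_classes = 3,
                     n_features = c(mrna = 50, methylation = 50, mirna = 50),
                     module_sizes = NULL,
                     within_module_rho = 0.6,
                     informative_fraction = 0.1,
                     effect_size = 1.5,
                     noise_sd = 1,
                     informative_classes = NULL,
                     seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (n_classes < 2) stop("n_classes must be at least 2")
  n_features <- unlist(n_features)              # tolerate YAML/list input
  if (!is.null(module_sizes)) module_sizes <- lapply(module_sizes, unlist)
  informative_fraction <- unlist(informative_fraction)
  if (is.null(names(n_features)))
    names(n_features) <- paste0("omics", seq_along(n_features))
  M <- length(n_features)
  if (is.null(module_sizes)) {
    module_sizes <- lapply(n_features, function(d) {
      k <- max(1L, d %/% 10L)
      sizes <- rep(d %/% k, k)
      if ((rem <- d - sum(sizes)) > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
      sizes
    })
  }
  if (length(module_sizes) != M) stop("module_sizes must have one entry per omics")
  for (m in seq_len(M)) {
    if (sum(module_sizes[[m]]) != n_features[m])
      stop(sprintf("module_sizes for '%s' must sum to %d", names(n_features)[m],
                   n_features[m]))
    if (any(module_sizes[[m]] < 1)) stop("module sizes must be positive")
  }
  if (within_module_rho < 0 || within_module_rho >= 1)
    stop("within_module_rho must lie in [0, 1)")
  informative_fraction <- rep_len(informative_fraction, M)
  if (any(informative_fraction < 0 | informative_fraction > 1))
    stop("informative_fraction must lie in [0, 1]")
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(informative_classes))
    informative_classes <- rep(list(seq_len(n_classes)), M)
  if (length(informative_classes) != M)
    stop("informative_classes must have one entry per omics")
  for (cl in informative_classes)
    if (length(cl) && any(cl < 1 | cl > n_classes))
      stop("informative_classes indices must lie in 1..n_classes")
  structure(list(
    n_subjects = as.integer(n_subjects), n_classes = as.integer(n_classes),
    n_features = n_features, module_sizes = module_sizes,
    within_module_rho = within_module_rho,
    informative_fraction = informative_fraction,
    effect_size = effect_size, noise_sd = noise_sd,
    informative_classes = informative_classes,
    seed = as.integer(seed)), class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec: %d subjects, %d classes, omics [%s], seed %d>\n",
              x$n_subjects, x$n_classes,
              paste(sprintf("%s:%d", names(x$n_features), x$n_features),
                    collapse = ", "), x$seed))
  invisible(x)
}

#' Indices of planted informative features
#'
#' @param spec A \code{sim_spec}.
#' @return Named list, one integer vector per omics block, giving the columns
#'   that carry a planted class signal.
#' @export
informative_features <- function(spec) {
  out <- lapply(seq_along(spec$n_features), function(m) {
    q <- round(spec$informative_fraction[m] * spec$n_features[m])
    seq_len(q)
  })
  names(out) <- names(spec$n_features)
  out
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws the cohort described by a [sim_spec()]: balanced integer labels and
#' one [omics_matrix()] per block. Regeneration from the same spec is
#' bit-identical.
#'
#' @param spec A \code{sim_spec}.
#' @return List with elements \code{omics} (named list of \code{omics_matrix})
#'   and \code{labels} (named integer vector in 1..K).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_subjects
  K <- spec$n_classes
  ids <- sprintf("S%04d", seq_len(n))
  labels <- ((seq_len(n) - 1L) %% K) + 1L
  names(labels) <- ids
  rho <- spec$within_module_rho
  omics <- vector("list", length(spec$n_features))
  names(omics) <- names(spec$n_features)
  for (m in seq_along(omics)) {
    d <- spec$n_features[m]
    set.seed(spec$seed + 7919L * m)   # independent substream per block
    X <- matrix(0, n, d)
    col <- 0L
    for (size in spec$module_sizes[[m]]) {
      f <- rnorm(n)                   # shared module factor
      E <- matrix(rnorm(n * size), n, size)
      X[, col + seq_len(size)] <- sqrt(rho) * f + sqrt(1 - rho) * E
      col <- col + size
    }
    X <- X * spec$noise_sd
    q <- round(spec$informative_fraction[m] * d)
    classes <- spec$informative_classes[[m]]
    if (q > 0 && length(classes) > 0 && spec$effect_size > 0) {
      for (j in seq_len(q)) {
        fav <- classes[((j - 1L) %% length(classes)) + 1L]
        X[labels == fav, j] <- X[labels == fav, j] +
          spec$effect_size * spec$noise_sd
      }
    }
    rownames(X) <- ids
    colnames(X) <- sprintf("%s_f%03d", names(omics)[m], seq_len(d))
    omics[[m]] <- omics_matrix(X, omics_name = names(omics)[m])
  }
  list(omics = omics, labels = labels)
}

#' Mask a fraction of a modality's features
#'
#' Replaces a uniformly random subset of \code{floor(ratio * d)} feature
#' columns by the masking value (default 0, the scaled minimum after [0, 1]
#' scaling, i.e. "signal removed"). Used by the robustness protocol to make a
#' modality increasingly uninformative at inference time.
#'
#' @param X An \code{omics_matrix}.
#' @param ratio Fraction of columns to mask, in [0, 1].
#' @param seed Integer seed for the column draw.
#' @param mask_value Value written into masked columns.
#' @return The masked \code{omics_matrix}; an attribute
#'   \code{"masked_features"} records the masked column names.
#' @export
mask_modality <- function(X, ratio, seed = 1, mask_value = 0) {
  stopifnot(inherits(X, "omics_matrix"))
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio < 0 || ratio > 1)
    stop("ratio must be a single value in [0, 1]")
  d <- ncol(X$values)
  n_mask <- floor(ratio * d)
  v <- X$values
  masked <- integer(0)
  if (n_mask > 0) {
    set.seed(seed)
    masked <- sort(sample.int(d, n_mask))
    v[, masked] <- mask_value
  }
  out <- omics_matrix(v, omics_name = X$omics_name)
  attr(out, "masked_features") <- colnames(v)[masked]
  out
}
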