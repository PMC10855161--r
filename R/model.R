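# Multi-omics evidential model: one GAT encoder per omics block, subjective-
# logic opinions, Dempster-Shafer fusion, and the global evidential loss.
# Training is plain Adam over hand-derived analytic gradients; the gradient
# path runs through the fusion rule itself (vector-Jacobian products of the
# pairwise combination), so the fused loss trains every encoder jointly.

# Forward over all omics for a batch. Xs: list of nb x d_m matrices.
model_forward <- function(Xs, model, keep_cache = FALSE,
                          dropout_masks = NULL) {
  M <- length(Xs)
  enc <- vector("list", M)
  for (m in seq_len(M)) {
    enc[[m]] <- encoder_forward(Xs[[m]], model$edges[[m]], model$params[[m]],
                                model$ops[[m]], keep_cache = keep_cache,
                                dropout_mask = dropout_masks[[m]])
  }
  Es <- lapply(enc, `[[`, "e")
  ops <- lapply(Es, opinion_from_evidence_batch)
  bs <- lapply(ops, `[[`, "b")
  us <- lapply(ops, `[[`, "u")
  fused <- ds_fuse_batch(bs, us)
  K <- model$K
  S_f <- K / fused$u
  e_fused <- fused$b * S_f
  list(enc = enc, Es = Es, bs = bs, us = us, fused = fused,
       e_fused = e_fused, alpha_fused = e_fused + 1,
       prob = fused$b + fused$u / K)    # fused Dirichlet mean
}

# Loss + full parameter gradients for one batch.
model_loss_grads <- function(fw, Xs, model, labels, lambda_t, gamma) {
  M <- length(Xs)
  K <- model$K
  n <- length(labels)
  Y <- one_hot(labels, K)

  alpha_per <- lapply(fw$Es, function(E) E + 1)
  logits_per <- lapply(fw$enc, `[[`, "gat_logits")
  breakdown <- global_loss(fw$alpha_fused, alpha_per, logits_per, labels,
                           lambda_t, gamma)

  # fused branch: dL/d alpha_F -> (b, u) of the fused opinion
  dalpha_F <- sample_loss_grad_batch(fw$alpha_fused, Y, lambda_t)
  u_f <- fw$fused$u
  S_f <- K / u_f
  db_f <- dalpha_F * S_f
  du_f <- -rowSums(dalpha_F * fw$fused$b) * K / u_f^2
  vj <- ds_fuse_vjp(fw$bs, fw$us, fw$fused, db_f, du_f)

  grads <- vector("list", M)
  for (m in seq_len(M)) {
    dE <- opinion_from_evidence_vjp(fw$Es[[m]], vj$dbs[[m]], vj$dus[[m]])
    dE <- dE + sample_loss_grad_batch(alpha_per[[m]], Y, lambda_t)
    sce <- softmax_ce_batch(logits_per[[m]], Y)
    dlogits <- gamma * sce$grad / n
    grads[[m]] <- encoder_backward(fw$enc[[m]]$cache, model$edges[[m]],
                                   model$params[[m]], model$ops[[m]],
                                   dE, dlogits)
  }
  names(grads) <- names(model$params)
  list(breakdown = breakdown, grads = grads)
}

# ---- flat parameter utilities (for Adam and for gradient checks) ----------

flatten_params <- function(p) {
  acc <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in seq_along(x)) {
        label <- if (!is.null(names(x)) && nzchar(names(x)[nm]))
          names(x)[nm] else as.character(nm)
        if (label == "cfg") next
        walk(x[[nm]], c(path, label))
      }
    } else {
      acc[[paste(path, collapse = "/")]] <<- x
    }
  }
  walk(p, character(0))
  acc
}

assign_flat <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, "/", fixed = TRUE)[[1]]
    p[[path]] <- flat[[key]]
  }
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0)
}

adam_step <- function(flat, gflat, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat)) {
    g <- gflat[[k]]
    if (weight_decay > 0 && grepl("(^|/)W$", k))
      g <- g + weight_decay * flat[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    flat[[k]] <- flat[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

# ---- model constructor ----------------------------------------------------

# Assemble an untrained model from processed omics blocks and their
# co-expression networks. Labels define the class dictionary.
init_model <- function(omics, networks, class_levels,
                       n_heads = 4, hidden = 8, evidence_hidden = 64,
                       leaky_slope = 0.2, include_g0 = TRUE) {
  M <- length(omics)
  K <- length(class_levels)
  edges <- lapply(networks, function(nw) edge_index(nw$edges))
  ops <- lapply(edges, function(e) new.env(parent = emptyenv()))
  params <- vector("list", M)
  names(params) <- make.unique(vapply(omics, `[[`, "", "omics_name"))
  for (m in seq_len(M)) {
    params[[m]] <- encoder_params(
      d = ncol(omics[[m]]$values), K = K, n_heads = n_heads, hidden = hidden,
      evidence_hidden = evidence_hidden, include_g0 = include_g0,
      leaky_slope = leaky_slope)
  }
  structure(list(params = params, edges = edges, ops = ops,
                 networks = networks, K = K, class_levels = class_levels,
                 omics_names = vapply(omics, `[[`, "", "omics_name"),
                 feature_names = lapply(omics, feature_names)),
            class = "trustfuse_model")
}

#' @export
print.trustfuse_model <- function(x, ...) {
  cat(sprintf("<trustfuse_model: %d omics [%s], %d classes%s>\n",
              length(x$params), paste(x$omics_names, collapse = ", "), x$K,
              if (isTRUE(x$fitted)) ", fitted" else ""))
  invisible(x)
}

#' Predict subjects with a fitted multi-omics model
#'
#' Runs each omics block through its encoder, converts evidence to
#' subjective-logic opinions, fuses them with the Dempster-Shafer rule and
#' reports fused Dirichlet-mean probabilities, labels, and the per-omics and
#' fused uncertainty masses.
#'
#' @param model A fitted \code{trustfuse_model} (from [train_model()]).
#' @param omics Named list of processed \code{omics_matrix} objects matching
#'   the model's omics blocks (same features, scaled like the training data).
#' @return List with \code{probabilities} (n x K), \code{label} (factor-like
#'   vector of class levels), \code{fused} (list: b matrix, u vector,
#'   conflict vector) and \code{per_omics} (per-block b and u).
#' @export
predict_subjects <- function(model, omics) {
  Xs <- aligned_values(model, omics)
  fw <- model_forward(Xs, model, keep_cache = FALSE)
  lab_idx <- max.col(fw$prob, ties.method = "first")
  per_omics <- lapply(seq_along(Xs), function(m)
    list(b = fw$bs[[m]], u = fw$us[[m]]))
  names(per_omics) <- model$omics_names
  list(probabilities = fw$prob,
       label = model$class_levels[lab_idx],
       fused = list(b = fw$fused$b, u = fw$fused$u, conflict = fw$fused$C),
       per_omics = per_omics)
}

# check feature alignment and extract value matrices in model order
aligned_values <- function(model, omics) {
  stopifnot(length(omics) == length(model$params))
  lapply(seq_along(omics), function(m) {
    X <- omics[[m]]
    if (!identical(feature_names(X), model$feature_names[[m]]))
      stop(sprintf("feature mismatch in omics block %d", m))
    X$values
  })
}

# ---- training -------------------------------------------------------------

#' Train the multi-omics evidential model
#'
#' Optimizes the global evidential objective end to end with Adam:
#' per-omics evidential losses, the fused-Dirichlet loss (gradients flow
#' through the Dempster-Shafer combination), and gamma-weighted per-omics
#' cross-entropy heads. The KL weight follows [lambda_schedule()]. Training
#' is deterministic given \code{seed}; the checkpoint with the best
#' validation accuracy is returned.
#'
#' @param omics Named list of processed training \code{omics_matrix} objects
#'   (shared subject order).
#' @param labels Class labels (any atomic type; the sorted unique values
#'   define the class dictionary).
#' @param networks List of \code{coexpression_network} objects, one per
#'   omics, fitted on training subjects.
#' @param val_omics,val_labels Optional validation split for early stopping
#'   and checkpoint selection.
#' @param epochs Maximum epochs.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty added to weight-matrix gradients.
#' @param batch_size Minibatch size (subjects).
#' @param gamma Weight of the per-omics cross-entropy terms.
#' @param lambda_cap,lambda_horizon KL annealing cap and warm-up horizon.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); ignored without a validation split.
#' @param n_heads,hidden,evidence_hidden,dropout Encoder hyperparameters
#'   (\code{dropout} acts on the fully connected hidden layer).
#' @param mask_augment Probability that a training sample's modality is
#'   masked: a ratio is drawn uniformly on (0, \code{mask_augment_max}) and
#'   that fraction of the modality's feature columns is zeroed for the
#'   sample (mirroring [mask_modality()]). Under the evidential loss, the
#'   network then learns to emit less class evidence — hence higher
#'   subjective-logic uncertainty — when a modality's features are
#'   suppressed, which is what makes the inference-time masking protocol
#'   raise the masked modality's uncertainty. Set to 0 to disable.
#' @param mask_augment_max Upper bound of the augmentation mask ratio.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @param verbose Print a line every 10 epochs?
#' @return A fitted \code{trustfuse_model} with a \code{history} data frame
#'   (per-epoch loss terms and validation accuracy).
#' @export
train_model <- function(omics, labels, networks,
                        val_omics = NULL, val_labels = NULL,
                        epochs = 200, lr = 1e-3, weight_decay = 1e-4,
                        batch_size = 32, gamma = 1,
                        lambda_cap = 1, lambda_horizon = 50,
                        patience = 20,
                        n_heads = 4, hidden = 8, evidence_hidden = 64,
                        dropout = 0.1, mask_augment = 0.5,
                        mask_augment_max = 0.8, seed = 1,
                        verbose = FALSE) {
  if (epochs < 1) stop("epochs must be >= 1")
  class_levels <- sort(unique(unname(labels)))
  y <- match(labels, class_levels)
  set.seed(seed)
  model <- init_model(omics, networks, class_levels, n_heads, hidden,
                      evidence_hidden)
  Xs <- lapply(omics, `[[`, "values")
  n <- nrow(Xs[[1]])
  for (X in Xs) if (nrow(X) != n) stop("omics blocks disagree on subjects")
  has_val <- !is.null(val_omics)
  val_Xs <- if (has_val) lapply(val_omics, `[[`, "values")
  yval <- if (has_val) match(val_labels, class_levels)

  flat <- flatten_params(model$params)
  opt <- adam_init(flat)
  best <- list(acc = -Inf, flat = flat, epoch = 0)
  hist <- list()
  wait <- 0
  eh <- evidence_hidden
  for (epoch in seq_len(epochs)) {
    lam <- lambda_schedule(epoch - 1, lambda_horizon, lambda_cap)
    ord <- sample.int(n)
    nb_tot <- ceiling(n / batch_size)
    ep_loss <- c(total = 0, fused = 0)
    for (bi in seq_len(nb_tot)) {
      idx <- ord[((bi - 1) * batch_size + 1):min(bi * batch_size, n)]
      Xb <- lapply(Xs, function(X) X[idx, , drop = FALSE])
      if (mask_augment > 0) {
        Xb <- lapply(Xb, function(X) {
          d_m <- ncol(X)
          for (s in seq_len(nrow(X))) {
            if (stats::runif(1) < mask_augment) {
              r <- stats::runif(1, 0, mask_augment_max)
              n_mask <- floor(r * d_m)
              if (n_mask > 0) X[s, sample.int(d_m, n_mask)] <- 0
            }
          }
          X
        })
      }
      masks <- if (dropout > 0) {
        lapply(Xb, function(X)
          matrix(stats::rbinom(length(idx) * eh, 1, 1 - dropout),
                 length(idx), eh) / (1 - dropout))
      } else NULL
      fw <- model_forward(Xb, model, keep_cache = TRUE,
                          dropout_masks = masks)
      lg <- model_loss_grads(fw, Xb, model, y[idx], lam, gamma)
      if (!is.finite(lg$breakdown$total))
        stop(sprintf("non-finite loss at epoch %d (total=%g); aborting",
                     epoch, lg$breakdown$total))
      gflat <- flatten_params(lg$grads)
      up <- adam_step(flat, gflat, opt, lr = lr,
                      weight_decay = weight_decay)
      flat <- up$flat; opt <- up$state
      model$params <- assign_flat(model$params, flat)
      w <- length(idx) / n
      ep_loss <- ep_loss + w * c(lg$breakdown$total, lg$breakdown$fused)
    }
    val_acc <- NA_real_
    if (has_val) {
      fwv <- model_forward(val_Xs, model)
      val_acc <- mean(max.col(fwv$prob, ties.method = "first") == yval)
      # accuracy first; ties broken by mean true-class probability, so the
      # checkpoint keeps maturing (evidence keeps growing) after accuracy
      # saturates
      val_p <- mean(fwv$prob[cbind(seq_along(yval), yval)])
      score <- val_acc + 0.01 * val_p
      if (score > best$acc + 1e-12) {
        best <- list(acc = score, flat = flat, epoch = epoch)
        wait <- 0
      } else wait <- wait + 1
    }
    hist[[epoch]] <- data.frame(epoch = epoch, total = ep_loss[1],
                                fused = ep_loss[2], lambda = lam,
                                val_acc = val_acc)
    if (verbose && epoch %% 10 == 0)
      message(sprintf("epoch %3d  loss %.4f  val_acc %s", epoch, ep_loss[1],
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    if (has_val && wait >= patience) break
  }
  if (has_val) model$params <- assign_flat(model$params, best$flat)
  model$fitted <- TRUE
  model$history <- do.call(rbind, hist)
  model$best_epoch <- if (has_val) best$epoch else epochs
  model
}
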