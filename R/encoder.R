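#' Multi-level graph-attention encoder
#'
#' @description
#' Each subject of an omics block is a graph G0: the block's co-expression
#' edge set with the subject's own scaled feature values on the nodes. A
#' multi-head graph-attention (GAT) layer updates G0 into G1, a second layer
#' updates G1 into G2, and the three levels are fused into one subject vector
#' (default: per-level node embeddings concatenated and flattened, preserving
#' node identity). A two-layer fully connected head with a softplus output
#' turns the fused vector into non-negative per-class evidence; a parallel
#' linear head provides the logits used by the per-omics cross-entropy term
#' of the training objective.
#'
#' Attention follows the standard formulation: for an edge j -> i,
#' \deqn{\alpha_{ij} = \mathrm{softmax}_{j \in N_i}\,
#'   \mathrm{LeakyReLU}(a^\top [W h_i \,\|\, W h_j])}
#' and each head aggregates \eqn{\sigma(\sum_j \alpha_{ij} W h_j)} with
#' \eqn{\sigma} = ELU; head outputs are concatenated. Self-loops are always
#' added, so isolated nodes still propagate their own feature.
#'
#' @name encoder
NULL

# ---- parameter containers -------------------------------------------------

#' Initialize parameters for one GAT attention head
#'
#' @param in_dim Input embedding dimension per node.
#' @param out_dim Output dimension of this head.
#' @return List with \code{W} (out_dim x in_dim), \code{a_src}, \code{a_dst}
#'   (the two halves of the attention vector \code{a}).
#' @export
gat_head_params <- function(in_dim, out_dim) {
  list(W = glorot(out_dim, in_dim),
       a_src = as.vector(glorot(out_dim, 1)),
       a_dst = as.vector(glorot(out_dim, 1)))
}

#' Initialize the full encoder parameter set for one omics block
#'
#' @param d Number of graph nodes (features of the block).
#' @param K Number of classes.
#' @param n_heads Attention heads T per level.
#' @param hidden Per-head output dimension h.
#' @param evidence_hidden Width of the fully connected evidence head.
#' @param readout \code{"flatten"} (concatenate node embeddings across levels
#'   and nodes) or \code{"mean"} (average over nodes per level).
#' @param include_g0 Should the raw level-0 node features enter the fused
#'   vector directly?
#' @param leaky_slope Negative slope of the LeakyReLU inside attention.
#' @return List of parameter tensors (class \code{encoder_params}).
#' @export
encoder_params <- function(d, K, n_heads = 4, hidden = 8,
                           evidence_hidden = 64,
                           readout = c("flatten", "mean"),
                           include_g0 = TRUE, leaky_slope = 0.2) {
  readout <- match.arg(readout)
  p1 <- n_heads * hidden
  l1 <- lapply(seq_len(n_heads), function(t) gat_head_params(1L, hidden))
  l2 <- lapply(seq_len(n_heads), function(t) gat_head_params(p1, hidden))
  names(l1) <- names(l2) <- paste0("h", seq_len(n_heads))
  per_node <- (if (include_g0) 1L else 0L) + 2L * p1
  D <- if (readout == "flatten") d * per_node else per_node
  structure(list(
    l1 = l1, l2 = l2,
    fc1 = list(W = glorot(evidence_hidden, D), b = numeric(evidence_hidden)),
    fc2 = list(W = glorot(K, evidence_hidden), b = numeric(K)),
    gat_head = list(W = glorot(K, D), b = numeric(K)),
    cfg = list(d = d, K = K, n_heads = n_heads, hidden = hidden,
               evidence_hidden = evidence_hidden, readout = readout,
               include_g0 = include_g0, leaky_slope = leaky_slope,
               fused_dim = D)),
    class = "encoder_params")
}

# ---- batched GAT layer ----------------------------------------------------

# Batch scatter/gather structure for an edge index replicated over nb
# subjects. All per-edge quantities live in flat vectors of length nb * nE
# (subject-major); G_src / G_dst are fixed 0/1 sparse matrices summing edge
# values into target / source node slots of the (nb * d)-long node space.
# Cached per batch size in an environment to avoid rebuilding every step.
batch_ops <- function(edge, nb, cache = NULL) {
  key <- as.character(nb)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  d <- edge$d; nE <- edge$n_edges
  rows <- rep((seq_len(nb) - 1L) * d, each = nE) + rep(edge$i, nb)
  cols <- rep((seq_len(nb) - 1L) * d, each = nE) + rep(edge$j, nb)
  ix <- seq_len(nb * nE)
  bo <- list(
    rows = rows, cols = cols, nb = nb,
    G_src = Matrix::sparseMatrix(i = rows, j = ix, x = 1,
                                 dims = c(nb * d, nb * nE)),
    G_dst = Matrix::sparseMatrix(i = cols, j = ix, x = 1,
                                 dims = c(nb * d, nb * nE)))
  if (!is.null(cache)) cache[[key]] <- bo
  bo
}

# Forward pass of one multi-head GAT layer over a batch of nb subjects that
# share the edge index. Hin: (nb*d) x p node-flat embeddings (subject-major
# rows). Returns concatenated head outputs and, optionally, a cache for the
# backward pass.
gat_layer_forward <- function(Hin, nb, edge, heads, bo, slope = 0.2,
                              keep_cache = FALSE) {
  nE <- edge$n_edges
  out <- vector("list", length(heads))
  cache <- if (keep_cache) vector("list", length(heads)) else NULL
  for (t in seq_along(heads)) {
    hp <- heads[[t]]
    Z <- Hin %*% t(hp$W)                              # (nb*d) x h
    ssrc <- as.vector(Z %*% hp$a_src)
    sdst <- as.vector(Z %*% hp$a_dst)
    raw <- ssrc[bo$rows] + sdst[bo$cols]              # per-edge scores
    act <- leaky_relu(raw, slope)
    if (max(act) > 30) {                              # softmax stabilization
      am <- matrix(act, nE, nb)                       # columns = subjects
      smax <- apply(am, 2, max)
      act <- act - rep(smax, each = nE)               # constant per subject
    }
    ex <- exp(act)
    denom <- as.vector(bo$G_src %*% ex)               # per (subject, node)
    alpha <- ex / denom[bo$rows]
    Zj <- Z[bo$cols, , drop = FALSE]                  # gathered source embeds
    Magg <- as.matrix(bo$G_src %*% (alpha * Zj))
    out[[t]] <- elu(Magg)
    if (keep_cache)
      cache[[t]] <- list(Z = Z, Zj = Zj, alpha = alpha, raw = raw,
                         Magg = Magg)
  }
  H <- do.call(cbind, out)
  if (keep_cache)
    list(H = H, cache = list(heads = cache, Hin = Hin))
  else list(H = H)
}

# Backward pass matching gat_layer_forward. dOut: gradient wrt the
# concatenated output. Returns dHin and per-head parameter gradients.
gat_layer_backward <- function(cache, edge, heads, bo, slope, dOut) {
  Hin <- cache$Hin
  h <- length(heads[[1]]$a_src)
  dHin <- matrix(0, nrow(Hin), ncol(Hin))
  grads <- vector("list", length(heads))
  for (t in seq_along(heads)) {
    hp <- heads[[t]]; cc <- cache$heads[[t]]
    dO <- dOut[, (t - 1L) * h + seq_len(h), drop = FALSE]
    dMagg <- dO * elu_grad(cc$Magg)
    dMagg_rows <- dMagg[bo$rows, , drop = FALSE]
    # aggregation gradient scattered back to source-node embeddings
    dZ <- as.matrix(bo$G_dst %*% (cc$alpha * dMagg_rows))
    # d alpha, then softmax backward within each (subject, node) group
    dalpha <- rowSums(dMagg_rows * cc$Zj)
    rowagg <- as.vector(bo$G_src %*% (cc$alpha * dalpha))
    dact <- cc$alpha * (dalpha - rowagg[bo$rows])
    dscore <- dact * (slope + (1 - slope) * (cc$raw > 0))
    d_ssrc <- as.vector(bo$G_src %*% dscore)
    d_sdst <- as.vector(bo$G_dst %*% dscore)
    dZ <- dZ + outer(d_ssrc, hp$a_src) + outer(d_sdst, hp$a_dst)
    grads[[t]] <- list(
      W = crossprod(dZ, Hin),
      a_src = as.vector(crossprod(cc$Z, d_ssrc)),
      a_dst = as.vector(crossprod(cc$Z, d_sdst)))
    dHin <- dHin + dZ %*% hp$W
  }
  names(grads) <- names(heads)
  list(dHin = dHin, grads = grads)
}

# ---- full encoder (batched) ----------------------------------------------

# Forward over a batch: X nb x d scaled values; returns evidence e (nb x K),
# per-omics logits (nb x K), fused matrix and (optionally) the full cache.
encoder_forward <- function(X, edge, params, ops = NULL,
                            keep_cache = FALSE, dropout_mask = NULL) {
  cfg <- params$cfg
  nb <- nrow(X); d <- cfg$d
  bo <- batch_ops(edge, nb, ops)
  H0 <- matrix(as.vector(t(X)), ncol = 1)
  f1 <- gat_layer_forward(H0, nb, edge, params$l1, bo, cfg$leaky_slope,
                          keep_cache)
  f2 <- gat_layer_forward(f1$H, nb, edge, params$l2, bo, cfg$leaky_slope,
                          keep_cache)
  if (cfg$readout == "flatten") {
    parts <- list(flat_to_wide(f1$H, nb, d), flat_to_wide(f2$H, nb, d))
    if (cfg$include_g0) parts <- c(list(X), parts)
  } else {
    pool <- function(H) {
      W <- flat_to_wide(H, nb, d)
      p <- ncol(W) / d
      out <- matrix(0, nb, p)
      for (k in seq_len(p))
        out[, k] <- rowMeans(W[, (k - 1) * d + seq_len(d), drop = FALSE])
      out
    }
    parts <- list(pool(f1$H), pool(f2$H))
    if (cfg$include_g0) parts <- c(list(matrix(rowMeans(X), ncol = 1)), parts)
  }
  Fmat <- do.call(cbind, parts)
  pre_hidden <- sweep(Fmat %*% t(params$fc1$W), 2, params$fc1$b, "+")
  hidden <- relu(pre_hidden)
  if (!is.null(dropout_mask)) hidden <- hidden * dropout_mask
  elogits <- sweep(hidden %*% t(params$fc2$W), 2, params$fc2$b, "+")
  e <- softplus(elogits)
  gat_logits <- sweep(Fmat %*% t(params$gat_head$W), 2, params$gat_head$b, "+")
  res <- list(e = e, gat_logits = gat_logits, fused = Fmat,
              H1 = f1$H, H2 = f2$H)
  if (keep_cache)
    res$cache <- list(c1 = f1$cache, c2 = f2$cache, Fmat = Fmat,
                      pre_hidden = pre_hidden, hidden = hidden,
                      elogits = elogits, dropout_mask = dropout_mask,
                      nb = nb, bo = bo)
  res
}

# Backward over a batch: de, dgat_logits are nb x K gradients. Returns the
# gradient list with the same shape as `params` (minus cfg).
encoder_backward <- function(cache, edge, params, ops, de, dgat_logits) {
  cfg <- params$cfg
  nb <- cache$nb; d <- cfg$d
  dlog2 <- de * sigmoid(cache$elogits)
  dfc2W <- crossprod(dlog2, cache$hidden)
  dfc2b <- colSums(dlog2)
  dhidden <- dlog2 %*% params$fc2$W
  if (!is.null(cache$dropout_mask)) dhidden <- dhidden * cache$dropout_mask
  dhidden <- dhidden * (cache$pre_hidden > 0)
  dfc1W <- crossprod(dhidden, cache$Fmat)
  dfc1b <- colSums(dhidden)
  dgatW <- crossprod(dgat_logits, cache$Fmat)
  dgatb <- colSums(dgat_logits)
  dF <- dhidden %*% params$fc1$W + dgat_logits %*% params$gat_head$W

  stopifnot(cfg$readout == "flatten")   # training uses the flatten readout
  p1 <- cfg$n_heads * cfg$hidden
  off <- if (cfg$include_g0) d else 0L
  dH1 <- wide_to_flat(dF[, off + seq_len(d * p1), drop = FALSE], nb, d)
  dH2 <- wide_to_flat(dF[, off + d * p1 + seq_len(d * p1), drop = FALSE],
                      nb, d)
  b2 <- gat_layer_backward(cache$c2, edge, params$l2, cache$bo,
                           cfg$leaky_slope, dH2)
  dH1 <- dH1 + b2$dHin
  b1 <- gat_layer_backward(cache$c1, edge, params$l1, cache$bo,
                           cfg$leaky_slope, dH1)
  list(l1 = b1$grads, l2 = b2$grads,
       fc1 = list(W = dfc1W, b = dfc1b),
       fc2 = list(W = dfc2W, b = dfc2b),
       gat_head = list(W = dgatW, b = dgatb))
}

# ---- exposed single-graph operations -------------------------------------

#' Attention weights of one node over its neighbourhood
#'
#' Computes the softmax-normalized attention coefficients of Eq.-style GAT
#' attention for a single node: scores are
#' \code{LeakyReLU(a_src . W h_i + a_dst . W h_j)} over the neighbours j,
#' then softmax-normalized; weights are positive and sum to 1.
#'
#' @param h_i Embedding of the focal node (length \code{in_dim}).
#' @param H_neighbors Matrix of neighbour embeddings (one per row; include
#'   the node itself to model the self-loop).
#' @param params A head parameter list from [gat_head_params()].
#' @param slope Negative slope of the LeakyReLU.
#' @return Numeric vector of attention weights over the rows of
#'   \code{H_neighbors}.
#' @export
attention_coefficients <- function(h_i, H_neighbors, params, slope = 0.2) {
  H_neighbors <- rbind(H_neighbors)
  if (nrow(H_neighbors) == 0) stop("neighbourhood must be non-empty")
  zi <- as.vector(params$W %*% h_i)
  Zj <- H_neighbors %*% t(params$W)
  scores <- leaky_relu(sum(params$a_src * zi) +
                         as.vector(Zj %*% params$a_dst), slope)
  ex <- exp(scores - max(scores))
  ex / sum(ex)
}

#' Apply one multi-head GAT layer to a single graph
#'
#' @param x Node-feature matrix (d x in_dim) or vector (scalar features).
#' @param E Symmetric binary edge matrix (self-loops added internally).
#' @param heads List of head parameter lists ([gat_head_params()]).
#' @param slope Negative slope of the LeakyReLU.
#' @return d x (T * out_dim) matrix of concatenated head outputs (ELU
#'   applied per head).
#' @export
multihead_layer <- function(x, E, heads, slope = 0.2) {
  x <- if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(x) != nrow(E)) stop("node count does not match the edge matrix")
  if (!isSymmetric(unname(E))) stop("edge matrix must be symmetric")
  edge <- edge_index(E)
  gat_layer_forward(x, 1L, edge, heads, batch_ops(edge, 1L), slope)$H
}

#' Encode one subject graph through the multi-level hierarchy
#'
#' Runs G0 -> G1 -> G2 through two multi-head GAT layers and fuses the
#' levels into one subject vector under the configured readout.
#'
#' @param graph A \code{subject_graph} from [build_subject_graphs()], or a
#'   list with \code{node_features} and \code{edges}.
#' @param params An [encoder_params()] object.
#' @return List with \code{h0}, \code{h1}, \code{h2} (per-level node
#'   embeddings) and \code{fused} (the subject vector).
#' @export
multilevel_encode <- function(graph, params) {
  x <- matrix(graph$node_features, nrow = 1)
  edge <- edge_index(graph$edges)
  fw <- encoder_forward(x, edge, params)
  list(h0 = as.vector(x),
       h1 = fw$H1, h2 = fw$H2,
       fused = as.vector(fw$fused))
}

#' Evidence head: fused vector to non-negative class evidence
#'
#' Two fully connected layers followed by a softplus activation, so the
#' output evidence is strictly positive for any finite input.
#'
#' @param fused Fused subject vector.
#' @param params An [encoder_params()] object (its \code{fc1}/\code{fc2} are
#'   used).
#' @return An \code{evidence} object (see [evidence()]).
#' @export
evidence_head <- function(fused, params) {
  hidden <- relu(as.vector(params$fc1$W %*% fused) + params$fc1$b)
  e <- softplus(as.vector(params$fc2$W %*% hidden) + params$fc2$b)
  evidence(e)
}
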