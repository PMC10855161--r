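test_that("attention weights are a softmax over the neighbourhood", {
  set.seed(71)
  hp <- gat_head_params(3, 4)
  h_i <- rnorm(3)
  H <- matrix(rnorm(5 * 3), 5, 3)
  w <- attention_coefficients(h_i, H, hp)
  expect_length(w, 5)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-6)
  # singleton neighbourhood gets weight 1; identical neighbours share equally
  expect_equal(attention_coefficients(h_i, H[1, , drop = FALSE], hp), 1)
  same <- rbind(H[2, ], H[2, ])
  expect_equal(attention_coefficients(h_i, same, hp), c(0.5, 0.5))
})

test_that("attention on a 3-node path matches the hand-computed softmax", {
  # scalar embeddings (1, 2, 3), W = 1, a = (1, 1), slope 0.2: node 2 attends
  # to {1, 2, 3} with scores LeakyReLU(h_2 + h_j)
  hp <- list(W = matrix(1, 1, 1), a_src = 1, a_dst = 1)
  w <- attention_coefficients(2, matrix(c(1, 2, 3), 3, 1), hp, slope = 0.2)
  scores <- c(2 + 1, 2 + 2, 2 + 3)            # all positive: LeakyReLU = id
  ref <- exp(scores) / sum(exp(scores))
  expect_equal(w, ref, tolerance = 1e-6)
  # negative scores go through the leaky slope
  hp2 <- list(W = matrix(1, 1, 1), a_src = 1, a_dst = 1)
  w2 <- attention_coefficients(-2, matrix(c(-1, 1), 2, 1), hp2, slope = 0.2)
  ref2 <- exp(c(0.2 * -3, 0.2 * -1))
  expect_equal(w2, ref2 / sum(ref2), tolerance = 1e-6)
})

test_that("a multi-head layer concatenates heads and honours self-loops", {
  set.seed(72)
  d <- 5
  E <- path_edges(d)
  x <- rnorm(d)
  heads <- list(gat_head_params(1, 4), gat_head_params(1, 4))
  H <- multihead_layer(x, E, heads)
  expect_equal(dim(H), c(d, 8))
  # an isolated node aggregates only itself: output = elu(W h_i) per head
  E0 <- matrix(0, 3, 3)
  x0 <- c(0.5, -1, 2)
  H0 <- multihead_layer(x0, E0, heads[1])
  ref <- trustfuse:::elu(outer(x0, as.vector(heads[[1]]$W)))
  expect_equal(unname(H0), unname(ref), tolerance = 1e-9)
  expect_error(multihead_layer(rnorm(4), E, heads), "node count")
})

test_that("the layer is permutation-equivariant in node labelling", {
  set.seed(73)
  for (i in 1:5) {
    d <- 6
    E <- matrix(0, d, d)
    for (k in 1:7) { ij <- sample(d, 2); E[ij[1], ij[2]] <- E[ij[2], ij[1]] <- 1 }
    x <- rnorm(d)
    heads <- list(gat_head_params(1, 3), gat_head_params(1, 3))
    perm <- sample(d)
    H <- multihead_layer(x, E, heads)
    Hp <- multihead_layer(x[perm], E[perm, perm], heads)
    expect_equal(Hp, H[perm, ], tolerance = 1e-9)
  }
})

test_that("multi-level encoding fuses levels with the expected dimensions", {
  set.seed(74)
  d <- 6
  X <- tiny_omics(n = 4, d = d, seed = 74)
  nw <- list(edges = path_edges(d))
  gs <- build_subject_graphs(X, nw$edges)
  params <- encoder_params(d = d, K = 3, n_heads = 2, hidden = 4,
                           evidence_hidden = 8)
  enc <- multilevel_encode(gs[[1]], params)
  Th <- 2 * 4
  expect_length(enc$fused, d * (1 + Th + Th))
  expect_equal(enc$h0, unname(gs[[1]]$node_features))
  expect_equal(dim(enc$h1), c(d, Th))
  # level-0 block of the fused vector is the raw node-feature vector
  expect_equal(enc$fused[seq_len(d)], unname(gs[[1]]$node_features))
  # deterministic given fixed parameters and input
  enc2 <- multilevel_encode(gs[[1]], params)
  expect_identical(enc$fused, enc2$fused)
})

test_that("the mean-pool readout yields one slot per channel and level", {
  set.seed(78)
  d <- 5
  params <- encoder_params(d = d, K = 2, n_heads = 2, hidden = 3,
                           evidence_hidden = 4, readout = "mean")
  g <- list(node_features = runif(d), edges = path_edges(d))
  enc <- multilevel_encode(g, params)
  expect_length(enc$fused, 1 + 6 + 6)   # g0 mean + T*h per level
  expect_equal(enc$fused[1], mean(g$node_features))
  ev <- evidence_head(enc$fused, params)
  expect_true(all(ev$e >= 0))
})

test_that("the evidence head emits non-negative monotone evidence", {
  set.seed(75)
  params <- encoder_params(d = 4, K = 3, n_heads = 2, hidden = 2,
                           evidence_hidden = 6)
  fused <- rnorm(params$cfg$fused_dim)
  ev <- evidence_head(fused, params)
  expect_s3_class(ev, "evidence")
  expect_true(all(ev$e >= 0))
  expect_equal(ev$alpha, ev$e + 1)
  expect_gte(ev$S, ev$K)
  # zero weights and biases: e = softplus(0) = ln 2 per class
  zp <- params
  zp$fc1$W[] <- 0; zp$fc1$b[] <- 0; zp$fc2$W[] <- 0; zp$fc2$b[] <- 0
  expect_equal(evidence_head(fused, zp)$e, rep(log(2), 3), tolerance = 1e-12)
  # raising every logit raises every evidence (softplus is monotone)
  up <- params; up$fc2$b <- up$fc2$b + 1
  expect_true(all(evidence_head(fused, up)$e > ev$e))
})

test_that("encoder gradients match finite differences through the whole model", {
  set.seed(76)
  n <- 6; d1 <- 5; d2 <- 4; K <- 3
  X1 <- matrix(runif(n * d1), n, d1)
  X2 <- matrix(runif(n * d2), n, d2)
  om1 <- omics_matrix(X1, omics_name = "a")
  om2 <- omics_matrix(X2, omics_name = "b")
  nws <- list(list(edges = path_edges(d1)), list(edges = path_edges(d2)))
  model <- trustfuse:::init_model(list(om1, om2), nws, 1:K, n_heads = 2,
                                  hidden = 3, evidence_hidden = 5)
  y <- sample(1:K, n, replace = TRUE)
  loss_of <- function(m) {
    fw <- trustfuse:::model_forward(list(X1, X2), m, keep_cache = TRUE)
    trustfuse:::model_loss_grads(fw, list(X1, X2), m, y, 0.7, 1.3)
  }
  lg <- loss_of(model)
  flat <- trustfuse:::flatten_params(model$params)
  gflat <- trustfuse:::flatten_params(lg$grads)
  expect_identical(names(flat), names(gflat))
  eps <- 1e-6
  for (key in names(flat)) {
    i <- sample(length(flat[[key]]), 1)
    fp <- flat; fp[[key]][i] <- fp[[key]][i] + eps
    mm <- model; mm$params <- trustfuse:::assign_flat(mm$params, fp)
    lp <- loss_of(mm)$breakdown$total
    fm <- flat; fm[[key]][i] <- fm[[key]][i] - eps
    mm$params <- trustfuse:::assign_flat(mm$params, fm)
    lm <- loss_of(mm)$breakdown$total
    num <- (lp - lm) / (2 * eps)
    ana <- gflat[[key]][i]
    # absolute-or-relative: near-zero gradients drown in FD cancellation
    expect_lt(abs(num - ana), 1e-6 + 1e-4 * max(abs(num), abs(ana)))
  }
})

test_that("gradients reach the parameters of every level", {
  set.seed(77)
  n <- 5; d <- 6; K <- 2
  X <- matrix(runif(n * d), n, d)
  om <- omics_matrix(X, omics_name = "a")
  model <- trustfuse:::init_model(list(om), list(list(edges = path_edges(d))),
                                  1:K, n_heads = 2, hidden = 3,
                                  evidence_hidden = 5)
  y <- sample(1:K, n, replace = TRUE)
  fw <- trustfuse:::model_forward(list(X), model, keep_cache = TRUE)
  lg <- trustfuse:::model_loss_grads(fw, list(X), model, y, 0.5, 1)
  g <- lg$grads[[1]]
  for (lvl in c("l1", "l2"))
    for (hd in g[[lvl]])
      expect_gt(sum(abs(hd$W)), 0)
  expect_gt(sum(abs(g$fc1$W)), 0)
  expect_gt(sum(abs(g$gat_head$W)), 0)
})
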