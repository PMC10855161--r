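test_that("evidential cross-entropy matches digamma recurrences", {
  # psi(x+1) = psi(x) + 1/x gives exact reference values
  expect_equal(evidential_ce(c(2, 1), c(1, 0)), 0.5)        # psi(3)-psi(2)
  expect_equal(evidential_ce(c(1, 1), c(1, 0)), 1)          # psi(2)-psi(1)
  expect_equal(evidential_ce(c(3, 1, 1), c(1, 0, 0)),
               digamma(5) - digamma(3))
  # loss -> 0 as true-class evidence grows
  big <- evidential_ce(c(1e8, 1, 1), c(1, 0, 0))
  expect_lt(big, 1e-6)
  expect_gte(evidential_ce(c(5, 2), c(0, 1)), 0)
  expect_error(evidential_ce(c(2, 1), c(1, 1)), "one-hot")
})

test_that("evidential cross-entropy equals the Dirichlet expectation", {
  # independent oracle: numerical integration of E[-log p_y] under Beta/Dir
  set.seed(61)
  for (i in 1:5) {
    a <- runif(2, 0.5, 6)
    ref <- integrate(function(p) -log(p) * dbeta(p, a[1], a[2]),
                     0, 1, rel.tol = 1e-10)$value
    expect_equal(evidential_ce(a, c(1, 0)), ref, tolerance = 1e-6)
  }
  # K = 3 via Monte Carlo on gamma draws
  a <- c(2.5, 1.2, 4)
  set.seed(62)
  G <- matrix(rgamma(3 * 4e5, shape = rep(a, each = 4e5)), ncol = 3)
  P1 <- G[, 1] / rowSums(G)
  expect_equal(evidential_ce(a, c(1, 0, 0)), mean(-log(P1)), tolerance = 5e-3)
})

test_that("adjusted_alpha removes only the true-class evidence", {
  expect_equal(adjusted_alpha(c(5, 2), c(1, 0)), c(1, 2))
  expect_equal(adjusted_alpha(c(1, 1, 1), c(0, 1, 0)), c(1, 1, 1))
  expect_equal(adjusted_alpha(c(4, 3, 2), c(0, 1, 0)), c(4, 1, 2))
})

test_that("KL to the uniform Dirichlet matches closed form and Monte Carlo", {
  expect_equal(kl_to_uniform(c(1, 1, 1)), 0)
  # alpha = (1, 2): ln 2 + (psi(2) - psi(3)) = ln 2 - 1/2
  expect_equal(kl_to_uniform(c(1, 2)), log(2) - 0.5, tolerance = 1e-12)
  expect_lt(abs(kl_to_uniform(c(1, 2)) - 0.1931), 1e-4)
  set.seed(63)
  for (i in 1:3) {
    a <- runif(3, 0.8, 5)
    G <- matrix(rgamma(3 * 1e6, shape = rep(a, each = 1e6)), ncol = 3)
    P <- G / rowSums(G)
    log_ratio <- colSums(t(log(P)) * (a - 1)) + lgamma(sum(a)) -
      sum(lgamma(a)) - lgamma(3)
    expect_equal(kl_to_uniform(a), mean(log_ratio), tolerance = 1e-2)
    expect_gte(kl_to_uniform(a), 0)
  }
})

test_that("sample_loss composes the CE and annealed KL terms", {
  expect_equal(sample_loss(c(2, 1), c(1, 0), 0),
               evidential_ce(c(2, 1), c(1, 0)))
  # adjusted alpha (1, 1) makes the KL vanish
  expect_equal(sample_loss(c(2, 1), c(1, 0), 1), 0.5)
  a <- c(5, 2); y <- c(1, 0)
  expect_gt(sample_loss(a, y, 1), sample_loss(a, y, 0))
  expect_error(sample_loss(a, y, -0.1), "non-negative")
})

test_that("the KL weight warms up linearly to its cap", {
  expect_equal(lambda_schedule(0, 50), 0)
  expect_equal(lambda_schedule(25, 50), 0.5)
  expect_equal(lambda_schedule(50, 50), 1)
  expect_equal(lambda_schedule(500, 50), 1)
  expect_equal(lambda_schedule(10, 50, cap = 0.2), 0.04)
  expect_error(lambda_schedule(-1, 50), "non-negative")
})

test_that("global loss sums its terms and handles degenerate settings", {
  set.seed(64)
  n <- 10; K <- 3
  y <- sample(1:K, n, replace = TRUE)
  aF <- matrix(rgamma(n * K, 2), n, K) + 1
  a1 <- matrix(rgamma(n * K, 2), n, K) + 1
  a2 <- matrix(rgamma(n * K, 2), n, K) + 1
  l1 <- matrix(rnorm(n * K), n, K)
  l2 <- matrix(rnorm(n * K), n, K)
  bd <- global_loss(aF, list(a1, a2), list(l1, l2), y, lambda_t = 0.5,
                    gamma = 1.5)
  expect_equal(bd$total,
               bd$fused + sum(bd$per_omics) + bd$gamma * sum(bd$gat_ce),
               tolerance = 1e-9)
  expect_true(all(unlist(bd[c("fused", "per_omics", "gat_ce")]) >= 0))
  # gamma = 0 removes the cross-entropy heads
  bd0 <- global_loss(aF, list(a1, a2), list(l1, l2), y, 0.5, gamma = 0)
  expect_equal(bd0$total, bd0$fused + sum(bd0$per_omics))
  # single modality: fused alpha equal to the omics alpha doubles its loss
  bd1 <- global_loss(a1, list(a1), list(l1), y, 0.5, gamma = 2)
  expect_equal(bd1$total, 2 * bd1$fused + 2 * bd1$gat_ce)
  expect_error(global_loss(aF, list(a1[1:5, ]), list(l1), y, 0, 1),
               "mismatched")
})

test_that("more true-class evidence lowers the sample loss", {
  set.seed(65)
  for (i in 1:10) {
    K <- sample(2:4, 1)
    alpha <- 1 + rgamma(K, 2)
    y <- rep(0, K); y[sample(K, 1)] <- 1
    lam <- runif(1)
    bump <- y * 1e-4
    expect_lt(sample_loss(alpha + bump, y, lam), sample_loss(alpha, y, lam))
  }
})

test_that("batched loss internals agree with the scalar definitions", {
  set.seed(66)
  n <- 12; K <- 3
  A <- 1 + matrix(rgamma(n * K, 2), n, K)
  y <- sample(1:K, n, replace = TRUE)
  Y <- trustfuse:::one_hot(y, K)
  lam <- 0.7
  ref <- mean(vapply(seq_len(n), function(i) sample_loss(A[i, ], Y[i, ], lam),
                     numeric(1)))
  expect_equal(trustfuse:::mean_sample_loss(A, Y, lam), ref, tolerance = 1e-12)
  # analytic gradient vs central differences
  g <- trustfuse:::sample_loss_grad_batch(A, Y, lam)
  eps <- 1e-6
  for (pick in list(c(1, 1), c(5, 2), c(12, 3))) {
    Ap <- A; Ap[pick[1], pick[2]] <- Ap[pick[1], pick[2]] + eps
    Am <- A; Am[pick[1], pick[2]] <- Am[pick[1], pick[2]] - eps
    num <- (trustfuse:::mean_sample_loss(Ap, Y, lam) -
              trustfuse:::mean_sample_loss(Am, Y, lam)) / (2 * eps)
    expect_equal(g[pick[1], pick[2]], num, tolerance = 1e-6)
  }
})
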