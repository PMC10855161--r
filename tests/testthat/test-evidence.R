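test_that("evidence maps to normalized opinions with the stated arithmetic", {
  # vacuous: zero evidence
  M0 <- opinion_from_evidence(c(0, 0, 0))
  expect_equal(M0$b, rep(0, 3))
  expect_equal(M0$u, 1)
  # K = 3, e = (3, 1, 0): S = 7
  M <- opinion_from_evidence(c(3, 1, 0))
  expect_equal(M$b, c(3, 1, 0) / 7)
  expect_equal(M$u, 3 / 7)
  expect_equal(M$u + sum(M$b), 1, tolerance = 1e-12)
  # K = 2, e = (98, 0)
  M2 <- opinion_from_evidence(c(98, 0))
  expect_equal(M2$b, c(0.98, 0))
  expect_equal(M2$u, 0.02)
  expect_error(opinion_from_evidence(evidence(c(1, 2))), NA)
  expect_error(evidence(c(-1, 2)), "non-negative")
})

test_that("opinion inversion round-trips and rejects zero uncertainty", {
  M <- sl_opinion(c(0.375, 0.125), 0.5)
  e <- evidence_from_opinion(M)
  expect_equal(e$e, c(1.5, 0.5))          # S = K/u = 4
  rt <- evidence_from_opinion(opinion_from_evidence(c(3, 1, 0)))
  expect_equal(rt$e, c(3, 1, 0), tolerance = 1e-12)
  expect_equal(evidence_from_opinion(sl_opinion(c(0, 0), 1))$e, c(0, 0))
  expect_error(evidence_from_opinion(sl_opinion(c(0.6, 0.4), 0)),
               "zero uncertainty")
})

test_that("the worked two-source fusion matches hand arithmetic", {
  M1 <- sl_opinion(c(0.6, 0.2), 0.2)
  M2 <- sl_opinion(c(0.4, 0.4), 0.2)
  fr <- ds_combine_pair(M1, M2)
  expect_equal(fr$conflict, 0.32)
  expect_equal(fr$opinion$b, c(0.44, 0.2) / 0.68, tolerance = 1e-9)
  expect_lt(abs(fr$opinion$b[1] - 0.6471), 1e-4)
  expect_lt(abs(fr$opinion$b[2] - 0.2941), 1e-4)
  expect_lt(abs(fr$opinion$u - 0.0588), 1e-4)
  expect_equal(sum(fr$opinion$b) + fr$opinion$u, 1, tolerance = 1e-12)
})

test_that("a vacuous opinion is the identity and total conflict errors", {
  set.seed(31)
  M1 <- random_opinion(4)
  vac <- sl_opinion(rep(0, 4), 1)
  fr <- ds_combine_pair(M1, vac)
  expect_equal(fr$opinion$b, M1$b, tolerance = 1e-12)
  expect_equal(fr$opinion$u, M1$u, tolerance = 1e-12)
  expect_error(ds_combine_pair(sl_opinion(c(1, 0), 0), sl_opinion(c(0, 1), 0)),
               "conflict")
  expect_error(ds_combine_pair(random_opinion(2), random_opinion(3)),
               "class count")
})

test_that("fusion is commutative and associative over random opinions", {
  set.seed(17)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    Ms <- list(random_opinion(K), random_opinion(K), random_opinion(K))
    ab_c <- ds_combine_pair(ds_combine_pair(Ms[[1]], Ms[[2]])$opinion,
                            Ms[[3]])$opinion
    a_bc <- ds_combine_pair(Ms[[1]],
                            ds_combine_pair(Ms[[2]], Ms[[3]])$opinion)$opinion
    expect_equal(ab_c$b, a_bc$b, tolerance = 1e-9)
    expect_equal(ab_c$u, a_bc$u, tolerance = 1e-9)
    ba <- ds_combine_pair(Ms[[2]], Ms[[1]])$opinion
    ab <- ds_combine_pair(Ms[[1]], Ms[[2]])$opinion
    expect_equal(ab$b, ba$b, tolerance = 1e-9)
    # every result stays normalized
    expect_equal(sum(ab_c$b) + ab_c$u, 1, tolerance = 1e-9)
  }
})

test_that("sequential fusion handles one, two or many sources", {
  set.seed(23)
  M <- random_opinion(3)
  single <- ds_combine_all(list(M))
  expect_equal(single$opinion$b, M$b)
  expect_equal(single$conflict, 0)
  Ms <- lapply(1:4, function(i) random_opinion(3))
  seq_res <- ds_combine_all(Ms)
  manual <- Reduce(function(a, b) ds_combine_pair(a, b)$opinion, Ms)
  expect_equal(seq_res$opinion$b, manual$b, tolerance = 1e-12)
  expect_error(ds_combine_all(list()), "at least one")
})

test_that("uncertainty falls as evidence grows and never rises under self-fusion", {
  e <- c(1, 2, 3)
  u0 <- opinion_from_evidence(e)$u
  for (k in 1:3) {
    e2 <- e; e2[k] <- e2[k] + 0.5
    expect_lt(opinion_from_evidence(e2)$u, u0)
  }
  set.seed(41)
  for (i in 1:20) {
    M <- random_opinion(3)
    expect_lte(ds_combine_pair(M, M)$opinion$u, M$u + 1e-12)
  }
  # a near-certain source dominates a vacuous one
  M1 <- opinion_from_evidence(c(1e6, 0, 0))
  fr <- ds_combine_pair(M1, sl_opinion(rep(0, 3), 1))
  expect_equal(fr$opinion$b, M1$b, tolerance = 1e-9)
})

test_that("fused predictions use the Dirichlet mean with smallest-index ties", {
  fr <- ds_combine_all(list(opinion_from_evidence(c(3, 1, 0))))
  pred <- predict_from_fusion(fr)
  expect_equal(pred$probabilities, c(4, 2, 1) / 7)
  expect_equal(pred$label, 1)
  vac <- ds_combine_all(list(sl_opinion(c(0, 0), 1)))
  pv <- predict_from_fusion(vac)
  expect_equal(pv$probabilities, c(0.5, 0.5))
  expect_equal(pv$label, 1)               # tie -> smallest class index
  strong <- ds_combine_all(list(opinion_from_evidence(c(0, 50, 1))))
  expect_equal(predict_from_fusion(strong)$label, 2)
})

test_that("batched opinion/fusion internals agree with the scalar API", {
  set.seed(53)
  K <- 3; n <- 25
  Es <- lapply(1:3, function(m) matrix(rgamma(n * K, 1.5), n, K))
  ops <- lapply(Es, trustfuse:::opinion_from_evidence_batch)
  fused <- trustfuse:::ds_fuse_batch(lapply(ops, `[[`, "b"),
                                     lapply(ops, `[[`, "u"))
  for (s in sample(n, 5)) {
    Ms <- lapply(Es, function(E) opinion_from_evidence(E[s, ]))
    ref <- ds_combine_all(Ms)
    expect_equal(fused$b[s, ], ref$opinion$b, tolerance = 1e-12)
    expect_equal(fused$u[s], ref$opinion$u, tolerance = 1e-12)
    expect_equal(fused$C[s], ref$conflict, tolerance = 1e-12)
  }
})
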