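# shared fixture builders (everything generated in code)

# a small raw omics matrix with known structure
tiny_omics <- function(n = 20, d = 8, seed = 1, name = "toy") {
  set.seed(seed)
  omics_matrix(matrix(rnorm(n * d), n, d,
                      dimnames = list(sprintf("S%02d", 1:n),
                                      sprintf("f%02d", 1:d))),
               omics_name = name)
}

# a random valid subjective-logic opinion
random_opinion <- function(K) {
  w <- rgamma(K + 1, shape = 1)
  w <- w / sum(w)
  sl_opinion(w[seq_len(K)], w[K + 1])
}

# a small path-graph edge matrix 1-2-...-d
path_edges <- function(d) {
  E <- matrix(0, d, d)
  for (i in seq_len(d - 1)) E[i, i + 1] <- E[i + 1, i] <- 1
  E
}

# quick pipeline fit on a small cohort (used by model-level unit tests)
quick_fit <- function(spec, seed = 1, epochs = 30, ...) {
  co <- generate_cohort(spec)
  fit_pipeline(co$omics, co$labels, seed = seed, lr = 1e-2, n_heads = 2,
               hidden = 3, evidence_hidden = 16, epochs = epochs,
               patience = epochs, batch_size = 32, ...)
}
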