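# small numeric helpers shared by the encoder and the losses
# (branch-free / index-assignment forms: these run on large matrices in the
# training inner loop, where ifelse() is too slow)

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}

elu_grad <- function(x) {
  g <- x
  neg <- x < 0
  g[!neg] <- 1
  g[neg] <- exp(x[neg])
  g
}

relu <- function(x) pmax(x, 0)

# row maxima of a matrix via the C-level max.col
row_max <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

# (nb*d) x p node-flat matrix  ->  nb x (d*p) subject-flat matrix,
# column layout (k-1)*d + i for node i, channel k
flat_to_wide <- function(H, nb, d) {
  p <- ncol(H)
  arr <- array(H, c(d, nb, p))
  out <- aperm(arr, c(2, 1, 3))
  dim(out) <- c(nb, d * p)
  out
}

wide_to_flat <- function(W, nb, d) {
  p <- ncol(W) / d
  arr <- array(W, c(nb, d, p))
  out <- aperm(arr, c(2, 1, 3))
  dim(out) <- c(nb * d, p)
  out
}

# Glorot-uniform init
glorot <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}
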