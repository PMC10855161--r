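#' Evidential cross-entropy (Dirichlet expected log loss)
#'
#' The expected cross-entropy of a one-hot label under a Dirichlet
#' distribution with concentration \code{alpha}:
#' \deqn{L = \sum_k y_k (\psi(S) - \psi(\alpha_k)),\quad S = \sum_k \alpha_k,}
#' with \eqn{\psi} the digamma function. Non-negative because
#' \eqn{\alpha_k \le S}, and it vanishes as the true-class evidence grows.
#'
#' @param alpha Positive concentration vector (from evidence: alpha >= 1).
#' @param y One-hot label vector.
#' @return Non-negative scalar loss.
#' @export
evidential_ce <- function(alpha, y) {
  check_one_hot(y, length(alpha))
  if (any(alpha <= 0)) stop("alpha must be positive")
  sum(y * (digamma(sum(alpha)) - digamma(alpha)))
}

#' Remove the true-class evidence from a Dirichlet parameter
#'
#' \code{alpha_tilde = y + (1 - y) * alpha}: the true-class component is set
#' to 1 (no evidence) while the others are kept, so a KL penalty on
#' \code{alpha_tilde} suppresses evidence for incorrect classes only.
#'
#' @param alpha Concentration vector.
#' @param y One-hot label vector.
#' @return The adjusted concentration vector.
#' @export
adjusted_alpha <- function(alpha, y) {
  check_one_hot(y, length(alpha))
  y + (1 - y) * alpha
}

#' KL divergence from a Dirichlet to the uniform Dirichlet
#'
#' Closed form of \eqn{KL[\mathrm{Dir}(\tilde\alpha)\,\|\,\mathrm{Dir}(1)]}
#' (natural log):
#' \deqn{\log\Gamma(\tilde S) - \sum_k \log\Gamma(\tilde\alpha_k)
#'   - \log\Gamma(K)
#'   + \sum_k (\tilde\alpha_k - 1)(\psi(\tilde\alpha_k) - \psi(\tilde S)).}
#'
#' @param alpha_tilde Positive concentration vector.
#' @return Non-negative scalar divergence (0 iff \code{alpha_tilde == 1}).
#' @export
kl_to_uniform <- function(alpha_tilde) {
  if (any(alpha_tilde <= 0)) stop("alpha_tilde must be positive")
  S <- sum(alpha_tilde)
  K <- length(alpha_tilde)
  lgamma(S) - sum(lgamma(alpha_tilde)) - lgamma(K) +
    sum((alpha_tilde - 1) * (digamma(alpha_tilde) - digamma(S)))
}

#' Per-sample evidential loss
#'
#' \code{evidential_ce(alpha, y) + lambda_t * kl_to_uniform(adjusted_alpha)}:
#' the Dirichlet expected cross-entropy plus the annealed KL penalty on
#' misclassified-class evidence.
#'
#' @param alpha Concentration vector.
#' @param y One-hot label.
#' @param lambda_t Non-negative annealing weight.
#' @return Scalar loss.
#' @export
sample_loss <- function(alpha, y, lambda_t) {
  if (lambda_t < 0) stop("lambda_t must be non-negative")
  evidential_ce(alpha, y) +
    lambda_t * kl_to_uniform(adjusted_alpha(alpha, y))
}

#' Linear warm-up schedule for the KL weight
#'
#' \code{lambda_t = cap * min(1, epoch / horizon)}: the KL penalty is phased
#' in linearly so early training can accumulate evidence freely.
#'
#' @param epoch Current epoch (0-based).
#' @param horizon Number of epochs over which to reach the cap.
#' @param cap Maximum weight.
#' @return The annealing weight at this epoch.
#' @export
lambda_schedule <- function(epoch, horizon = 50, cap = 1) {
  if (epoch < 0) stop("epoch must be non-negative")
  if (horizon < 1) stop("horizon must be >= 1")
  cap * min(1, epoch / horizon)
}

#' Global training objective for one batch
#'
#' Sums (averaged over the batch) the evidential loss of the fused Dirichlet,
#' the evidential losses of each omics' own Dirichlet, and a gamma-weighted
#' softmax cross-entropy on each omics' augmentation-module logits:
#' \deqn{L = L(\alpha^F) + \sum_m L(\alpha^m) + \gamma \sum_m L^m_{CE}.}
#'
#' @param alpha_fused n x K matrix of fused concentrations.
#' @param alpha_per_omics List of n x K matrices, one per omics.
#' @param logits_per_omics List of n x K logit matrices, one per omics.
#' @param labels Integer class labels in 1..K (length n).
#' @param lambda_t KL annealing weight.
#' @param gamma Weight of the per-omics cross-entropy terms (conventionally
#'   1).
#' @return A \code{loss_breakdown} list: \code{total}, \code{fused},
#'   \code{per_omics}, \code{gat_ce}, \code{lambda_t}, \code{gamma}.
#' @export
global_loss <- function(alpha_fused, alpha_per_omics, logits_per_omics,
                        labels, lambda_t = 0, gamma = 1) {
  if (gamma < 0) stop("gamma must be non-negative")
  n <- nrow(alpha_fused); K <- ncol(alpha_fused)
  stopifnot(length(labels) == n)
  for (A in alpha_per_omics)
    if (!all(dim(A) == c(n, K))) stop("mismatched subject sets across omics")
  Y <- one_hot(labels, K)
  fused <- mean_sample_loss(alpha_fused, Y, lambda_t)
  per_omics <- vapply(alpha_per_omics,
                      function(A) mean_sample_loss(A, Y, lambda_t), numeric(1))
  gat_ce <- vapply(logits_per_omics,
                   function(L) mean(softmax_ce_batch(L, Y)$loss), numeric(1))
  total <- fused + sum(per_omics) + gamma * sum(gat_ce)
  structure(list(total = total, fused = fused, per_omics = per_omics,
                 gat_ce = gat_ce, lambda_t = lambda_t, gamma = gamma),
            class = "loss_breakdown")
}

# ---- internal helpers -----------------------------------------------------

check_one_hot <- function(y, K) {
  if (length(y) != K || any(!(y %in% c(0, 1))) || sum(y) != 1)
    stop("y must be a one-hot vector")
  invisible(TRUE)
}

one_hot <- function(labels, K) {
  n <- length(labels)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), labels)] <- 1
  Y
}

# batched mean of sample_loss over rows
mean_sample_loss <- function(A, Y, lambda_t) {
  S <- rowSums(A)
  ce <- rowSums(Y * (digamma(S) - digamma(A)))
  At <- Y + (1 - Y) * A
  St <- rowSums(At)
  K <- ncol(A)
  kl <- lgamma(St) - rowSums(lgamma(At)) - lgamma(K) +
    rowSums((At - 1) * (digamma(At) - digamma(St)))
  mean(ce + lambda_t * kl)
}

# gradient of mean_sample_loss wrt A (already averaged over the batch)
sample_loss_grad_batch <- function(A, Y, lambda_t) {
  n <- nrow(A); K <- ncol(A)
  S <- rowSums(A)
  dce <- trigamma(S) - Y * trigamma(A)
  At <- Y + (1 - Y) * A
  St <- rowSums(At)
  dkl_dAt <- (At - 1) * trigamma(At) - (St - K) * trigamma(St)
  (dce + lambda_t * dkl_dAt * (1 - Y)) / n
}

# softmax cross-entropy with logits; returns loss per row and the gradient
softmax_ce_batch <- function(logits, Y) {
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  P <- ex / rowSums(ex)
  loss <- -rowSums(Y * log(pmax(P, 1e-300)))
  list(loss = loss, P = P, grad = P - Y)
}
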