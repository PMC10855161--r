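#' Dirichlet evidence for K classes
#'
#' Non-negative per-class evidence \code{e}; the induced Dirichlet
#' concentration is \code{alpha = e + 1} with strength \code{S = sum(alpha)}.
#'
#' @param e Numeric vector of non-negative evidence values.
#' @return Object of class \code{evidence} with fields \code{e},
#'   \code{alpha}, \code{S}, \code{K}.
#' @export
evidence <- function(e) {
  e <- as.numeric(e)
  if (any(e < 0)) stop("evidence must be non-negative")
  structure(list(e = e, alpha = e + 1, S = sum(e + 1), K = length(e)),
            class = "evidence")
}

#' @export
print.evidence <- function(x, ...) {
  cat(sprintf("<evidence K=%d: e = [%s], S = %.4g>\n", x$K,
              paste(signif(x$e, 4), collapse = ", "), x$S))
  invisible(x)
}

#' Subjective-logic opinion
#'
#' Belief masses \code{b} (one per class) and an uncertainty mass \code{u},
#' all non-negative with \code{u + sum(b) = 1}.
#'
#' @param b Numeric vector of belief masses.
#' @param u Uncertainty mass.
#' @return Object of class \code{sl_opinion}.
#' @export
sl_opinion <- function(b, u) {
  b <- as.numeric(b); u <- as.numeric(u)
  if (any(b < -1e-12) || u < -1e-12) stop("opinion components must be >= 0")
  if (abs(u + sum(b) - 1) > 1e-9)
    stop("opinion must satisfy u + sum(b) = 1")
  structure(list(b = pmax(b, 0), u = max(u, 0), K = length(b)),
            class = "sl_opinion")
}

#' @export
print.sl_opinion <- function(x, ...) {
  cat(sprintf("<opinion K=%d: b = [%s], u = %.4g>\n", x$K,
              paste(signif(x$b, 4), collapse = ", "), x$u))
  invisible(x)
}

#' Map evidence to a subjective-logic opinion
#'
#' With \code{S = sum(e + 1)}: belief \code{b_k = e_k / S} and uncertainty
#' \code{u = K / S}, so \code{u + sum(b) = 1} exactly. More evidence for any
#' class strictly lowers \code{u}; zero evidence gives the vacuous opinion
#' (\code{u = 1}).
#'
#' @param e An \code{evidence} object or non-negative numeric vector.
#' @return An \code{sl_opinion}.
#' @export
opinion_from_evidence <- function(e) {
  if (!inherits(e, "evidence")) e <- evidence(e)
  sl_opinion(e$e / e$S, e$K / e$S)
}

#' Invert an opinion back to evidence
#'
#' With \code{S = K / u}: \code{e_k = b_k * S}. Round-trips with
#' [opinion_from_evidence()]. Requires \code{u > 0} (zero uncertainty would
#' mean infinite evidence).
#'
#' @param M An \code{sl_opinion}.
#' @return An \code{evidence} object.
#' @export
evidence_from_opinion <- function(M) {
  stopifnot(inherits(M, "sl_opinion"))
  if (M$u <= 0) stop("cannot invert an opinion with zero uncertainty")
  S <- M$K / M$u
  evidence(M$b * S)
}

#' Combine two opinions by the Dempster-Shafer rule
#'
#' The reduced combination over singleton classes plus the unknown set:
#' \deqn{b_k^F = \frac{b_k^1 b_k^2 + b_k^1 u^2 + b_k^2 u^1}{1 - C},\qquad
#'       u^F = \frac{u^1 u^2}{1 - C},}
#' where \eqn{C = \sum_{i \ne j} b_i^1 b_j^2} is the conflict between the two
#' sources. A vacuous opinion (\code{u = 1}) is the identity element; total
#' conflict (\eqn{C \to 1}) raises an error rather than renormalizing
#' silently.
#'
#' @param M1,M2 \code{sl_opinion} objects over the same classes.
#' @return List of class \code{fusion_result}: \code{opinion} (fused
#'   \code{sl_opinion}), \code{conflict} (C), \code{evidence} (fused
#'   evidence via [evidence_from_opinion()], \code{NULL} when the fused
#'   uncertainty is 0) and \code{inputs}.
#' @export
ds_combine_pair <- function(M1, M2) {
  stopifnot(inherits(M1, "sl_opinion"), inherits(M2, "sl_opinion"))
  if (M1$K != M2$K) stop("opinions must share the class count")
  C <- sum(outer(M1$b, M2$b)) - sum(M1$b * M2$b)
  if (C >= 1 - 1e-12)
    stop("total conflict between opinions (C ~ 1); fusion undefined")
  g <- 1 - C
  b <- (M1$b * M2$b + M1$b * M2$u + M2$b * M1$u) / g
  u <- (M1$u * M2$u) / g
  fused <- sl_opinion(b, u)
  structure(list(opinion = fused, conflict = C,
                 evidence = if (fused$u > 0) evidence_from_opinion(fused) else NULL,
                 inputs = list(M1, M2)),
            class = "fusion_result")
}

#' Combine any number of opinions sequentially
#'
#' Applies [ds_combine_pair()] left to right in the given order. The rule is
#' commutative and associative up to floating point, so the order is
#' immaterial in exact arithmetic; the recorded conflict is that of the last
#' pairwise combination.
#'
#' @param opinions Non-empty list of \code{sl_opinion} objects sharing K.
#' @return A \code{fusion_result} (a single opinion fuses to itself with
#'   conflict 0).
#' @export
ds_combine_all <- function(opinions) {
  if (length(opinions) == 0) stop("need at least one opinion")
  if (length(opinions) == 1) {
    M <- opinions[[1]]
    return(structure(list(opinion = M, conflict = 0,
                          evidence = if (M$u > 0) evidence_from_opinion(M) else NULL,
                          inputs = opinions),
                     class = "fusion_result"))
  }
  res <- ds_combine_pair(opinions[[1]], opinions[[2]])
  for (m in seq_along(opinions)[-(1:2)])
    res <- ds_combine_pair(res$opinion, opinions[[m]])
  res$inputs <- opinions
  res
}

#' Class probabilities and label from a fusion result
#'
#' Probabilities are the fused Dirichlet mean \code{alpha_k / S}; the label
#' is the argmax, with ties resolved to the smallest class index.
#'
#' @param result A \code{fusion_result}.
#' @return List with \code{probabilities} (length K) and \code{label}
#'   (integer class index in 1..K).
#' @export
predict_from_fusion <- function(result) {
  stopifnot(inherits(result, "fusion_result"))
  M <- result$opinion
  # Dirichlet mean: alpha/S = b + u/K, well defined even at u = 0
  p <- M$b + M$u / M$K
  list(probabilities = p, label = which.max(p))
}

# ---- batched internals (training path) -----------------------------------
# B: n x K belief matrix, u: n vector. These mirror the scalar API above and
# are cross-checked against it in the tests.

opinion_from_evidence_batch <- function(E) {
  S <- rowSums(E) + ncol(E)
  list(b = E / S, u = ncol(E) / S)
}

# gradient of evidence -> opinion: given db (n x K), du (n), return de
opinion_from_evidence_vjp <- function(E, db, du) {
  K <- ncol(E)
  S <- rowSums(E) + K
  inner <- rowSums(db * E)
  db / S - (inner + du * K) / S^2
}

ds_pair_batch <- function(b1, u1, b2, u2) {
  C <- rowSums(b1) * rowSums(b2) - rowSums(b1 * b2)
  g <- 1 - C
  if (any(g <= 1e-12)) stop("total conflict encountered during fusion")
  list(b = (b1 * b2 + b1 * u2 + b2 * u1) / g,
       u = (u1 * u2) / g, C = C, g = g)
}

# VJP of ds_pair_batch: gradients wrt both input opinions
ds_pair_vjp <- function(b1, u1, b2, u2, fw, db_out, du_out) {
  g <- fw$g
  dN <- db_out / g
  dC <- (rowSums(db_out * fw$b) + du_out * fw$u) / g
  B1 <- rowSums(b1); B2 <- rowSums(b2)
  db1 <- dN * (b2 + u2) + dC * (B2 - b2) + du_out * 0
  du1 <- rowSums(dN * b2) + du_out * u2 / g
  db2 <- dN * (b1 + u1) + dC * (B1 - b1)
  du2 <- rowSums(dN * b1) + du_out * u1 / g
  list(db1 = db1, du1 = du1, db2 = db2, du2 = du2)
}

# Sequential fusion of a list of batched opinions; caches intermediates for
# the backward sweep.
ds_fuse_batch <- function(bs, us) {
  M <- length(bs)
  acc_b <- bs[[1]]; acc_u <- us[[1]]
  steps <- list()
  if (M > 1) {
    for (m in 2:M) {
      fw <- ds_pair_batch(acc_b, acc_u, bs[[m]], us[[m]])
      steps[[m - 1]] <- list(left_b = acc_b, left_u = acc_u, fw = fw)
      acc_b <- fw$b; acc_u <- fw$u
    }
  }
  list(b = acc_b, u = acc_u, steps = steps,
       C = if (M > 1) steps[[M - 1]]$fw$C else rep(0, nrow(bs[[1]])))
}

# Backward sweep over the sequential fusion: returns per-omics db, du.
ds_fuse_vjp <- function(bs, us, fused, db_out, du_out) {
  M <- length(bs)
  dbs <- vector("list", M); dus <- vector("list", M)
  if (M == 1) {
    dbs[[1]] <- db_out; dus[[1]] <- du_out
    return(list(dbs = dbs, dus = dus))
  }
  db_acc <- db_out; du_acc <- du_out
  for (m in M:2) {
    st <- fused$steps[[m - 1]]
    vj <- ds_pair_vjp(st$left_b, st$left_u, bs[[m]], us[[m]], st$fw,
                      db_acc, du_acc)
    dbs[[m]] <- vj$db2; dus[[m]] <- vj$du2
    db_acc <- vj$db1; du_acc <- vj$du1
  }
  dbs[[1]] <- db_acc; dus[[1]] <- du_acc
  list(dbs = dbs, dus = dus)
}
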