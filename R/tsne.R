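# Exact t-SNE (O(N^2)) for small feature sets.
#
# Straightforward implementation of t-distributed stochastic neighbor
# embedding: Gaussian input affinities calibrated per point to a target
# perplexity by bisection, Student-t output affinities, gradient descent
# with momentum and early exaggeration. Intended for the few hundred
# segments the evaluation harness visualizes, where the quadratic cost is
# negligible.

#' 2-D t-SNE embedding
#'
#' @param X `[N x d]` feature matrix.
#' @param perplexity target perplexity; capped at `(N - 1) / 3`.
#' @param n_iter gradient-descent iterations.
#' @param seed seed for the random initialization (fixed seed gives
#'   identical embeddings).
#' @return `[N x 2]` matrix of embedding coordinates.
#' @export
tsne_embed <- function(X, perplexity = 30, n_iter = 500L, seed = 1L) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 4L) stop_seizdg("t-SNE needs at least 4 points",
                          class = "seizdg_validation_error")
  perplexity <- min(perplexity, (N - 1) / 3)

  # squared distances and perplexity calibration
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(X), 0)
  target <- log(perplexity)
  P <- matrix(0, N, N)
  for (i in seq_len(N)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { h <- 0 } else {
        pr <- w / sw
        h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) {              # entropy too high -> sharper kernel
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- w / max(sum(w), 1e-300)
  }
  P <- (P + t(P)) / (2 * N)
  P <- pmax(P, 1e-12)

  set.seed(derive_seed(seed, "tsne"))
  Y <- matrix(stats::rnorm(N * 2, 0, 1e-4), N, 2)
  G <- matrix(0, N, 2)
  gains <- matrix(1, N, 2)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    exag <- if (it <= 100L) 4 else 1
    sy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sy, sy, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (exag * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 100L) momentum <- 0.8
  }
  Y
}
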