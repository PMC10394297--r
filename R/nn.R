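# Minimal neural-network layer library with hand-written backward passes.
#
# Layout conventions: dense features are [N x D] matrices; multichannel
# time series are [N x C x T] arrays (sample, channel, time). Every
# forward returns what its backward needs; backwards return gradients in
# the same shapes as their inputs/parameters. All gradients are verified
# against central finite differences in the test suite.

## ---- elementwise activations -------------------------------------------

elu_forward <- function(x) elu_fwd_cpp(x)

elu_backward <- function(dy, y, x) elu_bwd_cpp(dy, y, x)

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- dense layers -------------------------------------------------------

linear_forward <- function(X, W, b) {
  sweep(X %*% W, 2, b, "+")
}

linear_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# Softmax cross-entropy against integer labels in 1..K.
# weight scales both the loss and the gradient; reduction is mean over N
# unless weight_total overrides the denominator.
softmax_ce_forward <- function(logits, labels) {
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  idx <- cbind(seq_len(nrow(logits)), labels)
  loss <- -mean(log(pmax(probs[idx], 1e-300)))
  list(loss = loss, probs = probs)
}

softmax_ce_backward <- function(probs, labels, weight = 1) {
  G <- probs
  idx <- cbind(seq_len(nrow(G)), labels)
  G[idx] <- G[idx] - 1
  G * (weight / nrow(G))
}

## ---- temporal convolutions ----------------------------------------------

# Dense 1-D convolution over time (C input -> E output channels) with SAME
# zero padding, flattened layout [N*C x T] -> [N*E x T]. K: [C x E x S].
conv1d_forward <- function(X, K, b, N) {
  dk <- dim(K)
  Y <- conv1d_fwd_cpp(X, as.numeric(K), b, N, dk[2], dk[3])
  list(Y = Y, E = dk[2], S = dk[3], N = N)
}

conv1d_backward <- function(dY, cache, X, K) {
  out <- conv1d_bwd_cpp(dY, X, as.numeric(K), cache$N, cache$E, cache$S)
  out$dK <- array(out$dK, dim(K))
  out
}

# Depthwise (grouped, one filter per channel) valid convolution over time,
# in flattened matrix layout: X is [M x T] with M = N * C rows ordered
# sample-fastest (row m belongs to channel (m - 1) %/% N + 1).
# K: [C x S], b: length C. Output time length T - S + 1.
dwconv_forward <- function(X, K, b, N) {
  M <- nrow(X); Tt <- ncol(X)
  C <- M %/% N
  S <- ncol(K)
  Tout <- Tt - S + 1
  if (Tout < 1) stop_seizdg("time axis shorter than kernel", class = "seizdg_validation_error")
  Y <- dwconv_fwd_cpp(X, K, b, N)
  list(Y = Y, N = N, C = C, S = S, Tt = Tt, Tout = Tout)
}

dwconv_backward <- function(dY, cache, X, K) {
  dwconv_bwd_cpp(dY, X, K, cache$N)
}

# Channel-grouped batch normalization in the same [M x T] layout:
# statistics per channel over the N * T elements of its row group.
bn_mat_forward <- function(X, gamma, beta, running, N, train = TRUE,
                           momentum = 0.1, eps = 1e-5) {
  if (train) {
    st <- bn_stats_cpp(X, N)
    C <- length(gamma)
    mu <- st[1:C]
    v <- st[(C + 1):(2 * C)]
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  fw <- bn_mat_fwd_cpp(X, gamma, beta, mu, inv_sd, N)
  list(Y = fw$Y, Xhat = fw$Xhat, inv_sd = inv_sd, running = running,
       N = N, train = train)
}

bn_mat_backward <- function(dY, cache, gamma) {
  bn_mat_bwd_cpp(dY, cache$Xhat, gamma, cache$inv_sd, cache$N, cache$train)
}

# Adaptive average pooling of an [M x T] matrix to n_bins columns
# (contiguous near-equal bins), as a sparse projection matrix so the
# backward is a plain transpose.
pool_matrix <- function(Tt, n_bins) {
  edges <- floor(seq(0, Tt, length.out = n_bins + 1))
  P <- matrix(0, Tt, n_bins)
  for (j in seq_len(n_bins)) {
    idx <- (edges[j] + 1):edges[j + 1]
    P[idx, j] <- 1 / length(idx)
  }
  P
}

## ---- optimizer -----------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- parameter flattening (finite-difference checks, serialization) -----

flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  out <- template
  at <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    val <- vec[(at + 1L):(at + n)]
    attributes(val) <- attributes(template[[nm]])
    out[[nm]] <- val
    at <- at + n
  }
  out
}
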