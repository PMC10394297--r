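# Convolution-implemented discrete wavelet transform (Daubechies-4).
#
# The front-end performs multi-level wavelet decomposition as a strided
# convolution so it can sit inside a network graph: the signal is padded
# head-and-tail with its own wrap-around samples (periodic extension), then
# correlated with the 8-tap Db4 analysis pair at stride 2.

#' Daubechies order-4 analysis filter pair
#'
#' Returns the standard 8-tap Db4 decomposition (analysis) filters: the
#' scaling (low-pass) filter `g` and wavelet (high-pass) filter `h`, in
#' standard coefficient order, together with the stride used by the
#' convolutional implementation.
#'
#' The pair satisfies the orthonormal-wavelet identities
#' \eqn{\sum g = \sqrt 2}, \eqn{\sum h = 0}, \eqn{\sum g^2 = \sum h^2 = 1},
#' double-shift orthogonality, and `h` is the quadrature mirror of `g`
#' (`h[r] = (-1)^r g[R-1-r]`).
#'
#' @return a list of class `wavelet_filters` with elements `g`, `h`,
#'   `R` (filter length, 8) and `s` (stride, 2).
#' @export
#' @examples
#' f <- daubechies4_filters()
#' sum(f$g) - sqrt(2)   # ~ 0
daubechies4_filters <- function() {
  g <- c(0.230377813308896501,  0.714846570552915700,
         0.630880767929858910, -0.027983769416859854,
        -0.187034811719093090,  0.030841381835560764,
         0.032883011666885200, -0.010597401785069032)
  h <- (-1)^(0:7) * rev(g)
  structure(list(g = g, h = h, R = 8L, s = 2L), class = "wavelet_filters")
}

#' Periodic head/tail padding for boundary-safe convolution
#'
#' Pads a signal with its own wrap-around samples so that strided filtering
#' does not deform the boundaries: the last `R/2 - 1` samples are prepended
#' and the first `R/2 - 1` samples appended, giving length `N + R - 2`.
#'
#' @param x numeric vector of length `N >= R/2`.
#' @param R even filter length.
#' @return padded numeric vector of length `N + R - 2`.
#' @export
#' @examples
#' pad_head_tail(0:7, 4)  # 7 0 1 2 3 4 5 6 7 0
pad_head_tail <- function(x, R) {
  if (length(R) != 1L || R < 2L || R %% 2L != 0L) {
    stop_seizdg("filter length R must be a positive even integer",
                class = "seizdg_validation_error")
  }
  n <- length(x)
  if (n < R / 2) {
    stop_seizdg("signal too short for padding: length ", n, " < R/2 = ", R / 2,
                class = "seizdg_validation_error")
  }
  w <- R / 2 - 1
  if (w == 0) return(x)
  c(x[(n - w + 1):n], x, x[1:w])
}

# Matrix form: pad every row of an [M x T] matrix. Used by the batched
# front-end; single-signal pad_head_tail is the reference.
pad_head_tail_mat <- function(X, R) {
  n <- ncol(X)
  w <- R / 2 - 1
  if (w == 0) return(X)
  cbind(X[, (n - w + 1):n, drop = FALSE], X, X[, 1:w, drop = FALSE])
}

#' One level of convolutional wavelet decomposition
#'
#' Applies the analysis pair to an already-padded signal as a stride-2
#' correlation, producing approximation (`y_A`, low-pass) and detail
#' (`y_D`, high-pass) coefficients of length
#' `floor((length(xp) - R)/2) + 1`.
#'
#' Boundary handling and index alignment are chosen so that, for an
#' even-length input `x`, `conv_dwt_level(pad_head_tail(x, 8), f)`
#' reproduces a reference pyramidal DWT in periodized mode coefficient for
#' coefficient (zero offset).
#'
#' @param xp numeric vector, output of [pad_head_tail()].
#' @param filters a [daubechies4_filters()] object.
#' @return list with numeric vectors `y_A` and `y_D`.
#' @export
conv_dwt_level <- function(xp, filters) {
  R <- filters$R
  if (length(xp) < R) {
    stop_seizdg("padded signal shorter than filter", class = "seizdg_validation_error")
  }
  nout <- (length(xp) - R) %/% 2 + 1
  starts <- 2L * (seq_len(nout) - 1L)
  y_A <- numeric(nout)
  y_D <- numeric(nout)
  for (r in seq_len(R)) {
    xr <- xp[starts + r]
    y_A <- y_A + xr * filters$g[r]
    y_D <- y_D + xr * filters$h[r]
  }
  list(y_A = y_A, y_D = y_D)
}

# Batched single level over rows of X ([M x T]); odd T is first extended by
# repeating the last column (periodized convention). Returns A, D and the
# bookkeeping needed for the backward pass.
dwt_level_mat <- function(X, filters) {
  Tin <- ncol(X)
  odd <- Tin %% 2L == 1L
  if (odd) X <- cbind(X, X[, Tin])
  Xp <- pad_head_tail_mat(X, filters$R)
  nout <- (ncol(Xp) - filters$R) %/% 2 + 1
  ad <- dwt_level_fwd_cpp(Xp, filters$g, filters$h)
  list(A = ad$A, D = ad$D, Tin = Tin, odd = odd, nout = nout)
}

# Backward of dwt_level_mat: given dA, dD ([M x nout]), return gradient wrt
# the level input ([M x Tin]). Linearity makes this exact.
dwt_level_mat_backward <- function(dA, dD, filters, lev) {
  R <- filters$R
  w <- R / 2 - 1
  Tev <- lev$Tin + as.integer(lev$odd)
  dXp <- dwt_level_bwd_cpp(dA, dD, filters$g, filters$h, Tev + R - 2L)
  dX <- dXp[, (w + 1):(w + Tev), drop = FALSE]
  if (w > 0) {
    dX[, (Tev - w + 1):Tev] <- dX[, (Tev - w + 1):Tev] + dXp[, 1:w, drop = FALSE]
    dX[, 1:w] <- dX[, 1:w] + dXp[, (w + Tev + 1):(Tev + R - 2L), drop = FALSE]
  }
  if (lev$odd) {
    dX[, lev$Tin] <- dX[, lev$Tin] + dX[, Tev]
    dX <- dX[, 1:lev$Tin, drop = FALSE]
  }
  dX
}

#' Multi-level pyramidal decomposition into physiological sub-bands
#'
#' Recursively applies [conv_dwt_level()] to the approximation path for
#' `levels` levels (boundary padding reapplied at every level) and maps the
#' coefficients onto the five EEG bands by decomposition depth:
#' D1 -> gamma, D2 -> beta, D3 -> alpha, D4 -> theta, and the concatenation
#' of the final approximation with D5 -> delta.
#'
#' @param x numeric vector (one channel of one segment).
#' @param levels number of decomposition levels (default 5).
#' @param filters analysis pair, default [daubechies4_filters()].
#' @return named list of numeric vectors `delta`, `theta`, `alpha`,
#'   `beta`, `gamma`.
#' @export
dwt_pyramid <- function(x, levels = 5L, filters = daubechies4_filters()) {
  if (length(x) < 2^levels) {
    stop_seizdg("signal too short for ", levels, " decomposition levels",
                class = "seizdg_validation_error")
  }
  out <- dwt_pyramid_mat(matrix(x, 1L), levels, filters)
  lapply(out$bands, function(m) drop(m))
}

# Batched pyramid over rows of X. Returns the five band matrices (channel
# rows preserved) plus the per-level cache for backprop.
dwt_pyramid_mat <- function(X, levels = 5L, filters = daubechies4_filters()) {
  details <- vector("list", levels)
  caches <- vector("list", levels)
  cur <- X
  for (l in seq_len(levels)) {
    lev <- dwt_level_mat(cur, filters)
    details[[l]] <- lev$D
    caches[[l]] <- lev[c("Tin", "odd", "nout")]
    cur <- lev$A
  }
  bands <- list(
    delta = cbind(cur, details[[min(5L, levels)]]),
    theta = details[[4L]],
    alpha = details[[3L]],
    beta  = details[[2L]],
    gamma = details[[1L]]
  )
  list(bands = bands, caches = caches, n_approx = ncol(cur))
}

# Backward through the pyramid: band gradients -> gradient wrt X rows.
dwt_pyramid_mat_backward <- function(dbands, pyr, filters = daubechies4_filters()) {
  levels <- length(pyr$caches)
  na <- pyr$n_approx
  dA <- dbands$delta[, 1:na, drop = FALSE]
  dD <- list(
    dbands$gamma, dbands$beta, dbands$alpha, dbands$theta,
    dbands$delta[, (na + 1):ncol(dbands$delta), drop = FALSE]
  )
  for (l in rev(seq_len(levels))) {
    dA <- dwt_level_mat_backward(dA, dD[[l]], filters, pyr$caches[[l]])
  }
  dA
}

# Coefficient counts per band for a given window length; used to size the
# per-band projection layers before any data is seen.
dwt_band_sizes <- function(window_len, levels = 5L) {
  lens <- integer(levels)
  Tin <- window_len
  for (l in seq_len(levels)) {
    Tev <- Tin + Tin %% 2L
    lens[l] <- (Tev + 6L - 8L) %/% 2L + 1L
    Tin <- lens[l]
  }
  c(delta = lens[levels] * 2L, theta = lens[4L], alpha = lens[3L],
    beta = lens[2L], gamma = lens[1L])
}
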