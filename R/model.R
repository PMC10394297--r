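# Full network: multi-level temporal-spectral front-end, feature
# separation, and adversarial invariant-feature heads, with hand-written
# forward and backward passes.
#
# Parameter naming: a flat named list. "emb.*" embedding block, "spec.<band>.*"
# per-band spectral projections, "temp<i>.*" temporal branches, "se.*"
# squeeze-and-excitation, "c1.*"/"p.*" separation heads, "c2.*" main
# category classifier, "g.*"/"l1.*"/"l2.*" patient discriminators.

#' Model architecture configuration
#'
#' @param n_channels EEG channels C of the input segments.
#' @param n_patients number of training patients (output size of the
#'   patient classifier and discriminators).
#' @param window_len segment length in samples.
#' @param W width of each projected feature member; the paired
#'   spectral/temporal concatenation gives a feature vector of length
#'   `10 * W` (always even, as the downstream half-split requires).
#' @param E embedding-block output channels (stacked onto the raw data).
#' @param emb_kernel odd temporal kernel length of the embedding block.
#' @param k base temporal kernel height; the five branches use heights
#'   `{k, k, k/2, k/4, k/8}` (default k = 32).
#' @param se_ratio squeeze-and-excitation bottleneck reduction ratio.
#' @param h_c2 hidden width of the main category classifier; its ELU
#'   activations are the features used by the center loss and t-SNE export.
#' @param disc_widths two hidden widths of each patient discriminator.
#' @param levels wavelet decomposition levels (fixed at 5 for the
#'   physiological band mapping).
#' @param use_separation include the separation losses (Eqs. of the
#'   category/patient classifiers and max-divergence).
#' @param use_global include the global (marginal, DANN-style) adversary.
#' @param use_local include the per-class local (conditional, MADA-style)
#'   adversaries.
#' @param local_mask `"true"` masks local-adversary inputs with the true
#'   one-hot labels; `"soft"` uses the detached classifier posteriors
#'   (MADA-style).
#' @param clip_divergence optional ceiling on the per-sample squared
#'   distance entering the max-divergence loss (default `Inf`, no clip).
#' @return a list of class `seizdg_config`.
#' @export
model_config <- function(n_channels, n_patients, window_len = 250L,
                         W = 32L, E = 4L, emb_kernel = 5L, k = 32L,
                         se_ratio = 4L, h_c2 = 64L, disc_widths = c(64L, 32L),
                         levels = 5L,
                         use_separation = TRUE, use_global = TRUE,
                         use_local = TRUE, local_mask = c("true", "soft"),
                         clip_divergence = Inf) {
  if (levels != 5L) {
    stop_seizdg("the physiological band mapping requires 5 levels",
                class = "seizdg_config_error")
  }
  if (emb_kernel %% 2L != 1L) {
    stop_seizdg("emb_kernel must be odd (SAME padding)", class = "seizdg_config_error")
  }
  if (k %% 8L != 0L) {
    stop_seizdg("k must be divisible by 8", class = "seizdg_config_error")
  }
  if (window_len < k) {
    stop_seizdg("window_len must be >= k", class = "seizdg_config_error")
  }
  structure(list(
    n_channels = as.integer(n_channels), n_patients = as.integer(n_patients),
    window_len = as.integer(window_len), W = as.integer(W), E = as.integer(E),
    emb_kernel = as.integer(emb_kernel), k = as.integer(k),
    se_ratio = as.integer(se_ratio), h_c2 = as.integer(h_c2),
    disc_widths = as.integer(disc_widths), levels = 5L,
    kernel_heights = as.integer(c(k, k, k / 2, k / 4, k / 8)),
    use_separation = isTRUE(use_separation),
    use_global = isTRUE(use_global), use_local = isTRUE(use_local),
    local_mask = match.arg(local_mask),
    clip_divergence = clip_divergence
  ), class = "seizdg_config")
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / (fan_in + fan_out))), dims)
}

mlp3_init <- function(d_in, widths, d_out) {
  list(W1 = glorot(d_in, widths[1]), b1 = numeric(widths[1]),
       W2 = glorot(widths[1], widths[2]), b2 = numeric(widths[2]),
       W3 = glorot(widths[2], d_out), b3 = numeric(d_out))
}

# Initialize parameters, centers and BN running state for a config.
init_model <- function(cfg, seed = 1L) {
  set.seed(derive_seed(seed, "init"))
  C <- cfg$n_channels; E <- cfg$E; W <- cfg$W
  Cp <- C + E
  bands <- dwt_band_sizes(cfg$window_len, cfg$levels)
  hW <- 5L * W
  d_all <- 10L * W
  p <- list()
  p[["emb.K"]] <- glorot(C * cfg$emb_kernel, E, c(C, E, cfg$emb_kernel))
  p[["emb.b"]] <- numeric(E)
  p[["emb.bn.gamma"]] <- rep(1, E)
  p[["emb.bn.beta"]] <- numeric(E)
  for (b in names(bands)) {
    p[[paste0("spec.", b, ".W")]] <- glorot(Cp * bands[[b]], W)
    p[[paste0("spec.", b, ".b")]] <- numeric(W)
  }
  for (i in 1:5) {
    S <- cfg$kernel_heights[i]
    p[[paste0("temp", i, ".K")]] <- array(stats::rnorm(Cp * S, 0, sqrt(1 / S)),
                                          c(Cp, S))   # per-channel taps
    p[[paste0("temp", i, ".b")]] <- numeric(Cp)
    p[[paste0("temp", i, ".bn.gamma")]] <- rep(1, Cp)
    p[[paste0("temp", i, ".bn.beta")]] <- numeric(Cp)
  }
  m_se <- max(1L, 5L %/% cfg$se_ratio)
  p[["se.W1"]] <- glorot(5L, m_se)
  p[["se.b1"]] <- numeric(m_se)
  p[["se.W2"]] <- glorot(m_se, 5L)
  p[["se.b2"]] <- numeric(5L)
  p[["c1.W1"]] <- glorot(hW, hW); p[["c1.b1"]] <- numeric(hW)
  p[["c1.W2"]] <- glorot(hW, 2L); p[["c1.b2"]] <- numeric(2L)
  p[["p.W1"]] <- glorot(hW, hW); p[["p.b1"]] <- numeric(hW)
  p[["p.W2"]] <- glorot(hW, cfg$n_patients); p[["p.b2"]] <- numeric(cfg$n_patients)
  p[["c2.W1"]] <- glorot(d_all, cfg$h_c2); p[["c2.b1"]] <- numeric(cfg$h_c2)
  p[["c2.W2"]] <- glorot(cfg$h_c2, 2L); p[["c2.b2"]] <- numeric(2L)
  for (nm in c("g", "l1", "l2")) {
    mlp <- mlp3_init(d_all, cfg$disc_widths, cfg$n_patients)
    for (w in names(mlp)) p[[paste0(nm, ".", w)]] <- mlp[[w]]
  }
  state <- list(
    emb_bn = list(mean = numeric(E), var = rep(1, E)),
    temp_bn = lapply(1:5, function(i) list(mean = numeric(C + E),
                                           var = rep(1, C + E)))
  )
  list(params = p, centers = matrix(0, 2L, cfg$h_c2), state = state,
       band_sizes = bands)
}

# Shared front-end forward: embedding block -> (spectral, temporal)
# branches -> SE combination. Returns f_all plus every cache the backward
# needs. X: [N x C x T].
frontend_forward <- function(params, state, X, cfg, train = TRUE,
                             bn_momentum = 0.1) {
  d <- dim(X); N <- d[1]; C <- d[2]; Tt <- d[3]
  Cp <- C + cfg$E
  W <- cfg$W

  Xflat <- matrix(X, N * C, Tt)
  emb <- conv1d_forward(Xflat, params[["emb.K"]], params[["emb.b"]], N)
  ebn <- bn_mat_forward(emb$Y, params[["emb.bn.gamma"]], params[["emb.bn.beta"]],
                        state$emb_bn, N, train = train,
                        momentum = bn_momentum)
  state$emb_bn <- ebn$running
  # flattened layout [N*Cp x T], sample-fastest rows: raw channels first,
  # then the embedding channels (channel-wise concatenation)
  Xemb <- rbind(Xflat, ebn$Y)

  # spectral branch: batched 5-level pyramid over every (segment, channel)
  pyr <- dwt_pyramid_mat(Xemb, cfg$levels)
  band_names <- names(pyr$bands)
  f_spec <- list(); spec_in <- list()
  for (b in band_names) {
    nb <- ncol(pyr$bands[[b]])
    Fb <- matrix(array(pyr$bands[[b]], c(N, Cp * nb)), N)  # [N x Cp*nb]
    spec_in[[b]] <- Fb
    f_spec[[b]] <- linear_forward(Fb, params[[paste0("spec.", b, ".W")]],
                                  params[[paste0("spec.", b, ".b")]])
  }

  # temporal branch: five depthwise conv -> BN -> ELU -> pool -> channel mean
  f_temp <- list(); temp_cache <- list()
  for (i in 1:5) {
    cv <- dwconv_forward(Xemb, params[[paste0("temp", i, ".K")]],
                         params[[paste0("temp", i, ".b")]], N)
    bn <- bn_mat_forward(cv$Y, params[[paste0("temp", i, ".bn.gamma")]],
                         params[[paste0("temp", i, ".bn.beta")]],
                         state$temp_bn[[i]], N, train = train,
                         momentum = bn_momentum)
    state$temp_bn[[i]] <- bn$running
    act <- elu_forward(bn$Y)
    P <- pool_matrix(cv$Tout, W)
    pooled <- act %*% P                                     # [N*Cp x W]
    f_temp[[i]] <- rowsum(pooled, rep(seq_len(N), Cp)) / Cp # [N x W]
    temp_cache[[i]] <- list(cv = cv, bn = bn, act = act, P = P)
  }

  # groupwise spectral/temporal pairing + squeeze-and-excitation
  groups <- lapply(1:5, function(b) cbind(f_spec[[b]], f_temp[[b]]))
  z <- vapply(groups, rowMeans, numeric(N))
  if (N == 1L) z <- matrix(z, 1L)
  a1 <- linear_forward(z, params[["se.W1"]], params[["se.b1"]])
  r1 <- pmax(a1, 0)
  gates <- sigmoid(linear_forward(r1, params[["se.W2"]], params[["se.b2"]]))
  f_all <- do.call(cbind, lapply(1:5, function(b) groups[[b]] * gates[, b]))

  list(f_all = f_all, state = state,
       cache = list(emb = emb, ebn = ebn, Xemb = Xemb, pyr = pyr,
                    spec_in = spec_in, f_spec = f_spec, f_temp = f_temp,
                    temp_cache = temp_cache, groups = groups, z = z,
                    Xflat = Xflat,
                    a1 = a1, r1 = r1, gates = gates,
                    N = N, C = C, Cp = Cp, Tt = Tt, band_names = band_names))
}

# Backward through the front-end given d(f_all). Returns parameter grads
# (into `grads`, an environment-free named list) only; input grads are
# discarded.
frontend_backward <- function(df_all, params, cfg, fc) {
  N <- fc$N; C <- fc$C; Cp <- fc$Cp; Tt <- fc$Tt
  W <- cfg$W
  grads <- list()

  # SE backward
  dgroups <- vector("list", 5L)
  dgates <- matrix(0, N, 5L)
  for (b in 1:5) {
    cols <- ((b - 1L) * 2L * W + 1L):(b * 2L * W)
    dsc <- df_all[, cols, drop = FALSE]
    dgroups[[b]] <- dsc * fc$gates[, b]
    dgates[, b] <- rowSums(dsc * fc$groups[[b]])
  }
  da2 <- dgates * fc$gates * (1 - fc$gates)
  lb2 <- linear_backward(da2, fc$r1, params[["se.W2"]])
  grads[["se.W2"]] <- lb2$dW; grads[["se.b2"]] <- lb2$db
  dr1 <- lb2$dX * (fc$a1 > 0)
  lb1 <- linear_backward(dr1, fc$z, params[["se.W1"]])
  grads[["se.W1"]] <- lb1$dW; grads[["se.b1"]] <- lb1$db
  dz <- lb1$dX
  for (b in 1:5) {
    dgroups[[b]] <- dgroups[[b]] + dz[, b] / (2 * W)
  }

  dXemb <- matrix(0, N * Cp, Tt)

  # spectral path
  dbands <- list()
  for (b in 1:5) {
    bn_name <- fc$band_names[b]
    dspec <- dgroups[[b]][, 1:W, drop = FALSE]
    lb <- linear_backward(dspec, fc$spec_in[[bn_name]],
                          params[[paste0("spec.", bn_name, ".W")]])
    grads[[paste0("spec.", bn_name, ".W")]] <- lb$dW
    grads[[paste0("spec.", bn_name, ".b")]] <- lb$db
    nb <- ncol(fc$pyr$bands[[bn_name]])
    dbands[[bn_name]] <- matrix(array(lb$dX, c(N, Cp, nb)), N * Cp)
  }
  dXemb <- dXemb + dwt_pyramid_mat_backward(dbands, fc$pyr)

  # temporal path
  for (i in 1:5) {
    tc <- fc$temp_cache[[i]]
    dtemp <- dgroups[[i]][, (W + 1L):(2L * W), drop = FALSE]
    dpooled <- dtemp[rep(seq_len(N), Cp), , drop = FALSE] / Cp
    dact <- dpooled %*% t(tc$P)
    dbnY <- elu_backward(dact, tc$act, tc$bn$Y)
    bb <- bn_mat_backward(dbnY, tc$bn, params[[paste0("temp", i, ".bn.gamma")]])
    grads[[paste0("temp", i, ".bn.gamma")]] <- bb$dgamma
    grads[[paste0("temp", i, ".bn.beta")]] <- bb$dbeta
    cb <- dwconv_backward(bb$dX, tc$cv, fc$Xemb, params[[paste0("temp", i, ".K")]])
    grads[[paste0("temp", i, ".K")]] <- cb$dK
    grads[[paste0("temp", i, ".b")]] <- cb$db
    dXemb <- dXemb + cb$dX
  }

  # embedding block backward (original-data channels carry no parameters)
  dEmbY <- dXemb[(N * C + 1L):(N * Cp), , drop = FALSE]
  bb <- bn_mat_backward(dEmbY, fc$ebn, params[["emb.bn.gamma"]])
  grads[["emb.bn.gamma"]] <- bb$dgamma
  grads[["emb.bn.beta"]] <- bb$dbeta
  cb <- conv1d_backward(bb$dX, fc$emb, fc$Xflat, params[["emb.K"]])
  grads[["emb.K"]] <- cb$dK
  grads[["emb.b"]] <- cb$db
  grads
}

mlp3_forward <- function(X, params, prefix) {
  g <- function(w) params[[paste0(prefix, ".", w)]]
  a1 <- linear_forward(X, g("W1"), g("b1")); h1 <- elu_forward(a1)
  a2 <- linear_forward(h1, g("W2"), g("b2")); h2 <- elu_forward(a2)
  logits <- linear_forward(h2, g("W3"), g("b3"))
  list(a1 = a1, h1 = h1, a2 = a2, h2 = h2, logits = logits)
}

mlp3_backward <- function(dlogits, X, fwd, params, prefix) {
  g <- function(w) params[[paste0(prefix, ".", w)]]
  grads <- list()
  lb3 <- linear_backward(dlogits, fwd$h2, g("W3"))
  grads[[paste0(prefix, ".W3")]] <- lb3$dW
  grads[[paste0(prefix, ".b3")]] <- lb3$db
  da2 <- elu_backward(lb3$dX, fwd$h2, fwd$a2)
  lb2 <- linear_backward(da2, fwd$h1, g("W2"))
  grads[[paste0(prefix, ".W2")]] <- lb2$dW
  grads[[paste0(prefix, ".b2")]] <- lb2$db
  da1 <- elu_backward(lb2$dX, fwd$h1, fwd$a1)
  lb1 <- linear_backward(da1, X, g("W1"))
  grads[[paste0(prefix, ".W1")]] <- lb1$dW
  grads[[paste0(prefix, ".b1")]] <- lb1$db
  list(grads = grads, dX = lb1$dX)
}

# Full forward pass. y in {0,1}, d in 1..P (NULL for pure prediction).
# Returns losses, per-head caches and the updated BN state.
model_forward <- function(params, state, centers, X, y, d, cfg,
                          train = TRUE, heads = TRUE, bn_momentum = 0.1) {
  fe <- frontend_forward(params, state, X, cfg, train = train,
                         bn_momentum = bn_momentum)
  f_all <- fe$f_all
  hW <- ncol(f_all) %/% 2L
  Fc <- f_all[, 1:hW, drop = FALSE]
  Fp <- f_all[, (hW + 1L):(2L * hW), drop = FALSE]
  Fprime <- cbind(Fc, Fp)             # recombination, category half first

  # main category classifier (its ELU activations feed the center loss)
  a_pen <- linear_forward(Fprime, params[["c2.W1"]], params[["c2.b1"]])
  pen <- elu_forward(a_pen)
  logits2 <- linear_forward(pen, params[["c2.W2"]], params[["c2.b2"]])
  out <- list(state = fe$state, f_all = f_all, Fc = Fc, Fp = Fp,
              Fprime = Fprime, pen = pen, a_pen = a_pen, logits2 = logits2,
              fe_cache = fe$cache)
  sm2 <- NULL
  if (!is.null(y)) {
    sm2 <- softmax_ce_forward(logits2, y + 1L)
    out$L_cls_2 <- sm2$loss
    out$probs2 <- sm2$probs
    diff_cent <- pen - centers[y + 1L, , drop = FALSE]
    # per-sample (mean) form of the center-loss sum, so the joint objective
    # keeps commensurate term scales under full-batch training
    out$L_cent <- 0.5 * sum(diff_cent^2) / nrow(pen)
    out$diff_cent <- diff_cent
  }
  if (!heads || is.null(y) || is.null(d)) return(out)

  N <- nrow(f_all)
  if (cfg$use_separation) {
    a1 <- linear_forward(Fc, params[["c1.W1"]], params[["c1.b1"]])
    h1 <- elu_forward(a1)
    logits1 <- linear_forward(h1, params[["c1.W2"]], params[["c1.b2"]])
    sm1 <- softmax_ce_forward(logits1, y + 1L)
    ap <- linear_forward(Fp, params[["p.W1"]], params[["p.b1"]])
    hp <- elu_forward(ap)
    logitsp <- linear_forward(hp, params[["p.W2"]], params[["p.b2"]])
    smp <- softmax_ce_forward(logitsp, d)
    dist2 <- rowSums((Fc - Fp)^2)
    clipped <- dist2 > cfg$clip_divergence
    out$sep <- list(a1 = a1, h1 = h1, sm1 = sm1, ap = ap, hp = hp,
                    smp = smp, clipped = clipped)
    out$L_cls_1 <- sm1$loss
    out$L_p <- smp$loss
    out$L_max_divergence <- -mean(pmin(dist2, cfg$clip_divergence))
  }
  if (cfg$use_global) {
    gfwd <- mlp3_forward(Fprime, params, "g")      # GRL: identity forward
    smg <- softmax_ce_forward(gfwd$logits, d)
    out$glob <- list(fwd = gfwd, sm = smg)
    out$L_global <- smg$loss
  }
  if (cfg$use_local) {
    masks <- matrix(0, N, 2L)
    if (cfg$local_mask == "true") {
      masks[cbind(seq_len(N), y + 1L)] <- 1
    } else {
      masks <- sm2$probs                            # detached posteriors
    }
    loc <- vector("list", 2L)
    L_local <- 0
    for (k in 1:2) {
      Zk <- Fprime * masks[, k]
      lfwd <- mlp3_forward(Zk, params, paste0("l", k))
      sml <- softmax_ce_forward(lfwd$logits, d)
      loc[[k]] <- list(Zk = Zk, fwd = lfwd, sm = sml)
      L_local <- L_local + sml$loss
    }
    out$loc <- loc
    out$masks <- masks
    out$L_local <- L_local
  }
  out
}

# Backward pass for the joint objective. lambda weights the auxiliary and
# center terms of the joint objective; grl_lambda scales the reversed gradient flowing
# from the adversaries into the features (the GRL; pass -1 to disable the
# reversal for diagnostics). Discriminator parameters receive the plain
# (positive) gradients of their own cross-entropies, which realizes the
# arg-max side of the minimax.
model_backward <- function(fw, params, centers, y, d, cfg,
                           lambda = 0.1, grl_lambda = lambda) {
  grads <- list()
  N <- nrow(fw$f_all)
  hW <- ncol(fw$f_all) %/% 2L

  # main classifier + center loss
  dlogits2 <- softmax_ce_backward(fw$probs2, y + 1L, weight = 1)
  lb <- linear_backward(dlogits2, fw$pen, params[["c2.W2"]])
  grads[["c2.W2"]] <- lb$dW; grads[["c2.b2"]] <- lb$db
  dpen <- lb$dX + (lambda / N) * fw$diff_cent
  da_pen <- elu_backward(dpen, fw$pen, fw$a_pen)
  lb <- linear_backward(da_pen, fw$Fprime, params[["c2.W1"]])
  grads[["c2.W1"]] <- lb$dW; grads[["c2.b1"]] <- lb$db
  dFprime <- lb$dX

  if (cfg$use_separation) {
    sep <- fw$sep
    dlog1 <- softmax_ce_backward(sep$sm1$probs, y + 1L, weight = lambda)
    lb2 <- linear_backward(dlog1, sep$h1, params[["c1.W2"]])
    grads[["c1.W2"]] <- lb2$dW; grads[["c1.b2"]] <- lb2$db
    da1 <- elu_backward(lb2$dX, sep$h1, sep$a1)
    lb1 <- linear_backward(da1, fw$Fc, params[["c1.W1"]])
    grads[["c1.W1"]] <- lb1$dW; grads[["c1.b1"]] <- lb1$db
    dFc <- lb1$dX

    dlogp <- softmax_ce_backward(sep$smp$probs, d, weight = lambda)
    lb2 <- linear_backward(dlogp, sep$hp, params[["p.W2"]])
    grads[["p.W2"]] <- lb2$dW; grads[["p.b2"]] <- lb2$db
    dap <- elu_backward(lb2$dX, sep$hp, sep$ap)
    lb1 <- linear_backward(dap, fw$Fp, params[["p.W1"]])
    grads[["p.W1"]] <- lb1$dW; grads[["p.b1"]] <- lb1$db
    dFp <- lb1$dX

    # max-divergence: L = -sum min(||Fc - Fp||^2, clip)
    dd <- fw$Fc - fw$Fp
    if (any(sep$clipped)) dd[sep$clipped, ] <- 0
    dFc <- dFc + (lambda / N) * (-2) * dd
    dFp <- dFp + (lambda / N) * 2 * dd

    dFprime[, 1:hW] <- dFprime[, 1:hW, drop = FALSE] + dFc
    dFprime[, (hW + 1L):(2L * hW)] <-
      dFprime[, (hW + 1L):(2L * hW), drop = FALSE] + dFp
  }

  if (cfg$use_global) {
    dlogg <- softmax_ce_backward(fw$glob$sm$probs, d, weight = 1)
    mb <- mlp3_backward(dlogg, fw$Fprime, fw$glob$fwd, params, "g")
    grads <- c(grads, mb$grads)
    dFprime <- dFprime + (-grl_lambda) * mb$dX
  }
  if (cfg$use_local) {
    for (k in 1:2) {
      lc <- fw$loc[[k]]
      dlogl <- softmax_ce_backward(lc$sm$probs, d, weight = 1)
      mb <- mlp3_backward(dlogl, lc$Zk, lc$fwd, params, paste0("l", k))
      grads <- c(grads, mb$grads)
      dFprime <- dFprime + (-grl_lambda) * (mb$dX * fw$masks[, k])
    }
  }

  fe_grads <- frontend_backward(dFprime, params, cfg, fw$fe_cache)
  c(grads, fe_grads)
}
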