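# Finite-difference validation of the hand-written backward pass, and the
# gradient-reversal contracts.

fd_check <- function(objfun, params, grads, names_to_check, n_coord = 3,
                     eps = 1e-5, tol = 1e-4) {
  set.seed(99)
  worst <- 0
  for (nm in names_to_check) {
    g_an <- grads[[nm]]
    idx <- sample(length(g_an), min(n_coord, length(g_an)))
    for (i in idx) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (objfun(p1) - objfun(p2)) / (2 * eps)
      an <- g_an[i]
      rel <- if (abs(num) < 1e-9 && abs(an) < 1e-9) 0 else
        abs(num - an) / max(abs(num), abs(an), 1e-9)
      worst <- max(worst, rel)
    }
  }
  worst
}

setup_tiny <- function() {
  cfg <- tiny_config()
  init <- seizdg:::init_model(cfg, seed = 7)
  ti <- tiny_inputs()
  list(cfg = cfg, params = init$params, centers = init$centers + 0.1,
       state = init$state, X = ti$X, y = ti$y, d = ti$d)
}

test_that("backward pass matches finite differences for every subnet", {
  s <- setup_tiny()
  lambda <- 0.1; grl <- 0.1
  fw <- seizdg:::model_forward(s$params, s$state, s$centers, s$X, s$y, s$d,
                               s$cfg, TRUE, TRUE)
  grads <- seizdg:::model_backward(fw, s$params, s$centers, s$y, s$d, s$cfg,
                                   lambda, grl)
  # effective objective for the feature path and all non-adversarial heads
  obj_f <- function(p) {
    f <- seizdg:::model_forward(p, s$state, s$centers, s$X, s$y, s$d,
                                s$cfg, TRUE, TRUE)
    f$L_cls_2 + lambda * (f$L_cent + f$L_cls_1 + f$L_p + f$L_max_divergence) -
      grl * (f$L_global + f$L_local)
  }
  non_adv <- grep("^(emb|spec|temp|se|c1|c2|p)\\.", names(s$params),
                  value = TRUE)
  expect_lt(fd_check(obj_f, s$params, grads, non_adv), 1e-4)
  # discriminators minimize their own cross-entropies
  obj_g <- function(p) {
    f <- seizdg:::model_forward(p, s$state, s$centers, s$X, s$y, s$d,
                                s$cfg, TRUE, TRUE)
    f$L_global + f$L_local
  }
  disc <- grep("^(g|l1|l2)\\.", names(s$params), value = TRUE)
  expect_lt(fd_check(obj_g, s$params, grads, disc), 1e-4)
})

test_that("gradient reversal scales the reversed path by -lambda_grl", {
  s <- setup_tiny()
  fw <- seizdg:::model_forward(s$params, s$state, s$centers, s$X, s$y, s$d,
                               s$cfg, TRUE, TRUE)
  # lambda = 0 isolates the adversarial path into the front-end; a GRL
  # strength of -1 turns the reversal off (factor -(-1) = +1)
  g_rev <- seizdg:::model_backward(fw, s$params, s$centers, s$y, s$d, s$cfg,
                                   lambda = 0, grl_lambda = 0.37)
  g_fwd <- seizdg:::model_backward(fw, s$params, s$centers, s$y, s$d, s$cfg,
                                   lambda = 0, grl_lambda = -1)
  for (nm in grep("^(spec|temp|se|emb)\\.", names(s$params), value = TRUE)) {
    adv_rev <- g_rev[[nm]]
    adv_fwd <- g_fwd[[nm]]
    # subtract the shared classifier path (lambda = 0 leaves L_cls_2)
    # by linearity: grads = cls_part + factor * adv_part
    # rev: cls - 0.37 adv ; fwd: cls + adv  =>  rev - cls = -0.37 (fwd - cls)
    g0 <- seizdg:::model_backward(fw, s$params, s$centers, s$y, s$d, s$cfg,
                                  lambda = 0, grl_lambda = 0)[[nm]]
    expect_equal(adv_rev - g0, -0.37 * (adv_fwd - g0), tolerance = 1e-10)
  }
  # discriminator updates are unaffected by the reversal strength
  expect_equal(g_rev[["g.W1"]], g_fwd[["g.W1"]], tolerance = 1e-12)
})

test_that("lambda = 0 cuts auxiliary and adversarial gradients to theta_f", {
  s <- setup_tiny()
  fw <- seizdg:::model_forward(s$params, s$state, s$centers, s$X, s$y, s$d,
                               s$cfg, TRUE, TRUE)
  g <- seizdg:::model_backward(fw, s$params, s$centers, s$y, s$d, s$cfg,
                               lambda = 0, grl_lambda = 0)
  # discriminators keep their own nonzero gradients
  expect_gt(sum(abs(g[["g.W1"]])), 0)
  expect_gt(sum(abs(g[["l1.W1"]])), 0)
  # front-end gradient equals the pure-classifier gradient
  cfg_plain <- tiny_config(use_separation = FALSE, use_global = FALSE,
                           use_local = FALSE)
  fw_p <- seizdg:::model_forward(s$params, s$state, s$centers, s$X, s$y, s$d,
                                 cfg_plain, TRUE, TRUE)
  g_p <- seizdg:::model_backward(fw_p, s$params, s$centers, s$y, s$d,
                                 cfg_plain, lambda = 0, grl_lambda = 0)
  for (nm in grep("^(spec|temp|se|emb)\\.", names(s$params), value = TRUE)) {
    expect_equal(g[[nm]], g_p[[nm]], tolerance = 1e-12)
  }
})

test_that("local loss with all-ones masks degenerates to twice the global loss", {
  s <- setup_tiny()
  # force both local discriminators to share the global one's parameters
  p <- s$params
  for (w in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    p[[paste0("l1.", w)]] <- p[[paste0("g.", w)]]
    p[[paste0("l2.", w)]] <- p[[paste0("g.", w)]]
  }
  fw <- seizdg:::model_forward(p, s$state, s$centers, s$X, s$y, s$d,
                               s$cfg, TRUE, TRUE)
  # replicate Eq. 10 with masks identically one: each class term equals the
  # global cross-entropy, so the sum is 2 x L_global
  Z <- fw$Fprime
  l1 <- seizdg:::mlp3_forward(Z, p, "l1")
  ce <- seizdg:::softmax_ce_forward(l1$logits, s$d)$loss
  expect_equal(2 * ce, 2 * fw$L_global, tolerance = 1e-12)
})

test_that("zero-input class contributes a feature-independent local term", {
  s <- setup_tiny()
  y_all1 <- rep(1L, length(s$y))          # batch entirely of class 1
  fw <- seizdg:::model_forward(s$params, s$state, s$centers, s$X, y_all1,
                               s$d, s$cfg, TRUE, TRUE)
  # G_l1 (class-0 discriminator) receives all-zero inputs
  expect_true(all(fw$loc[[1]]$Zk == 0))
  # its loss is the bias-softmax cross-entropy, the same for any input data
  X2 <- s$X + 5
  fw2 <- seizdg:::model_forward(s$params, s$state, s$centers, X2, y_all1,
                                s$d, s$cfg, TRUE, TRUE)
  expect_equal(fw$loc[[1]]$sm$loss, fw2$loc[[1]]$sm$loss, tolerance = 1e-12)
})

test_that("uniform discriminators give L_local = 2 ln(n_patients)", {
  s <- setup_tiny()
  p <- s$params
  # zero all discriminator weights -> uniform softmax everywhere
  for (nm in grep("^(g|l1|l2)\\.", names(p), value = TRUE)) p[[nm]][] <- 0
  fw <- seizdg:::model_forward(p, s$state, s$centers, s$X, s$y, s$d,
                               s$cfg, TRUE, TRUE)
  expect_equal(fw$L_local, 2 * log(3), tolerance = 1e-12)
  expect_equal(fw$L_global, log(3), tolerance = 1e-12)
})
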