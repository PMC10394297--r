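test_that("training is reproducible and records a full-batch history", {
  b <- small_cohort_batches()[1:2]
  cfg <- model_config(n_channels = 3, n_patients = 2, W = 4, E = 1, k = 16,
                      h_c2 = 8, disc_widths = c(8, 6), clip_divergence = 100)
  tc <- train_config(epochs = 5, seed = 42)
  m1 <- train_model(b, cfg, tc)
  m2 <- train_model(b, cfg, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$history), 5L)           # one row (one step) per epoch
  expect_equal(m1$history$epoch, 1:5)
  expect_true(all(is.finite(m1$history$L_sum)))
  # a different seed changes the trajectory
  m3 <- train_model(b, cfg, train_config(epochs = 5, seed = 43))
  expect_false(identical(m1$history, m3$history))
  # L_sum column satisfies the joint-objective identity
  for (ep in c(1L, 5L)) {
    parts <- as.list(m1$history[ep, ])
    expect_equal(m1$history$L_sum[ep], total_loss(parts, tc$lambda))
  }
})

test_that("training reduces the main classification loss (learning happens)", {
  b <- small_cohort_batches()
  cfg <- model_config(n_channels = 3, n_patients = 4, W = 4, E = 1, k = 16,
                      h_c2 = 16, disc_widths = c(16, 8), clip_divergence = 100)
  wins <- 0
  for (seed in 1:5) {
    m <- train_model(b, cfg, train_config(epochs = 30, lr_network = 0.02,
                                          grl_lambda = 0.5, seed = seed))
    wins <- wins + (m$history$L_cls_2[30] < m$history$L_cls_2[1])
  }
  expect_gte(wins, 3)
})

test_that("configuration errors are caught before any training", {
  b <- small_cohort_batches()[1:2]
  cfg1 <- model_config(n_channels = 3, n_patients = 1, W = 4, E = 1, k = 16)
  expect_error(train_model(b[1], cfg1), class = "seizdg_config_error")
  cfg3 <- model_config(n_channels = 3, n_patients = 3, W = 4, E = 1, k = 16)
  expect_error(train_model(b, cfg3), class = "seizdg_config_error")
  expect_error(train_config(epochs = 0), class = "seizdg_validation_error")
  expect_error(model_config(n_channels = 3, n_patients = 2, k = 12),
               class = "seizdg_config_error")
})

test_that("saved models reload to identical predictions", {
  b <- small_cohort_batches()[1:2]
  cfg <- model_config(n_channels = 3, n_patients = 2, W = 4, E = 1, k = 16,
                      h_c2 = 8, disc_widths = c(8, 6), clip_divergence = 100)
  m <- train_model(b, cfg, train_config(epochs = 3, seed = 1))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  p1 <- predict(m, b[[1]])
  p2 <- predict(m2, b[[1]])
  expect_identical(p1, p2)
  unlink(path)
})

test_that("grid search scores every configuration and avoids sabotage", {
  b <- small_cohort_batches()[1:3]
  cfgf <- function(n) model_config(n_channels = 3, n_patients = n, W = 4,
                                   E = 1, k = 16, h_c2 = 8,
                                   disc_widths = c(8, 6),
                                   clip_divergence = 100)
  base <- train_config(epochs = 3, seed = 1)
  g1 <- grid_search(b, list(lambda = 0.1), base, cfgf)
  expect_equal(nrow(g1$scores), 1L)
  expect_equal(g1$best$lambda, 0.1)
  base2 <- train_config(epochs = 15, lr_network = 0.02, seed = 1)
  g2 <- grid_search(b, list(lr_network = c(0.02, 1e6)), base2, cfgf)
  expect_equal(nrow(g2$scores), 2L)
  expect_equal(g2$best$lr_network, 0.02)
  expect_error(grid_search(b, list(), base, cfgf),
               class = "seizdg_validation_error")
})

test_that("discriminator updates move along the arg-max direction", {
  # one Adam step with only the global adversary active: theta_g's update
  # direction must match directly MINIMIZING L_global (equivalently
  # maximizing the -lambda L_global term of the joint objective)
  cfg <- tiny_config(use_separation = FALSE, use_local = FALSE)
  init <- seizdg:::init_model(cfg, seed = 3)
  ti <- tiny_inputs()
  fw <- seizdg:::model_forward(init$params, init$state, init$centers + 0.1,
                               ti$X, ti$y, ti$d, cfg, TRUE, TRUE)
  g <- seizdg:::model_backward(fw, init$params, init$centers + 0.1, ti$y,
                               ti$d, cfg, lambda = 0.1, grl_lambda = 0.1)
  # numeric direction of decreasing L_global for a few coordinates
  set.seed(12)
  idx <- sample(length(init$params[["g.W3"]]), 4)
  eps <- 1e-5
  for (i in idx) {
    p1 <- init$params; p1[["g.W3"]][i] <- p1[["g.W3"]][i] + eps
    p2 <- init$params; p2[["g.W3"]][i] <- p2[["g.W3"]][i] - eps
    f1 <- seizdg:::model_forward(p1, init$state, init$centers + 0.1, ti$X,
                                 ti$y, ti$d, cfg, TRUE, TRUE)$L_global
    f2 <- seizdg:::model_forward(p2, init$state, init$centers + 0.1, ti$X,
                                 ti$y, ti$d, cfg, TRUE, TRUE)$L_global
    num <- (f1 - f2) / (2 * eps)
    if (abs(num) > 1e-8) expect_equal(sign(g[["g.W3"]][i]), sign(num))
  }
})

test_that("center updates follow their dedicated optimizer", {
  b <- small_cohort_batches()[1:2]
  cfg <- model_config(n_channels = 3, n_patients = 2, W = 4, E = 1, k = 16,
                      h_c2 = 8, disc_widths = c(8, 6), clip_divergence = 100)
  m1 <- train_model(b, cfg, train_config(epochs = 4, seed = 1))
  expect_false(all(m1$centers == 0))          # centers moved from zero init
  expect_equal(dim(m1$centers), c(2L, 8L))
  # centers move toward the class feature means
  db <- seizdg:::bind_batches(b)
  fw <- seizdg:::model_forward(m1$params, m1$state, m1$centers, db$X, db$y,
                               db$d, m1$config, train = FALSE, heads = FALSE)
  for (k in 1:2) {
    mu <- colMeans(fw$pen[db$y == (k - 1L), , drop = FALSE])
    expect_lt(sqrt(sum((m1$centers[k, ] - mu)^2)), sqrt(sum(mu^2)) + 1)
  }
})
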