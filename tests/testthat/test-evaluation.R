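test_that("metric formulas reproduce the printed examples", {
  m <- compute_metrics(list(TP = 9, TN = 9, FP = 1, FN = 1))
  expect_equal(unname(m), c(0.9, 0.9, 0.9))
  expect_equal(unname(compute_metrics(list(TP = 5, TN = 3, FP = 2, FN = 0))["SN"]), 1)
  m2 <- compute_metrics(list(TP = 0, TN = 4, FP = 1, FN = 0))
  expect_true(is.na(m2["SN"]))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               class = "seizdg_validation_error")
})

test_that("metrics agree with brute-force counting on random predictions", {
  set.seed(21)
  for (case in 1:1000) {
    n <- sample(3:40, 1)
    y <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    cc <- confusion_counts(y, pred)
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
    m <- compute_metrics(cc)
    expect_equal(unname(m["ACC"]), mean(y == pred))
    if (any(y == 1)) expect_equal(unname(m["SN"]), mean(pred[y == 1] == 1))
    if (any(y == 0)) expect_equal(unname(m["SP"]), mean(pred[y == 0] == 0))
  }
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  set.seed(22)
  for (case in 1:50) {
    n <- sample(10:60, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- rnorm(n) + y * runif(1, 0, 2)
    auc <- roc_curve_auc(scores, y)$auc
    # rank-statistic oracle
    r <- rank(scores)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    u <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-10)
  }
})

test_that("AUC has the documented boundary behavior", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_curve_auc(c(0.1, 0.2, 0.8, 0.9), y)$auc, 1)
  expect_equal(roc_curve_auc(c(0.9, 0.8, 0.2, 0.1), y)$auc, 0)
  set.seed(23)
  y_big <- sample(0:1, 4000, replace = TRUE)
  expect_equal(roc_curve_auc(rnorm(4000), y_big)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_curve_auc(rnorm(5), rep(1, 5)),
               class = "seizdg_validation_error")
})

test_that("our AUC matches an established ROC implementation", {
  set.seed(24)
  y <- sample(0:1, 80, replace = TRUE)
  s <- rnorm(80) + y
  ours <- roc_curve_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("LOSO harness trains one fold per patient and never leaks", {
  b <- small_cohort_batches()[1:3]
  cfgf <- function(n) model_config(n_channels = 3, n_patients = n,
                                   W = 4, E = 1, k = 16, h_c2 = 8,
                                   disc_widths = c(8, 6),
                                   clip_divergence = 100)
  rep_ <- loso_cross_validation(b, cfgf, train_config(epochs = 3, seed = 1))
  expect_equal(nrow(rep_$per_patient), 3L)
  for (f in rep_$folds) {
    expect_false(f$held_out %in% f$trained_on)
    expect_length(f$trained_on, 2L)
  }
  # aggregate equals recomputation from the per-patient rows
  expect_equal(rep_$average["ACC", "mean"], mean(rep_$per_patient$ACC))
  expect_equal(rep_$average["ACC", "sd"], stats::sd(rep_$per_patient$ACC))
  expect_error(loso_cross_validation(b[1:2], cfgf),
               class = "seizdg_validation_error")
})

test_that("ablation variants toggle exactly the intended loss terms", {
  b <- small_cohort_batches()[1:3]
  cfgf <- variant_config(list(n_channels = 3, W = 4, E = 1, k = 16,
                              h_c2 = 8, disc_widths = c(8, 6),
                              clip_divergence = 100))
  tc <- train_config(epochs = 2, seed = 1)
  m_full <- train_model(b[1:2], cfgf(2, "full"), tc)
  m_dann <- train_model(b[1:2], cfgf(2, "dann_only"), tc)
  m_mada <- train_model(b[1:2], cfgf(2, "mada_only"), tc)
  m_nosep <- train_model(b[1:2], cfgf(2, "no_separation"), tc)
  expect_true(all(!is.na(m_full$history[, c("L_cls_1", "L_p",
                                            "L_max_divergence", "L_global",
                                            "L_local")])))
  expect_true(all(is.na(m_dann$history$L_local)))
  expect_false(anyNA(m_dann$history$L_global))
  expect_true(all(is.na(m_mada$history$L_global)))
  expect_false(anyNA(m_mada$history$L_local))
  expect_true(all(is.na(m_nosep$history[, c("L_cls_1", "L_p",
                                            "L_max_divergence")])))
})

test_that("t-SNE export is deterministic and row-complete", {
  b <- small_cohort_batches()[[1]]
  cfg <- model_config(n_channels = 3, n_patients = 2, W = 4, E = 1, k = 16,
                      h_c2 = 8, disc_widths = c(8, 6), clip_divergence = 100)
  m <- train_model(small_cohort_batches()[1:2], cfg,
                   train_config(epochs = 2, seed = 1))
  sub <- b
  keep <- seq_len(30)
  sub$x <- b$x[keep, , , drop = FALSE]; sub$n <- 30L
  sub$y <- b$y[keep]; sub$patient_label <- b$patient_label[keep]
  sub$segment_index <- b$segment_index[keep]; sub$start <- b$start[keep]
  e1 <- tsne_export(m, sub, perplexity = 8, seed = 3)
  e2 <- tsne_export(m, sub, perplexity = 8, seed = 3)
  expect_equal(nrow(e1), 30L)
  expect_identical(e1, e2)
  expect_equal(e1$category, sub$y)
  m$trained <- FALSE
  expect_error(tsne_export(m, sub), class = "seizdg_state_error")
})

test_that("t-SNE separates well-separated clusters", {
  set.seed(25)
  X <- rbind(matrix(rnorm(40 * 4), 40), matrix(rnorm(40 * 4) + 8, 40))
  emb <- tsne_embed(X, perplexity = 10, seed = 1)
  lab <- rep(1:2, each = 40)
  sil <- cluster::silhouette(lab, stats::dist(emb))
  expect_gt(mean(sil[, 3]), 0.5)
})
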