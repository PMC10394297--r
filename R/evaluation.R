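# Leave-one-patient-out evaluation harness, metrics, ROC/AUC, ablations.

#' Confusion counts from labels and predictions
#'
#' Seizure (label 1) is the positive class.
#'
#' @param y true 0/1 labels.
#' @param pred predicted 0/1 labels.
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y, pred) {
  list(TP = sum(y == 1L & pred == 1L), TN = sum(y == 0L & pred == 0L),
       FP = sum(y == 0L & pred == 1L), FN = sum(y == 1L & pred == 0L))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SN = TP/(TP+FN)`, `SP = TN/(TN+FP)`.
#' A zero denominator yields `NA` (undefined, not 0).
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector `ACC`, `SN`, `SP`.
#' @export
#' @examples
#' compute_metrics(list(TP = 9, TN = 9, FP = 1, FN = 1))  # all 0.9
compute_metrics <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) {
    stop_seizdg("all confusion counts are zero", class = "seizdg_validation_error")
  }
  sn_den <- counts$TP + counts$FN
  sp_den <- counts$TN + counts$FP
  c(ACC = (counts$TP + counts$TN) / tot,
    SN = if (sn_den > 0) counts$TP / sn_den else NA_real_,
    SP = if (sp_den > 0) counts$TN / sp_den else NA_real_)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all unique scores as thresholds (predict positive when
#' `score >= t`) and integrates the curve with the trapezoidal rule. The
#' result equals the normalized Mann-Whitney U statistic.
#'
#' @param scores per-segment seizure scores (higher = more seizure-like).
#' @param y true 0/1 labels; both classes must be present.
#' @return list with `curve` (data frame `fpr`, `tpr`, `threshold`) and
#'   scalar `auc`.
#' @export
roc_curve_auc <- function(scores, y) {
  y <- as.integer(y)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_seizdg("ROC needs both classes present", class = "seizdg_validation_error")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    p <- scores >= thr[i]
    tpr[i] <- sum(p & y == 1L) / n_pos
    fpr[i] <- sum(p & y == 0L) / n_neg
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Leave-one-patient-out cross-validation
#'
#' For each patient: trains on all other patients and evaluates every
#' segment of the held-out patient, so no held-out segment ever enters a
#' training batch. Aggregates per-patient ACC/SN/SP/AUC as mean and sample
#' standard deviation across folds.
#'
#' @param batches list of labeled per-patient `segment_batch` objects
#'   (>= 3 patients).
#' @param cfg_fn function(n_patients) returning the [model_config()] for a
#'   fold (the fold's training-set size differs from the cohort size).
#' @param tc a [train_config()].
#' @param keep_models keep each fold's trained model in the report.
#' @return object of class `eval_report`: `per_patient` (one row per
#'   fold with counts and metrics), `average` (mean/sd matrix), `folds`
#'   (held-out vs training patient ids), optionally `models`.
#' @export
loso_cross_validation <- function(batches, cfg_fn, tc = train_config(),
                                  keep_models = FALSE) {
  P <- length(batches)
  if (P < 3L) {
    stop_seizdg("leave-one-patient-out needs >= 3 patients",
                class = "seizdg_validation_error")
  }
  rows <- vector("list", P)
  folds <- vector("list", P)
  models <- if (keep_models) vector("list", P) else NULL
  for (p in seq_len(P)) {
    train_idx <- setdiff(seq_len(P), p)
    cfg <- cfg_fn(length(train_idx))
    model <- tryCatch(
      train_model(batches[train_idx], cfg, tc),
      error = function(e) {
        stop_seizdg("fold ", p, " (held-out ", batches[[p]]$patient_id,
                    ") failed: ", conditionMessage(e),
                    class = "seizdg_fold_error")
      })
    held <- batches[[p]]
    pr <- predict(model, held)
    cc <- confusion_counts(held$y, pr$pred)
    met <- compute_metrics(cc)
    auc <- roc_curve_auc(pr$score, held$y)$auc
    rows[[p]] <- data.frame(patient_id = held$patient_id,
                            TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
                            ACC = met["ACC"], SN = met["SN"], SP = met["SP"],
                            AUC = auc, row.names = NULL)
    folds[[p]] <- list(held_out = held$patient_id,
                       trained_on = vapply(batches[train_idx],
                                           function(b) b$patient_id, ""))
    if (keep_models) models[[p]] <- model
  }
  per_patient <- do.call(rbind, rows)
  avg <- rbind(mean = colMeans(per_patient[, c("ACC", "SN", "SP", "AUC")]),
               sd = apply(per_patient[, c("ACC", "SN", "SP", "AUC")], 2, stats::sd))
  structure(list(per_patient = per_patient, average = t(avg), folds = folds,
                 models = models),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> leave-one-patient-out over",
      nrow(x$per_patient), "patients\n")
  a <- x$average
  cat(sprintf("  ACC %.3f (+/-%.3f)  SN %.3f (+/-%.3f)  SP %.3f (+/-%.3f)  AUC %.3f\n",
              a["ACC", "mean"], a["ACC", "sd"], a["SN", "mean"], a["SN", "sd"],
              a["SP", "mean"], a["SP", "sd"], a["AUC", "mean"]))
  invisible(x)
}

#' Ablation suite over model variants
#'
#' Runs [loso_cross_validation()] for each requested variant under
#' identical folds and seeds: `full` (all terms), `no_separation` (drops
#' the category/patient classifiers and max-divergence of the separation
#' network), `dann_only` (keeps only the global marginal adversary) and
#' `mada_only` (keeps only the per-class local adversaries, with
#' MADA-style predicted-label masking).
#'
#' @param batches list of labeled per-patient `segment_batch` objects.
#' @param cfg_fn function(n_patients, variant) returning the variant's
#'   [model_config()]; use [variant_config()] for the standard mapping.
#' @param tc a [train_config()].
#' @param variants character subset of
#'   `c("full", "no_separation", "dann_only", "mada_only")`.
#' @return list of class `ablation_report`: `reports` (named list of
#'   `eval_report`s), `comparison` (variant x metric table), `paired`
#'   (per-fold ACC differences of each variant against `full`).
#' @export
ablation_suite <- function(batches, cfg_fn, tc = train_config(),
                           variants = c("full", "no_separation",
                                        "dann_only", "mada_only")) {
  reports <- lapply(stats::setNames(variants, variants), function(v) {
    loso_cross_validation(batches, function(n) cfg_fn(n, v), tc)
  })
  comparison <- do.call(rbind, lapply(variants, function(v) {
    a <- reports[[v]]$average
    data.frame(variant = v, ACC = a["ACC", "mean"], ACC_sd = a["ACC", "sd"],
               SN = a["SN", "mean"], SP = a["SP", "mean"],
               AUC = a["AUC", "mean"], row.names = NULL)
  }))
  paired <- NULL
  if ("full" %in% variants) {
    full_acc <- reports[["full"]]$per_patient$ACC
    paired <- do.call(rbind, lapply(setdiff(variants, "full"), function(v) {
      data.frame(variant = v,
                 patient_id = reports[[v]]$per_patient$patient_id,
                 acc_diff = full_acc - reports[[v]]$per_patient$ACC,
                 row.names = NULL)
    }))
  }
  structure(list(reports = reports, comparison = comparison, paired = paired),
            class = "ablation_report")
}

#' Standard variant-to-configuration mapping for the ablation suite
#'
#' @param base_args named list of arguments passed through to
#'   [model_config()] (everything except `n_patients` and the variant
#'   switches).
#' @return function(n_patients, variant) returning a [model_config()].
#' @export
variant_config <- function(base_args = list()) {
  function(n_patients, variant = "full") {
    args <- base_args
    args$n_patients <- n_patients
    sw <- switch(variant,
      full = list(use_separation = TRUE, use_global = TRUE, use_local = TRUE,
                  local_mask = "true"),
      no_separation = list(use_separation = FALSE, use_global = TRUE,
                           use_local = TRUE, local_mask = "true"),
      dann_only = list(use_separation = TRUE, use_global = TRUE,
                       use_local = FALSE, local_mask = "true"),
      mada_only = list(use_separation = TRUE, use_global = FALSE,
                       use_local = TRUE, local_mask = "soft"),
      stop_seizdg("unknown variant: ", variant, class = "seizdg_config_error"))
    do.call(model_config, c(args, sw))
  }
}

#' Export a 2-D t-SNE embedding of classifier-input features
#'
#' Extracts the invariant features (the main classifier's input,
#' `F_all_prime`) for a batch, embeds them to 2-D with t-SNE and returns a
#' table ready for plotting: one row per segment with coordinates, the
#' category label and the patient label.
#'
#' @param model a trained `seizdg_model`.
#' @param batch a labeled `segment_batch`.
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   for small batches).
#' @param seed seed for the embedding initialization.
#' @return data frame with columns `x`, `y`, `category`, `patient`.
#' @export
tsne_export <- function(model, batch, perplexity = 30, seed = 1L) {
  if (!isTRUE(model$trained)) {
    stop_seizdg("model is untrained", class = "seizdg_state_error")
  }
  feats <- extract_features(model, batch, "invariant")
  emb <- tsne_embed(feats, perplexity = perplexity, seed = seed)
  data.frame(x = emb[, 1], y = emb[, 2],
             category = batch$y %||% rep(NA_integer_, nrow(emb)),
             patient = batch$patient_label %||% rep(NA_integer_, nrow(emb)))
}

#' Linear-probe accuracy of a feature set for a label
#'
#' Fits a multinomial logistic regression on a random train split of the
#' features and reports a held-out score — a standard probe for how much
#' linearly decodable information about `labels` a representation carries.
#' Accuracy saturates for easy targets; the held-out mean log-loss
#' (`metric = "logloss"`, lower is better) stays sensitive at the ceiling.
#'
#' @param features `[N x d]` matrix.
#' @param labels integer labels (any coding).
#' @param train_frac fraction used for fitting.
#' @param seed split seed.
#' @param metric `"accuracy"` (higher is better) or `"logloss"` (held-out
#'   mean cross-entropy, lower is better).
#' @return held-out score.
#' @export
linear_probe_accuracy <- function(features, labels, train_frac = 0.7,
                                  seed = 1L,
                                  metric = c("accuracy", "logloss")) {
  metric <- match.arg(metric)
  labels <- factor(labels)
  N <- nrow(features)
  set.seed(derive_seed(seed, "probe-split"))
  idx <- sample.int(N, round(train_frac * N))
  df <- data.frame(features)
  df$.y <- labels
  fit <- nnet::multinom(.y ~ ., df[idx, , drop = FALSE],
                        trace = FALSE, MaxNWts = 100000, maxit = 200)
  if (metric == "accuracy") {
    pred <- predict(fit, df[-idx, , drop = FALSE])
    return(mean(pred == labels[-idx]))
  }
  pr <- predict(fit, df[-idx, , drop = FALSE], type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)   # binomial case
  i <- cbind(seq_len(nrow(pr)), as.integer(labels[-idx]))
  -mean(log(pmax(pr[i], 1e-12)))
}
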