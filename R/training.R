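# Joint minimax training: full-batch Adam on the network, SGD on the
# class centers, gradient reversal realizing the adversarial max.

#' Training configuration
#'
#' Defaults follow the training protocol: full-batch optimization, Adam
#' with learning rate 0.005 for all network parameters, SGD with learning
#' rate 0.05 for the class centers, 200 epochs, trade-off weight
#' `lambda = 0.1`.
#'
#' @param epochs training rounds.
#' @param lr_network Adam learning rate for every network parameter
#'   (feature extractor, classifiers and — through the reversed gradients —
#'   the discriminators).
#' @param lr_centers SGD learning rate for the class centers.
#' @param lambda trade-off weight of the joint objective.
#' @param grl_lambda gradient-reversal strength; defaults to `lambda`
#'   (single knob).
#' @param grl_ramp logical; ramp the reversal strength from 0 to
#'   `grl_lambda` over training with the standard domain-adversarial
#'   schedule `2/(1 + exp(-10 p)) - 1` (p = training progress), letting the
#'   classifier find its footing before the adversaries bite. Default
#'   `TRUE`.
#' @param seed master seed (parameter init and any sampling fan out from
#'   it through named substreams).
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, lr_network = 0.005, lr_centers = 0.05,
                         lambda = 0.1, grl_lambda = lambda, grl_ramp = TRUE,
                         seed = 1L) {
  if (epochs < 1L || lr_network <= 0 || lr_centers <= 0) {
    stop_seizdg("epochs and learning rates must be positive",
                class = "seizdg_validation_error")
  }
  structure(list(epochs = as.integer(epochs), lr_network = lr_network,
                 lr_centers = lr_centers, lambda = lambda,
                 grl_lambda = grl_lambda, grl_ramp = isTRUE(grl_ramp),
                 seed = as.integer(seed)),
            class = "train_config")
}

loss_terms <- c("L_cls_1", "L_p", "L_max_divergence", "L_cls_2", "L_cent",
                "L_global", "L_local")

#' Train the full model on a set of patients
#'
#' Runs `epochs` full-batch steps of the joint objective: the network
#' parameters follow Adam on the combined loss with the gradient-reversal
#' layer turning the patient discriminators' minimization into the feature
#' extractor's maximization; the class centers follow their own SGD
#' updates. Training history records every loss term per epoch.
#'
#' @param batches list of labeled per-patient `segment_batch` objects
#'   (at least two — the adversarial terms need patient diversity).
#' @param cfg a [model_config()]; `n_patients` must equal
#'   `length(batches)`.
#' @param tc a [train_config()].
#' @param verbose print the loss every 25 epochs.
#' @return object of class `seizdg_model` with elements `params`,
#'   `centers`, `state` (batch-norm running statistics), `config`,
#'   `train_config`, `history` (data frame, one row per epoch).
#' @export
train_model <- function(batches, cfg, tc = train_config(), verbose = FALSE) {
  if (length(batches) < 2L) {
    stop_seizdg("training needs >= 2 patients", class = "seizdg_config_error")
  }
  if (cfg$n_patients != length(batches)) {
    stop_seizdg("cfg$n_patients (", cfg$n_patients, ") != number of training",
                " batches (", length(batches), ")", class = "seizdg_config_error")
  }
  db <- bind_batches(batches)
  if (any(!db$y %in% c(0L, 1L))) {
    stop_seizdg("category labels must be 0/1", class = "seizdg_validation_error")
  }

  init <- init_model(cfg, seed = tc$seed)
  params <- init$params
  centers <- init$centers
  state <- init$state
  opt <- adam_init(params)

  hist <- as.data.frame(matrix(NA_real_, tc$epochs, length(loss_terms) + 2L))
  names(hist) <- c("epoch", loss_terms, "L_sum")

  for (ep in seq_len(tc$epochs)) {
    fw <- model_forward(params, state, centers, db$X, db$y, db$d, cfg,
                        train = TRUE, heads = TRUE)
    state <- fw$state
    parts <- lapply(stats::setNames(loss_terms, loss_terms),
                    function(nm) fw[[nm]] %||% NA_real_)
    for (nm in loss_terms) {
      v <- parts[[nm]]
      if (!is.na(v) && !is.finite(v)) {
        stop_seizdg("training diverged: ", nm, " is non-finite at epoch ", ep,
                    class = "seizdg_divergence_error")
      }
    }
    hist[ep, "epoch"] <- ep
    for (nm in loss_terms) hist[ep, nm] <- parts[[nm]]
    hist[ep, "L_sum"] <- total_loss(parts, tc$lambda)

    grl_ep <- if (isTRUE(tc$grl_ramp)) {
      tc$grl_lambda * (2 / (1 + exp(-10 * ep / tc$epochs)) - 1)
    } else tc$grl_lambda
    grads <- model_backward(fw, params, centers, db$y, db$d, cfg,
                            lambda = tc$lambda, grl_lambda = grl_ep)
    st <- adam_step(params, grads, opt, tc$lr_network)
    params <- st$params
    opt <- st$state

    # center optimizer: count-normalized SGD on the center loss
    for (k in 1:2) {
      idx <- db$y == (k - 1L)
      nk <- sum(idx)
      if (nk > 0L) {
        delta <- (nk * centers[k, ] -
                    colSums(fw$pen[idx, , drop = FALSE])) / (1 + nk)
        centers[k, ] <- centers[k, ] - tc$lr_centers * delta
      }
    }
    if (verbose && (ep %% 25L == 0L || ep == 1L)) {
      message(sprintf("epoch %4d  L_sum %.4f  L_cls_2 %.4f",
                      ep, hist[ep, "L_sum"], hist[ep, "L_cls_2"]))
    }
  }

  # batch-norm recalibration: recompute the running statistics under the
  # final weights so evaluation-mode normalization matches the trained
  # network (the running averages lag the moving batch statistics)
  fw <- model_forward(params, state, centers, db$X, db$y, db$d, cfg,
                      train = TRUE, heads = FALSE, bn_momentum = 1)
  state <- fw$state

  structure(list(params = params, centers = centers, state = state,
                 config = cfg, train_config = tc, history = hist,
                 train_patient_ids = vapply(batches, function(b) b$patient_id, ""),
                 trained = TRUE),
            class = "seizdg_model")
}

#' @export
print.seizdg_model <- function(x, ...) {
  cat(sprintf(
    "<seizdg_model> %d ch x %d samples, %d patients, %d epochs (final L_sum %.4f)\n",
    x$config$n_channels, x$config$window_len, x$config$n_patients,
    nrow(x$history), x$history$L_sum[nrow(x$history)]))
  invisible(x)
}

#' Predict seizure probabilities for a segment batch
#'
#' Runs the front-end and main category classifier in evaluation mode
#' (batch-norm running statistics). The decision rule is the softmax
#' argmax, with ties broken toward the normal class.
#'
#' @param object a trained `seizdg_model`.
#' @param batch a `segment_batch`.
#' @param ... unused.
#' @return data frame with `score` (seizure probability) and `pred`
#'   (0/1 class).
#' @export
predict.seizdg_model <- function(object, batch, ...) {
  fw <- model_forward(object$params, object$state, object$centers,
                      batch$x, NULL, NULL, object$config,
                      train = FALSE, heads = FALSE)
  m <- apply(fw$logits2, 1, max)
  ex <- exp(fw$logits2 - m)
  probs <- ex / rowSums(ex)
  data.frame(score = probs[, 2],
             pred = as.integer(probs[, 2] > probs[, 1]))
}

#' Extract features from a trained model
#'
#' @param model a trained `seizdg_model`.
#' @param batch a `segment_batch`.
#' @param stage `"f_all"` (post-SE front-end features), `"separated"`
#'   (list of halves), `"invariant"` (the classifier-input features
#'   `F_all_prime`), or `"penultimate"` (the classifier's hidden ELU
#'   activations, the center-loss features).
#' @return matrix (or `separated_features` for `"separated"`).
#' @export
extract_features <- function(model, batch,
                             stage = c("invariant", "f_all", "separated",
                                       "penultimate")) {
  stage <- match.arg(stage)
  if (!isTRUE(model$trained)) {
    stop_seizdg("model is untrained", class = "seizdg_state_error")
  }
  fw <- model_forward(model$params, model$state, model$centers,
                      batch$x, NULL, NULL, model$config,
                      train = FALSE, heads = FALSE)
  switch(stage,
         f_all = fw$f_all,
         separated = structure(list(F_category_related = fw$Fc,
                                    F_patient_related = fw$Fp),
                               class = "separated_features"),
         invariant = fw$Fprime,
         penultimate = fw$pen)
}

#' Hyperparameter grid search by inner leave-one-patient-out accuracy
#'
#' Exhaustively evaluates every combination in `grid` (named lists of
#' candidate values for [train_config()] fields) with
#' [loso_cross_validation()] over the supplied patients, and returns the
#' configuration with the highest mean held-out accuracy. Ties are broken
#' toward the smallest `lambda`, then the smallest `lr_network`.
#'
#' @param batches list of labeled per-patient `segment_batch` objects.
#' @param grid named list, e.g.
#'   `list(lambda = c(0.05, 0.1), lr_network = c(0.005))`.
#' @param base_tc baseline [train_config()] supplying unsearched fields.
#' @param cfg_fn function(n_patients) returning the [model_config()] used
#'   for each inner fold.
#' @return list with `best` (a `train_config`) and `scores` (one row per
#'   grid point).
#' @export
grid_search <- function(batches, grid, base_tc, cfg_fn) {
  if (length(grid) == 0L || any(vapply(grid, length, 0L) == 0L)) {
    stop_seizdg("empty hyperparameter grid", class = "seizdg_validation_error")
  }
  tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  tab$mean_acc <- NA_real_
  tcs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    tc <- base_tc
    for (nm in names(grid)) tc[[nm]] <- tab[[nm]][i]
    if (identical(tc$grl_lambda, base_tc$grl_lambda) && "lambda" %in% names(grid)) {
      tc$grl_lambda <- tc$lambda
    }
    tcs[[i]] <- tc
    rep_i <- tryCatch(loso_cross_validation(batches, cfg_fn, tc),
                      error = function(e) NULL)   # divergent config
    tab$mean_acc[i] <- if (is.null(rep_i)) NA_real_ else
      rep_i$average["ACC", "mean"]
  }
  ord <- order(-tab$mean_acc,
               if ("lambda" %in% names(tab)) tab$lambda else seq_len(nrow(tab)),
               if ("lr_network" %in% names(tab)) tab$lr_network else seq_len(nrow(tab)),
               na.last = TRUE)
  list(best = tcs[[ord[1]]], scores = tab)
}

#' Save / load a trained model
#'
#' Round-trips through RDS; a reloaded model reproduces predictions
#' bit-identically.
#'
#' @param model a `seizdg_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}
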