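# User-facing loss and feature operations. These are the pure-function
# counterparts of what the training loop computes internally; the model
# code and these definitions are kept numerically identical.

#' Split a feature matrix into category- and patient-related halves
#'
#' The first half of every feature vector (by index) is the
#' category-related component, the second half the patient-related
#' component.
#'
#' @param f_all numeric matrix `[N x d]` (or a vector, treated as one row)
#'   with even `d`.
#' @return list of class `separated_features` with `F_category_related`,
#'   `F_patient_related`.
#' @export
#' @examples
#' split_features(matrix(c(1, 2, 3, 4), 1))  # [1 2] vs [3 4]
split_features <- function(f_all) {
  if (is.null(dim(f_all))) f_all <- matrix(f_all, 1L)
  d <- ncol(f_all)
  if (d %% 2L != 0L) {
    stop_seizdg("feature dimension must be even, got ", d,
                class = "seizdg_config_error")
  }
  structure(list(
    F_category_related = f_all[, 1:(d / 2), drop = FALSE],
    F_patient_related = f_all[, (d / 2 + 1):d, drop = FALSE]
  ), class = "separated_features")
}

#' Recombine separated features (category half first)
#'
#' @param sep a `separated_features` object.
#' @return numeric matrix, the concatenation
#'   `[F_category_related | F_patient_related]`.
#' @export
recombine <- function(sep) {
  stopifnot(inherits(sep, "separated_features"))
  cbind(sep$F_category_related, sep$F_patient_related)
}

#' Maximum-divergence loss between feature halves
#'
#' The negated squared Euclidean distance between the two halves, summed
#' over the batch: always `<= 0`, zero iff the halves coincide; minimizing
#' it pushes the halves apart.
#'
#' @param sep a `separated_features` object, or a matrix whose halves are
#'   split first.
#' @return scalar loss.
#' @export
#' @examples
#' max_divergence_loss(matrix(c(1, 0, 0, 0), 1))  # -1
max_divergence_loss <- function(sep) {
  if (!inherits(sep, "separated_features")) sep <- split_features(sep)
  a <- sep$F_category_related
  b <- sep$F_patient_related
  if (!all(dim(a) == dim(b))) {
    stop_seizdg("feature halves differ in dimension", class = "seizdg_validation_error")
  }
  -sum((a - b)^2)
}

#' Mean cross-entropy loss
#'
#' `-(1/N) sum_i log p_i[label_i]`. Accepts either class probabilities or
#' raw logits (softmaxed internally when rows do not sum to one).
#'
#' @param scores `[N x K]` matrix of probabilities or logits.
#' @param labels integer labels; either `0..K-1` or `1..K`.
#' @return scalar loss.
#' @export
#' @examples
#' cross_entropy_loss(matrix(0.5, 2, 2), c(0, 1))  # log(2)
cross_entropy_loss <- function(scores, labels) {
  if (is.null(dim(scores))) scores <- matrix(scores, 1L)
  K <- ncol(scores)
  labels <- as.integer(labels)
  if (min(labels) == 0L) labels <- labels + 1L
  if (any(labels < 1L | labels > K)) {
    stop_seizdg("label outside 1..", K, class = "seizdg_validation_error")
  }
  if (any(abs(rowSums(scores) - 1) > 1e-8) || any(scores < 0)) {
    scores <- exp(scores - apply(scores, 1, max))
    scores <- scores / rowSums(scores)
  }
  idx <- cbind(seq_len(nrow(scores)), labels)
  -mean(log(pmax(scores[idx], 1e-300)))
}

#' Center loss
#'
#' Half the summed squared distances between features and their class
#' centers (a sum over the batch, not a mean).
#'
#' @param features `[N x d]` feature matrix.
#' @param y integer class labels `0..K-1`.
#' @param centers `[K x d]` matrix of class centers.
#' @return scalar loss.
#' @export
#' @examples
#' center_loss(matrix(c(2, 0), 1), 0, matrix(0, 2, 2))  # 2
center_loss <- function(features, y, centers) {
  if (is.null(dim(features))) features <- matrix(features, 1L)
  if (is.null(centers)) {
    stop_seizdg("centers not initialized", class = "seizdg_state_error")
  }
  0.5 * sum((features - centers[as.integer(y) + 1L, , drop = FALSE])^2)
}

#' Gradient reversal (forward pass)
#'
#' Identity in the forward direction; during backpropagation the training
#' loop multiplies the gradient flowing through this point by
#' `-lambda_grl`. The attribute records the factor the backward pass
#' applies.
#'
#' @param x features.
#' @param lambda_grl reversal strength.
#' @return `x` unchanged, with attribute `grl_lambda`.
#' @export
gradient_reversal <- function(x, lambda_grl = 0.1) {
  attr(x, "grl_lambda") <- lambda_grl
  x
}

#' Joint objective of the full model
#'
#' Combines the named loss terms:
#' `L_sum = L_cls_2 + lambda * (L_cent + L_cls_1 + L_p + L_max_divergence)
#'  - lambda * (L_global + L_local)`,
#' where the patient-classifier term plays the subject-loss role. Terms
#' absent from `parts` (disabled ablation variants) contribute zero.
#'
#' @param parts named list (or `loss_breakdown`) with any of `L_cls_2`,
#'   `L_cent`, `L_cls_1`, `L_p`, `L_max_divergence`, `L_global`, `L_local`.
#' @param lambda trade-off weight (default 0.1).
#' @return scalar `L_sum`.
#' @export
#' @examples
#' total_loss(list(L_cls_2 = 1), lambda = 0.1)               # 1
#' total_loss(list(L_global = 1), lambda = 0.1)              # -0.1
total_loss <- function(parts, lambda = 0.1) {
  g <- function(nm) {
    v <- parts[[nm]]
    if (is.null(v)) return(0)
    if (is.nan(v)) return(NaN)
    if (is.na(v)) 0 else v
  }
  terms <- c(g("L_cls_2"), g("L_cent"), g("L_cls_1"), g("L_p"),
             g("L_max_divergence"), g("L_global"), g("L_local"))
  if (any(is.nan(terms))) {
    stop_seizdg("NaN loss term", class = "seizdg_divergence_error")
  }
  g("L_cls_2") +
    lambda * (g("L_cent") + g("L_cls_1") + g("L_p") + g("L_max_divergence")) -
    lambda * (g("L_global") + g("L_local"))
}
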