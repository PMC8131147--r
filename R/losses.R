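# Training objectives. The compound loss sums (i) per-feature losses
# (each stream-level feature fed to its own classifier), (ii) the loss on
# the fused feature, and (iii) a decision-fusion loss, each computed with
# the additive-margin softmax unless stated otherwise.

check_labels <- function(labels, c) {
  if (any(labels != round(labels)) || any(labels < 0) || any(labels >= c))
    abort_input("labels must be integers in 0..c-1")
  as.integer(labels)
}

onehot <- function(labels, c) {
  m <- matrix(0, length(labels), c)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Cross-entropy (softmax) classification loss
#'
#' Mean over the batch of the negative log softmax probability of the true
#' class, with logits `w_j' x_i + b_j`.
#'
#' @param features Batch matrix, one feature row per sample.
#' @param labels Integer class labels in `0..c-1`.
#' @param weights `d x c` matrix of per-class weight columns.
#' @param biases Length-c per-class offsets.
#' @return Scalar loss (>= 0).
#' @export
cross_entropy_loss <- function(features, labels, weights, biases = NULL) {
  features <- as_mat(features)
  c <- ncol(weights)
  labels <- check_labels(labels, c)
  logits <- features %*% weights
  if (!is.null(biases)) logits <- sweep(logits, 2L, as.vector(biases), `+`)
  ce_from_logits(logits, labels)
}

ce_from_logits <- function(logits, labels) {
  mx <- apply(logits, 1L, max)
  lse <- log(rowSums(exp(logits - mx))) + mx
  true_logit <- logits[cbind(seq_along(labels), labels + 1L)]
  mean(lse - true_logit)
}

#' Cosine softmax loss
#'
#' Cross-entropy on cosine-similarity logits: both the feature vectors and
#' the per-class weight vectors are normalized to unit length, so the loss
#' is invariant to the scale of either.
#'
#' @inheritParams cross_entropy_loss
#' @return Scalar loss.
#' @export
cosine_softmax_loss <- function(features, labels, weights) {
  features <- as_mat(features)
  labels <- check_labels(labels, ncol(weights))
  if (any(sqrt(rowSums(features^2)) == 0) || any(sqrt(colSums(weights^2)) == 0))
    abort_input("cosine loss is undefined for zero-norm vectors")
  ce_from_logits(cosine_logits(features, weights), labels)
}

cosine_logits <- function(features, weights) {
  xn <- features / sqrt(rowSums(features^2))
  wn <- sweep(weights, 2L, sqrt(colSums(weights^2)), `/`)
  xn %*% wn
}

#' Additive-margin softmax (AM-Softmax) loss
#'
#' Cosine logits with an additive margin `m` subtracted from the true-class
#' cosine and a scale `s`:
#' target logit `s (cos theta_y - m)`, non-target logits `s cos theta_j`.
#' With `s = 1, m = 0` this reduces exactly to [cosine_softmax_loss()];
#' for fixed cosines the loss is strictly increasing in `m`.
#'
#' @inheritParams cosine_softmax_loss
#' @param s Scale (> 0).
#' @param m Additive margin in `[0, 1)`.
#' @return Scalar loss.
#' @export
am_softmax_loss <- function(features, labels, weights, s = 30, m = 0.35) {
  if (!is_scalar_number(s) || s <= 0) abort_config("scale s must be > 0")
  if (!is_scalar_number(m) || m < 0 || m >= 1)
    abort_config("margin m must be in [0, 1)")
  features <- as_mat(features)
  labels <- check_labels(labels, ncol(weights))
  if (any(sqrt(rowSums(features^2)) == 0) || any(sqrt(colSums(weights^2)) == 0))
    abort_input("AM-Softmax is undefined for zero-norm vectors")
  cosm <- cosine_logits(features, weights)
  cosm[cbind(seq_along(labels), labels + 1L)] <-
    cosm[cbind(seq_along(labels), labels + 1L)] - m
  ce_from_logits(s * cosm, labels)
}

#' Compound training loss
#'
#' `total = loss_F + loss_SF + loss_DF`, where `loss_F` sums the
#' AM-Softmax loss of every supervised feature, `loss_SF` is the loss on
#' the fused feature, and `loss_DF` is the decision-fusion loss
#' (AM-Softmax applied to the log of the averaged class posteriors).
#' Disabled branches (`NULL` inputs) contribute exactly 0.
#'
#' @param features List of batch feature matrices `f_1..f_n`.
#' @param labels Integer labels in `0..c-1`.
#' @param classifiers List of `d x c` weight matrices, one per feature.
#' @param sf_feature Fused-feature batch matrix (or `NULL`).
#' @param sf_classifier Weight matrix for the fused feature.
#' @param df_posterior Batch matrix of averaged class posteriors (rows sum
#'   to 1), or `NULL`.
#' @param df_classifier Weight matrix for the decision-fusion branch.
#' @param s,m AM-Softmax scale and margin.
#' @return A `loss_breakdown` list: `loss_F`, `loss_SF`, `loss_DF`,
#'   `total` (exactly their sum).
#' @export
total_loss <- function(features, labels, classifiers,
                       sf_feature = NULL, sf_classifier = NULL,
                       df_posterior = NULL, df_classifier = NULL,
                       s = 30, m = 0.35) {
  if (length(features) != length(classifiers))
    abort_input("one classifier per supervised feature is required")
  loss_F <- 0
  for (i in seq_along(features))
    loss_F <- loss_F + am_softmax_loss(features[[i]], labels, classifiers[[i]],
                                       s = s, m = m)
  loss_SF <- if (is.null(sf_feature)) 0 else
    am_softmax_loss(sf_feature, labels, sf_classifier, s = s, m = m)
  loss_DF <- if (is.null(df_posterior)) 0 else
    am_softmax_loss(log(as_mat(df_posterior) + 1e-12), labels, df_classifier,
                    s = s, m = m)
  structure(list(loss_F = loss_F, loss_SF = loss_SF, loss_DF = loss_DF,
                 total = loss_F + loss_SF + loss_DF),
            class = "loss_breakdown")
}

# ---- autodiff forms ----------------------------------------------------

# features: B x d node; weights: d x c node; labels 0-based.
ad_am_softmax <- function(features, labels, weights, s = 30, m = 0.35) {
  c <- ncol(ad_value(weights))
  oh <- onehot(labels, c)
  xn <- ad_rownorm(features)
  wn <- ad_t(ad_rownorm(ad_t(weights)))
  cosm <- ad_matmul(xn, wn)
  logits <- ad_scale(ad_sub(cosm, ad_scale(ad_const(oh), m)), s)
  lse <- ad_logsumexp_rows(logits)
  true_logit <- ad_rowsums(ad_mul(logits, ad_const(oh)))
  ad_mean(ad_sub(lse, true_logit))
}
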