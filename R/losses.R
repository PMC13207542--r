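# Task losses and their adaptive multi-task combination.
#
# Classification uses a Focal-BCE loss on the binary lesion-presence task:
# per sample, -omega_i (1 - p_t)^gamma log(p_t), where p_t is the predicted
# probability of the true class, omega_i is the lesion-class weight
# N_neg / N_pos for lesion samples (1 for normals) and gamma focuses the
# loss on hard samples. Segmentation uses soft Dice loss with an epsilon
# smoothing term. Both are combined with learnable homoscedastic
# uncertainties: L = (1/D) sum_i [ L_i / (2 sigma_i^2) + log sigma_i ],
# parameterized through s_i = log sigma_i^2 so positivity is automatic.
# Losses are reduced by the batch mean, giving a batch-size-independent
# scale.

#' Lesion-class weight from a training fold
#'
#' Merges benign and malignant samples into the positive (lesion) class and
#' returns omega = N_neg / N_pos. Computed on the training subset of one
#' fold only, so the weight adapts to fold-specific imbalance.
#'
#' @param categories character vector of per-sample categories, a manifest
#'   data.frame with a \code{category} column, or a list of
#'   \linkS4class{ImageSample} objects
#' @return the scalar weight omega
#' @examples
#' computeClassWeight(rep(c("benign", "malignant", "normal"), c(437, 210, 133)))
#' @export
computeClassWeight <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  if (is.list(categories)) {
    categories <- vapply(categories, category, character(1))
  }
  npos <- sum(categories %in% c("benign", "malignant"))
  nneg <- sum(categories == "normal")
  if (npos == 0) stop("cannot compute class weight: no lesion samples in fold")
  nneg / npos
}

#' Focal-BCE classification loss
#'
#' @param zeta predicted lesion probabilities in [0, 1]
#' @param xi ground-truth labels, 1 = lesion, 0 = normal
#' @param omega lesion-class weight applied to lesion samples (normals get 1)
#' @param gamma focusing parameter (gamma = 0 recovers weighted BCE)
#' @param clamp probability floor keeping log(p_t) finite
#' @return mean focal loss over the batch
#' @export
focalBCE <- function(zeta, xi, omega = 1, gamma = 2, clamp = 1e-7) {
  if (any(zeta < 0 | zeta > 1)) {
    stop("predicted probabilities must lie in [0, 1]")
  }
  if (!all(xi %in% c(0, 1))) stop("labels must be 0/1")
  p <- pmin(pmax(zeta, clamp), 1 - clamp)
  pt <- ifelse(xi == 1, p, 1 - p)
  w <- ifelse(xi == 1, omega, 1)
  mean(-w * (1 - pt)^gamma * log(pt))
}

#' Soft Dice segmentation loss
#'
#' 1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps), computed per image and
#' averaged over the batch. Empty-empty agreement gives exactly 0 because
#' the eps terms cancel.
#'
#' @param p predicted per-pixel probabilities in [0, 1]; a matrix (one
#'   image) or an H x W x N array (a batch)
#' @param g ground-truth binary mask(s) of the same shape
#' @param epsilon smoothing constant (default 1e-5)
#' @return mean Dice loss over the batch
#' @export
diceLoss <- function(p, g, epsilon = 1e-5) {
  if (!identical(dim(p), dim(g))) stop("prediction and mask shapes differ")
  if (any(p < 0 | p > 1)) stop("predicted probabilities must lie in [0, 1]")
  one <- function(pi, gi) {
    1 - (2 * sum(pi * gi) + epsilon) / (sum(pi) + sum(gi) + epsilon)
  }
  d <- dim(p)
  if (length(d) == 3L) {
    mean(vapply(seq_len(d[3]), function(i) one(p[, , i], g[, , i]), numeric(1)))
  } else {
    one(p, g)
  }
}

#' Adaptive multi-task loss combination
#'
#' (1/D) sum_i [ L_i / (2 sigma_i^2) + log sigma_i ] with
#' sigma_i = exp(logVar_i / 2). At the initialization sigma_1 = sigma_2 = 1
#' this is exactly (L_cls + L_seg) / 4; holding L_i fixed, the minimizing
#' sigma_i is sqrt(L_i).
#'
#' @param lossCls,lossSeg finite non-negative task losses
#' @param state a \linkS4class{LossState} carrying the log-variances
#' @return the combined scalar loss
#' @export
amtlCombine <- function(lossCls, lossSeg, state = lossState()) {
  L <- c(lossCls, lossSeg)
  if (!all(is.finite(L))) {
    stop("non-finite ", c("classification", "segmentation")[!is.finite(L)][1],
         " loss passed to the multi-task combination")
  }
  s <- state@logVar
  mean(L / (2 * exp(s)) + s / 2)
}

## ---- graph-building versions used by the training loop --------------------

# logits: [N, 2] node (col 1 = lesion); xi: 0/1 numeric labels
graph_focal_bce <- function(ctx, logits, xi, omega, gamma, clamp = 1e-7) {
  tp <- ctx$tape
  # softmax over two classes == sigmoid of the logit difference
  p <- op_sigmoid(tp, op_sub(tp, op_col(tp, logits, 1L),
                             op_col(tp, logits, 2L)))
  p <- op_clamp(tp, p, clamp, 1 - clamp)
  pt <- op_addc(tp, op_mulc(tp, p, 2 * xi - 1), 1 - xi)
  w <- ifelse(xi == 1, omega, 1)
  focal <- op_pow(tp, op_addc(tp, op_neg(tp, pt), 1), gamma)
  op_mean(tp, op_mulc(tp, op_mul(tp, focal, op_log(tp, pt)), -w))
}

# seg: [H, W, N, 1] probability node; gmask: [H, W, N, 1] numeric array
graph_dice <- function(ctx, seg, gmask, epsilon) {
  tp <- ctx$tape
  inter <- op_spatsum(tp, op_mulc(tp, seg, gmask))
  psum <- op_spatsum(tp, seg)
  gsum <- colSums(matrix(gmask, prod(dim(gmask)[1:2]), dim(gmask)[3]))
  num <- op_addc(tp, op_mulc(tp, inter, 2), epsilon)
  den <- op_addc(tp, psum, gsum + epsilon)
  op_mean(tp, op_addc(tp, op_neg(tp, op_div(tp, num, den)), 1))
}

# combine task-loss nodes through the learnable log-variances of the
# model's amtl module
graph_amtl <- function(ctx, lcls, lseg, amtl_mod) {
  tp <- ctx$tape
  lv <- param_leaf(ctx, amtl_mod, "logVar")
  term <- function(L, i) {
    s <- op_index(tp, lv, i)
    op_add(tp, op_mulc(tp, op_mul(tp, L, op_exp(tp, op_neg(tp, s))), 0.5),
           op_mulc(tp, s, 0.5))
  }
  op_mulc(tp, op_add(tp, term(lcls, 1L), term(lseg, 2L)), 0.5)
}
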