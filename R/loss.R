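# Hybrid segmentation loss: mean cross-entropy plus soft Dice loss
# (squared-denominator variant) over the foreground classes.

#' One-hot encode a label mask
#'
#' @param mask Integer `H x W` matrix of class IDs in `0:(n_classes-1)`, or a
#'   list of such matrices (stacked along the batch axis).
#' @param n_classes Number of classes.
#' @return Numeric array `(N, n_classes, H, W)` of 0/1 indicators.
#' @export
one_hot_mask <- function(mask, n_classes = 4L) {
  if (is.matrix(mask)) mask <- list(mask)
  N <- length(mask)
  H <- nrow(mask[[1]])
  W <- ncol(mask[[1]])
  y <- array(0, dim = c(N, n_classes, H, W))
  for (n in seq_len(N)) {
    m <- mask[[n]]
    stopifnot(all(m %in% 0:(n_classes - 1L)))
    for (c in seq_len(n_classes)) y[n, c, , ] <- (m == c - 1L)
  }
  y
}

check_probs <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("prediction and target shapes differ")
}

# Accept either a full (N,C,H,W) distribution or a plain numeric vector /
# matrix treated as a single-class soft mask.
as_class_arrays <- function(pred, target, classes = NULL) {
  if (is.null(dim(pred)) || length(dim(pred)) < 4L) {
    pred <- array(pred, dim = c(1L, 1L, 1L, length(pred)))
    target <- array(target, dim = dim(pred))
    classes <- 1L
  } else if (is.null(classes)) {
    classes <- if (dim(pred)[2] > 1L) 2:dim(pred)[2] else 1L
  }
  list(pred = pred, target = target, classes = classes)
}

#' Soft Dice loss
#'
#' `1 - mean_c (2 * sum(p_c y_c) + eps) / (sum(p_c^2) + sum(y_c^2) + eps)`,
#' averaged over the foreground classes (all classes but the first channel)
#' when given a 4-D `(N, C, H, W)` distribution; a plain vector or matrix is
#' treated as a single soft mask.
#'
#' @param pred Predicted probabilities (rows of the class axis sum to 1), or
#'   a single soft mask.
#' @param target One-hot target of the same shape (see [one_hot_mask()]).
#' @param classes Class indices (1-based channel positions) to average over;
#'   default all but the background channel.
#' @param eps Smoothing constant.
#' @return Scalar in `[0, 1]` (up to `eps` effects).
#' @export
dice_loss <- function(pred, target, classes = NULL, eps = 1e-6) {
  a <- as_class_arrays(pred, target, classes)
  check_probs(a$pred, a$target)
  node <- ad_dice(ad_leaf(a$pred), a$target, a$classes, eps)
  node$value
}

#' Mean cross-entropy loss
#'
#' Mean over pixels of the negative log-probability assigned to the true
#' class; probabilities are clamped at `eps` before the log.
#'
#' @inheritParams dice_loss
#' @param eps Clamp for the log argument.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(pred, target, eps = 1e-12) {
  if (is.null(dim(pred)) || length(dim(pred)) < 4L) {
    pred <- array(pred, dim = c(1L, 1L, 1L, length(pred)))
    target <- array(target, dim = dim(pred))
  }
  check_probs(pred, target)
  ad_ce(ad_leaf(pred), target, eps)$value
}

#' Hybrid cross-entropy + Dice loss
#'
#' `w_ce * cross_entropy + w_dice * dice_loss`, the training objective.
#' Returns all three terms for logging.
#'
#' @inheritParams dice_loss
#' @param w_ce,w_dice Term weights (both 1 by default).
#' @return List with elements `ce`, `dice`, `hybrid`.
#' @export
hybrid_loss <- function(pred, target, w_ce = 1, w_dice = 1,
                        classes = NULL, eps_dice = 1e-6, eps_ce = 1e-12) {
  ce <- cross_entropy_loss(pred, target, eps = eps_ce)
  dl <- dice_loss(pred, target, classes = classes, eps = eps_dice)
  list(ce = ce, dice = dl, hybrid = w_ce * ce + w_dice * dl)
}

# Loss node on top of logits for training: softmax -> ce + dice.
hybrid_loss_node <- function(logits, target_onehot, w_ce = 1, w_dice = 1,
                             classes = NULL) {
  probs <- if (is.null(logits$logits)) ad_softmax(logits) else logits
  d <- dim4(probs$value)
  if (is.null(classes)) classes <- if (d[2] > 1L) 2:d[2] else 1L
  ce <- ad_ce(probs, target_onehot)
  dl <- ad_dice(probs, target_onehot, classes)
  loss <- ad_wsum(ce, dl, w_ce, w_dice)
  loss$ce <- ce$value
  loss$dice <- dl$value
  loss
}
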