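# Training loop: seeded epoch shuffling, hybrid CE+Dice loss, Adam updates,
# one validation pass per epoch and best-checkpoint tracking.

#' Training configuration
#'
#' @param batch_size Minibatch size (default 2).
#' @param epochs Training rounds; one validation pass and one checkpoint per
#'   round (default 15).
#' @param learning_rate Adam learning rate.
#' @param w_ce,w_dice Weights of the cross-entropy and Dice terms of the
#'   hybrid loss.
#' @param rng_seed Seed controlling shuffling (and nothing else); training
#'   on CPU is bit-reproducible under a fixed seed.
#' @param checkpoint_dir Directory for per-epoch checkpoints; `NULL` keeps
#'   checkpoints in memory only.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 2L, epochs = 15L, learning_rate = 1e-4,
                         w_ce = 1, w_dice = 1, rng_seed = 1L,
                         checkpoint_dir = NULL) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, w_ce = w_ce, w_dice = w_dice,
                 rng_seed = as.integer(rng_seed),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

# Stack a list of pairs into input/target arrays.
batch_arrays <- function(pairs, n_classes) {
  H <- nrow(pairs[[1]]$image)
  W <- ncol(pairs[[1]]$image)
  x <- array(0, dim = c(length(pairs), 1L, H, W))
  for (i in seq_along(pairs)) x[i, 1L, , ] <- pairs[[i]]$image / 255
  y <- one_hot_mask(lapply(pairs, `[[`, "mask"), n_classes)
  list(x = x, y = y)
}

model_state <- function(model) {
  list(values = lapply(model$params, function(p) p$value),
       bn = lapply(model$bns, function(e)
         list(mean = e$running_mean, var = e$running_var)))
}

load_model_state <- function(model, state) {
  stopifnot(length(state$values) == length(model$params))
  for (i in seq_along(model$params)) model$params[[i]]$value <- state$values[[i]]
  for (i in seq_along(model$bns)) {
    model$bns[[i]]$running_mean <- state$bn[[i]]$mean
    model$bns[[i]]$running_var <- state$bn[[i]]$var
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the network configuration, all weights and batch-norm
#' running statistics, and the package version.
#'
#' @param model A `spine_unet`.
#' @param path File path.
#' @return `load_checkpoint()` returns a reconstructed `spine_unet`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, state = model_state(model),
               version = as.character(utils::packageVersion("spineseg"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  load_model_state(model, ck$state)
  model
}

# Validation pass: mean hybrid loss + pixel-level metrics in eval mode.
validate_pass <- function(model, val_set, cfg) {
  nc <- model$cfg$n_classes
  losses <- numeric(0)
  preds <- truths <- list()
  i <- 1L
  while (i <= length(val_set)) {
    take <- val_set[seq(i, min(i + cfg$batch_size - 1L, length(val_set)))]
    ba <- batch_arrays(take, nc)
    probs <- forward_model(model, ba$x, training = FALSE)
    loss <- hybrid_loss_node(probs, ba$y, cfg$w_ce, cfg$w_dice)
    losses <- c(losses, loss$value)
    pm <- probs_to_mask(probs$value)
    preds <- c(preds, pm)
    truths <- c(truths, lapply(take, `[[`, "mask"))
    i <- i + cfg$batch_size
  }
  counts <- confusion_counts(preds, truths, unit = "pixel")
  met <- suppressWarnings(seg_metrics(counts, digits = NULL))
  list(loss = mean(losses), metrics = met)
}

#' Train the segmentation network
#'
#' Standard epoch loop: seeded shuffle, forward pass, hybrid CE+Dice loss,
#' backpropagation, Adam step; after each epoch a validation pass computes
#' the validation loss and pixel-level P/R/Dice, and the epoch's weights are
#' checkpointed. The returned fit carries the full per-epoch log and the
#' weights of the best epoch (lowest validation loss). Training is a pure
#' function of (data, config seed) on CPU. A non-finite loss aborts with a
#' diagnostic.
#'
#' Note: `model` is updated in place (parameters are reference objects); the
#' returned fit holds the best-epoch state, which is also loaded back into
#' `model`.
#'
#' @param model A `spine_unet` from [build_model()].
#' @param train_set,val_set Non-empty lists of `list(image, mask)` pairs;
#'   images `H x W` in 0-255, masks integer class IDs.
#' @param cfg A [train_config()].
#' @return An object of class `spineseg_fit`: list with `model`, `log`
#'   (one row per epoch), `best_epoch`, `cfg`.
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config()) {
  stopifnot(inherits(model, "spine_unet"), inherits(cfg, "train_config"))
  if (length(train_set) == 0L || length(val_set) == 0L)
    stop("training and validation sets must be non-empty")
  nc <- model$cfg$n_classes
  opt <- adam_state(model$params, lr = cfg$learning_rate)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    train_ce = numeric(0), train_dice_loss = numeric(0),
                    val_loss = numeric(0), val_P = numeric(0),
                    val_R = numeric(0), val_dice = numeric(0))
  best <- list(loss = Inf, state = NULL, epoch = 0L)
  if (!is.null(cfg$checkpoint_dir))
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  with_rng(cfg$rng_seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(length(train_set))
      eloss <- ece <- edice <- numeric(0)
      i <- 1L
      while (i <= length(idx)) {
        take <- train_set[idx[seq(i, min(i + cfg$batch_size - 1L, length(idx)))]]
        ba <- batch_arrays(take, nc)
        probs <- forward_model(model, ba$x, training = TRUE)
        loss <- hybrid_loss_node(probs, ba$y, cfg$w_ce, cfg$w_dice)
        if (!is.finite(loss$value))
          stop(sprintf("non-finite loss at epoch %d (ce=%g, dice=%g): aborting",
                       epoch, loss$ce, loss$dice))
        ad_zero_grad(model$params)
        ad_backward(loss)
        opt <- adam_step(model$params, opt)
        eloss <- c(eloss, loss$value)
        ece <- c(ece, loss$ce)
        edice <- c(edice, loss$dice)
        i <- i + cfg$batch_size
      }
      val <- validate_pass(model, val_set, cfg)
      log[epoch, ] <- list(epoch, mean(eloss), mean(ece), mean(edice),
                           val$loss, val$metrics[["P"]], val$metrics[["R"]],
                           val$metrics[["Dice"]])
      if (!is.null(cfg$checkpoint_dir))
        save_checkpoint(model, file.path(cfg$checkpoint_dir,
                                         sprintf("epoch_%03d.rds", epoch)))
      if (val$loss < best$loss)
        best <- list(loss = val$loss, state = model_state(model), epoch = epoch)
    }
  })
  load_model_state(model, best$state)
  structure(list(model = model, log = log, best_epoch = best$epoch, cfg = cfg),
            class = "spineseg_fit")
}

#' Evaluate a model on a test set
#'
#' Predicts a mask for every image and accumulates confusion counts at both
#' granularities: image level (one presence verdict per image-class pair)
#' and pixel level (per-pixel class membership over the foreground classes).
#'
#' @param model A `spine_unet` or `spineseg_fit`.
#' @param test_set List of `list(image, mask)` pairs.
#' @return List with `report` (data.frame rows per granularity: TP, FP, FN,
#'   P, R, Dice), `counts_image`, `counts_pixel`, and `predictions`.
#' @export
evaluate_model <- function(model, test_set) {
  if (inherits(model, "spineseg_fit")) model <- model$model
  preds <- lapply(test_set, function(p) predict_mask(model, p$image))
  truths <- lapply(test_set, `[[`, "mask")
  ci <- confusion_counts(class_presence(preds), class_presence(truths),
                         unit = "image")
  cp <- confusion_counts(preds, truths, unit = "pixel")
  mk_row <- function(unit, cc) {
    m <- suppressWarnings(seg_metrics(cc))
    data.frame(unit = unit, TP = cc$TP, FP = cc$FP, FN = cc$FN,
               P = m[["P"]], R = m[["R"]], Dice = m[["Dice"]])
  }
  list(report = rbind(mk_row("image", ci), mk_row("pixel", cp)),
       counts_image = ci, counts_pixel = cp, predictions = preds)
}

#' @export
print.spineseg_fit <- function(x, ...) {
  cat(sprintf("spineseg_fit: %d epochs, best epoch %d (val loss %.4f)\n",
              nrow(x$log), x$best_epoch, x$log$val_loss[x$best_epoch]))
  cat(sprintf("  final val Dice: %.2f%%\n", x$log$val_dice[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.spineseg_fit <- function(object, ...) {
  cat("Training log (per epoch):\n")
  print(object$log, row.names = FALSE, digits = 4)
  invisible(object$log)
}

#' @export
predict.spineseg_fit <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(predict_mask(object$model, newdata))
  lapply(newdata, function(p)
    predict_mask(object$model, if (is.list(p)) p$image else p))
}

#' @export
plot.spineseg_fit <- function(x, ...) {
  log <- x$log
  graphics::plot(log$epoch, log$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "hybrid loss",
                 ylim = range(c(log$train_loss, log$val_loss)), ...)
  graphics::lines(log$epoch, log$val_loss, col = "firebrick")
  graphics::legend("topright", legend = c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
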