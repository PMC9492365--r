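# Assembly of the attention-gated residual U-Net and the baseline
# Attention U-Net configuration.

#' Network configuration
#'
#' @param n_levels Number of downsampling (2x2 max-pool) stages. Defaults to
#'   3 for the improved variant and 4 for the baseline Attention U-Net.
#' @param base_channels Feature channels at the first encoder level; doubled
#'   at every downsampling.
#' @param n_classes Output classes (background + 3 tissue classes by default).
#' @param in_channels Input image channels (grayscale MRI: 1).
#' @param variant `"improved"` (residual blocks, 3 levels) or
#'   `"baseline_attention_unet"` (plain double-conv blocks, 4 levels).
#' @param upsample_mode Decoder upsampling: `"transposed_conv"` (learned 2x2
#'   stride-2 deconvolution, the default) or `"bilinear"` (fixed bilinear x2
#'   followed by a 1x1 channel-reducing convolution).
#' @param gate_combine How the two projected branches inside each attention
#'   gate are fused: `"add"` (default) or `"mul"`.
#' @return A `net_config` list.
#' @export
net_config <- function(n_levels = NULL, base_channels = 32L, n_classes = 4L,
                       in_channels = 1L,
                       variant = c("improved", "baseline_attention_unet"),
                       upsample_mode = c("transposed_conv", "bilinear"),
                       gate_combine = c("add", "mul")) {
  variant <- match.arg(variant)
  upsample_mode <- match.arg(upsample_mode)
  gate_combine <- match.arg(gate_combine)
  if (is.null(n_levels))
    n_levels <- if (variant == "improved") 3L else 4L
  n_levels <- as.integer(n_levels)
  base_channels <- as.integer(base_channels)
  n_classes <- as.integer(n_classes)
  if (n_levels < 1L) stop("n_levels must be >= 1")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  structure(list(n_levels = n_levels, base_channels = base_channels,
                 n_classes = n_classes, in_channels = as.integer(in_channels),
                 variant = variant, upsample_mode = upsample_mode,
                 gate_combine = gate_combine),
            class = "net_config")
}

#' Build the segmentation network
#'
#' Constructs the U-shaped network: an encoder of residual blocks (shallow at
#' the first level, deep at the others), each followed by 2x2 stride-2 max
#' pooling; a deep residual bottleneck; and a decoder that upsamples, gates
#' the matching encoder skip through an attention gate, concatenates and
#' convolves back down (deep blocks, shallow at the final full-resolution
#' level). A 1x1 convolution head produces per-pixel class scores, turned
#' into probabilities by a channel softmax. The
#' `"baseline_attention_unet"` variant swaps all residual blocks for plain
#' double-3x3-convolution blocks and uses 4 pooling stages instead of 3.
#'
#' @param cfg A [net_config()].
#' @return An object of class `spine_unet`.
#' @export
build_model <- function(cfg = net_config()) {
  stopifnot(inherits(cfg, "net_config"))
  L <- cfg$n_levels
  b <- cfg$base_channels
  enc_ch <- b * 2L^(seq_len(L) - 1L)
  improved <- cfg$variant == "improved"
  mk_block <- function(in_ch, out_ch, level) {
    if (!improved) return(new_plain_block(in_ch, out_ch))
    if (level == 1L) new_shallow_block(in_ch, out_ch)
    else new_deep_block(in_ch, out_ch)
  }
  enc <- vector("list", L)
  in_ch <- cfg$in_channels
  for (i in seq_len(L)) {
    enc[[i]] <- mk_block(in_ch, enc_ch[i], i)
    in_ch <- enc_ch[i]
  }
  bottleneck <- mk_block(enc_ch[L], 2L * enc_ch[L], L + 1L)
  up <- gates <- dec <- vector("list", L)
  for (i in rev(seq_len(L))) {
    hi_ch <- 2L * enc_ch[i]
    up[[i]] <- if (cfg$upsample_mode == "transposed_conv") {
      convt_layer(hi_ch, enc_ch[i])
    } else {
      conv_layer(hi_ch, enc_ch[i], 1L)
    }
    gates[[i]] <- new_attention_gate(enc_ch[i], hi_ch, combine = cfg$gate_combine)
    dec[[i]] <- mk_block(2L * enc_ch[i], enc_ch[i], i)
  }
  head <- conv_layer(enc_ch[1], cfg$n_classes, 1L)
  params <- c(
    unlist(lapply(enc, `[[`, "params"), recursive = FALSE),
    bottleneck$params,
    unlist(lapply(up, conv_params), recursive = FALSE),
    unlist(lapply(gates, `[[`, "params"), recursive = FALSE),
    unlist(lapply(dec, `[[`, "params"), recursive = FALSE),
    conv_params(head)
  )
  bns <- c(
    unlist(lapply(enc, `[[`, "bns"), recursive = FALSE),
    bottleneck$bns,
    unlist(lapply(gates, `[[`, "bns"), recursive = FALSE),
    unlist(lapply(dec, `[[`, "bns"), recursive = FALSE)
  )
  structure(list(cfg = cfg, enc = enc, bottleneck = bottleneck, up = up,
                 gates = gates, dec = dec, head = head, params = params,
                 bns = bns),
            class = "spine_unet")
}

# Forward pass returning the softmax node (and logits). `x` is an
# (N, in_channels, H, W) node or array.
forward_model <- function(model, x, training = TRUE) {
  if (!is.environment(x)) x <- ad_leaf(x)
  d <- dim4(x$value)
  L <- model$cfg$n_levels
  if (d[3] %% 2L^L != 0L || d[4] %% 2L^L != 0L)
    stop("input spatial size must be divisible by 2^n_levels = ", 2L^L)
  skips <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    skips[[i]] <- block_forward_node(model$enc[[i]], h, training)
    h <- ad_maxpool2(skips[[i]])
  }
  h <- block_forward_node(model$bottleneck, h, training)
  alphas <- vector("list", L)
  for (i in rev(seq_len(L))) {
    u <- if (model$cfg$upsample_mode == "transposed_conv") {
      ad_convt2x2(h, model$up[[i]]$w, model$up[[i]]$b)
    } else {
      conv_fw(model$up[[i]], ad_upsample2_bilinear(h))
    }
    gated <- attention_gate_node(model$gates[[i]], skips[[i]], h, training)
    alphas[[i]] <- gated$alpha
    h <- block_forward_node(model$dec[[i]], ad_concat(u, gated), training)
  }
  logits <- conv_fw(model$head, h)
  probs <- ad_softmax(logits)
  probs$logits <- logits
  probs$alphas <- alphas
  probs
}

#' Per-pixel class probabilities for a batch of images
#'
#' @param model A `spine_unet` from [build_model()].
#' @param x Numeric array `(N, in_channels, H, W)` with values in `[0, 1]`,
#'   or a grayscale matrix in `[0, 255]` (converted automatically).
#' @param training Logical; batch statistics (TRUE) vs running statistics.
#' @return Numeric array `(N, n_classes, H, W)`; channel sums are 1 at every
#'   pixel.
#' @export
predict_probs <- function(model, x, training = FALSE) {
  x <- as_model_input(x, model$cfg$in_channels)
  forward_model(model, x, training = training)$value
}

as_model_input <- function(x, in_channels = 1L) {
  if (is.matrix(x)) {
    x <- array(x / 255, dim = c(1L, in_channels, nrow(x), ncol(x)))
  }
  stopifnot(length(dim(x)) == 4L)
  x
}

#' Predict a label mask for one grayscale image
#'
#' Runs the network and takes the per-pixel argmax over the class softmax.
#' Ties are broken toward the lowest class ID.
#'
#' @param model A `spine_unet`.
#' @param image Grayscale matrix (`H x W`, values 0-255) or `(1, C, H, W)`
#'   array already scaled to `[0, 1]`.
#' @return Integer `H x W` matrix of class IDs (0 = background, 1 = L,
#'   2 = LD, 3 = S).
#' @export
predict_mask <- function(model, image) {
  p <- predict_probs(model, image)
  probs_to_mask(p)[[1]]
}

# argmax over the class axis with lowest-ID tie-break; returns a list of
# H x W integer matrices, one per batch element.
probs_to_mask <- function(p) {
  d <- dim4(p)
  lapply(seq_len(d[1]), function(n) {
    best <- matrix(0L, d[3], d[4])
    bestp <- p[n, 1L, , ]
    if (d[2] > 1L) for (c in 2:d[2]) {
      pc <- p[n, c, , ]
      take <- pc > bestp          # strict: ties keep the lower class ID
      best[take] <- c - 1L
      bestp[take] <- pc[take]
    }
    best
  })
}

#' @export
print.spine_unet <- function(x, ...) {
  cfg <- x$cfg
  npar <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf(
    "spine_unet (%s)\n  levels: %d  base channels: %d  classes: %d\n  upsampling: %s  gate combine: %s\n  parameters: %s\n",
    cfg$variant, cfg$n_levels, cfg$base_channels, cfg$n_classes,
    cfg$upsample_mode, cfg$gate_combine, format(npar, big.mark = ",")))
  invisible(x)
}
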