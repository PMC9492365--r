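# Building blocks of the attention-gated residual U-Net: convolution and
# batch-norm layers, the two residual blocks, the plain double-conv block of
# the baseline variant, and the multilevel-fusion attention gate.

conv_layer <- function(in_ch, out_ch, k) {
  w <- new_param(init_conv_weight(c(out_ch, in_ch, k, k)))
  b <- new_param(numeric(out_ch))
  list(w = w, b = b, k = k)
}

convt_layer <- function(in_ch, out_ch) {
  w <- new_param(init_conv_weight(c(in_ch, out_ch, 2L, 2L),
                                  fan_in = in_ch * 4L))
  b <- new_param(numeric(out_ch))
  list(w = w, b = b)
}

bn_layer <- function(ch, eps = 1e-5, momentum = 0.1) {
  e <- new.env(parent = emptyenv())
  e$gamma <- new_param(rep(1, ch))
  e$beta <- new_param(numeric(ch))
  e$running_mean <- numeric(ch)
  e$running_var <- rep(1, ch)
  e$eps <- eps
  e$momentum <- momentum
  e
}

conv_fw <- function(layer, x) ad_conv2d(x, layer$w, layer$b)
bn_fw <- function(layer, x, training) ad_bn(x, layer$gamma, layer$beta, layer, training)

conv_params <- function(layer) list(layer$w, layer$b)
bn_params <- function(layer) list(layer$gamma, layer$beta)

# Bilinear x2 upsampling with half-pixel centers (edge-clamped), used as the
# non-learned Up inside attention gates and for the bilinear decoder option.
up2_weights <- function(H) {
  o <- seq_len(2L * H) - 1L
  src <- o %/% 2L
  even <- o %% 2L == 0L
  i1 <- ifelse(even, pmax(src - 1L, 0L), src) + 1L
  i2 <- ifelse(even, src, pmin(src + 1L, H - 1L)) + 1L
  w1 <- ifelse(even, 0.25, 0.75)
  w2 <- 1 - w1
  w1[i1 == i2] <- 0.5
  w2[i1 == i2] <- 0.5
  list(i1 = i1, i2 = i2, w1 = w1, w2 = w2)
}

scale_dim3 <- function(a, w) {
  d <- dim(a)
  v <- a
  dim(v) <- c(d[1] * d[2] * d[3], d[4])
  v <- v * rep(w, each = d[1] * d[2])
  dim(v) <- d
  v
}

scale_dim4 <- function(a, w) {
  d <- dim(a)
  v <- a
  dim(v) <- c(d[1] * d[2] * d[3], d[4])
  v <- sweep(v, 2L, w, "*")
  dim(v) <- d
  v
}

upsample2_bilinear_fw <- function(x) {
  d <- dim4(x)
  uh <- up2_weights(d[3])
  uw <- up2_weights(d[4])
  a <- scale_dim3(x[, , uh$i1, , drop = FALSE], uh$w1) +
    scale_dim3(x[, , uh$i2, , drop = FALSE], uh$w2)
  scale_dim4(a[, , , uw$i1, drop = FALSE], uw$w1) +
    scale_dim4(a[, , , uw$i2, drop = FALSE], uw$w2)
}

upsample2_bilinear_bw <- function(g, hin, win) {
  d <- dim4(g)
  uh <- up2_weights(hin)
  uw <- up2_weights(win)
  ga <- array(0, c(d[1], d[2], d[3], win))
  for (o in seq_len(d[4])) {
    gs <- g[, , , o, drop = FALSE]
    ga[, , , uw$i1[o]] <- ga[, , , uw$i1[o], drop = FALSE] + gs * uw$w1[o]
    ga[, , , uw$i2[o]] <- ga[, , , uw$i2[o], drop = FALSE] + gs * uw$w2[o]
  }
  gx <- array(0, c(d[1], d[2], hin, win))
  for (o in seq_len(d[3])) {
    gs <- ga[, , o, , drop = FALSE]
    gx[, , uh$i1[o], ] <- gx[, , uh$i1[o], , drop = FALSE] + gs * uh$w1[o]
    gx[, , uh$i2[o], ] <- gx[, , uh$i2[o], , drop = FALSE] + gs * uh$w2[o]
  }
  gx
}

ad_upsample2_bilinear <- function(x) {
  d <- dim4(x$value)
  node <- ad_node(upsample2_bilinear_fw(x$value), list(x), NULL)
  node$backward <- function(g) {
    ad_accum(x, upsample2_bilinear_bw(g, d[3], d[4]))
  }
  node
}

## ---- blocks ----

#' Create a shallow residual block
#'
#' The block used at the outermost (full-resolution) encoder and decoder
#' layers: a main path of two 3x3 convolutions, each followed by batch
#' normalization and ReLU, summed with a 1x1-convolution shortcut projection
#' of the input. With a zeroed main path the block reduces to its shortcut.
#'
#' @param in_ch,out_ch Input/output channel counts.
#' @return A block object; pass to [block_forward()].
#' @export
new_shallow_block <- function(in_ch, out_ch) {
  b <- list(
    type = "shallow",
    conv1 = conv_layer(in_ch, out_ch, 3L), bn1 = bn_layer(out_ch),
    conv2 = conv_layer(out_ch, out_ch, 3L), bn2 = bn_layer(out_ch),
    shortcut = conv_layer(in_ch, out_ch, 1L)
  )
  b$params <- c(conv_params(b$conv1), bn_params(b$bn1),
                conv_params(b$conv2), bn_params(b$bn2),
                conv_params(b$shortcut))
  b$bns <- list(b$bn1, b$bn2)
  class(b) <- "spineseg_block"
  b
}

#' Create a deep residual block
#'
#' The block used at the inner layers and the bottleneck: two parallel 5x5
#' convolution branches (each with batch normalization and ReLU) are
#' channel-concatenated, doubling the channel count, fused by a 3x3
#' convolution + BN + ReLU down to `out_ch`, and summed with a 1x1 shortcut
#' projection of the input.
#'
#' @inheritParams new_shallow_block
#' @return A block object; pass to [block_forward()].
#' @export
new_deep_block <- function(in_ch, out_ch) {
  b <- list(
    type = "deep",
    conv5a = conv_layer(in_ch, in_ch, 5L), bn5a = bn_layer(in_ch),
    conv5b = conv_layer(in_ch, in_ch, 5L), bn5b = bn_layer(in_ch),
    fuse = conv_layer(2L * in_ch, out_ch, 3L), bnf = bn_layer(out_ch),
    shortcut = conv_layer(in_ch, out_ch, 1L)
  )
  b$params <- c(conv_params(b$conv5a), bn_params(b$bn5a),
                conv_params(b$conv5b), bn_params(b$bn5b),
                conv_params(b$fuse), bn_params(b$bnf),
                conv_params(b$shortcut))
  b$bns <- list(b$bn5a, b$bn5b, b$bnf)
  class(b) <- "spineseg_block"
  b
}

# Plain double 3x3 conv block (the baseline Attention U-Net convolution unit).
new_plain_block <- function(in_ch, out_ch) {
  b <- list(
    type = "plain",
    conv1 = conv_layer(in_ch, out_ch, 3L), bn1 = bn_layer(out_ch),
    conv2 = conv_layer(out_ch, out_ch, 3L), bn2 = bn_layer(out_ch)
  )
  b$params <- c(conv_params(b$conv1), bn_params(b$bn1),
                conv_params(b$conv2), bn_params(b$bn2))
  b$bns <- list(b$bn1, b$bn2)
  class(b) <- "spineseg_block"
  b
}

block_forward_node <- function(block, x, training = TRUE) {
  if (block$type == "shallow") {
    h <- ad_relu(bn_fw(block$bn1, conv_fw(block$conv1, x), training))
    h <- ad_relu(bn_fw(block$bn2, conv_fw(block$conv2, h), training))
    ad_add(h, conv_fw(block$shortcut, x))
  } else if (block$type == "deep") {
    b1 <- ad_relu(bn_fw(block$bn5a, conv_fw(block$conv5a, x), training))
    b2 <- ad_relu(bn_fw(block$bn5b, conv_fw(block$conv5b, x), training))
    h <- ad_concat(b1, b2)
    h <- ad_relu(bn_fw(block$bnf, conv_fw(block$fuse, h), training))
    ad_add(h, conv_fw(block$shortcut, x))
  } else {
    h <- ad_relu(bn_fw(block$bn1, conv_fw(block$conv1, x), training))
    ad_relu(bn_fw(block$bn2, conv_fw(block$conv2, h), training))
  }
}

#' Run a residual or plain convolution block on a feature map
#'
#' @param block A block from [new_shallow_block()], [new_deep_block()].
#' @param x Numeric 4-D array `(N, C, H, W)`.
#' @param training Logical; use batch statistics (TRUE) or running statistics
#'   in batch normalization.
#' @return Numeric 4-D array `(N, out_ch, H, W)`.
#' @export
block_forward <- function(block, x, training = FALSE) {
  stopifnot(length(dim(x)) == 4L)
  block_forward_node(block, ad_leaf(x), training)$value
}

#' Convenience wrappers for one-off block application
#'
#' `shallow_residual_block()` and `deep_residual_block()` build a freshly
#' initialized block (weights drawn from the current RNG state) and apply it
#' to `x`; use the `new_*` constructors to keep and reuse weights.
#'
#' @param x Numeric 4-D array `(N, C, H, W)`.
#' @param out_channels Output channel count.
#' @return Numeric 4-D array `(N, out_channels, H, W)`.
#' @export
shallow_residual_block <- function(x, out_channels) {
  block_forward(new_shallow_block(dim4(x)[2], out_channels), x, training = TRUE)
}

#' @rdname shallow_residual_block
#' @export
deep_residual_block <- function(x, out_channels) {
  block_forward(new_deep_block(dim4(x)[2], out_channels), x, training = TRUE)
}

## ---- attention gate ----

#' Create an attention gate
#'
#' Multilevel-fusion attention gate for a skip connection. The encoder skip
#' features `x` pass through a 1x1 convolution + batch normalization; the
#' coarser decoder gating signal `g` is upsampled (bilinear x2) and likewise
#' projected by 1x1 convolution + BN; the two branches are combined
#' (elementwise addition by default, elementwise multiplication with
#' `combine = "mul"`), passed through ReLU, a 1x1 convolution to a single
#' channel and a sigmoid, giving per-pixel attention coefficients
#' `alpha` in `[0, 1]` that scale `x` across all channels.
#'
#' @param x_ch Channels of the encoder skip features.
#' @param g_ch Channels of the gating signal.
#' @param inter_ch Intermediate channel width; default
#'   `max(1, floor(min(x_ch, g_ch) / 2))`.
#' @param combine `"add"` (default) or `"mul"` for how the two projected
#'   branches are fused before ReLU.
#' @return A gate object; pass to [attention_gate()].
#' @export
new_attention_gate <- function(x_ch, g_ch,
                               inter_ch = max(1L, min(x_ch, g_ch) %/% 2L),
                               combine = c("add", "mul")) {
  combine <- match.arg(combine)
  gt <- list(
    theta = conv_layer(x_ch, inter_ch, 1L), bn_x = bn_layer(inter_ch),
    phi = conv_layer(g_ch, inter_ch, 1L), bn_g = bn_layer(inter_ch),
    psi = conv_layer(inter_ch, 1L, 1L),
    combine = combine
  )
  gt$params <- c(conv_params(gt$theta), bn_params(gt$bn_x),
                 conv_params(gt$phi), bn_params(gt$bn_g),
                 conv_params(gt$psi))
  gt$bns <- list(gt$bn_x, gt$bn_g)
  class(gt) <- "spineseg_gate"
  gt
}

attention_gate_node <- function(gate, x, g, training = TRUE) {
  dx <- dim4(x$value)
  dg <- dim4(g$value)
  if (all(dg[3:4] * 2L == dx[3:4])) {
    g <- ad_upsample2_bilinear(g)
  } else if (!all(dg[3:4] == dx[3:4])) {
    stop("gating signal must match the skip features or be one level coarser")
  }
  bx <- bn_fw(gate$bn_x, conv_fw(gate$theta, x), training)
  bg <- bn_fw(gate$bn_g, conv_fw(gate$phi, g), training)
  comb <- if (gate$combine == "mul") {
    node <- ad_node(bx$value * bg$value, list(bx, bg), NULL)
    node$backward <- function(gr) {
      ad_accum(bx, gr * bg$value)
      ad_accum(bg, gr * bx$value)
    }
    node
  } else {
    ad_add(bx, bg)
  }
  alpha <- ad_sigmoid(conv_fw(gate$psi, ad_relu(comb)))
  out <- ad_gate_mul(alpha, x)
  out$alpha <- alpha
  out
}

#' Apply an attention gate
#'
#' @param gate A gate from [new_attention_gate()]; if `NULL`, a freshly
#'   initialized gate matching the input channels is created.
#' @param x Encoder skip features, numeric array `(N, Cx, H, W)`.
#' @param g Gating signal, numeric array `(N, Cg, H/2, W/2)` (one level
#'   coarser) or `(N, Cg, H, W)`.
#' @param training Logical; batch vs running statistics in the gate's BN.
#' @return Gated features, same shape as `x`, with the attention
#'   coefficients (shape `(N, 1, H, W)`, values in `[0, 1]`) attached as
#'   attribute `"alpha"`.
#' @export
attention_gate <- function(x, g, gate = NULL, training = TRUE) {
  stopifnot(length(dim(x)) == 4L, length(dim(g)) == 4L)
  if (is.null(gate)) gate <- new_attention_gate(dim(x)[2], dim(g)[2])
  node <- attention_gate_node(gate, ad_leaf(x), ad_leaf(g), training)
  out <- node$value
  attr(out, "alpha") <- node$alpha$value
  out
}
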