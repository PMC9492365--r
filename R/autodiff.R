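# Reverse-mode autodiff over 4-D feature maps (N, C, H, W).
#
# Nodes are environments holding `value`, `grad`, `parents` and a `backward`
# closure that routes the incoming gradient to the parents. Parameters are
# plain leaf nodes that persist across forward passes; op nodes are created
# fresh each pass. Backward walks a DFS topological order from the loss node.

.ad_env <- new.env(parent = emptyenv())
.ad_env$visit <- 0L

ad_leaf <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backward <- NULL
  e
}

ad_node <- function(value, parents, backward) {
  e <- ad_leaf(value)
  e$parents <- parents
  e$backward <- backward
  e
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

ad_zero_grad <- function(nodes) {
  for (n in nodes) n$grad <- NULL
  invisible(nodes)
}

# Topological order by iterative post-order DFS over parents.
ad_topo <- function(root) {
  tag <- .ad_env$visit + 1L
  .ad_env$visit <- tag
  order <- vector("list", 256L)
  norder <- 0L
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$expanded) {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
      next
    }
    if (identical(node$.vid, tag)) next
    node$.vid <- tag
    stack[[length(stack) + 1L]] <- list(node = node, expanded = TRUE)
    for (p in node$parents)
      if (!identical(p$.vid, tag))
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
  }
  order[seq_len(norder)]
}

# Backpropagate from a scalar loss node.
ad_backward <- function(root) {
  order <- ad_topo(root)
  root$grad <- 1
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node$grad)
  }
  invisible(root)
}

dim4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# Broadcast a (N,1,H,W) array across C channels -> (N,C,H,W).
bcast_channels <- function(a, C) {
  a[, rep(1L, C), , , drop = FALSE]
}

# Sum an (N,C,H,W) array over the channel axis -> (N,1,H,W).
sum_channels <- function(a) {
  d <- dim4(a)
  out <- a[, 1L, , , drop = FALSE]
  if (d[2] > 1L) for (c in 2:d[2]) out <- out + a[, c, , , drop = FALSE]
  out
}

# Per-channel sums of an (N,C,H,W) array -> length-C vector.
channel_sums <- function(x) {
  d <- dim4(x)
  v <- x
  dim(v) <- c(d[1] * d[2], d[3] * d[4])
  s <- rowSums(v)
  dim(s) <- c(d[1], d[2])
  colSums(s)
}

# Scale/shift an (N,C,H,W) array with per-channel vectors: x * a[c] + b[c].
channel_affine <- function(x, a, b = NULL) {
  d <- dim4(x)
  v <- x
  dim(v) <- c(d[1] * d[2], d[3] * d[4])
  fa <- rep(a, each = d[1])
  v <- v * fa
  if (!is.null(b)) v <- v + rep(b, each = d[1])
  dim(v) <- d
  v
}

## ---- ops ----

ad_conv2d <- function(x, w, b) {
  kd <- dim(w$value)
  ph <- (kd[3] - 1L) %/% 2L
  pw <- (kd[4] - 1L) %/% 2L
  y <- cpp_conv2d(x$value, w$value, b$value, ph, pw)
  node <- ad_node(y, list(x, w, b), NULL)
  node$backward <- function(g) {
    gr <- cpp_conv2d_grad(x$value, w$value, g, ph, pw)
    ad_accum(x, gr$gx)
    ad_accum(w, gr$gw)
    ad_accum(b, gr$gb)
  }
  node
}

ad_convt2x2 <- function(x, w, b) {
  y <- cpp_convt2x2(x$value, w$value, b$value)
  node <- ad_node(y, list(x, w, b), NULL)
  node$backward <- function(g) {
    gr <- cpp_convt2x2_grad(x$value, w$value, g)
    ad_accum(x, gr$gx)
    ad_accum(w, gr$gw)
    ad_accum(b, gr$gb)
  }
  node
}

ad_maxpool2 <- function(x) {
  d <- dim4(x$value)
  r <- cpp_maxpool2(x$value)
  node <- ad_node(r$y, list(x), NULL)
  node$backward <- function(g) {
    ad_accum(x, cpp_maxpool2_grad(g, r$idx, d[3], d[4]))
  }
  node
}

# Nearest-neighbour x2 upsampling.
ad_upsample2 <- function(x) {
  d <- dim4(x$value)
  y <- x$value[, , rep(seq_len(d[3]), each = 2L), rep(seq_len(d[4]), each = 2L),
               drop = FALSE]
  node <- ad_node(y, list(x), NULL)
  node$backward <- function(g) {
    ho <- seq(1L, 2L * d[3], by = 2L)
    wo <- seq(1L, 2L * d[4], by = 2L)
    gx <- g[, , ho, wo, drop = FALSE] + g[, , ho + 1L, wo, drop = FALSE] +
      g[, , ho, wo + 1L, drop = FALSE] + g[, , ho + 1L, wo + 1L, drop = FALSE]
    ad_accum(x, gx)
  }
  node
}

ad_relu <- function(x) {
  mask <- x$value > 0
  node <- ad_node(x$value * mask, list(x), NULL)
  node$backward <- function(g) ad_accum(x, g * mask)
  node
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  node <- ad_node(s, list(x), NULL)
  node$backward <- function(g) ad_accum(x, g * s * (1 - s))
  node
}

ad_add <- function(a, b) {
  node <- ad_node(a$value + b$value, list(a, b), NULL)
  node$backward <- function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  }
  node
}

# Gate multiply: alpha (N,1,H,W) times x (N,C,H,W), broadcast over channels.
ad_gate_mul <- function(alpha, x) {
  C <- dim4(x$value)[2]
  A <- bcast_channels(alpha$value, C)
  node <- ad_node(A * x$value, list(alpha, x), NULL)
  node$backward <- function(g) {
    ad_accum(x, g * A)
    ad_accum(alpha, sum_channels(g * x$value))
  }
  node
}

ad_concat <- function(a, b) {
  da <- dim4(a$value)
  db <- dim4(b$value)
  stopifnot(all(da[c(1, 3, 4)] == db[c(1, 3, 4)]))
  y <- array(0, dim = c(da[1], da[2] + db[2], da[3], da[4]))
  y[, seq_len(da[2]), , ] <- a$value
  y[, da[2] + seq_len(db[2]), , ] <- b$value
  node <- ad_node(y, list(a, b), NULL)
  node$backward <- function(g) {
    ad_accum(a, g[, seq_len(da[2]), , , drop = FALSE])
    ad_accum(b, g[, da[2] + seq_len(db[2]), , , drop = FALSE])
  }
  node
}

# Batch normalization. `layer` carries running stats (updated in training mode).
ad_bn <- function(x, gamma, beta, layer, training = TRUE) {
  d <- dim4(x$value)
  m <- d[1] * d[3] * d[4]
  if (training) {
    mu <- channel_sums(x$value) / m
    xc <- channel_affine(x$value, rep(1, d[2]), -mu)
    var <- channel_sums(xc * xc) / m
    inv <- 1 / sqrt(var + layer$eps)
    xhat <- channel_affine(xc, inv)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * var
  } else {
    inv <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- channel_affine(x$value, inv, -layer$running_mean * inv)
  }
  y <- channel_affine(xhat, gamma$value, beta$value)
  node <- ad_node(y, list(x, gamma, beta), NULL)
  node$backward <- function(g) {
    ad_accum(gamma, channel_sums(g * xhat))
    ad_accum(beta, channel_sums(g))
    if (training) {
      gxh <- channel_affine(g, gamma$value)
      s1 <- channel_sums(gxh) / m
      s2 <- channel_sums(gxh * xhat) / m
      gx <- channel_affine(gxh - channel_affine(xhat, s2), inv, 0 * inv) -
        channel_affine(array(1, d), inv * s1)
      ad_accum(x, gx)
    } else {
      ad_accum(x, channel_affine(g, gamma$value * inv))
    }
  }
  node
}

# Channel softmax: per-pixel distribution over classes.
ad_softmax <- function(x) {
  d <- dim4(x$value)
  C <- d[2]
  mx <- x$value[, 1L, , , drop = FALSE]
  if (C > 1L) for (c in 2:C) mx <- pmax(mx, x$value[, c, , , drop = FALSE])
  e <- exp(x$value - bcast_channels(mx, C))
  p <- e / bcast_channels(sum_channels(e), C)
  node <- ad_node(p, list(x), NULL)
  node$backward <- function(g) {
    dot <- sum_channels(g * p)
    ad_accum(x, p * (g - bcast_channels(dot, C)))
  }
  node
}

# Mean cross-entropy of one-hot targets against probabilities. The log
# argument is clamped at `eps`; the gradient is zero on the clamped (flat)
# region.
ad_ce <- function(p, y, eps = 1e-12) {
  d <- dim4(p$value)
  npix <- d[1] * d[3] * d[4]
  pc <- pmax(p$value, eps)
  live <- p$value >= eps
  val <- -sum(y * log(pc)) / npix
  node <- ad_node(val, list(p), NULL)
  node$backward <- function(g) ad_accum(p, -(y * live / pc) * (g / npix))
  node
}

# Soft Dice loss over the given class indices (squared denominator).
ad_dice <- function(p, y, classes, eps = 1e-6) {
  K <- length(classes)
  num <- den <- numeric(K)
  for (i in seq_len(K)) {
    c <- classes[i]
    pc <- p$value[, c, , , drop = FALSE]
    yc <- y[, c, , , drop = FALSE]
    num[i] <- 2 * sum(pc * yc) + eps
    den[i] <- sum(pc * pc) + sum(yc * yc) + eps
  }
  val <- 1 - mean(num / den)
  node <- ad_node(val, list(p), NULL)
  node$backward <- function(g) {
    gp <- array(0, dim4(p$value))
    for (i in seq_len(K)) {
      c <- classes[i]
      pc <- p$value[, c, , , drop = FALSE]
      yc <- y[, c, , , drop = FALSE]
      gp[, c, , ] <- -(2 * yc * den[i] - num[i] * 2 * pc) / den[i]^2 * (g / K)
    }
    ad_accum(p, gp)
  }
  node
}

# Weighted sum of two scalar nodes.
ad_wsum <- function(a, b, wa = 1, wb = 1) {
  node <- ad_node(wa * a$value + wb * b$value, list(a, b), NULL)
  node$backward <- function(g) {
    ad_accum(a, wa * g)
    ad_accum(b, wb * g)
  }
  node
}

## ---- parameters and optimizer ----

# Kaiming-uniform initialization for a conv weight of the given shape,
# fan-in = prod of all but the first (output-channel) axis.
init_conv_weight <- function(shape, fan_in = prod(shape[-1])) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(shape), -bound, bound), dim = shape)
}

new_param <- function(value) ad_leaf(value)

adam_state <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
             m = lapply(params, function(p) 0 * p$value),
             v = lapply(params, function(p) 0 * p$value))
  st
}

adam_step <- function(params, st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g * g
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    p$value <- p$value - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  st
}
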