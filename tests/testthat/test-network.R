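test_that("residual blocks preserve spatial size and project channels", {
  set.seed(40)
  x <- array(rnorm(1 * 3 * 12 * 12), c(1, 3, 12, 12))
  ys <- shallow_residual_block(x, 6)
  yd <- deep_residual_block(x, 6)
  expect_identical(dim(ys), c(1L, 6L, 12L, 12L))
  expect_identical(dim(yd), c(1L, 6L, 12L, 12L))
  # the deep block's fusion conv consumes the channel-doubled concatenation
  blk <- new_deep_block(3, 6)
  expect_identical(dim(blk$fuse$w$value), c(6L, 6L, 3L, 3L))  # 2 * 3 inputs
})

test_that("blocks reduce to their shortcut path under zeroed main weights", {
  set.seed(41)
  x <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  for (ctor in list(new_shallow_block, new_deep_block)) {
    blk <- ctor(3, 5)
    # zero every main-path parameter, keep the 1x1 shortcut
    for (layer in blk[setdiff(names(blk), c("type", "shortcut", "params",
                                            "bns"))]) {
      if (is.environment(layer)) next
      layer$w$value[] <- 0
      layer$b$value[] <- 0
    }
    for (bn in blk$bns) bn$beta$value[] <- 0
    y <- block_forward(blk, x, training = TRUE)
    sc <- spineseg:::cpp_conv2d(x, blk$shortcut$w$value,
                                blk$shortcut$b$value, 0L, 0L)
    expect_equal(y, sc, tolerance = 1e-12)
    # and with a zeroed shortcut too, the output vanishes
    blk$shortcut$w$value[] <- 0
    blk$shortcut$b$value[] <- 0
    expect_true(all(block_forward(blk, x, training = TRUE) == 0))
  }
})

test_that("attention gates emit coefficients in [0, 1] at the skip size", {
  set.seed(42)
  x <- array(rnorm(1 * 4 * 8 * 8), c(1, 4, 8, 8))
  g <- array(rnorm(1 * 8 * 4 * 4), c(1, 8, 4, 4))
  out <- attention_gate(x, g)
  expect_identical(dim(out), dim(x))
  alpha <- attr(out, "alpha")
  expect_identical(dim(alpha), c(1L, 1L, 8L, 8L))
  expect_true(all(alpha >= 0 & alpha <= 1))
  # equal-size gating signal is accepted, one-level-coarser required otherwise
  expect_silent(attention_gate(x, array(rnorm(1 * 8 * 8 * 8), c(1, 8, 8, 8))))
  expect_error(attention_gate(x, array(rnorm(1 * 8 * 2 * 2), c(1, 8, 2, 2))),
               "coarser")
})

test_that("a zeroed final gate convolution forces alpha = 0.5 exactly", {
  set.seed(43)
  gate <- new_attention_gate(4, 8)
  gate$psi$w$value[] <- 0
  gate$psi$b$value[] <- 0
  x <- array(rnorm(1 * 4 * 8 * 8), c(1, 4, 8, 8))
  g <- array(rnorm(1 * 8 * 4 * 4), c(1, 8, 4, 4))
  out <- attention_gate(x, g, gate = gate)
  expect_true(all(attr(out, "alpha") == 0.5))
  expect_equal(out, 0.5 * x, ignore_attr = TRUE)
})

test_that("attention gate gradients match finite differences", {
  set.seed(44)
  gate <- new_attention_gate(2, 4)
  x <- array(rnorm(1 * 2 * 4 * 4), c(1, 2, 4, 4))
  g <- array(rnorm(1 * 4 * 2 * 2), c(1, 4, 2, 2))
  # scalar probe: sum(sin(gate output))
  loss_of <- function(xv) {
    node <- spineseg:::attention_gate_node(gate, spineseg:::ad_leaf(
      array(xv, dim(x))), spineseg:::ad_leaf(g), training = TRUE)
    sum(sin(node$value))
  }
  xl <- spineseg:::ad_leaf(x)
  node <- spineseg:::attention_gate_node(gate, xl, spineseg:::ad_leaf(g),
                                         training = TRUE)
  probe <- spineseg:::ad_node(sum(sin(node$value)), list(node), NULL)
  probe$backward <- function(gr) spineseg:::ad_accum(node, gr * cos(node$value))
  spineseg:::ad_backward(probe)
  num <- fd_gradient(loss_of, x)
  expect_lt(max(abs(num - as.vector(xl$grad)) / pmax(abs(num), 1e-3)), 1e-4)
})

test_that("deep residual block gradients match finite differences", {
  set.seed(45)
  blk <- new_deep_block(2, 3)
  x <- array(rnorm(1 * 2 * 6 * 6), c(1, 2, 6, 6))
  loss_of <- function(xv) {
    sum(sin(block_forward(blk, array(xv, dim(x)), training = TRUE)))
  }
  xl <- spineseg:::ad_leaf(x)
  node <- spineseg:::block_forward_node(blk, xl, training = TRUE)
  probe <- spineseg:::ad_node(sum(sin(node$value)), list(node), NULL)
  probe$backward <- function(gr) spineseg:::ad_accum(node, gr * cos(node$value))
  spineseg:::ad_backward(probe)
  num <- fd_gradient(loss_of, x)
  expect_lt(max(abs(num - as.vector(xl$grad)) / pmax(abs(num), 1e-3)), 1e-4)
})

test_that("the improved network contract holds on a 64x64 forward pass", {
  set.seed(46)
  model <- build_model(net_config(base_channels = 4))
  expect_identical(model$cfg$n_levels, 3L)
  x <- array(runif(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  probs <- predict_probs(model, x, training = TRUE)
  expect_identical(dim(probs), c(1L, 4L, 64L, 64L))
  sums <- apply(probs, c(1, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(probs >= 0))
  # encoder widths double while spatial sizes halve
  enc_w <- vapply(model$enc, function(b) dim(b$shortcut$w$value)[1], 0L)
  expect_identical(enc_w, c(4L, 8L, 16L))
  node <- spineseg:::forward_model(model, x, training = TRUE)
  for (al in node$alphas)
    expect_true(all(al$value >= 0 & al$value <= 1))
  expect_identical(vapply(node$alphas,
                          function(a) dim(a$value)[3], 0L),
                   c(64L, 32L, 16L))
})

test_that("the baseline variant has four pooling stages, the improved three", {
  improved <- build_model(net_config(base_channels = 2))
  baseline <- build_model(net_config(base_channels = 2,
                                     variant = "baseline_attention_unet"))
  expect_identical(improved$cfg$n_levels, 3L)
  expect_identical(baseline$cfg$n_levels, 4L)
  expect_length(improved$enc, 3)
  expect_length(baseline$enc, 4)
  # block types differ: residual blocks vs plain double-conv blocks
  expect_identical(improved$enc[[1]]$type, "shallow")
  expect_identical(improved$enc[[2]]$type, "deep")
  expect_true(all(vapply(baseline$enc, `[[`, "", "type") == "plain"))
  # improved rejects sizes not divisible by 8; baseline needs 16
  x24 <- array(runif(24 * 24), c(1, 1, 24, 24))
  expect_silent(predict_probs(improved, x24, training = TRUE))
  expect_error(predict_probs(baseline, x24, training = TRUE), "divisible")
})

test_that("argmax decoding breaks ties toward the lowest class ID", {
  p <- array(0.25, c(1, 4, 2, 2))          # exact four-way tie
  expect_true(all(spineseg:::probs_to_mask(p)[[1]] == 0L))
  p[1, 3, 1, 1] <- 0.5
  p[1, , 1, 1] <- p[1, , 1, 1] / sum(p[1, , 1, 1])
  expect_identical(spineseg:::probs_to_mask(p)[[1]][1, 1], 2L)
  # codomain of predict_mask is the class set
  set.seed(47)
  model <- build_model(net_config(base_channels = 2))
  mask <- predict_mask(model, small_phantom(1)$image)
  expect_true(all(mask %in% 0:3))
})

test_that("gradient reaches every parameter in one backward pass", {
  set.seed(48)
  for (variant in c("improved", "baseline_attention_unet")) {
    model <- build_model(net_config(base_channels = 2, variant = variant))
    hw <- if (variant == "improved") 16L else 16L
    x <- array(runif(hw * hw), c(1, 1, hw, hw))
    y <- one_hot_mask(matrix(sample(0:3, hw * hw, TRUE), hw, hw))
    probs <- spineseg:::forward_model(model, x, training = TRUE)
    loss <- spineseg:::hybrid_loss_node(probs, y)
    spineseg:::ad_zero_grad(model$params)
    spineseg:::ad_backward(loss)
    missing <- vapply(model$params, function(p) is.null(p$grad), TRUE)
    expect_identical(sum(missing), 0L)
    # a few ReLU channels can be dead at random init in so small a net,
    # but the overwhelming majority of parameters must receive signal
    nonzero <- vapply(model$params, function(p) any(p$grad != 0), TRUE)
    expect_gt(mean(nonzero), 0.8)
  }
})
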