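test_that("cross-entropy matches hand-computed values", {
  # perfect one-hot prediction
  y <- one_hot_mask(matrix(c(0L, 1L, 2L, 3L), 2, 2))
  expect_equal(cross_entropy_loss(y, y), 0, tolerance = 1e-9)
  # uniform prediction over 4 classes costs ln 4 per pixel
  p <- array(0.25, dim(y))
  expect_equal(cross_entropy_loss(p, y), log(4), tolerance = 1e-12)
  # 2-pixel case with true-class probabilities 0.5 and 0.25
  p2 <- array(0, c(1, 2, 1, 2))
  y2 <- array(0, c(1, 2, 1, 2))
  p2[1, , 1, 1] <- c(0.5, 0.5)
  p2[1, , 1, 2] <- c(0.75, 0.25)
  y2[1, 1, 1, 1] <- 1
  y2[1, 2, 1, 2] <- 1
  expect_equal(cross_entropy_loss(p2, y2), -(log(0.5) + log(0.25)) / 2,
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(p2, y2[, , , 1, drop = FALSE]), "shapes")
})

test_that("soft Dice loss matches hand-evaluated overlaps", {
  y <- one_hot_mask(matrix(c(1L, 1L, 0L, 0L), 2, 2))
  expect_lt(dice_loss(y, y), 1e-6)
  # disjoint single-class masks
  a <- one_hot_mask(matrix(c(1L, 1L, 0L, 0L), 2, 2))
  b <- one_hot_mask(matrix(c(0L, 0L, 1L, 1L), 2, 2))
  expect_gt(dice_loss(a, b, classes = 2L), 1 - 1e-5)
  # 4-pixel worked case on plain vectors: 1 - 2*1/(2+2) = 0.5
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5,
               tolerance = 1e-6)
})

test_that("the hybrid loss is the weighted sum of its terms", {
  set.seed(50)
  y <- one_hot_mask(matrix(sample(0:3, 16, TRUE), 4, 4))
  raw <- array(runif(64) + 0.1, c(1, 4, 4, 4))
  p <- raw / spineseg:::bcast_channels(spineseg:::sum_channels(raw), 4)
  hl <- hybrid_loss(p, y)
  expect_equal(hl$hybrid, hl$ce + hl$dice, tolerance = 1e-14)
  expect_equal(hl$ce, cross_entropy_loss(p, y), tolerance = 1e-14)
  expect_equal(hl$dice, dice_loss(p, y), tolerance = 1e-14)
  hw <- hybrid_loss(p, y, w_ce = 0.3, w_dice = 2)
  expect_equal(hw$hybrid, 0.3 * hw$ce + 2 * hw$dice, tolerance = 1e-14)
  # perfect prediction drives the hybrid to ~0
  expect_lt(hybrid_loss(y, y)$hybrid, 1e-6)
})

test_that("hybrid-loss gradients w.r.t. logits match finite differences", {
  set.seed(51)
  logits <- array(rnorm(1 * 4 * 4 * 4), c(1, 4, 4, 4))
  y <- one_hot_mask(matrix(sample(0:3, 16, TRUE), 4, 4))
  loss_of <- function(z) {
    node <- spineseg:::hybrid_loss_node(
      spineseg:::ad_leaf(array(z, dim(logits))), y)
    node$value
  }
  zl <- spineseg:::ad_leaf(logits)
  node <- spineseg:::hybrid_loss_node(zl, y)
  spineseg:::ad_backward(node)
  num <- fd_gradient(loss_of, logits)
  expect_lt(max(abs(num - as.vector(zl$grad)) / pmax(abs(num), 1e-3)), 1e-4)
})

test_that("confusion counts agree with a brute-force pairwise comparison", {
  set.seed(52)
  for (rep in 1:4) {
    pred <- runif(100) > 0.5
    truth <- runif(100) > 0.4
    cc <- confusion_counts(pred, truth)
    ref <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
    for (i in 1:100) {
      k <- if (pred[i] && truth[i]) "TP" else if (pred[i]) "FP"
      else if (truth[i]) "FN" else "TN"
      ref[k] <- ref[k] + 1L
    }
    expect_identical(c(TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN), ref)
  }
  # all correct positives
  cc <- confusion_counts(rep(TRUE, 10), rep(TRUE, 10))
  expect_identical(c(cc$TP, cc$FP, cc$FN), c(10L, 0L, 0L))
})

test_that("pixel-level confusion counts match direct set arithmetic", {
  ph <- small_phantom(9)
  pred <- ph$mask
  pred[1:8, ] <- 0L                        # damage the prediction
  cc <- confusion_counts(pred, ph$mask, unit = "pixel")
  tp <- sum(vapply(1:3, function(cl) sum(pred == cl & ph$mask == cl), 0))
  fn <- sum(vapply(1:3, function(cl) sum(pred != cl & ph$mask == cl), 0))
  expect_identical(cc$TP, as.integer(tp))
  expect_identical(cc$FN, as.integer(fn))
  # perfect prediction: P = R = Dice = 100
  perfect <- confusion_counts(ph$mask, ph$mask, unit = "pixel")
  expect_identical(unname(seg_metrics(perfect)), c(100, 100, 100))
})

test_that("seg_metrics reproduces the published benchmark rows", {
  # the strongest published configuration
  m <- seg_metrics(list(TP = 743, FP = 35, FN = 43))
  expect_identical(unname(m), c(95.50, 94.53, 95.01))
  # a single-improvement ablation row, checked at +/-0.01
  m2 <- seg_metrics(list(TP = 728, FP = 46, FN = 47), digits = NULL)
  expect_lt(max(abs(m2 - c(94.06, 93.94, 93.99))), 0.01 + 1e-9)
  # degenerate cases
  expect_identical(unname(seg_metrics(list(TP = 5, FP = 0, FN = 0))),
                   c(100, 100, 100))
  expect_warning(seg_metrics(list(TP = 0, FP = 0, FN = 3)), "zero denominator")
  expect_error(seg_metrics(list(TP = -1, FP = 0, FN = 0)), "nonnegative")
})

test_that("benchmark table flags exactly the arithmetically inconsistent rows", {
  bench <- lumbar_benchmarks()
  expect_identical(nrow(bench), 10L)
  expect_identical(bench$model[!bench$consistent], c("R-CNN", "U-Net"))
  # Dice is the harmonic mean of P and R on every consistent row
  cons <- bench[bench$consistent, ]
  hm <- round(2 * cons$P * cons$R / (cons$P + cons$R), 2)
  expect_true(all(abs(hm - cons$Dice) <= 0.01 + 1e-9))
})
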