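test_that("bilinear resize follows the half-pixel center convention", {
  img <- matrix(c(0, 0, 100, 100), 2, 2)   # two columns: 0 and 100
  out <- resize_linear(img, c(2, 4))
  # src = (dst + 0.5)/2 - 0.5 -> columns 0, 0.25, 0.75, 1 of the source
  expect_equal(out[1, ], c(0L, 25L, 75L, 100L))
  expect_equal(out[2, ], c(0L, 25L, 75L, 100L))
  # identity at own size
  ph <- small_phantom(1)
  expect_identical(resize_linear(ph$image, dim(ph$image)), ph$image)
  # any input reaches the full working resolution
  big <- resize_linear(ph$image, c(512, 512))
  expect_identical(dim(big), c(512L, 512L))
  expect_error(resize_linear(ph$image, c(0, 10)), "positive")
})

test_that("mask resize never blends class IDs", {
  ph <- small_phantom(2)
  up <- resize_nearest(ph$mask, c(128, 128))
  expect_true(all(up %in% 0:3))
  expect_identical(sort(unique(as.vector(up))), sort(unique(as.vector(ph$mask))))
  expect_identical(resize_nearest(ph$mask, dim(ph$mask)), ph$mask)
})

test_that("histogram equalization maps levels through the scaled CDF", {
  # two-level image: 75% at gray 50, 25% at gray 200
  img <- matrix(c(rep(50L, 75), rep(200L, 25)), 10, 10)
  out <- hist_equalize(img)
  expect_identical(sort(unique(as.vector(out))), c(191L, 255L))
  expect_true(all(out[img == 50] == 191))   # round(0.75 * 255)
  expect_true(all(out[img == 200] == 255))
  # near-uniform histogram stays close to identity
  flat <- matrix(rep(0:255, length.out = 256 * 8), 64, 32)
  eq <- hist_equalize(flat)
  expect_lt(max(abs(as.numeric(eq) - as.numeric(flat))), 2)
})

test_that("equalization flattens the cumulative distribution", {
  cdf_dist <- function(img) {
    cdf <- cumsum(tabulate(as.integer(img) + 1L, 256)) / length(img)
    mean(abs(cdf - (1:256) / 256))
  }
  for (seed in 1:20) {
    ph <- small_phantom(seed)
    expect_lte(cdf_dist(hist_equalize(ph$image)), cdf_dist(ph$image) + 1e-9)
  }
})

test_that("histogram equalization is idempotent up to one gray level", {
  for (seed in c(3, 11)) {
    e1 <- hist_equalize(small_phantom(seed)$image)
    e2 <- hist_equalize(e1)
    expect_lte(max(abs(e2 - e1)), 1)
  }
})

test_that("unclipped single-tile CLAHE reproduces global equalization", {
  for (seed in c(4, 12)) {
    ph <- small_phantom(seed)
    he <- hist_equalize(ph$image)
    cl <- clahe(ph$image, clahe_params(clip_limit = Inf, tile_grid = c(1, 1)))
    expect_lte(max(abs(cl - he)), 1)
  }
})

test_that("CLAHE respects basic contracts", {
  const <- matrix(77L, 32, 32)
  out <- clahe(const, clahe_params(tile_grid = c(2, 2)))
  expect_true(length(unique(as.vector(out))) == 1L)
  ph <- small_phantom(6, size = 64)
  out <- clahe(ph$image, clahe_params(clip_limit = 2, tile_grid = c(4, 4)))
  expect_identical(dim(out), dim(ph$image))
  expect_true(min(out) >= 0 && max(out) <= 255)
  expect_error(clahe(matrix(1, 4, 4), clahe_params(tile_grid = c(8, 8))),
               "finer")
  expect_error(clahe_params(clip_limit = 0.5), "clip_limit")
  expect_error(clahe_params(n_bins = 1), "n_bins")
})

test_that("contrast limiting amplifies background noise less than plain
           equalization", {
  worse <- 0
  for (seed in 1:6) {
    ph <- small_phantom(seed, size = 128, noise = 5)
    bg <- ph$mask == 0L
    sd_he <- stats::sd(hist_equalize(ph$image)[bg])
    sd_cl <- stats::sd(clahe(ph$image, clahe_params(clip_limit = 2,
                                                    tile_grid = c(4, 4)))[bg])
    if (sd_cl >= sd_he) worse <- worse + 1
    expect_lt(sd_cl, sd_he)
  }
})

test_that("LBP codes match a hand-enumerated 3x3 example", {
  expect_true(all(lbp(matrix(42L, 8, 8)) == 255L))
  img <- matrix(10L, 9, 9)
  img[5, 5] <- 200L
  expect_identical(lbp(img)[5, 5], 0L)
  # brute-force enumeration on a worked 3x3 block
  m <- matrix(c(5, 9, 1,
                3, 6, 7,
                8, 2, 4), 3, 3, byrow = TRUE)
  got <- lbp(m, radius = 1, n_neighbors = 8)
  # hand enumeration, bits k = 0..7 counterclockwise from +x:
  # neighbors 7, 4, 2, 8, 3, 5, 9, 1 vs center 6 -> bits 0, 3 and 6 set
  expect_identical(got[2, 2], 1L + 8L + 64L)
  expect_error(lbp(matrix(1, 2, 2)), "too small")
})
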