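test_that("phantoms are deterministic under a fixed seed", {
  a <- generate_phantom(phantom_spec(image_size = 64, rng_seed = 7))
  b <- generate_phantom(phantom_spec(image_size = 64, rng_seed = 7))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_phantom(phantom_spec(image_size = 64, rng_seed = 8))
  expect_false(identical(a$image, c$image))
})

test_that("phantom masks carry the full anatomical inventory", {
  for (seed in c(1, 7, 33)) {
    ph <- small_phantom(seed)
    inv <- mask_inventory(ph$mask)
    expect_identical(inv, c(L = 5L, LD = 5L, S = 1L))
    expect_identical(dim(ph$image), dim(ph$mask))
    expect_true(min(ph$image) >= 0 && max(ph$image) <= 255)
    expect_true(all(ph$mask %in% 0:3))
  }
  # configurable inventory
  ph <- generate_phantom(phantom_spec(image_size = 96, n_vertebrae = 4,
                                      n_discs = 3, include_sacrum = FALSE,
                                      rng_seed = 2))
  expect_identical(mask_inventory(ph$mask), c(L = 4L, LD = 3L, S = 0L))
})

test_that("noise-free phantoms hit the exact configured intensities", {
  ph <- generate_phantom(phantom_spec(
    image_size = 64, noise_sigma = 0, rng_seed = 3,
    background_intensity_range = c(50, 50),
    vertebra_intensity_range = c(200, 200),
    disc_intensity_range = c(120, 120)))
  expect_true(all(ph$image[ph$mask == 1L] == 200))
  expect_true(all(ph$image[ph$mask == 0L] == 50))
  expect_true(all(ph$image[ph$mask == 2L] == 120))
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(image_size = 0), "positive")
  expect_error(phantom_spec(n_discs = 6, n_vertebrae = 5), "exceed")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(vertebra_intensity_range = c(300, 400)), "ranges")
})

test_that("augmentation core transforms behave as specified", {
  ph <- small_phantom(5)
  # identity draw
  out <- apply_augment(ph$image, ph$mask)
  expect_identical(out$image, ph$image)
  expect_identical(out$mask, ph$mask)
  # horizontal flip is an involution
  f1 <- apply_augment(ph$image, ph$mask, flip = TRUE)
  f2 <- apply_augment(f1$image, f1$mask, flip = TRUE)
  expect_identical(f2$mask, ph$mask)
  expect_identical(f2$image, ph$image)
  # masks keep integer classes under rotation
  r <- apply_augment(ph$image, ph$mask, angle = 8)
  expect_true(all(r$mask %in% 0:3))
  expect_identical(dim(r$mask), dim(ph$mask))
  expect_error(apply_augment(ph$image, ph$mask[1:10, ]), "shapes differ")
})

test_that("small rotations change per-class pixel counts by under 15%", {
  for (seed in 1:20) {
    ph <- small_phantom(seed)
    aug <- augment(ph$image, ph$mask, rng_seed = seed + 500)
    for (cl in 1:3) {
      n0 <- sum(ph$mask == cl)
      n1 <- sum(aug$mask == cl)
      expect_lt(abs(n1 - n0) / n0, 0.15)
    }
  }
})

test_that("augmented masks stay registered with the transformed image", {
  # noise-free phantom: transform image and mask, re-derive the vertebra
  # region from the image by thresholding, and require every mask pixel to
  # lie within 2 px (Chebyshev) of that region.
  ph <- generate_phantom(phantom_spec(
    image_size = 64, noise_sigma = 0, rng_seed = 9, include_sacrum = FALSE,
    background_intensity_range = c(50, 50),
    disc_intensity_range = c(60, 60),
    vertebra_intensity_range = c(200, 200)))
  out <- apply_augment(ph$image, ph$mask, flip = TRUE, angle = 9)
  region <- out$image > 125
  near <- spineseg:::dilate_binary(region, 2L)
  expect_true(all(near[out$mask == 1L]))
})

test_that("expand_dataset keeps originals and is seed-deterministic", {
  pairs <- phantom_pairs(1:3, size = 64)
  expect_identical(expand_dataset(pairs, 3), pairs)
  big1 <- expand_dataset(pairs, 10, rng_seed = 4)
  big2 <- expand_dataset(pairs, 10, rng_seed = 4)
  expect_length(big1, 10)
  expect_identical(big1[1:3], pairs)
  expect_identical(big1, big2)
  expect_false(identical(big1, expand_dataset(pairs, 10, rng_seed = 5)))
  expect_error(expand_dataset(list(), 5), "non-empty")
  expect_error(expand_dataset(pairs, 2), "target_count")
})

test_that("split_dataset honors 7:2:1 sizes and partitions the input", {
  pairs <- as.list(seq_len(1000))
  sp <- split_dataset(pairs, c(0.7, 0.2, 0.1), rng_seed = 1)
  expect_identical(lengths(sp), c(train = 700L, val = 200L, test = 100L))
  all_items <- c(sp$train, sp$val, sp$test)
  expect_setequal(unlist(all_items), 1:1000)
  expect_identical(sp, split_dataset(pairs, c(0.7, 0.2, 0.1), rng_seed = 1))
  # degenerate ratios
  sp2 <- split_dataset(as.list(1:10), c(1, 0, 0), rng_seed = 2)
  expect_length(sp2$train, 10)
  expect_length(sp2$val, 0)
  expect_error(split_dataset(as.list(1:2), c(0.5, 0.3, 0.2)), "fewer pairs")
})
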