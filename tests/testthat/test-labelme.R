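triangle_ann <- function() {
  new_annotation(list(list(label = "L",
                           points = cbind(x = c(2, 10, 2), y = c(2, 2, 10)))),
                 c(20, 20))
}

test_that("LabelMe JSON round-trips through write and read", {
  ann <- new_annotation(list(
    list(label = "L", points = cbind(x = c(1, 8, 8, 1), y = c(1, 1, 6, 6))),
    list(label = "LD", points = cbind(x = c(2, 9, 5), y = c(8, 8, 12))),
    list(label = "S", points = cbind(x = c(3, 12, 9), y = c(14, 14, 18)))
  ), c(20, 20))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_labelme(ann, path)
  back <- read_labelme(path)
  expect_length(back$shapes, 3)
  expect_identical(vapply(back$shapes, `[[`, "", "label"), c("L", "LD", "S"))
  expect_identical(back$image_size, c(20L, 20L))
  expect_equal(back$shapes[[2]]$points, ann$shapes[[2]]$points,
               ignore_attr = TRUE)
  # the three label categories map to class IDs 1, 2, 3 on rasterization
  m <- rasterize_annotation(back)
  expect_setequal(unique(as.vector(m)), c(0L, 1L, 2L, 3L))
})

test_that("unknown labels and malformed annotations are rejected", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  writeLines(jsonlite::toJSON(list(
    shapes = list(list(label = "XX", points = list(c(0, 0), c(3, 0), c(0, 3)))),
    imageHeight = 10, imageWidth = 10), auto_unbox = TRUE), path)
  expect_error(read_labelme(path), "XX")
  writeLines("{\"foo\": 1}", path)
  expect_error(read_labelme(path), "shapes")
  expect_error(new_annotation(list(list(label = "L",
                                        points = cbind(0:1, 0:1))), c(5, 5)),
               "3 vertices")
})

test_that("an axis-aligned rectangle rasterizes to the exact pixel count", {
  ann <- new_annotation(list(list(
    label = "L", points = cbind(x = c(0, 9, 9, 0), y = c(0, 0, 9, 9)))),
    c(20, 20))
  m <- rasterize_annotation(ann)
  expect_identical(sum(m == 1L), 100L)
  expect_true(all(m[1:10, 1:10] == 1L))
})

test_that("later shapes overwrite earlier ones and empty lists give zeros", {
  ann <- new_annotation(list(
    list(label = "L", points = cbind(x = c(0, 9, 9, 0), y = c(0, 0, 9, 9))),
    list(label = "LD", points = cbind(x = c(5, 14, 14, 5), y = c(5, 5, 14, 14)))
  ), c(20, 20))
  m <- rasterize_annotation(ann)
  expect_identical(m[7, 7], 2L)            # overlap goes to the later shape
  expect_identical(m[3, 3], 1L)
  empty <- rasterize_annotation(new_annotation(list(), c(8, 8)))
  expect_identical(empty, matrix(0L, 8, 8))
})

test_that("rasterization agrees with a brute-force even-odd oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:7, 1)
    poly <- cbind(x = runif(n, 0, 31), y = runif(n, 0, 31))
    ann <- new_annotation(list(list(label = "L", points = poly)), c(32, 32))
    m <- rasterize_annotation(ann)
    for (py in 0:31) for (px in 0:31) {
      expected <- brute_point_in_polygon(px, py, poly) ||
        brute_on_outline(px, py, poly)
      expect_identical(unname(m[py + 1, px + 1] == 1L), expected)
    }
  }
})

test_that("phantom annotations rasterize close to the phantom mask", {
  ph <- small_phantom(3)
  m <- rasterize_annotation(ph$annotation)
  expect_gt(mean(m == ph$mask), 0.93)
  # per-class overlap: boundary-inclusive polygon fill inflates thin
  # structures (discs, sacrum wedge) by ~1 px, so their Jaccard is lower
  iou <- vapply(1:3, function(cl)
    sum(m == cl & ph$mask == cl) / sum(m == cl | ph$mask == cl), 0)
  expect_gt(iou[1], 0.7)
  expect_true(all(iou[2:3] > 0.55))
})

test_that("colorize and decolorize are mutually inverse", {
  ph <- small_phantom(4)
  rgb <- colorize_mask(ph$mask)
  expect_identical(decolorize_mask(rgb), ph$mask)
  # all-background mask -> solid red
  red <- colorize_mask(matrix(0L, 5, 5))
  expect_true(all(red[, , 1] == 255L) && all(red[, , 2] == 0L) &&
                all(red[, , 3] == 0L))
  # solid green -> all vertebra class
  green <- array(0L, c(4, 4, 3))
  green[, , 2] <- 255L
  expect_true(all(decolorize_mask(green) == 1L))
  # a mask with all four classes shows exactly four distinct colors
  m4 <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  cols <- apply(colorize_mask(m4), c(1, 2), paste, collapse = ",")
  expect_length(unique(as.vector(cols)), 4)
  expect_error(colorize_mask(matrix(7L, 2, 2)), "outside")
})

test_that("decolorize tolerates small color perturbations", {
  set.seed(31)
  ph <- small_phantom(6)
  rgb <- colorize_mask(ph$mask)
  noisy <- spineseg:::clip8(rgb + sample(-5:5, length(rgb), replace = TRUE))
  expect_identical(decolorize_mask(noisy), ph$mask)
  far <- array(128L, c(2, 2, 3))
  expect_error(decolorize_mask(far, tolerance = 10), "tolerance")
})

test_that("grayscale and mask PNGs round-trip", {
  ph <- small_phantom(8)
  p1 <- tempfile(fileext = ".png")
  p2 <- tempfile(fileext = ".png")
  p3 <- tempfile(fileext = ".png")
  on.exit(unlink(c(p1, p2, p3)))
  write_gray_png(ph$image, p1)
  expect_identical(read_gray_png(p1), ph$image)
  write_mask_png(ph$mask, p2)
  expect_identical(read_mask_png(p2), ph$mask)
  write_rgb_png(colorize_mask(ph$mask), p3)
  expect_identical(read_mask_png(p3), ph$mask)   # RGB masks decode too
})
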