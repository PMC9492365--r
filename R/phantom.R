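# Synthetic sagittal lumbar-spine phantoms with paired ground-truth masks.
#
# A phantom is a vertically stacked spinal column on a darker soft-tissue
# background: bright superelliptic (rounded-rectangle) vertebral bodies
# alternating with thin, deliberately low-contrast elliptic intervertebral
# discs, and a wedge-shaped sacrum at the bottom. Geometry follows a gentle
# lordosis-like lateral curve; structure intensities are drawn per structure
# from configurable 8-bit ranges and Gaussian noise is added and clipped.

#' Phantom generator specification
#'
#' @param image_size Canvas size in pixels, `c(H, W)` or a single integer
#'   (default 512; tests typically use 64-128).
#' @param n_vertebrae Number of vertebral bodies (class 1, "L").
#' @param n_discs Number of intervertebral discs (class 2, "LD"); must not
#'   exceed `n_vertebrae` (each disc sits below a vertebra).
#' @param include_sacrum Add the wedge-shaped sacrum (class 3, "S").
#' @param vertebra_intensity_range,disc_intensity_range,background_intensity_range
#'   8-bit gray ranges the per-structure intensities are drawn from. Discs
#'   are deliberately low-contrast against the background, mirroring their
#'   relative darkness on T1 MRI.
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   gray levels.
#' @param rng_seed Integer seed; identical seeds give bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 512L, n_vertebrae = 5L, n_discs = 5L,
                         include_sacrum = TRUE,
                         vertebra_intensity_range = c(170, 220),
                         disc_intensity_range = c(90, 130),
                         background_intensity_range = c(40, 80),
                         noise_sigma = 8, rng_seed = 1L) {
  size <- parse_size(image_size)
  n_vertebrae <- as.integer(n_vertebrae)
  n_discs <- as.integer(n_discs)
  if (n_vertebrae < 1L) stop("n_vertebrae must be >= 1")
  if (n_discs < 0L) stop("n_discs must be >= 0")
  if (n_discs > n_vertebrae) stop("n_discs must not exceed n_vertebrae")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  for (r in list(vertebra_intensity_range, disc_intensity_range,
                 background_intensity_range))
    if (length(r) != 2L || any(r < 0) || any(r > 255) || r[1] > r[2])
      stop("intensity ranges must be increasing pairs within [0, 255]")
  structure(list(image_size = size, n_vertebrae = n_vertebrae,
                 n_discs = n_discs, include_sacrum = isTRUE(include_sacrum),
                 vertebra_intensity_range = vertebra_intensity_range,
                 disc_intensity_range = disc_intensity_range,
                 background_intensity_range = background_intensity_range,
                 noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Pixel membership of a superellipse |dx/a|^p + |dy/b|^p <= 1 (p = 4 gives
# the rounded-rectangle vertebra look, p = 2 an ellipse).
superellipse_pixels <- function(H, W, yc, xc, b, a, p) {
  py <- rep(seq_len(H) - 1, times = W)
  px <- rep(seq_len(W) - 1, each = H)
  matrix((abs((py - yc) / b))^p + (abs((px - xc) / a))^p <= 1, H, W)
}

superellipse_polygon <- function(yc, xc, b, a, p, n = 48L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  sgnpow <- function(u, q) sign(u) * abs(u)^q
  cbind(x = xc + a * sgnpow(cos(t), 2 / p),
        y = yc + b * sgnpow(sin(t), 2 / p))
}

triangle_pixels <- function(H, W, v) {
  py <- rep(seq_len(H) - 1, times = W)
  px <- rep(seq_len(W) - 1, each = H)
  side <- function(p1, p2) (px - p1[1]) * (p2[2] - p1[2]) - (py - p1[2]) * (p2[1] - p1[1])
  s1 <- side(v[1, ], v[2, ])
  s2 <- side(v[2, ], v[3, ])
  s3 <- side(v[3, ], v[1, ])
  matrix((s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0), H, W)
}

#' Generate a synthetic spine phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (integer `H x W` matrix, 0-255), `mask`
#'   (integer `H x W` class-ID matrix) and `annotation` (the analytic shape
#'   outlines as a LabelMe-style annotation, see [rasterize_annotation()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_rng(spec$rng_seed, {
    H <- spec$image_size[1]
    W <- spec$image_size[2]
    nv <- spec$n_vertebrae
    nd <- spec$n_discs
    sac <- spec$include_sacrum

    bg <- round(stats::runif(1, spec$background_intensity_range[1],
                             spec$background_intensity_range[2]))
    image <- matrix(as.numeric(bg), H, W)
    mask <- matrix(0L, H, W)
    shapes <- list()

    top <- 0.06 * H
    usable <- H * (if (sac) 0.86 else 0.90) - top
    unit <- usable / (nv + 0.38 * nd + if (sac) 1.25 else 0)
    gap <- max(1.5, 0.08 * unit)
    hv <- unit - gap                      # vertebra height budget
    hd <- 0.38 * unit - gap               # disc height budget
    wv <- 0.26 * W

    curve_x <- function(y) W * (0.5 + 0.05 * sin(pi * (y / H - 0.15)))

    paint <- function(pix, class_id, intensity, poly, label) {
      image[pix] <<- intensity
      mask[pix] <<- class_id
      shapes[[length(shapes) + 1L]] <<- list(label = label, points = poly)
    }

    y <- top
    for (i in seq_len(nv)) {
      # vertebra
      b2 <- max(1.2, hv / 2 * stats::runif(1, 0.92, 1))
      a2 <- max(1.5, wv / 2 * stats::runif(1, 0.9, 1.1))
      yc <- y + hv / 2
      xc <- curve_x(yc)
      vint <- round(stats::runif(1, spec$vertebra_intensity_range[1],
                                 spec$vertebra_intensity_range[2]))
      paint(superellipse_pixels(H, W, yc, xc, b2, a2, 4),
            1L, vint, superellipse_polygon(yc, xc, b2, a2, 4), "L")
      y <- y + hv + gap
      # disc below vertebra i (first n_discs vertebrae get one)
      if (i <= nd) {
        bd <- max(1.0, hd / 2 * stats::runif(1, 0.9, 1))
        ad <- max(1.5, a2 * stats::runif(1, 1.0, 1.12))
        ycd <- y + hd / 2
        xcd <- curve_x(ycd)
        dint <- round(stats::runif(1, spec$disc_intensity_range[1],
                                   spec$disc_intensity_range[2]))
        paint(superellipse_pixels(H, W, ycd, xcd, bd, ad, 2),
              2L, dint, superellipse_polygon(ycd, xcd, bd, ad, 2), "LD")
        y <- y + hd + gap
      }
    }
    if (sac) {
      hs <- 1.15 * unit
      xc <- curve_x(y)
      v <- rbind(c(xc - 0.55 * wv, y),
                 c(xc + 0.55 * wv, y),
                 c(xc + 0.18 * W, min(y + hs, H - 2)))
      sint <- round(stats::runif(1, spec$vertebra_intensity_range[1] - 30,
                                 spec$vertebra_intensity_range[1]))
      paint(triangle_pixels(H, W, v), 3L, sint, cbind(x = v[, 1], y = v[, 2]), "S")
    }

    if (spec$noise_sigma > 0)
      image <- image + stats::rnorm(H * W, 0, spec$noise_sigma)
    list(image = clip8(image), mask = mask,
         annotation = new_annotation(shapes, c(H, W)))
  })
}

#' Apply a fixed augmentation to an image/mask pair
#'
#' The deterministic core of [augment()]: optional horizontal flip, rotation
#' about the image center (bilinear for the image, nearest-neighbour with
#' background fill for the mask, so class IDs are never blended) and a
#' multiplicative intensity gain (image only, clipped to `[0, 255]`).
#'
#' @param image Integer grayscale matrix.
#' @param mask Integer label matrix of the same size.
#' @param flip Logical: mirror left-right.
#' @param angle Rotation in degrees.
#' @param gain Intensity scale factor.
#' @return List with transformed `image` and `mask`.
#' @export
apply_augment <- function(image, mask, flip = FALSE, angle = 0, gain = 1) {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  if (flip) {
    image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (angle != 0) {
    image <- rotate_raster(image, angle, "bilinear")
    mask <- rotate_raster(mask, angle, "nearest", fill = 0L)
  }
  if (gain != 1) image <- image * gain
  list(image = clip8(image), mask = mask)
}

#' Randomly augment an image/mask pair
#'
#' Samples a combination of anatomy-preserving transforms: horizontal flip
#' (probability 1/2), rotation uniform in \[-10, 10\] degrees (probability
#' 1/2) and intensity scaling uniform in \[0.9, 1.1\] (probability 1/2);
#' geometric transforms are applied identically to image and mask.
#'
#' @inheritParams apply_augment
#' @param rng_seed Integer seed; the draw is a pure function of it.
#' @return List with augmented `image` and `mask`.
#' @export
augment <- function(image, mask, rng_seed) {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  with_rng(rng_seed, {
    flip <- stats::runif(1) < 0.5
    angle <- if (stats::runif(1) < 0.5) stats::runif(1, -10, 10) else 0
    gain <- if (stats::runif(1) < 0.5) stats::runif(1, 0.9, 1.1) else 1
    apply_augment(image, mask, flip, angle, gain)
  })
}

#' Expand a dataset to a target size by augmentation
#'
#' Keeps every original pair and appends augmented copies of uniformly
#' sampled originals until `target_count` pairs exist.
#'
#' @param pairs Non-empty list of `list(image, mask)` pairs.
#' @param target_count Desired total; must be at least `length(pairs)`.
#' @param rng_seed Integer seed.
#' @return List of `target_count` pairs; the first `length(pairs)` are the
#'   unmodified originals.
#' @export
expand_dataset <- function(pairs, target_count, rng_seed = 1L) {
  if (length(pairs) == 0L) stop("pairs must be non-empty")
  if (target_count < length(pairs))
    stop("target_count must be >= length(pairs)")
  n_extra <- target_count - length(pairs)
  if (n_extra == 0L) return(pairs)
  with_rng(rng_seed, {
    src <- sample.int(length(pairs), n_extra, replace = TRUE)
    seeds <- sample.int(.Machine$integer.max, n_extra)
    extra <- lapply(seq_len(n_extra), function(i) {
      p <- pairs[[src[i]]]
      augment(p$image, p$mask, seeds[i])
    })
    c(pairs, extra)
  })
}

#' Split a dataset into train / validation / test subsets
#'
#' Deterministic seeded shuffle; subset sizes are `round(n * ratio)` with
#' the remainder assigned to the training set.
#'
#' @param pairs List of pairs.
#' @param ratios Length-3 positive weights `(train, val, test)`, normalized
#'   to sum to 1.
#' @param rng_seed Integer seed.
#' @return List with elements `train`, `val`, `test`; disjoint, union = input.
#' @export
split_dataset <- function(pairs, ratios = c(0.7, 0.2, 0.1), rng_seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0)
    stop("ratios must be 3 nonnegative weights with positive sum")
  ratios <- ratios / sum(ratios)
  n <- length(pairs)
  if (n < sum(ratios > 0)) stop("fewer pairs than nonzero ratio buckets")
  n_val <- round(n * ratios[2])
  n_test <- round(n * ratios[3])
  n_train <- n - n_val - n_test
  if (n_train < 0) stop("rounding left no training items; adjust ratios")
  with_rng(rng_seed, {
    idx <- sample.int(n)
    list(train = pairs[idx[seq_len(n_train)]],
         val = pairs[idx[n_train + seq_len(n_val)]],
         test = pairs[idx[n_train + n_val + seq_len(n_test)]])
  })
}

#' Generate and write a batch of phantom pairs
#'
#' Writes `image_%03d.png`, `mask_%03d.png` (class IDs as pixel values) and
#' optionally LabelMe-style JSON per phantom.
#'
#' @param n Number of phantoms.
#' @param spec Base [phantom_spec()]; each phantom uses `rng_seed + i - 1`.
#' @param dir Output directory (created if needed).
#' @param labelme Also write LabelMe JSON annotations.
#' @return Invisibly, the list of generated pairs.
#' @export
write_phantoms <- function(n, spec = phantom_spec(), dir, labelme = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$rng_seed <- spec$rng_seed + i - 1L
    ph <- generate_phantom(sp)
    write_gray_png(ph$image, file.path(dir, sprintf("image_%03d.png", i)))
    write_mask_png(ph$mask, file.path(dir, sprintf("mask_%03d.png", i)))
    if (labelme)
      write_labelme(ph$annotation, file.path(dir, sprintf("image_%03d.json", i)))
    pairs[[i]] <- ph[c("image", "mask")]
  }
  invisible(pairs)
}
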