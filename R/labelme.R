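# LabelMe polygon annotation I/O, polygon rasterization to class-ID masks,
# and the fixed color scheme for colorized masks.

label_to_class <- c(L = 1L, LD = 2L, S = 3L)

#' The fixed mask color scheme
#'
#' Background is red, vertebral bodies (L) green, intervertebral discs (LD)
#' yellow and the sacrum (S) blue.
#'
#' @return Integer matrix `4 x 3` (rows = class IDs 0-3, columns = R, G, B).
#' @export
color_scheme <- function() {
  m <- rbind(background = c(255L, 0L, 0L),
             L = c(0L, 255L, 0L),
             LD = c(255L, 255L, 0L),
             S = c(0L, 0L, 255L))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Construct an annotation
#'
#' @param shapes List of `list(label, points)` where `label` is one of
#'   `"L"`, `"LD"`, `"S"` and `points` is an `n x 2` matrix of polygon
#'   vertices in pixel coordinates (columns x, y; 0-based, pixel centers at
#'   integers), `n >= 3`.
#' @param image_size `c(H, W)`.
#' @return An `annotation` object.
#' @export
new_annotation <- function(shapes, image_size) {
  for (s in shapes) {
    if (!s$label %in% names(label_to_class))
      stop("unknown label '", s$label, "' (expected L, LD or S)")
    if (nrow(s$points) < 3L)
      stop("polygons need at least 3 vertices")
  }
  structure(list(shapes = shapes, image_size = as.integer(image_size)),
            class = "annotation")
}

#' Read a LabelMe JSON annotation
#'
#' Parses the `shapes` list (label + polygon points) and the image size from
#' a LabelMe-format JSON file. Labels outside `{L, LD, S}` are rejected.
#'
#' @param path Path to the JSON file.
#' @return An `annotation` object.
#' @export
read_labelme <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$shapes)) stop("not a LabelMe annotation: no 'shapes' field")
  shapes <- lapply(j$shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    colnames(pts) <- c("x", "y")
    list(label = as.character(s$label), points = pts)
  })
  H <- j$imageHeight
  W <- j$imageWidth
  if (is.null(H) || is.null(W)) stop("annotation lacks imageHeight/imageWidth")
  new_annotation(shapes, c(as.integer(H), as.integer(W)))
}

#' Write a LabelMe JSON annotation
#'
#' @param ann An `annotation`.
#' @param path Output path.
#' @param image_path Value for the `imagePath` field.
#' @export
write_labelme <- function(ann, path, image_path = "") {
  stopifnot(inherits(ann, "annotation"))
  j <- list(
    version = "5.0.0",
    flags = structure(list(), names = character(0)),
    shapes = lapply(ann$shapes, function(s) list(
      label = s$label,
      points = lapply(seq_len(nrow(s$points)),
                      function(i) as.numeric(s$points[i, ])),
      group_id = NULL,
      shape_type = "polygon",
      flags = structure(list(), names = character(0))
    )),
    imagePath = image_path,
    imageData = NULL,
    imageHeight = ann$image_size[1],
    imageWidth = ann$image_size[2]
  )
  writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, null = "null", digits = 8),
             path)
}

# Even-odd interior test for one polygon at all pixel centers of an H x W
# canvas (0-based integer coordinates), half-open edge rule.
polygon_interior <- function(poly, H, W) {
  inside <- matrix(FALSE, H, W)
  xs <- poly[, 1]
  ys <- poly[, 2]
  n <- length(xs)
  x2 <- xs[c(2:n, 1)]
  y2 <- ys[c(2:n, 1)]
  for (py in 0:(H - 1)) {
    cross <- (ys <= py) != (y2 <= py)
    if (!any(cross)) next
    cx <- xs[cross] + (py - ys[cross]) * (x2[cross] - xs[cross]) / (y2[cross] - ys[cross])
    cx <- sort(cx)
    for (k in seq(1, length(cx) - 1, by = 2)) {
      lo <- ceiling(cx[k])
      hi <- ceiling(cx[k + 1]) - 1
      if (hi >= lo) {
        lo <- max(lo, 0)
        hi <- min(hi, W - 1)
        if (hi >= lo) inside[py + 1, (lo:hi) + 1] <- TRUE
      }
    }
  }
  inside
}

# Pixels covered by the polygon outline (dense sampling of each edge,
# rounded to the nearest pixel center).
polygon_outline <- function(poly, H, W) {
  out <- matrix(FALSE, H, W)
  n <- nrow(poly)
  for (i in seq_len(n)) {
    p1 <- poly[i, ]
    p2 <- poly[if (i == n) 1L else i + 1L, ]
    steps <- max(2L, ceiling(2 * max(abs(p2 - p1))) + 1L)
    t <- seq(0, 1, length.out = steps)
    px <- round(p1[1] + t * (p2[1] - p1[1]))
    py <- round(p1[2] + t * (p2[2] - p1[2]))
    keep <- px >= 0 & px < W & py >= 0 & py < H
    out[cbind(py[keep] + 1, px[keep] + 1)] <- TRUE
  }
  out
}

#' Rasterize an annotation to a class-ID mask
#'
#' Each polygon is filled by the even-odd rule evaluated at pixel centers
#' (0-based integer coordinates), plus its outline pixels, so vertices lying
#' on integer coordinates are included. Later shapes overwrite earlier ones.
#' An empty shape list yields an all-background mask.
#'
#' @param ann An `annotation`.
#' @return Integer `H x W` label matrix.
#' @export
rasterize_annotation <- function(ann) {
  stopifnot(inherits(ann, "annotation"))
  H <- ann$image_size[1]
  W <- ann$image_size[2]
  mask <- matrix(0L, H, W)
  for (s in ann$shapes) {
    pix <- polygon_interior(s$points, H, W) | polygon_outline(s$points, H, W)
    mask[pix] <- label_to_class[[s$label]]
  }
  mask
}

#' Colorize a label mask
#'
#' @param mask Integer label matrix with classes in `0:3`.
#' @param scheme Color scheme matrix (rows = classes, columns = R, G, B).
#' @return Integer `H x W x 3` RGB array (0-255).
#' @export
colorize_mask <- function(mask, scheme = color_scheme()) {
  if (any(!(mask %in% (seq_len(nrow(scheme)) - 1L))))
    stop("mask contains class IDs outside the scheme")
  H <- nrow(mask)
  W <- ncol(mask)
  rgb <- array(0L, dim = c(H, W, 3L))
  for (ch in 1:3) rgb[, , ch] <- scheme[mask + 1L, ch]
  rgb
}

#' Recover a label mask from a colorized mask
#'
#' Exact scheme colors map back directly; other pixels are assigned the
#' nearest scheme color, provided it lies within `tolerance` (Euclidean RGB
#' distance), so lightly perturbed color masks still decode.
#'
#' @param rgb Integer `H x W x 3` RGB array.
#' @param scheme Color scheme matrix.
#' @param tolerance Maximum accepted distance to the nearest scheme color.
#' @return Integer `H x W` label matrix.
#' @export
decolorize_mask <- function(rgb, scheme = color_scheme(), tolerance = 64) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  H <- dim(rgb)[1]
  W <- dim(rgb)[2]
  flat <- matrix(as.numeric(rgb), H * W, 3L)
  d2 <- vapply(seq_len(nrow(scheme)), function(k) {
    (flat[, 1] - scheme[k, 1])^2 + (flat[, 2] - scheme[k, 2])^2 +
      (flat[, 3] - scheme[k, 3])^2
  }, numeric(H * W))
  best <- max.col(-d2, ties.method = "first")
  mind <- d2[cbind(seq_len(H * W), best)]
  if (any(mind > tolerance^2))
    stop("pixels farther than the tolerance from every scheme color")
  matrix(as.integer(best - 1L), H, W)
}

## ---- PNG I/O ----

#' Read / write grayscale and class-ID PNGs
#'
#' Grayscale images are stored as ordinary 8-bit PNGs. Class-ID masks are
#' stored as 8-bit grayscale PNGs whose pixel values are the class IDs
#' (0-3); RGB mask PNGs in the fixed color scheme are also readable via
#' [decolorize_mask()].
#'
#' @param image Integer grayscale matrix (0-255).
#' @param mask Integer label matrix.
#' @param rgb Integer `H x W x 3` array (0-255).
#' @param path File path.
#' @return Readers return the matrix/array; writers return the path
#'   invisibly.
#' @name png_io
NULL

#' @rdname png_io
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  clip8(x * 255)
}

#' @rdname png_io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    decolorize_mask(clip8(x[, , 1:3] * 255))
  } else {
    m <- clip8(x * 255)
    m
  }
}

#' @rdname png_io
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_rgb_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3L))
  clip8(x[, , 1:3] * 255)
}
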