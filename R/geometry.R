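# Geometric raster transforms with an explicit pixel-center convention:
# pixel (i, j) (1-based matrix indices) has its center at the 0-based
# continuous coordinate (i-1, j-1); resizing maps centers by the half-pixel
# rule src = (dst + 0.5) * scale - 0.5, the convention that keeps a
# same-size resize the identity and treats both image edges symmetrically.

# Gather with bilinear weights at fractional (row, col) source coordinates,
# edge-clamped. `sr`, `sc` are 0-based and recycled against each other.
bilinear_gather <- function(image, sr, sc) {
  H <- nrow(image)
  W <- ncol(image)
  sr <- pmin(pmax(sr, 0), H - 1)
  sc <- pmin(pmax(sc, 0), W - 1)
  r0 <- floor(sr)
  c0 <- floor(sc)
  fr <- sr - r0
  fc <- sc - c0
  r1 <- pmin(r0 + 1, H - 1)
  c1 <- pmin(c0 + 1, W - 1)
  i00 <- (c0) * H + r0 + 1
  i10 <- (c0) * H + r1 + 1
  i01 <- (c1) * H + r0 + 1
  i11 <- (c1) * H + r1 + 1
  v <- image[i00] * (1 - fr) * (1 - fc) + image[i10] * fr * (1 - fc) +
    image[i01] * (1 - fr) * fc + image[i11] * fr * fc
  v
}

nearest_gather <- function(image, sr, sc, fill = NULL) {
  H <- nrow(image)
  W <- ncol(image)
  out_of <- sr < -0.5 | sr > H - 0.5 | sc < -0.5 | sc > W - 0.5
  r <- pmin(pmax(round(sr), 0), H - 1)
  c <- pmin(pmax(round(sc), 0), W - 1)
  v <- image[c * H + r + 1]
  if (!is.null(fill)) v[out_of] <- fill
  v
}

#' Resize a grayscale image by bilinear interpolation
#'
#' Half-pixel center convention, edge-clamped. Intended for intensity
#' images only; label masks must go through [resize_nearest()] so class IDs
#' are never blended.
#'
#' @param image Numeric matrix (values 0-255).
#' @param size Target size `c(H, W)` (a single integer is used for both).
#' @return Integer matrix of the requested size.
#' @export
resize_linear <- function(image, size) {
  check_gray(image)
  size <- parse_size(size)
  if (identical(dim(image), size)) return(clip8(image))
  g <- resize_grid(dim(image), size)
  clip8(matrix(bilinear_gather(image, g$sr, g$sc), size[1], size[2]))
}

#' Resize a label mask by nearest-neighbour sampling
#'
#' @param mask Integer label matrix.
#' @param size Target size `c(H, W)`.
#' @return Integer matrix of the requested size.
#' @export
resize_nearest <- function(mask, size) {
  size <- parse_size(size)
  g <- resize_grid(dim(mask), size)
  m <- matrix(nearest_gather(mask, g$sr, g$sc), size[1], size[2])
  storage.mode(m) <- "integer"
  m
}

parse_size <- function(size) {
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  if (any(size <= 0L)) stop("target size must be positive")
  size
}

resize_grid <- function(from, to) {
  sr <- (seq_len(to[1]) - 0.5) * from[1] / to[1] - 0.5
  sc <- (seq_len(to[2]) - 0.5) * from[2] / to[2] - 0.5
  list(sr = rep(sr, times = to[2]), sc = rep(sc, each = to[1]))
}

# Rotate about the image center by `angle` degrees (counterclockwise in
# matrix row/col space). Bilinear for images (edge-clamped), nearest with a
# fill value for masks.
rotate_raster <- function(x, angle, interp = c("bilinear", "nearest"),
                          fill = 0L) {
  interp <- match.arg(interp)
  H <- nrow(x)
  W <- ncol(x)
  th <- angle * pi / 180
  cr <- (H - 1) / 2
  cc <- (W - 1) / 2
  dr <- rep(seq_len(H) - 1 - cr, times = W)
  dc <- rep(seq_len(W) - 1 - cc, each = H)
  sr <- cos(th) * dr + sin(th) * dc + cr
  sc <- -sin(th) * dr + cos(th) * dc + cc
  if (interp == "bilinear") {
    matrix(bilinear_gather(x, sr, sc), H, W)
  } else {
    m <- matrix(nearest_gather(x, sr, sc, fill = fill), H, W)
    storage.mode(m) <- "integer"
    m
  }
}
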