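# Postprocessing: per-class extraction from color masks via gray
# thresholding, and clinician-readable overlays of mask fills or edges on
# the original image.

#' Overlay parameters
#'
#' @param alpha Blend weight in `[0, 1]` for the mask color over the image.
#' @param edge_thickness Edge dilation radius in pixels (Chebyshev).
#' @param add_labels Stamp class-name text at each class centroid.
#' @param blend_background Blend the background class too (whole-frame
#'   fusion) instead of leaving background pixels as the plain image.
#' @return An `overlay_params` list.
#' @export
overlay_params <- function(alpha = 0.4, edge_thickness = 1L,
                           add_labels = FALSE, blend_background = FALSE) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (edge_thickness < 1L) stop("edge_thickness must be >= 1")
  structure(list(alpha = alpha, edge_thickness = as.integer(edge_thickness),
                 add_labels = isTRUE(add_labels),
                 blend_background = isTRUE(blend_background)),
            class = "overlay_params")
}

# Luma (ITU-R 601) of an RGB triple or image.
luma601 <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

#' Extract one class from a colorized mask by gray thresholding
#'
#' Converts the RGB mask to grayscale with ITU-R 601 luma weights, derives
#' the target class's unique gray level from its scheme color, and selects
#' pixels within `tolerance` gray levels of it. Equivalent to
#' `decolorize_mask(rgb) == target_class` on clean masks.
#'
#' @param mask_rgb Integer `H x W x 3` color mask in the fixed scheme.
#' @param target_class Class ID (0-3).
#' @param scheme Color scheme.
#' @param tolerance Gray-level half-width of the selection band.
#' @return Logical `H x W` matrix; all-FALSE when the class is absent.
#' @export
extract_class <- function(mask_rgb, target_class, scheme = color_scheme(),
                          tolerance = 2) {
  stopifnot(target_class %in% (seq_len(nrow(scheme)) - 1L))
  gray <- round(luma601(mask_rgb[, , 1], mask_rgb[, , 2], mask_rgb[, , 3]))
  levels <- round(luma601(scheme[, 1], scheme[, 2], scheme[, 3]))
  if (anyDuplicated(levels))
    stop("scheme colors do not have distinct gray levels")
  abs(gray - levels[target_class + 1L]) <= tolerance
}

gray_to_rgb <- function(image) {
  array(rep(as.numeric(image), 3L), dim = c(dim(image), 3L))
}

#' Overlay a label mask on a grayscale image
#'
#' `out = (1 - alpha) * image + alpha * color(class)` on foreground pixels
#' (on every pixel with `blend_background = TRUE`); optionally stamps the
#' class names at the class centroids.
#'
#' @param image Integer grayscale matrix.
#' @param mask Integer label matrix of the same size.
#' @param params An [overlay_params()].
#' @param scheme Color scheme.
#' @return Integer `H x W x 3` RGB array.
#' @export
overlay_mask <- function(image, mask, params = overlay_params(),
                         scheme = color_scheme()) {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  rgb <- gray_to_rgb(image)
  colors <- colorize_mask(mask, scheme)
  sel <- if (params$blend_background) mask >= 0L else mask > 0L
  a <- params$alpha
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    cplane <- colors[, , ch]
    plane[sel] <- (1 - a) * plane[sel] + a * cplane[sel]
    rgb[, , ch] <- plane
  }
  if (params$add_labels) rgb <- stamp_labels(rgb, mask, scheme)
  clip8(rgb)
}

# Boundary pixels: foreground pixels with at least one 4-neighbor of a
# different class (image border counts as background).
mask_edges <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  diff_n <- (pad[1:H, 2:(W + 1)] != ctr) | (pad[3:(H + 2), 2:(W + 1)] != ctr) |
    (pad[2:(H + 1), 1:W] != ctr) | (pad[2:(H + 1), 3:(W + 2)] != ctr)
  ctr > 0L & diff_n
}

# Chebyshev dilation by r pixels.
dilate_binary <- function(b, r) {
  if (r <= 0L) return(b)
  H <- nrow(b)
  W <- ncol(b)
  out <- b
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    ys <- pmin(pmax(seq_len(H) + dy, 1L), H)
    xs <- pmin(pmax(seq_len(W) + dx, 1L), W)
    out <- out | b[ys, xs]
  }
  out
}

#' Overlay class edges on a grayscale image
#'
#' Draws the boundary of every foreground region (pixels with a 4-neighbor
#' of a different class), dilated to `edge_thickness`, in the class color
#' over the grayscale image.
#'
#' @inheritParams overlay_mask
#' @return Integer `H x W x 3` RGB array.
#' @export
overlay_edges <- function(image, mask, params = overlay_params(),
                          scheme = color_scheme()) {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  rgb <- gray_to_rgb(image)
  edges <- mask_edges(mask)
  for (c in sort(unique(mask[mask > 0L]))) {
    sel <- dilate_binary(edges & mask == c, params$edge_thickness - 1L)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- scheme[c + 1L, ch]
      rgb[, , ch] <- plane
    }
  }
  clip8(rgb)
}

# 3x5 bitmap glyphs for the class labels (L, D, S).
.glyphs <- list(
  L = rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1, 1)),
  D = rbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 1), c(1, 0, 1), c(1, 1, 0)),
  S = rbind(c(0, 1, 1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0))
)

stamp_labels <- function(rgb, mask, scheme) {
  H <- dim(rgb)[1]
  W <- dim(rgb)[2]
  for (c in sort(unique(mask[mask > 0L]))) {
    name <- class_names()[as.character(c)]
    idx <- which(mask == c, arr.ind = TRUE)
    cy <- round(mean(idx[, 1]))
    cx <- round(mean(idx[, 2]))
    x0 <- cx - 2L * nchar(name)
    for (ci in seq_len(nchar(name))) {
      gl <- .glyphs[[substr(name, ci, ci)]]
      for (gy in 1:5) for (gx in 1:3) {
        if (gl[gy, gx] == 1) {
          py <- cy - 3L + gy
          px <- x0 + (ci - 1L) * 4L + gx
          if (py >= 1L && py <= H && px >= 1L && px <= W)
            rgb[py, px, ] <- c(255, 255, 255)
        }
      }
    }
  }
  rgb
}
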