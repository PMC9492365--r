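# Image preparation: global histogram equalization, contrast-limited
# adaptive histogram equalization (CLAHE), and the local binary pattern
# texture operator. All operators keep the 8-bit [0, 255] contract.

#' CLAHE parameters
#'
#' @param clip_limit Histogram clip threshold as a multiple of the uniform
#'   bin height (`tile_pixels / n_bins`); must be >= 1. `Inf` disables
#'   clipping, reducing each tile to plain equalization.
#' @param tile_grid `c(rows, cols)` of contextual tiles.
#' @param n_bins Histogram bins (2-256).
#' @return A `clahe_params` list.
#' @export
clahe_params <- function(clip_limit = 2.0, tile_grid = c(8L, 8L),
                         n_bins = 256L) {
  if (length(tile_grid) == 1L) tile_grid <- c(tile_grid, tile_grid)
  tile_grid <- as.integer(tile_grid)
  n_bins <- as.integer(n_bins)
  if (clip_limit < 1) stop("clip_limit must be >= 1")
  if (any(tile_grid < 1L)) stop("tile counts must be >= 1")
  if (n_bins < 2L || n_bins > 256L) stop("n_bins must lie in [2, 256]")
  structure(list(clip_limit = clip_limit, tile_grid = tile_grid,
                 n_bins = n_bins), class = "clahe_params")
}

#' Global histogram equalization
#'
#' Counts the gray-level histogram, forms the cumulative distribution and
#' maps each level `g` to `round(255 * cdf(g))`. Improves global contrast
#' but amplifies noise, which motivates the contrast-limited variant
#' ([clahe()]) actually used in the pipeline.
#'
#' @param image Integer grayscale matrix (0-255).
#' @return Equalized integer matrix.
#' @export
hist_equalize <- function(image) {
  check_gray(image)
  h <- tabulate(as.integer(image) + 1L, nbins = 256L)
  map <- round(255 * cumsum(h) / length(image))
  out <- matrix(map[as.integer(image) + 1L], nrow(image), ncol(image))
  storage.mode(out) <- "integer"
  out
}

tile_bounds <- function(n, k) {
  start <- floor((seq_len(k) - 1L) * n / k) + 1L
  end <- floor(seq_len(k) * n / k)
  list(start = start, end = end, center = (start + end) / 2)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a grid of tiles; each tile's histogram is
#' clipped at `clip_limit` times the uniform bin height, the clipped excess
#' is redistributed uniformly across all bins in a single pass, and the
#' clipped cumulative distribution defines the tile's gray-level mapping.
#' Each pixel is transformed by bilinear interpolation between the mappings
#' of the four nearest tile centers (clamped at the borders), which removes
#' tile-boundary artifacts. Limiting the per-bin mass bounds the slope of
#' the mapping and hence the noise amplification of plain equalization.
#'
#' With `clip_limit = Inf` and a single 1x1 tile the operator reduces to
#' [hist_equalize()].
#'
#' @param image Integer grayscale matrix (0-255).
#' @param params A [clahe_params()].
#' @return Integer matrix.
#' @export
clahe <- function(image, params = clahe_params()) {
  check_gray(image)
  H <- nrow(image)
  W <- ncol(image)
  R <- params$tile_grid[1]
  C <- params$tile_grid[2]
  nb <- params$n_bins
  if (R > H || C > W) stop("tile grid finer than the image")
  tb_r <- tile_bounds(H, R)
  tb_c <- tile_bounds(W, C)

  bin <- matrix(pmin(floor(as.numeric(image) * nb / 256), nb - 1) + 1L, H, W)
  maps <- matrix(0, nb, R * C)
  for (j in seq_len(C)) {
    for (i in seq_len(R)) {
      tb <- bin[tb_r$start[i]:tb_r$end[i], tb_c$start[j]:tb_c$end[j]]
      h <- tabulate(tb, nbins = nb)
      npx <- length(tb)
      if (is.finite(params$clip_limit)) {
        thr <- params$clip_limit * npx / nb
        excess <- sum(pmax(h - thr, 0))
        h <- pmin(h, thr) + excess / nb
      }
      maps[, (j - 1L) * R + i] <- round(255 * cumsum(h) / npx)
    }
  }

  # bilinear blending between tile-center mappings, clamped at the borders
  interp_axis <- function(pos, centers) {
    i1 <- findInterval(pos, centers)
    i1c <- pmin(pmax(i1, 1L), length(centers))
    i2c <- pmin(i1 + 1L, length(centers))
    w2 <- ifelse(i1 < 1L, 1, ifelse(i1 >= length(centers), 0,
                                    (pos - centers[i1c]) /
                                      (centers[i2c] - centers[i1c])))
    i1c <- pmax(i1c, 1L)
    list(i1 = i1c, i2 = pmax(i2c, 1L), w2 = w2)
  }
  ay <- interp_axis(seq_len(H), tb_r$center)
  ax <- interp_axis(seq_len(W), tb_c$center)

  lookup <- function(ti, tj) {
    tile <- (rep(tj, each = H) - 1L) * R + rep(ti, times = W)
    matrix(maps[bin + (tile - 1L) * nb], H, W)
  }
  wy2 <- matrix(ay$w2, H, W)
  wx2 <- matrix(ax$w2, H, W, byrow = TRUE)
  out <- (1 - wy2) * (1 - wx2) * lookup(ay$i1, ax$i1) +
    wy2 * (1 - wx2) * lookup(ay$i2, ax$i1) +
    (1 - wy2) * wx2 * lookup(ay$i1, ax$i2) +
    wy2 * wx2 * lookup(ay$i2, ax$i2)
  clip8(out)
}

#' Local binary pattern operator
#'
#' Encodes each pixel as the `n_neighbors`-bit pattern of the comparisons
#' `neighbor >= center` over neighbors at the given radius (integer offsets
#' on the rounded circle, counterclockwise from the +x axis, bit `k`
#' weighted `2^k`). Borders are handled by edge replication. A constant
#' image maps to the all-ones code (255 for 8 neighbors).
#'
#' @param image Integer grayscale matrix.
#' @param radius Neighborhood radius in pixels.
#' @param n_neighbors Number of sampled neighbors (at most 8 so codes stay
#'   within the 8-bit range).
#' @return Integer matrix of LBP codes.
#' @export
lbp <- function(image, radius = 1L, n_neighbors = 8L) {
  check_gray(image)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  if (n_neighbors < 1L || n_neighbors > 8L)
    stop("n_neighbors must lie in [1, 8]")
  H <- nrow(image)
  W <- ncol(image)
  if (H < 2L * radius + 1L || W < 2L * radius + 1L)
    stop("image too small for the given radius")
  code <- matrix(0L, H, W)
  ang <- 2 * pi * (seq_len(n_neighbors) - 1L) / n_neighbors
  dx <- round(radius * cos(ang))
  dy <- round(radius * sin(ang))
  rows <- seq_len(H)
  cols <- seq_len(W)
  for (k in seq_len(n_neighbors)) {
    r <- pmin(pmax(rows + dy[k], 1L), H)
    c <- pmin(pmax(cols + dx[k], 1L), W)
    code <- code + (2L^(k - 1L)) * (image[r, c] >= image)
  }
  storage.mode(code) <- "integer"
  code
}
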