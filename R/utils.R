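# Shared helpers: seeded evaluation, 8-bit clipping, connected components.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

clip8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

check_gray <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (nrow(image) < 1L || ncol(image) < 1L) stop("image dimensions must be > 0")
  if (min(image) < 0 || max(image) > 255)
    stop("gray values must lie in [0, 255]")
  invisible(image)
}

#' Count connected components of one class in a label mask
#'
#' Run-based union-find over rows, 4-connectivity.
#'
#' @param mask Integer label matrix.
#' @param class Class ID whose components are counted.
#' @return Integer component count.
#' @export
mask_components <- function(mask, class) {
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prev <- NULL  # list(start, end, id) of runs on the previous row
  all_ids <- integer(0)
  for (r in seq_len(nrow(mask))) {
    v <- mask[r, ] == class
    d <- diff(c(0L, as.integer(v), 0L))
    starts <- which(d == 1L)
    ends <- which(d == -1L) - 1L
    cur <- vector("list", length(starts))
    for (k in seq_along(starts)) {
      id <- length(parent) + 1L
      parent[id] <- id
      all_ids <- c(all_ids, id)
      if (!is.null(prev)) {
        for (p in prev) {
          if (starts[k] <= p$end && ends[k] >= p$start) {
            ra <- find(id)
            rb <- find(p$id)
            if (ra != rb) parent[ra] <- rb
          }
        }
      }
      cur[[k]] <- list(start = starts[k], end = ends[k], id = id)
    }
    prev <- cur
  }
  length(unique(vapply(all_ids, find, integer(1))))
}

#' Class inventory of a label mask
#'
#' @param mask Integer label matrix with classes in `{0, 1, 2, 3}`.
#' @return Named integer vector: connected components per foreground class.
#' @export
mask_inventory <- function(mask) {
  c(L = mask_components(mask, 1L),
    LD = mask_components(mask, 2L),
    S = mask_components(mask, 3L))
}

#' Fixed class naming of the segmentation problem
#'
#' @return Named character vector mapping class IDs to names.
#' @export
class_names <- function() {
  c(`0` = "background", `1` = "L", `2` = "LD", `3` = "S")
}
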