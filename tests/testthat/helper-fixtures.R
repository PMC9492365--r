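# Shared fixtures: small phantoms are cached per session so several test
# files can reuse them without regenerating.

.fixture_env <- new.env()

small_phantom <- function(seed = 7L, size = 64L, noise = 6) {
  key <- paste0("ph_", seed, "_", size, "_", noise)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantom(
      phantom_spec(image_size = size, rng_seed = seed, noise_sigma = noise))
  .fixture_env[[key]]
}

phantom_pairs <- function(seeds, size = 64L, noise = 6) {
  lapply(seeds, function(s) small_phantom(s, size, noise)[c("image", "mask")])
}

# Brute-force even-odd point-in-polygon at a pixel center (independent of the
# scanline implementation): cast a ray toward -x and count edge crossings.
brute_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  crossings <- 0L
  for (i in seq_len(n)) {
    p1 <- poly[i, ]
    p2 <- poly[if (i == n) 1L else i + 1L, ]
    if ((p1[2] <= py) != (p2[2] <= py)) {
      cx <- p1[1] + (py - p1[2]) * (p2[1] - p1[1]) / (p2[2] - p1[2])
      if (cx <= px) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# Distance from a point to a polygon edge segment (for boundary inclusion).
brute_on_outline <- function(px, py, poly, tol = 0.5) {
  n <- nrow(poly)
  for (i in seq_len(n)) {
    p1 <- poly[i, ]
    p2 <- poly[if (i == n) 1L else i + 1L, ]
    # nearest rounded sample along the edge
    steps <- max(2L, ceiling(2 * max(abs(p2 - p1))) + 1L)
    t <- seq(0, 1, length.out = steps)
    if (any(round(p1[1] + t * (p2[1] - p1[1])) == px &
            round(p1[2] + t * (p2[2] - p1[2])) == py)) return(TRUE)
  }
  FALSE
}

# Finite-difference gradient of f at x (central differences).
fd_gradient <- function(f, x, idx = seq_along(x), eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
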