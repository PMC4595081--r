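# Shared geometry helpers: direction/orientation codes, polyline resampling,
# rasterization. Conventions used package-wide:
#   * images are numeric matrices, [row, col], 1-based, origin top-left;
#   * direction codes 0..7 step through 45 degrees starting at "east"
#     (increasing column), with row increasing downwards;
#   * orientation codes 0..3 are direction codes modulo 4 (axis only).

.dirs8 <- matrix(c(0L, 1L,   # 0 E
                   1L, 1L,   # 1 SE
                   1L, 0L,   # 2 S
                   1L, -1L,  # 3 SW
                   0L, -1L,  # 4 W
                   -1L, -1L, # 5 NW
                   -1L, 0L,  # 6 N
                   -1L, 1L), # 7 NE
                 ncol = 2L, byrow = TRUE)

dir_vec <- function(code) .dirs8[code + 1L, , drop = FALSE]

dir_code <- function(dr, dc) {
  # quantize an arbitrary step to the nearest of the 8 compass directions
  if (dr == 0 && dc == 0) return(NA_integer_)
  ang <- atan2(dr, dc) # row plays the role of y (downwards)
  code <- round(ang / (pi / 4)) %% 8
  as.integer(code)
}

# circular distance between two direction codes, in 45-degree steps (0..4)
dir_circ_dist <- function(a, b) {
  d <- abs(a - b) %% 8L
  pmin(d, 8L - d)
}

# unit axis vector (along the segment) for an orientation code
orient_axis <- function(o) {
  switch(o + 1L,
         c(0, 1),
         c(1, 1) / sqrt(2),
         c(1, 0),
         c(1, -1) / sqrt(2))
}

# unit normal (the gradient axis of edges with this orientation); positive
# polarity edges have intensity increasing along this vector
orient_normal <- function(o) {
  switch(o + 1L,
         c(1, 0),
         c(1, -1) / sqrt(2),
         c(0, 1),
         c(1, 1) / sqrt(2))
}

# slot (1..8) of an edge type in the edge array: orientation 0..3, polarity +-1
edge_slot <- function(orientation, polarity) {
  2L * as.integer(orientation) + ifelse(polarity > 0, 1L, 2L)
}

edge_type_names <- function() {
  c("e0+", "e0-", "e45+", "e45-", "e90+", "e90-", "e135+", "e135-")
}

# cumulative arc length of a polyline (n x 2 matrix)
arc_length <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(d))
}

# resample a polyline to n points equally spaced in arc length
resample_polyline <- function(pts, n) {
  s <- arc_length(pts)
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polyline: zero arc length")
  # guard against repeated vertices
  keep <- c(TRUE, diff(s) > 0)
  pts <- pts[keep, , drop = FALSE]
  s <- s[keep]
  at <- seq(0, total, length.out = n)
  cbind(approx(s, pts[, 1], xout = at)$y,
        approx(s, pts[, 2], xout = at)$y)
}

# moving-average smoothing of a polyline with edge replication
smooth_polyline <- function(pts, window = 5L) {
  n <- nrow(pts)
  if (n <= 2 || window <= 1) return(pts)
  half <- window %/% 2L
  idx <- function(i) pmin(pmax(i, 1L), n)
  out <- pts
  for (i in seq_len(n)) {
    rows <- idx((i - half):(i + half))
    out[i, ] <- colMeans(pts[rows, , drop = FALSE])
  }
  out
}

# integer pixels of the digital line from a to b (both length-2 integer
# vectors), endpoints inclusive; classic Bresenham, mirrored in src/dp.cpp
bresenham <- function(a, b) {
  r0 <- a[1]; c0 <- a[2]; r1 <- b[1]; c1 <- b[2]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  out <- matrix(0L, nrow = dr + dc + 1L, ncol = 2L)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
  }
  out[seq_len(k), , drop = FALSE]
}

# symmetric Hausdorff distance between two point sets (n x 2 matrices)
hausdorff_dist <- function(a, b) {
  cross <- function(p, q) {
    # for each row of p, distance to the nearest row of q
    dr <- outer(p[, 1], q[, 1], "-")
    dc <- outer(p[, 2], q[, 2], "-")
    sqrt(apply(dr^2 + dc^2, 1, min))
  }
  max(max(cross(a, b)), max(cross(b, a)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
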