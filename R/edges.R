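#' Detect oriented binary edges
#'
#' Computes the eight binary edge arrays (four orientations, two polarities)
#' from a grayscale image. An edge of a given orientation is declared at a
#' pixel when the intensity difference between the adjacent pixel pair along
#' the orientation's normal exceeds \code{threshold} in magnitude, and that
#' magnitude exceeds the magnitudes of the differences of the two flanking
#' neighboring pairs along the same direction (local non-maximum
#' suppression). The polarity is the sign of the difference. Multiple edge
#' types can be present at the same pixel. The criteria depend only on
#' intensity differences, making the edge map invariant to affine intensity
#' changes as long as the scaled contrast stays above threshold.
#'
#' Orientation here refers to the direction of the edge line itself:
#' orientation 0 is a horizontal edge (vertical intensity step, difference
#' \code{I[r+1, c] - I[r, c]}), orientation 90 a vertical edge, 45 and 135
#' the two diagonals (differences between diagonal pixel neighbors).
#' Positive polarity means intensity increases along the orientation's
#' normal, i.e. with increasing row for orientation 0, increasing column for
#' orientation 90, and along the (+row, -col) and (+row, +col) diagonals for
#' orientations 45 and 135. Each edge is registered at the first pixel of
#' its pair.
#'
#' @param image numeric matrix of intensities (rows x cols), at least 8 x 8,
#'   finite and non-negative.
#' @param threshold positive intensity-difference threshold.
#' @return An object of class \code{worm_edges}: a list with \code{arrays}
#'   (logical array \code{nrow x ncol x 8}, slices named
#'   \code{"e0+", "e0-", "e45+", ..., "e135-"}) and \code{threshold}.
#' @examples
#' img <- matrix(0, 16, 16); img[, 9:16] <- 200
#' e <- detect_edges(img, 50)
#' which(e$arrays[, , "e90+"], arr.ind = TRUE) # vertical edges at the step
#' @export
detect_edges <- function(image, threshold) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (nrow(image) < 8 || ncol(image) < 8)
    stop("image must be at least 8 x 8 pixels")
  if (!all(is.finite(image)))
    stop("image contains non-finite pixel values")
  if (any(image < 0))
    stop("image intensities must be non-negative")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number")

  nr <- nrow(image); nc <- ncol(image)
  arrays <- array(FALSE, dim = c(nr, nc, 8),
                  dimnames = list(NULL, NULL, edge_type_names()))

  # shift helper: d[r, c] = I[r + dr, c + dc] - I[r, c], NA outside
  shift_diff <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    r_src <- seq_len(nr - abs(dr)); c_src <- seq_len(nc - abs(dc))
    r_dst <- r_src + max(dr, 0); c_dst <- c_src + max(dc, 0)
    r_at <- r_src + max(-dr, 0); c_at <- c_src + max(-dc, 0)
    # value at (r_at, c_at) pairs with (r_at + dr, c_at + dc)
    out[r_at, c_at] <- image[r_at + dr, c_at + dc] - image[r_at, c_at]
    out
  }

  # flanking-pair comparison: a difference survives only if no
  # same-polarity difference within two steps along its own direction is
  # larger (ties resolve toward the earlier pixel). Opposite-polarity
  # neighbors never suppress each other, so closely spaced inverse edge
  # pairs (as inside the head) are preserved while a blurred boundary ramp
  # yields a single edge line.
  nms_fire <- function(d, dr, dc) {
    a <- abs(d)
    shift_val <- function(sr, sc) {
      out <- matrix(0, nr, nc)
      rs <- seq_len(nr); cs <- seq_len(nc)
      r_from <- rs + sr; c_from <- cs + sc
      ok_r <- r_from >= 1 & r_from <= nr
      ok_c <- c_from >= 1 & c_from <= nc
      v <- d[r_from[ok_r], c_from[ok_c]]
      v[is.na(v)] <- 0
      out[rs[ok_r], cs[ok_c]] <- v
      out
    }
    suppressed <- matrix(FALSE, nr, nc)
    for (k in c(-2L, -1L, 1L, 2L)) {
      fk <- shift_val(k * dr, k * dc)
      same <- !is.na(d) & d * fk > 0
      bigger <- abs(fk) > a | (abs(fk) == a & k > 0)
      suppressed <- suppressed | (same & bigger)
    }
    ok <- !is.na(d) & a > threshold & !suppressed
    ok[is.na(ok)] <- FALSE
    ok
  }

  steps <- list(c(1L, 0L),   # orientation 0: horizontal edge line
                c(1L, -1L),  # orientation 45
                c(0L, 1L),   # orientation 90
                c(1L, 1L))   # orientation 135
  for (o in 0:3) {
    st <- steps[[o + 1]]
    d <- shift_diff(st[1], st[2])
    fire <- nms_fire(d, st[1], st[2])
    pos <- fire & !is.na(d) & d > 0
    neg <- fire & !is.na(d) & d < 0
    pos[is.na(pos)] <- FALSE; neg[is.na(neg)] <- FALSE
    arrays[, , edge_slot(o, 1)] <- pos
    arrays[, , edge_slot(o, -1)] <- neg
  }

  structure(list(arrays = arrays, threshold = threshold,
                 dim = c(nr, nc)),
            class = "worm_edges")
}

#' @export
print.worm_edges <- function(x, ...) {
  counts <- apply(x$arrays, 3, sum)
  cat(sprintf("worm_edges: %d x %d image, threshold %.3g\n",
              x$dim[1], x$dim[2], x$threshold))
  print(counts)
  invisible(x)
}

# ---- feature masks ---------------------------------------------------------

# integer offsets of a band: centered at `offset` along the normal of
# orientation `o`, extending `len` along the axis and `thick` across it
band_offsets <- function(o, offset, len, thick) {
  u <- orient_axis(o); n <- orient_normal(o)
  s <- seq(-len / 2, len / 2, by = 0.5)
  t <- seq(offset - thick / 2, offset + thick / 2, by = 0.5)
  grid <- expand.grid(s = s, t = t)
  pts <- cbind(round(grid$s * u[1] + grid$t * n[1]),
               round(grid$s * u[2] + grid$t * n[2]))
  unique(pts)
}

# the maximum attainable matching-edge count in an area: the largest number
# of its pixels that a single digital line with the mask's orientation can
# cover (an ideal boundary contributes one edge per lattice step)
max_line_count <- function(offsets, o) {
  step <- switch(o + 1L, c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  # project each offset onto the line index: pixels on a common digital line
  # share the perpendicular coordinate
  key <- switch(o + 1L,
                offsets[, 1],                   # horizontal lines: same row
                offsets[, 1] - offsets[, 2],    # 45: constant r - c
                offsets[, 2],                   # vertical: same col
                offsets[, 1] + offsets[, 2])    # 135: constant r + c
  max(table(key))
}

#' Build head, body and double-body feature masks
#'
#' Each mask is a spatial arrangement of areas with elevated probability for
#' specific oriented, polarized edge types, scaled to the expected worm
#' width. Body masks place two inversely polarized edge areas one worm width
#' apart (the two sides of the dark body); double-body masks place them two
#' worm widths apart, detecting two body segments pressed together, and
#' register detections at the hypothesized centers of the two segments. Head
#' masks add an inner, inversely polarized edge pair produced by the lighter
#' anterior interior. Areas are bands (width \code{worm_width/2}, length
#' \code{1.5 * worm_width} along the segment axis; inner head bands are
#' \code{worm_width/4} wide at offsets of a quarter width), which makes the
#' tests invariant to the exact edge location and robust to width variation.
#'
#' @param worm_width expected worm width in pixels (>= 4).
#' @param feature_threshold_frac the count test fires at this fraction of
#'   the mask's maximum attainable count (default 0.6).
#' @return List of 12 masks (4 head, 4 body, 4 double-body orientations);
#'   each mask is a list with \code{feature_type}, \code{orientation}
#'   (0, 45, 90 or 135 degrees as code 0..3), \code{areas} (each with an
#'   edge-type slot and an integer offset matrix), \code{on_threshold},
#'   \code{max_count} and \code{register_offsets}.
#' @export
build_masks <- function(worm_width, feature_threshold_frac = 0.6) {
  if (!is.numeric(worm_width) || worm_width < 4)
    stop("worm_width must be at least 4 pixels")
  w <- worm_width
  masks <- list()
  for (o in 0:3) {
    n <- orient_normal(o)
    # diagonal bands are half as thick: axis-aligned boundaries also produce
    # diagonal pixel-pair differences (several edge orientations can coexist
    # at a pixel), and the narrower band keeps that cross-talk safely below
    # the count threshold while an aligned boundary still fills the band
    thick <- if (o %% 2L == 1L) w / 4 else w / 2
    outer_pos <- band_offsets(o, +w / 2, 1.5 * w, thick)
    outer_neg <- band_offsets(o, -w / 2, 1.5 * w, thick)
    inner_neg <- band_offsets(o, +w / 4, 1.5 * w, thick / 2)
    inner_pos <- band_offsets(o, -w / 4, 1.5 * w, thick / 2)
    # dark body on light background: intensity increases along +normal at the
    # +w/2 boundary (body to background), so that side expects + polarity
    body_areas <- list(
      list(edge = edge_slot(o, +1), offsets = outer_pos),
      list(edge = edge_slot(o, -1), offsets = outer_neg))
    head_areas <- c(body_areas, list(
      # the lighter head core inverts the gradient at the inner boundaries
      list(edge = edge_slot(o, -1), offsets = inner_neg),
      list(edge = edge_slot(o, +1), offsets = inner_pos)))
    dbody_areas <- list(
      list(edge = edge_slot(o, +1), offsets = band_offsets(o, +w, 1.5 * w, thick)),
      list(edge = edge_slot(o, -1), offsets = band_offsets(o, -w, 1.5 * w, thick)))
    mk <- function(type, areas, register) {
      area_max <- vapply(areas, function(a) max_line_count(a$offsets, o), 0)
      maxc <- sum(area_max)
      # body-type masks also require each area to pass on its own: a single
      # curved boundary sweeping through both bands must not mimic the
      # two-sided geometry of a body segment
      area_frac <- if (type == "double_body") 0.65 else 0.5
      per_area <- if (type == "head") rep(0L, length(areas))
      else ceiling(area_frac * feature_threshold_frac / 0.6 * area_max)
      list(feature_type = type, orientation = o, areas = areas,
           max_count = maxc, area_max = area_max,
           on_threshold = ceiling(feature_threshold_frac * maxc),
           area_thresholds = per_area,
           register_offsets = register)
    }
    masks[[length(masks) + 1]] <- mk("head", head_areas, matrix(c(0, 0), 1))
    masks[[length(masks) + 1]] <- mk("body", body_areas, matrix(c(0, 0), 1))
    masks[[length(masks) + 1]] <-
      mk("double_body", dbody_areas,
         rbind(round(+w / 2 * n), round(-w / 2 * n)))
  }
  masks
}

# ---- feature detection -----------------------------------------------------

feature_slot <- function(type, o) {
  base <- c(head = 0L, body = 4L, double_body = 8L)[[type]]
  base + o + 1L
}

coarse_center_px <- function(z, unit) (z - 1L) * unit + ceiling(unit / 2)

#' Detect mid-level features on the coarse grid
#'
#' Evaluates every mask's likelihood-ratio count test at the pixel centers of
#' all coarse-grid cells: a feature fires where the number of matching edges
#' inside the mask's areas reaches the mask's \code{on_threshold}. Fired
#' double-body tests are registered at the coarse cells containing the
#' hypothesized centers of the two pressed body segments.
#'
#' @param edges a \code{worm_edges} object.
#' @param masks mask list from [build_masks].
#' @param coarse_unit pixels per coarse-grid cell (>= 1); the coarse grid has
#'   \code{ceiling(dim / coarse_unit)} cells per dimension.
#' @return An object of class \code{worm_features}: logical array
#'   \code{Hr x Hc x 12} (slices 1-4 head, 5-8 body, 9-12 double-body, by
#'   orientation code), plus \code{coarse_unit} and \code{counts} (the raw
#'   count of matching edges per cell for each mask).
#' @export
detect_features <- function(edges, masks, coarse_unit) {
  stopifnot(inherits(edges, "worm_edges"))
  if (coarse_unit < 1) stop("coarse_unit must be >= 1")
  nr <- edges$dim[1]; nc <- edges$dim[2]
  pad <- max(vapply(masks, function(m)
    max(abs(unlist(lapply(m$areas, `[[`, "offsets")))), 0)) + 1L
  if (2 * pad >= min(nr, nc)) stop("mask larger than image")

  Hr <- ceiling(nr / coarse_unit); Hc <- ceiling(nc / coarse_unit)
  zr <- coarse_center_px(seq_len(Hr), coarse_unit)
  zc <- coarse_center_px(seq_len(Hc), coarse_unit)

  # padded edge planes so offset lookups need no bounds checks
  nrp <- nr + 2L * pad; ncp <- nc + 2L * pad
  planes <- vector("list", 8)
  for (e in 1:8) {
    p <- matrix(FALSE, nrp, ncp)
    p[(pad + 1):(pad + nr), (pad + 1):(pad + nc)] <- edges$arrays[, , e]
    planes[[e]] <- p
  }
  # linear indices of all cell centers in the padded plane
  base_idx <- as.vector(outer(zr + pad, (zc + pad - 1L) * nrp, "+"))

  fmap <- array(FALSE, dim = c(Hr, Hc, 12))
  counts_out <- vector("list", length(masks))
  for (mi in seq_along(masks)) {
    m <- masks[[mi]]
    counts <- numeric(length(base_idx))
    pass_each <- rep(TRUE, length(base_idx))
    for (ai in seq_along(m$areas)) {
      a <- m$areas[[ai]]
      pl <- planes[[a$edge]]
      off <- a$offsets
      deltas <- off[, 1] + off[, 2] * nrp
      acount <- numeric(length(base_idx))
      for (d in deltas) acount <- acount + pl[base_idx + d]
      # duplicate parallel edges (e.g. a two-pixel rim) add no evidence:
      # an area can contribute at most one edge per lattice step
      acount <- pmin(acount, m$area_max[ai])
      counts <- counts + acount
      if (m$area_thresholds[ai] > 0)
        pass_each <- pass_each & acount >= m$area_thresholds[ai]
    }
    fired <- matrix(counts >= m$on_threshold & pass_each, Hr, Hc)
    slot <- feature_slot(m$feature_type, m$orientation)
    if (m$feature_type == "double_body") {
      # register at the two hypothesized segment centers
      hits <- which(fired, arr.ind = TRUE)
      if (nrow(hits) > 0) {
        plane <- fmap[, , slot]
        for (k in seq_len(nrow(m$register_offsets))) {
          tz_r <- clamp(ceiling((zr[hits[, 1]] + m$register_offsets[k, 1]) /
                                  coarse_unit), 1L, Hr)
          tz_c <- clamp(ceiling((zc[hits[, 2]] + m$register_offsets[k, 2]) /
                                  coarse_unit), 1L, Hc)
          plane[cbind(tz_r, tz_c)] <- TRUE
        }
        fmap[, , slot] <- plane
      }
    } else {
      fmap[, , slot] <- fmap[, , slot] | fired
    }
    counts_out[[mi]] <- matrix(counts, Hr, Hc)
  }

  structure(list(arrays = fmap, coarse_unit = coarse_unit,
                 dim = c(Hr, Hc), counts = counts_out),
            class = "worm_features")
}

#' @export
print.worm_features <- function(x, ...) {
  nm <- c(paste0("head", c(0, 45, 90, 135)),
          paste0("body", c(0, 45, 90, 135)),
          paste0("dbody", c(0, 45, 90, 135)))
  counts <- apply(x$arrays, 3, sum)
  names(counts) <- nm
  cat(sprintf("worm_features: %d x %d coarse grid (unit %d px)\n",
              x$dim[1], x$dim[2], x$coarse_unit))
  print(counts)
  invisible(x)
}
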