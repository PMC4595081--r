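# Fine (pixel-resolution) boundary detection: corridors around the coarse
# result define admissible sets; a chain-structured dynamic program maximizes
# the edge data model plus orientation prior; midpoints of opposite boundary
# points give the refined midline.

coarse_to_px <- function(points, unit) {
  cbind(coarse_center_px(points[, 1], unit),
        coarse_center_px(points[, 2], unit))
}

#' Build the fine search space from a coarse instantiation
#'
#' The coarse midline is smoothed (moving average), converted to pixel
#' coordinates and offset by half a worm width on both sides to hypothesize
#' the left and right body boundaries. The boundary index runs from the left
#' side of the tail, through the tip of the head, to the right side of the
#' tail (2n + 1 points). Each admissible set contains the pixels within
#' \code{corridor_halfwidth} of the hypothesized boundary point; expected
#' segment orientations are quantized to 45-degree directions.
#'
#' @param coarse a \code{worm_coarse} object (at least 3 points).
#' @param params a \code{worm_config}.
#' @param dims image dimensions \code{c(nrow, ncol)}.
#' @param n_segments number of boundary samples per side; default places
#'   consecutive points about \code{boundary_spacing} pixels apart.
#' @return An object of class \code{worm_finespace}: list with
#'   \code{admissible} (list of integer pixel matrices), \code{hyp}
#'   (hypothesized boundary points), \code{beta} (expected direction code
#'   0..7 per segment), \code{edge_type} (expected edge slot 1..8 per
#'   segment), \code{tip_index} (index of the head tip, i.e. n + 1 in
#'   1-based indexing) and \code{midline_px} (the smoothed dense midline,
#'   tail to head).
#' @export
build_search_space <- function(coarse, params, dims, n_segments = NULL) {
  stopifnot(inherits(coarse, "worm_coarse"))
  if (nrow(coarse$points) < 3) stop("coarse instantiation too short")
  w <- params$worm_width
  ch <- params$corridor_halfwidth

  pts <- coarse_to_px(coarse$points, coarse$coarse_unit)
  pts <- pts[nrow(pts):1, , drop = FALSE]           # tail -> head
  sm <- smooth_polyline(pts, window = 3L)
  # the coarse search stops where features stop, which is short of the
  # narrow tapered tail (and of the tip of the head); extend the
  # hypothesized midline at both ends so the corridors cover the true
  # tips. The extension adapts to the length budget implied by the prior:
  # when the coarse midline already spans the expected body length the
  # corridors barely extend, when it stops short they reach out for the
  # missing piece (up to 3/4 worm width per end).
  coarse_len <- arc_length(sm)[nrow(sm)]
  expected_len <- params$lambda * coarse$coarse_unit
  ext <- clamp((expected_len + w - coarse_len) / 2, 2, 0.75 * w)
  tail_dir <- sm[1, ] - sm[min(4, nrow(sm)), ]
  tail_dir <- tail_dir / max(sqrt(sum(tail_dir^2)), 1e-9)
  sm <- rbind(sm[1, ] + tail_dir * ext, sm)
  total_len <- arc_length(sm)[nrow(sm)]
  dense <- resample_polyline(sm, max(16L, ceiling(total_len)))
  nd <- nrow(dense)

  # tangents and normals along the dense midline
  tangents <- rbind(dense[2, ] - dense[1, ],
                    (dense[3:nd, , drop = FALSE] - dense[1:(nd - 2), , drop = FALSE]) / 2,
                    dense[nd, ] - dense[nd - 1, ])
  tn <- sqrt(rowSums(tangents^2)); tn[tn == 0] <- 1
  tangents <- tangents / tn
  normals <- cbind(-tangents[, 2], tangents[, 1])

  # half-width profile of the hypothesized boundary: full half width along
  # the body, closing toward the tip over the last worm width at the head
  # and narrowing at the tail
  s <- arc_length(dense)
  L <- s[nd]
  cap_head <- pmin(1, pmax(0, (L - s) / w))
  cap_head <- sqrt(1 - (1 - cap_head)^2)
  cap_tail <- pmin(1, 0.5 + 0.5 * s / (w / 2))
  halfw <- (w / 2) * cap_head * cap_tail

  left <- dense + normals * halfw
  right <- dense - normals * halfw
  tip <- dense[nd, ] + tangents[nd, ] * ext

  if (is.null(n_segments))
    n_segments <- max(8L, ceiling((L + ext) / params$boundary_spacing))
  n <- n_segments
  lb <- resample_polyline(left, n)
  rb <- resample_polyline(right, n)
  hyp <- rbind(lb, tip, rb[n:1, , drop = FALSE])    # eta_0 .. eta_2n
  m <- nrow(hyp)                                    # 2n + 1

  # midline sample associated with each boundary index (for body side)
  mid_idx <- c(round(seq(1, nd, length.out = n)), nd,
               round(seq(nd, 1, length.out = n)))

  # admissible pixel sets: disk of radius corridor_halfwidth, clipped
  rad <- ceiling(ch)
  disk <- as.matrix(expand.grid(dr = -rad:rad, dc = -rad:rad))
  disk <- disk[disk[, 1]^2 + disk[, 2]^2 <= ch^2 + 1e-9, , drop = FALSE]
  if (nrow(disk) == 0) disk <- matrix(0L, 1, 2)
  admissible <- vector("list", m)
  for (i in seq_len(m)) {
    ctr <- round(hyp[i, ])
    px <- cbind(disk[, 1] + ctr[1], disk[, 2] + ctr[2])
    px <- px[px[, 1] >= 1 & px[, 1] <= dims[1] &
               px[, 2] >= 1 & px[, 2] <= dims[2], , drop = FALSE]
    if (nrow(px) == 0)
      px <- matrix(clamp(ctr, c(1, 1), dims), 1, 2)
    admissible[[i]] <- px
  }

  beta <- integer(m - 1)
  edge_type <- integer(m - 1)
  for (i in 2:m) {
    stepv <- hyp[i, ] - hyp[i - 1, ]
    code <- dir_code(stepv[1], stepv[2])
    if (is.na(code)) code <- if (i > 2) beta[i - 2] else 0L
    beta[i - 1] <- code
    o <- code %% 4L
    segmid <- (hyp[i, ] + hyp[i - 1, ]) / 2
    body_dir <- dense[mid_idx[i], ] - segmid
    grad <- -body_dir                               # dark body -> bright bg
    pol <- sum(grad * orient_normal(o))
    edge_type[i - 1] <- edge_slot(o, if (pol >= 0) 1 else -1)
  }

  structure(list(admissible = admissible, hyp = hyp, beta = beta,
                 edge_type = edge_type, tip_index = n + 1L,
                 midline_px = dense, dims = dims),
            class = "worm_finespace")
}

#' Expected edge type of a boundary segment
#'
#' Maps a quantized segment orientation and the side on which the (dark)
#' body lies to the oriented, polarized edge type expected on that boundary,
#' consistent with the polarity convention of [detect_edges]: intensity
#' increases from the body toward the background.
#'
#' @param orientation orientation code 0..3 (0, 45, 90, 135 degrees).
#' @param body_dir numeric length-2 vector (row, col) pointing from the
#'   boundary toward the body interior.
#' @return edge slot 1..8 (see [edge_type_names]).
#' @export
segment_edge_type <- function(orientation, body_dir) {
  stopifnot(orientation %in% 0:3, length(body_dir) == 2)
  pol <- sum(-body_dir * orient_normal(orientation))
  edge_slot(orientation, if (pol >= 0) 1 else -1)
}

# per-edge-type log-likelihood-ratio maps for the fine data model
edge_llr_maps <- function(edges, params) {
  on <- log(params$p_obj / params$p_bg)
  off <- log((1 - params$p_obj) / (1 - params$p_bg))
  dims <- edges$dim
  maps <- array(off, dim = c(dims, 8))
  for (e in 1:8) {
    plane <- matrix(off, dims[1], dims[2])
    plane[edges$arrays[, , e]] <- on
    maps[, , e] <- plane
  }
  maps
}

#' Fine log-posterior of a candidate boundary
#'
#' Reference implementation of the fine objective: for each segment, the
#' log-likelihood-ratio of the segment's expected edge type is summed over
#' the rasterized segment pixels (first segment includes both endpoints;
#' later segments skip their start pixel so joins count once), and the
#' orientation prior subtracts \code{B} per 45-degree step of circular
#' deviation between the actual and expected segment direction. Zero-length
#' segments contribute only their prior term (deviation zero).
#'
#' @param boundary integer matrix \code{(2n+1) x 2} of boundary points.
#' @param edges a \code{worm_edges} object.
#' @param space a \code{worm_finespace}.
#' @param params a \code{worm_config}.
#' @return scalar log-posterior (background-relative).
#' @export
fine_objective <- function(boundary, edges, space, params) {
  maps <- edge_llr_maps(edges, params)
  fine_objective_maps(boundary, maps, space, params)
}

fine_objective_maps <- function(boundary, maps, space, params) {
  m <- nrow(boundary)
  stopifnot(m == length(space$admissible))
  total <- 0
  for (i in 2:m) {
    a <- boundary[i - 1, ]; b <- boundary[i, ]
    px <- bresenham(a, b)
    if (i > 2) px <- px[-1, , drop = FALSE]
    if (nrow(px) > 0) {
      plane <- maps[, , space$edge_type[i - 1]]
      total <- total + sum(plane[px])
    }
    code <- dir_code(b[1] - a[1], b[2] - a[2])
    if (!is.na(code))
      total <- total - params$B * dir_circ_dist(code, space$beta[i - 1])
  }
  total
}

#' Dynamic-programming boundary detection
#'
#' Finds the global maximizer of the fine objective over the product of
#' admissible sets by a chain-structured dynamic program (the log-posterior
#' is a sum of terms of successive point pairs, so the problem is reduced by
#' one variable at a time).
#'
#' @inheritParams fine_objective
#' @param space a \code{worm_finespace} from [build_search_space].
#' @return An object of class \code{worm_fine}: list with \code{boundary}
#'   (\code{(2n+1) x 2} pixel coordinates), \code{head_tip_index},
#'   \code{log_post} and \code{midline} (see [boundaries_to_midline];
#'   computed lazily by callers).
#' @export
dp_solve <- function(edges, space, params) {
  stopifnot(inherits(space, "worm_finespace"))
  maps <- edge_llr_maps(edges, params)
  res <- dp_solve_cpp(lapply(space$admissible, function(x) {
    storage.mode(x) <- "integer"; x
  }), maps, as.integer(space$edge_type), as.integer(space$beta), params$B)
  structure(list(boundary = res$boundary,
                 head_tip_index = space$tip_index,
                 log_post = res$log_post),
            class = "worm_fine")
}

#' Derive the midline from detected boundaries
#'
#' Opposite boundary points (\code{eta_i} and \code{eta_{2n-i}}) are paired
#' and their midpoints form the midline from the tail to the head tip,
#' which is then resampled to \code{n_samples} points equally spaced in arc
#' length.
#'
#' @param fine a \code{worm_fine} object.
#' @param n_samples number of midline samples (default 21, giving the 20
#'   equal intervals used by the posture analytics).
#' @return Numeric matrix \code{n_samples x 2}, tail first, head tip last.
#' @export
boundaries_to_midline <- function(fine, n_samples = 21L) {
  stopifnot(inherits(fine, "worm_fine"))
  b <- fine$boundary
  m <- nrow(b)
  n <- fine$head_tip_index - 1L          # eta_n is at row n + 1
  mid <- (b[1:(n + 1L), , drop = FALSE] +
            b[m:(m - n), , drop = FALSE]) / 2
  if (arc_length(mid)[nrow(mid)] <= 0)
    stop("degenerate boundary: zero-length midline")
  resample_polyline(mid, n_samples)
}
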