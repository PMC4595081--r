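#' Read and write grayscale frames
#'
#' Reads PNG or TIFF frames (8- or 16-bit grayscale) into a numeric matrix
#' of intensities in [0, 255] (rows x columns, origin top-left). Color
#' images are reduced to their first channel.
#'
#' @param path file path (.png, .tif/.tiff).
#' @return numeric intensity matrix.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("cannot read frame: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) dat <- dat[, , 1]
  t(dat) * 255
}

#' @rdname read_frame
#' @param image numeric intensity matrix in [0, 255].
#' @export
write_frame <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(image / 255)), path)
  invisible(path)
}

#' Detect the posture of a worm in a single frame
#'
#' Runs the full coarse-to-fine detection on one grayscale frame: oriented
#' edge extraction, likelihood-ratio feature tests on the coarse grid,
#' head-first beam search for the maximum a posteriori coarse midline, and
#' dynamic-programming refinement of the body boundaries, from which the
#' midline is derived. Each frame is processed independently (no state is
#' shared across frames), so batches parallelize trivially.
#'
#' @param image numeric intensity matrix, or a file path readable by
#'   [read_frame].
#' @param config a [worm_config].
#' @param masks optional precomputed masks (reused across frames in
#'   batches).
#' @return An object of class \code{worm_detection} with components
#'   \code{midline} (\code{n_midline x 2}, tail first), \code{head} and
#'   \code{tail} (pixel coordinates), \code{boundary}, \code{coarse} (the
#'   \code{worm_coarse} result), \code{log_post_coarse},
#'   \code{log_post_fine}, \code{length} (midline arc length in pixels) and
#'   \code{status}.
#' @examples
#' sc <- render_scene(scene_spec(sample_posture("sinuous", seed = 1)))
#' fit <- detect_posture(sc$image)
#' fit
#' @export
detect_posture <- function(image, config = worm_config(), masks = NULL) {
  if (is.character(image)) image <- read_frame(image)
  if (is.null(masks))
    masks <- build_masks(config$worm_width, config$feature_threshold_frac)
  edges <- detect_edges(image, config$edge_threshold)
  features <- detect_features(edges, masks, config$coarse_unit)
  coarse <- detect_coarse(image, config, masks = masks, features = features)
  space <- build_search_space(coarse, config, dim(image))
  fine <- dp_solve(edges, space, config)
  midline <- boundaries_to_midline(fine, config$n_midline)
  structure(list(
    midline = midline,
    head = midline[nrow(midline), ],
    tail = midline[1, ],
    boundary = fine$boundary,
    coarse = coarse,
    log_post_coarse = coarse$log_post,
    log_post_fine = fine$log_post,
    length = arc_length(midline)[nrow(midline)],
    status = coarse$status,
    dim = dim(image)),
    class = "worm_detection")
}

#' @export
print.worm_detection <- function(x, ...) {
  cat(sprintf("worm_detection: midline length %.1f px, status %s\n",
              x$length, x$status))
  cat(sprintf("  head (%.1f, %.1f), tail (%.1f, %.1f)\n",
              x$head[1], x$head[2], x$tail[1], x$tail[2]))
  cat(sprintf("  log-posterior: coarse %.2f, fine %.2f\n",
              x$log_post_coarse, x$log_post_fine))
  invisible(x)
}

#' @export
summary.worm_detection <- function(object, ...) {
  ang <- midline_angles(object$midline)
  coils <- detect_coils(object$midline)
  out <- list(length = object$length,
              status = object$status,
              n_coarse_points = nrow(object$coarse$points),
              head_len = object$coarse$head_len,
              log_post_coarse = object$log_post_coarse,
              log_post_fine = object$log_post_fine,
              total_turning = sum(ang$angles) / 2,
              anterior_coil = coils$anterior,
              posterior_coil = coils$posterior)
  class(out) <- "summary.worm_detection"
  out
}

#' @export
print.summary.worm_detection <- function(x, ...) {
  cat(sprintf("worm_detection summary\n"))
  cat(sprintf("  midline length: %.1f px (%d coarse points, head %d)\n",
              x$length, x$n_coarse_points, x$head_len))
  cat(sprintf("  total turning: %.2f rad\n", x$total_turning))
  cat(sprintf("  coils: anterior %s, posterior %s\n",
              x$anterior_coil, x$posterior_coil))
  cat(sprintf("  log-posterior: coarse %.2f, fine %.2f; status %s\n",
              x$log_post_coarse, x$log_post_fine, x$status))
  invisible(x)
}

#' Plot a detection over its frame
#'
#' @param x a \code{worm_detection}.
#' @param image optional intensity matrix to draw under the overlay.
#' @param ... passed to [graphics::image].
#' @export
plot.worm_detection <- function(x, image = NULL, ...) {
  if (!is.null(image)) {
    nr <- nrow(image); nc <- ncol(image)
    graphics::image(x = seq_len(nc), y = seq_len(nr),
                    z = t(image[nr:1, , drop = FALSE]),
                    col = gray(seq(0, 1, length.out = 256)),
                    xlab = "col", ylab = "row", useRaster = TRUE, ...)
    flip <- function(p) cbind(p[, 2], nr + 1 - p[, 1])
    graphics::lines(flip(x$boundary), col = "red")
    graphics::lines(flip(x$midline), col = "green", lwd = 2)
    graphics::points(x$head[2], nr + 1 - x$head[1], col = "blue", pch = 19)
    graphics::points(x$tail[2], nr + 1 - x$tail[1], col = "magenta", pch = 19)
  } else {
    plot(x$boundary[, 2], -x$boundary[, 1], type = "l", col = "red",
         xlab = "col", ylab = "-row", asp = 1, ...)
    graphics::lines(x$midline[, 2], -x$midline[, 1], col = "green", lwd = 2)
    graphics::points(x$head[2], -x$head[1], col = "blue", pch = 19)
    graphics::points(x$tail[2], -x$tail[1], col = "magenta", pch = 19)
  }
  invisible(x)
}
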