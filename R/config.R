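#' Detector and analytics configuration
#'
#' Builds the full parameter set used by the detection pipeline and the
#' posture analytics, with frozen defaults. All values were set once, during
#' development, against the synthetic renderer and are not tuned per dataset.
#'
#' Geometry is expressed in pixels. The coarse grid unit defaults to one
#' quarter of the worm width; the expected coarse midline length
#' \code{lambda} defaults to \code{worm_length / coarse_unit}.
#'
#' Key parameters:
#' \describe{
#'   \item{worm_width, worm_length}{nominal body width and length in pixels
#'     (known per developmental stage and magnification).}
#'   \item{edge_threshold}{minimum absolute adjacent-pixel intensity
#'     difference for an edge, in intensity units. Default 7, i.e. 5\% of
#'     the nominal object/background contrast of 140 (body 60 on background 200), small enough that
#'     boundary gradients survive Gaussian blur up to sigma = 3 px at half
#'     contrast.}
#'   \item{feature_threshold_frac}{feature likelihood-ratio tests fire when
#'     the matching-edge count reaches this fraction of the mask's maximum
#'     attainable count (default 0.6).}
#'   \item{p_high, p_med, p_low}{probabilities of a correctly oriented
#'     feature on the midline, adjacent to the midline, and anywhere else;
#'     estimated once from labelled synthetic scenes.}
#'   \item{A, lambda}{length-prior precision and expected coarse length; the
#'     prior is \code{exp(-A (n - lambda)^2)}.}
#'   \item{alpha}{beam tolerance multiplier; the beam keeps candidates
#'     within \code{DIFF = alpha * (best-case minus worst-case per-point
#'     log-likelihood-ratio)} of the best posterior.}
#'   \item{head_stop, body_stop}{consecutive non-improving iterations before
#'     the head (2) and body (3) searches stop.}
#'   \item{p_obj, p_bg}{probability of the matching oriented edge on a body
#'     boundary pixel vs anywhere else (fine model).}
#'   \item{B}{orientation-prior precision per 45-degree step of deviation
#'     between actual and expected boundary-segment orientation.}
#'   \item{corridor_halfwidth}{radius in pixels of the admissible region
#'     around each hypothesized boundary point (default worm_width / 2).}
#'   \item{boundary_spacing}{target spacing in pixels between consecutive
#'     boundary points (default 2).}
#'   \item{n_midline}{number of resampled midline points (21, giving 20
#'     equal intervals and 18 relative angles).}
#'   \item{coil_fraction, coil_exclusion}{head/tail proximity threshold and
#'     arc-length exclusion zone for coil detection, as fractions of the
#'     midline length.}
#'   \item{kmeans_k, kmeans_redundancy}{posture clustering defaults (50, 5).}
#' }
#'
#' @param ... named overrides of any default.
#' @return An object of class \code{worm_config} (a named list).
#' @examples
#' cfg <- worm_config(worm_width = 10)
#' cfg$coarse_unit
#' @export
worm_config <- function(...) {
  cfg <- list(
    # geometry
    worm_width = 12,
    worm_length = 180,
    coarse_unit = NULL,       # default worm_width / 4
    # edges and features
    edge_threshold = 7,
    feature_threshold_frac = 0.6,
    # coarse model (feature probabilities estimated once from labelled
    # synthetic scenes: on-midline, adjacent to midline, background)
    p_high = 0.80,
    p_med = 0.70,
    p_low = 0.01,
    lambda = NULL,            # default worm_length / coarse_unit
    A = 0.15,
    alpha = 3,
    head_stop = 2L,
    body_stop = 3L,
    use_double_body = TRUE,
    multi_head = TRUE,
    # fine model (edge probabilities estimated the same way: matching
    # oriented edges on true boundaries vs anywhere)
    p_obj = 0.40,
    p_bg = 0.01,
    B = 1.5,
    corridor_halfwidth = NULL, # default worm_width / 2
    boundary_spacing = 2,
    n_midline = 21L,
    # analytics
    coil_fraction = 0.05,
    coil_exclusion = 0.15,
    kmeans_k = 50L,
    kmeans_redundancy = 5L,
    loco_window = 2,          # seconds
    loco_maxlag = 0.5,        # seconds
    loco_min_cor = 0.5,
    quiescence_threshold = 0.005, # mean |angle change| per frame, radians
    # orchestration
    seed = 1L,
    workers = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config parameters: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (is.null(cfg$coarse_unit)) cfg$coarse_unit <- max(1L, round(cfg$worm_width / 4))
  if (is.null(cfg$lambda)) cfg$lambda <- cfg$worm_length / cfg$coarse_unit
  if (is.null(cfg$corridor_halfwidth)) cfg$corridor_halfwidth <- cfg$worm_width / 2
  validate_worm_config(cfg)
  class(cfg) <- "worm_config"
  cfg
}

validate_worm_config <- function(cfg) {
  stopifnot(
    cfg$worm_width >= 4,
    cfg$worm_length > cfg$worm_width,
    cfg$coarse_unit >= 1,
    cfg$edge_threshold > 0,
    cfg$feature_threshold_frac > 0, cfg$feature_threshold_frac <= 1,
    cfg$p_low > 0, cfg$p_low < cfg$p_med, cfg$p_med < cfg$p_high,
    cfg$p_high < 1,
    cfg$A >= 0, cfg$alpha > 0,
    cfg$head_stop >= 1, cfg$body_stop >= 1,
    cfg$p_bg > 0, cfg$p_bg < cfg$p_obj, cfg$p_obj < 1,
    cfg$B >= 0,
    cfg$corridor_halfwidth >= 0,
    cfg$n_midline >= 5,
    cfg$coil_fraction > 0, cfg$coil_fraction < 1,
    cfg$coil_exclusion >= 0, cfg$coil_exclusion < 0.5
  )
  invisible(cfg)
}

#' @export
print.worm_config <- function(x, ...) {
  cat("worm_config:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write configuration files
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path file path.
#' @param cfg a \code{worm_config} object.
#' @return \code{read_worm_config} returns a \code{worm_config};
#'   \code{write_worm_config} returns \code{path} invisibly.
#' @export
read_worm_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(worm_config, vals)
}

#' @rdname read_worm_config
#' @export
write_worm_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "worm_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
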