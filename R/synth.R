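# Synthetic worm postures and rendered scenes with exact ground truth.
# Postures are defined by a curvature profile over arc length built from at
# most six smooth (cosine) basis functions; scenes emulate the imaging
# conditions of the detector's target data: dark body on a lighter uniform
# background, a lighter interior band in the anterior 15% of the body (the
# origin of the head's inner edge pair), contrast scalings 0.5-1.5,
# Gaussian blur of sigma 2-3 px, and additive sensor noise.

N_BASIS <- 6L

# orthonormal cosine basis on [0, 1]; coefficient 1 equals the total body
# turning in radians (the other basis functions integrate to zero)
curvature_basis <- function(u, j) {
  if (j == 1) rep(1, length(u)) else sqrt(2) * cos((j - 1) * pi * u)
}

curvature_profile <- function(coefficients, u) {
  k <- numeric(length(u))
  for (j in seq_along(coefficients))
    if (coefficients[j] != 0) k <- k + coefficients[j] * curvature_basis(u, j)
  k
}

# project an arbitrary curvature shape onto the first N_BASIS basis functions
project_basis <- function(fun_vals, u) {
  du <- c(diff(u), 0)
  vapply(seq_len(N_BASIS), function(j)
    sum(fun_vals * curvature_basis(u, j) * du), 0)
}

# maximum curvature the body can support: minimal bend radius of one worm
# width (biomechanical constraint)
curvature_cap <- function(width) 1 / width

new_posture_spec <- function(coefficients, length, width, pose, chirality,
                             family, noise = NULL, seed = NA_integer_) {
  structure(list(coefficients = coefficients, length = length, width = width,
                 pose = pose, chirality = chirality, family = family,
                 noise = noise, seed = seed),
            class = "posture_spec")
}

#' @export
print.posture_spec <- function(x, ...) {
  cat(sprintf("posture_spec: family %s, length %.0f px, width %.0f px\n",
              x$family, x$length, x$width))
  cat("  coefficients:", paste(sprintf("%.2f", x$coefficients), collapse = " "),
      "\n")
  invisible(x)
}

#' Ground-truth midline of a posture
#'
#' Integrates the curvature profile into a midline polyline, tail (arc
#' length 0) to head. The heading convention matches [midline_angles]:
#' positive curvature turns the heading counter-clockwise in image
#' coordinates.
#'
#' @param spec a \code{posture_spec}.
#' @param step integration step in pixels (default 0.5).
#' @return numeric matrix (points x 2) of (row, col) coordinates.
#' @export
posture_midline <- function(spec, step = 0.5) {
  L <- spec$length
  n <- ceiling(L / step)
  s <- seq(0, L, length.out = n + 1)
  u <- s / L
  kappa <- curvature_profile(spec$coefficients, u) / L
  if (!is.null(spec$noise)) {
    iv <- pmin(length(spec$noise), floor(u * length(spec$noise)) + 1L)
    kappa <- kappa + spec$noise[iv]
  }
  kappa <- spec$chirality * kappa
  ds <- diff(s)
  psi <- spec$pose$heading + c(0, cumsum(kappa[-length(kappa)] * ds))
  pts <- cbind(c(0, cumsum(sin(psi[-length(psi)]) * ds)),
               c(0, cumsum(cos(psi[-length(psi)]) * ds)))
  ctr <- colMeans(pts)
  sweep(pts, 2, ctr - spec$pose$position, "-")
}

# simple-midline check: no two points with arc separation above `gap`
# pixels may come closer than `min_dist`
is_simple_midline <- function(pts, gap = 6, min_dist = 0.75) {
  n <- nrow(pts)
  sub <- pts[seq(1, n, by = 2), , drop = FALSE]
  s <- arc_length(sub)
  m <- nrow(sub)
  dr <- outer(sub[, 1], sub[, 1], "-")
  dc <- outer(sub[, 2], sub[, 2], "-")
  d2 <- dr^2 + dc^2
  sep <- abs(outer(s, s, "-"))
  all(d2[sep > gap] > min_dist^2)
}

max_abs_curvature <- function(spec, n_grid = 400) {
  u <- seq(0, 1, length.out = n_grid)
  max(abs(curvature_profile(spec$coefficients, u))) / spec$length
}

# Reference eigenbasis for spool certification: PCA of a fixed ensemble of
# coiled postures with independently drawn anterior and posterior bends
# (emulating equal sampling of anterior- and posterior-coiled frames), so
# the two leading modes localize to anterior and posterior curvature. Each
# leading mode is flipped to have a non-negative total loading, which makes
# the sign of a1 * a2 well defined: same-signed anterior and posterior
# bending gives a positive product.
.synth_cache <- new.env(parent = emptyenv())
reference_eigen <- function(length = 180, width = 12) {
  key <- sprintf("ref_%s_%s", length, width)
  if (!is.null(.synth_cache[[key]])) return(.synth_cache[[key]])
  u <- seq(0, 1, length.out = 400)
  g_post <- exp(-((u - 0.25) / 0.18)^2)
  g_ant <- exp(-((u - 0.75) / 0.18)^2)
  cap <- curvature_cap(width)
  ang <- with_seed(771234, t(vapply(seq_len(500), function(i) {
    prof <- (rnorm(1, 0, 3.5) * g_ant + rnorm(1, 0, 3.5) * g_post) +
      rnorm(1, 0, 1.5)
    coef <- project_basis(prof, u) + rnorm(N_BASIS) * 0.3
    mx <- max(abs(curvature_profile(coef, u))) / length
    if (mx > 0.9 * cap) coef <- coef * (0.9 * cap / mx)
    sp <- new_posture_spec(coef, length, width,
                           list(position = c(0, 0), heading = 0), 1,
                           "reference")
    midline_angles(posture_midline(sp))$angles
  }, numeric(18))))
  eg <- eigenworms(ang)
  flip <- ifelse(colSums(eg$modes) < 0, -1, 1)
  eg$modes <- sweep(eg$modes, 2, flip, "*")
  eg$amplitudes <- sweep(eg$amplitudes, 2, flip, "*")
  .synth_cache[[key]] <- eg
  eg
}

#' Sample a synthetic worm posture
#'
#' Draws a posture from one of the built-in families, deterministic given
#' the seed. All families respect the biomechanical curvature cap (minimal
#' bend radius of one worm width) and keep the midline simple
#' (non-self-intersecting) even when the rendered body touches itself.
#'
#' Families: \code{straight} (zero curvature); \code{sinuous} (moderate
#' random low-order bends, the typical crawling posture); \code{omega}
#' (deep bend bringing the head within 5\% of the midline length of the
#' mid-body, as in omega turns); \code{spool} (inward spiral with
#' same-signed anterior and posterior curvature, body pressed against
#' itself; certified to satisfy a1*a2 > 1 in the generator's reference
#' eigenbasis); \code{figure8} (opposite-signed end curvatures);
#' \code{random} (independent coefficients on all six curvature basis
#' functions, optionally plus band-unlimited curvature noise via
#' \code{params$noise_sd}).
#'
#' @param family posture family name.
#' @param params optional list: \code{length}, \code{width} (pixels),
#'   \code{position}, \code{heading}, \code{chirality} (+1/-1),
#'   \code{noise_sd} (per-interval white curvature noise, 1/px units).
#' @param seed integer seed; the same seed always returns the same spec.
#' @return a \code{posture_spec}.
#' @export
sample_posture <- function(family = c("straight", "sinuous", "omega", "spool",
                                      "figure8", "random"),
                           params = list(), seed = 1L) {
  family <- match.arg(family)
  L <- params$length %||% 180
  w <- params$width %||% 12
  pose <- list(position = params$position %||% c(0, 0),
               heading = params$heading %||% 0)
  chir <- params$chirality %||% 1
  cap <- curvature_cap(w)
  u_grid <- seq(0, 1, length.out = 400)

  build <- function(coef, noise = NULL) {
    sp <- new_posture_spec(coef, L, w, pose, chir, family, noise, seed)
    if (max_abs_curvature(sp) > cap * 1.0001)
      stop("posture exceeds the biomechanical curvature cap")
    sp
  }
  rescale_to_cap <- function(coef, frac = 1) {
    mx <- max(abs(curvature_profile(coef, u_grid))) / L
    if (mx > frac * cap) coef * (frac * cap / mx) else coef
  }

  spec <- with_seed(seed, switch(
    family,
    straight = build(numeric(N_BASIS)),
    sinuous = {
      coef <- c(0, rnorm(3) * c(2.2, 1.6, 1.0), 0, 0)
      build(rescale_to_cap(coef, 0.55))
    },
    omega = {
      # a deep mid-body bend, scaled until the head approaches the body
      bump <- exp(-((u_grid - 0.55) / 0.28)^2)
      base <- project_basis(bump / sum(bump * c(diff(u_grid), 0)), u_grid)
      found <- NULL
      for (attempt in 1:10) {
        pert <- base + c(0, 0, rnorm(2) * 0.12, 0, 0)
        for (scale in seq(4.3, 7.0, by = 0.05)) {
          cand <- new_posture_spec(pert * scale / pert[1], L, w, pose, chir,
                                   family, seed = seed)
          if (max_abs_curvature(cand) > cap) break
          ml <- posture_midline(cand)
          if (!is_simple_midline(ml)) break
          cl <- detect_coils(ml)
          if (cl$anterior && !cl$posterior) { found <- cand; break }
        }
        if (!is.null(found)) break
      }
      if (is.null(found))
        stop("could not construct an omega posture within the curvature cap")
      found
    },
    spool = {
      # inward spiral of ~1.5 turns whose successive turns lie about one
      # worm width apart (bodies pressed, outer boundaries two widths apart)
      ka <- 0.35 / w; kb <- 0.95 / w
      amp <- runif(1, 0.95, 1.04)
      prof <- (ka + (kb - ka) * u_grid) * L * amp
      coef <- project_basis(prof, u_grid) + c(0, rnorm(2) * 0.12, 0, 0, 0)
      coef <- rescale_to_cap(coef, 0.98)
      sp <- build(coef)
      ref <- reference_eigen(L, w)
      a <- predict(ref, midline_angles(posture_midline(sp))$angles)
      if (a[1] * a[2] <= 1)
        stop("spool construction failed its amplitude certificate")
      sp
    },
    figure8 = {
      amp <- 9.0 * runif(1, 0.92, 1.05) * sample(c(-1, 1), 1)
      coef <- c(0, amp, 0, rnorm(1) * 0.3, 0, 0)
      coef <- rescale_to_cap(coef, 0.9)
      sp <- build(coef)
      k0 <- curvature_profile(sp$coefficients, 0)
      k1 <- curvature_profile(sp$coefficients, 1)
      if (k0 * k1 >= 0) stop("figure8 end curvatures must have opposite signs")
      sp
    },
    random = {
      noise_sd <- params$noise_sd %||% 0
      for (try in 0:20) {
        coef <- rnorm(N_BASIS) * c(4.2, 3.2, 2.4, 1.8, 1.3, 1.0)
        coef <- rescale_to_cap(coef, 0.9)
        noise <- if (noise_sd > 0) rnorm(20) * noise_sd else NULL
        sp <- new_posture_spec(coef, L, w, pose, chir, family, noise, seed)
        if (is_simple_midline(posture_midline(sp))) break
        sp <- NULL
      }
      if (is.null(sp)) stop("could not sample a simple random posture")
      sp
    }))
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scene specification
#'
#' Photometric and geometric parameters of one rendered frame. The body is
#' darker than the background by at least twice the default edge threshold
#' before perturbation; the anterior 15\% of the body carries a lighter
#' interior band (head core) producing the head's inner edge pair.
#'
#' @param posture a \code{posture_spec}.
#' @param background_level,body_level,head_core_level intensities (0-255).
#' @param contrast_scale object contrast multiplier (0.5-1.5 emulates
#'   digitally rescaled contrast).
#' @param blur_sigma Gaussian blur standard deviation in pixels (0, 2 or 3).
#' @param noise_sd additive Gaussian sensor noise, intensity units.
#' @param seed noise seed.
#' @param dims frame dimensions (rows, cols).
#' @return a \code{scene_spec} object.
#' @export
scene_spec <- function(posture, background_level = 200, body_level = 60,
                       head_core_level = 150, contrast_scale = 1,
                       blur_sigma = 0, noise_sd = 0, seed = 1L,
                       dims = c(288L, 288L)) {
  stopifnot(inherits(posture, "posture_spec"),
            background_level > body_level,
            contrast_scale >= 0.25, contrast_scale <= 2,
            blur_sigma >= 0, noise_sd >= 0)
  structure(list(posture = posture, background_level = background_level,
                 body_level = body_level, head_core_level = head_core_level,
                 contrast_scale = contrast_scale, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, seed = seed, dims = as.integer(dims)),
            class = "scene_spec")
}

# local half-width of the body: constant along the trunk, sharply tapered
# at the tail, rounded at the head
halfwidth_profile <- function(s, L, width) {
  t_tail <- clamp(s / (0.12 * L), 0, 1)
  t_head <- sqrt(clamp((L - s) / (0.06 * L), 0, 1))
  (width / 2) * t_tail * t_head
}

#' Render a synthetic scene
#'
#' Sweeps a tapered tube of the configured width along the posture midline
#' (tail sharper than head), fills it at the body level, adds the lighter
#' head-core band over the anterior 15\% of the body, then applies contrast
#' scaling (relative to the background level), Gaussian blur and additive
#' noise. Ground truth (midline, head, tail, boundary, arc length) refers
#' to the unperturbed geometry.
#'
#' @param spec a \code{scene_spec}.
#' @return An object of class \code{worm_scene}: list with \code{image}
#'   (intensity matrix) and \code{truth} (list: \code{midline} dense,
#'   \code{midline21}, \code{head}, \code{tail}, \code{boundary},
#'   \code{length}, \code{family}).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  dims <- spec$dims
  post <- spec$posture
  # center the midline in the frame unless a position was given
  ml <- posture_midline(post, step = 0.5)
  if (all(post$pose$position == c(0, 0))) {
    ctr <- c(mean(range(ml[, 1])), mean(range(ml[, 2])))
    ml <- sweep(ml, 2, ctr - dims / 2, "-")
  }
  s <- arc_length(ml)
  L <- s[length(s)]
  h <- halfwidth_profile(s, L, post$width)
  margin <- max(h) + 2
  if (min(ml) < margin || max(ml[, 1]) > dims[1] - margin ||
      max(ml[, 2]) > dims[2] - margin)
    stop("posture does not fit in the frame")

  img <- matrix(spec$background_level, dims[1], dims[2])
  paint <- function(img, centers, radii, level) {
    rmax <- ceiling(max(radii))
    disk <- as.matrix(expand.grid(dr = -rmax:rmax, dc = -rmax:rmax))
    dd <- disk[, 1]^2 + disk[, 2]^2
    for (i in seq_len(nrow(centers))) {
      if (radii[i] <= 0) next
      sel <- dd <= radii[i]^2
      rr <- round(centers[i, 1]) + disk[sel, 1]
      cc <- round(centers[i, 2]) + disk[sel, 2]
      at <- cbind(rr, cc)
      img[at] <- pmin(img[at], level)
    }
    img
  }
  img <- paint(img, ml, h, spec$body_level)
  core <- s >= 0.85 * L
  core_img <- matrix(Inf, dims[1], dims[2])
  core_img <- paint(core_img, ml[core, , drop = FALSE], h[core] * 0.7,
                    spec$head_core_level)
  sel_core <- is.finite(core_img)
  img[sel_core] <- core_img[sel_core]

  img <- spec$background_level +
    (img - spec$background_level) * spec$contrast_scale
  if (spec$blur_sigma > 0) {
    eb <- EBImage::gblur(EBImage::Image(t(img)), sigma = spec$blur_sigma)
    img <- t(EBImage::imageData(eb))
  }
  if (spec$noise_sd > 0)
    img <- img + with_seed(spec$seed,
                           matrix(rnorm(length(img), sd = spec$noise_sd),
                                  nrow(img)))
  img <- clamp(img, 0, 255)

  # ground-truth boundary polygon: left side, head cap, right side
  tang <- rbind(ml[2, ] - ml[1, ],
                (ml[-(1:2), ] - ml[1:(nrow(ml) - 2), ]) / 2,
                ml[nrow(ml), ] - ml[nrow(ml) - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  norm <- cbind(-tang[, 2], tang[, 1])
  boundary <- rbind(ml + norm * h, ml[nrow(ml):1, ] - norm[nrow(ml):1, ] * h)

  structure(list(
    image = img,
    truth = list(midline = ml,
                 midline21 = resample_polyline(ml, 21L),
                 head = ml[nrow(ml), ],
                 tail = ml[1, ],
                 boundary = boundary,
                 length = L,
                 family = post$family),
    spec = spec), class = "worm_scene")
}

#' @export
print.worm_scene <- function(x, ...) {
  cat(sprintf(
    "worm_scene: %d x %d frame, %s posture, length %.1f px\n",
    nrow(x$image), ncol(x$image), x$truth$family, x$truth$length))
  cat(sprintf("  contrast %.2f, blur %.1f px, noise sd %.1f\n",
              x$spec$contrast_scale, x$spec$blur_sigma, x$spec$noise_sd))
  invisible(x)
}

#' Generate a reproducible synthetic dataset
#'
#' Renders \code{n} scenes with families stratified per \code{mix} and
#' photometric perturbations matching the detector's documented operating
#' conditions: contrast scale uniform in [0.5, 1.5], blur sigma cycling
#' through 0, 2 and 3 px, sensor noise of 2 intensity units, and random
#' pose. Everything is reproducible from \code{master_seed}; the manifest
#' records every scene's parameters.
#'
#' @param n number of frames (>= 1).
#' @param mix named family proportions (defaults cover all posture
#'   families).
#' @param master_seed integer seed.
#' @param config a [worm_config] (supplies worm length/width).
#' @param perturb logical; \code{FALSE} renders unperturbed scenes.
#' @return list with \code{scenes} (list of \code{worm_scene}) and
#'   \code{manifest} (data frame).
#' @export
generate_dataset <- function(n, mix = c(straight = 0.10, sinuous = 0.25,
                                        omega = 0.20, spool = 0.20,
                                        figure8 = 0.15, random = 0.10),
                             master_seed = 1L, config = worm_config(),
                             perturb = TRUE) {
  stopifnot(n >= 1, abs(sum(mix) - 1) < 1e-6)
  counts <- diff(c(0, round(cumsum(mix) * n)))
  families <- rep(names(mix), counts)
  if (length(families) < n)
    families <- c(families, rep(names(mix)[which.max(mix)],
                                n - length(families)))
  draws <- with_seed(master_seed, list(
    seeds = sample.int(2^31 - 2, n),
    contrast = if (perturb) runif(n, 0.5, 1.5) else rep(1, n),
    blur = if (perturb) rep_len(c(0, 2, 3), n) else rep(0, n),
    heading = runif(n, 0, 2 * pi),
    chirality = sample(c(-1, 1), n, replace = TRUE)))
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    post <- sample_posture(families[i],
                           params = list(length = config$worm_length,
                                         width = config$worm_width,
                                         heading = draws$heading[i],
                                         chirality = draws$chirality[i]),
                           seed = draws$seeds[i])
    sc <- scene_spec(post, contrast_scale = draws$contrast[i],
                     blur_sigma = draws$blur[i],
                     noise_sd = if (perturb) 2 else 0,
                     seed = draws$seeds[i])
    scenes[[i]] <- render_scene(sc)
  }
  manifest <- data.frame(
    frame = sprintf("frame_%04d", seq_len(n)),
    family = families,
    seed = draws$seeds,
    contrast = draws$contrast,
    blur = draws$blur,
    noise_sd = if (perturb) 2 else 0,
    length = vapply(scenes, function(s) s$truth$length, 0))
  list(scenes = scenes, manifest = manifest)
}

#' Generate a posture ensemble for eigen-analysis
#'
#' Samples \code{n} random band-limited postures (six curvature basis
#' functions) and adds white per-interval curvature noise calibrated so the
#' noise carries the requested fraction of the ensemble's angle-space
#' variance. Returns the 18-angle matrix computed from the ground-truth
#' midlines.
#'
#' @param n ensemble size.
#' @param seed integer seed.
#' @param noise_rel relative noise power (default 0.05).
#' @param length,width worm geometry in pixels.
#' @return numeric matrix (n x 18).
#' @export
generate_posture_ensemble <- function(n, seed = 2L, noise_rel = 0.05,
                                      length = 180, width = 12) {
  seeds <- with_seed(seed, sample.int(2^31 - 2, n))
  params <- list(length = length, width = width)
  clean <- lapply(seeds, function(sd) sample_posture("random", params, sd))
  ang_clean <- t(vapply(clean, function(sp)
    midline_angles(posture_midline(sp))$angles, numeric(18)))
  if (noise_rel <= 0) return(ang_clean)
  vtot <- mean(apply(ang_clean, 2, var))
  sigma_angle <- sqrt(noise_rel * vtot)
  ell <- length / 20
  sigma_kappa <- sigma_angle / (ell * sqrt(2))
  noisy <- t(vapply(seq_len(n), function(i) {
    sp <- clean[[i]]
    sp$noise <- with_seed(seeds[i] + 1L, rnorm(20) * sigma_kappa)
    midline_angles(posture_midline(sp))$angles
  }, numeric(18)))
  noisy
}

#' Simulate posture dynamics with ground truth
#'
#' Generates a time series of 18-angle postures (and midlines) with known
#' locomotion states and coil annotations, for validating
#' [classify_locomotion], [detect_coils] and the event statistics. Three
#' regimes are provided: \code{wildtype-like} (directed locomotion with
#' rare, brief omega-turn coils, coil flags on under 5\% of frames),
#' \code{static-coiler} (locomotion bouts interrupted by locking into a
#' frozen spool posture for Weibull-distributed durations, dwelling
#' throughout the coil) and \code{loopy-mover} (continuous high-amplitude
#' waves with coiling during directed motion).
#'
#' @param duration recording length in seconds (duration * fps >= 100).
#' @param fps frames per second.
#' @param regime one of \code{"wildtype-like"}, \code{"static-coiler"},
#'   \code{"loopy-mover"}.
#' @param seed integer seed.
#' @return list with \code{time}, \code{angles} (frames x 18, tail to
#'   head), \code{midlines} (list of 21 x 2 matrices), \code{states}
#'   (ground-truth factor), \code{anterior}, \code{posterior} (ground-truth
#'   coil flags), \code{fps}, \code{regime}.
#' @export
simulate_behavior <- function(duration, fps,
                              regime = c("wildtype-like", "static-coiler",
                                         "loopy-mover"),
                              seed = 1L) {
  regime <- match.arg(regime)
  T_ <- round(duration * fps)
  if (T_ < 100) stop("need at least 100 frames (duration * fps)")
  j <- 1:18

  wave <- function(tt, dir, amp = 0.5, freq = 0.4) {
    # dir = +1: bends propagate head -> tail (forward; pattern moves toward
    # lower tail-to-head index as time advances)
    amp * sin(2 * pi * (outer(tt * freq * dir, j / 12, "+")))
  }
  spool_angles <- with_seed(seed + 99, {
    sp <- sample_posture("spool", seed = seed + 99)
    midline_angles(posture_midline(sp))$angles
  })
  omega_bend <- 0.9 * exp(-((j - 13) / 3)^2)

  out <- with_seed(seed, {
    angles <- matrix(0, T_, 18)
    states <- rep("dwell", T_)
    ant <- logical(T_); post <- logical(T_)
    tt <- (seq_len(T_) - 1) / fps

    if (regime == "wildtype-like") {
      t0 <- 1L
      dir <- 1
      while (t0 <= T_) {
        len <- max(3L, round(fps * rexp(1, 1 / ifelse(dir > 0, 12, 3))))
        idx <- t0:min(T_, t0 + len - 1L)
        angles[idx, ] <- wave(tt[idx], dir)
        states[idx] <- if (dir > 0) "forward" else "backward"
        t0 <- t0 + len
        # brief dwell at the switch, occasionally an omega-turn coil
        if (t0 <= T_) {
          dlen <- max(2L, round(fps * 0.6))
          idx <- t0:min(T_, t0 + dlen - 1L)
          angles[idx, ] <- wave(tt[idx], dir, amp = 0.25)
          states[idx] <- "dwell"
          t0 <- t0 + dlen
          if (dir < 0 && runif(1) < 0.35 && t0 + fps < T_) {
            clen <- max(3L, round(fps * rweibull(1, 1.6, 0.9)))
            idx <- t0:min(T_, t0 + clen - 1L)
            angles[idx, ] <- wave(tt[idx], 1, amp = 0.35) +
              matrix(omega_bend, length(idx), 18, byrow = TRUE)
            states[idx] <- "forward"
            ant[idx] <- TRUE
            t0 <- t0 + clen
          }
          dir <- -dir
        }
      }
    } else if (regime == "static-coiler") {
      t0 <- 1L
      moving <- TRUE
      while (t0 <= T_) {
        if (moving) {
          len <- max(5L, round(fps * rexp(1, 1 / 8)))
          idx <- t0:min(T_, t0 + len - 1L)
          angles[idx, ] <- wave(tt[idx], 1)
          states[idx] <- "forward"
        } else {
          len <- max(5L, round(fps * rweibull(1, 1.5, 10)))
          idx <- t0:min(T_, t0 + len - 1L)
          jitter <- matrix(rnorm(length(idx) * 18, sd = 0.02),
                           length(idx), 18)
          angles[idx, ] <- matrix(spool_angles, length(idx), 18,
                                  byrow = TRUE) + jitter
          states[idx] <- "dwell"
          ant[idx] <- TRUE
          post[idx] <- TRUE
        }
        t0 <- t0 + length(idx)
        moving <- !moving
      }
    } else { # loopy-mover
      envelope <- 0.55 + 0.45 * sin(2 * pi * tt / 12)^2
      dirseq <- rep(1, T_)
      nrev <- max(1L, round(duration / 15))
      for (r in seq_len(nrev)) {
        rs <- sample.int(T_ - round(2 * fps), 1)
        dirseq[rs:(rs + round(2 * fps))] <- -1
      }
      for (t in seq_len(T_)) {
        angles[t, ] <- envelope[t] *
          wave(tt[t], dirseq[t], amp = 1)[1, ] +
          0.55 * envelope[t] * spool_angles / max(abs(spool_angles))
      }
      states <- ifelse(dirseq > 0, "forward", "backward")
      coil_on <- envelope > 0.85
      ant[coil_on] <- TRUE
      post[coil_on] <- TRUE
    }
    list(angles = angles, states = states, ant = ant, post = post, tt = tt)
  })

  midlines <- lapply(seq_len(T_), function(t)
    angles_to_midline(out$angles[t, ], 120))
  list(time = out$tt, angles = out$angles,
       midlines = midlines,
       states = factor(out$states, levels = c("forward", "backward", "dwell",
                                              "quiescent")),
       anterior = out$ant, posterior = out$post,
       fps = fps, regime = regime)
}

#' Reconstruct a midline from 18 relative angles
#'
#' Inverts the representation of [midline_angles]: builds a 21-point
#' polyline with 20 equal intervals whose next-nearest-neighbor relative
#' angles equal the given vector (up to the free rigid motion, fixed by
#' starting at the origin heading along increasing column).
#'
#' @param angles numeric vector of 18 relative angles.
#' @param length total arc length in pixels.
#' @return numeric matrix 21 x 2, tail first.
#' @export
angles_to_midline <- function(angles, length = 120) {
  stopifnot(length(angles) == 18)
  psi <- numeric(20)
  psi[1] <- 0
  psi[2] <- angles[1] / 2
  for (jj in 1:18) psi[jj + 2] <- psi[jj] + angles[jj]
  ell <- length / 20
  pts <- rbind(c(0, 0), cbind(cumsum(ell * sin(psi)), cumsum(ell * cos(psi))))
  pts
}
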