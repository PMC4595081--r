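# Posture analytics: the 18-relative-angle representation, coil detection,
# locomotion states, eigenworm PCA, spool classification, clustering, event
# statistics and transition-aligned summaries.

#' 18-angle posture representation
#'
#' Resamples a midline into 20 equal arc-length intervals and returns the 18
#' signed relative angles between all next-nearest-neighbor interval pairs
#' (interval j vs interval j + 2), which track the curvature of the body.
#' Ordering is tail to head (element 1 is the most posterior angle). The
#' sign convention is the right-handed angle in image coordinates (x = col,
#' y = row increasing downward): positive when the more anterior interval is
#' rotated counter-clockwise on screen relative to the posterior one. Angles
#' are invariant under rigid motions and uniform scaling of the midline.
#'
#' @param midline numeric matrix (>= 5 points x 2, tail first) of (row, col)
#'   coordinates.
#' @param frame_time optional time stamp in seconds.
#' @return An object of class \code{worm_angles}: list with \code{angles}
#'   (length 18) and \code{frame_time}.
#' @examples
#' straight <- cbind(seq(0, 100, length.out = 21), 50)
#' midline_angles(straight)$angles  # all zero
#' @export
midline_angles <- function(midline, frame_time = NA_real_) {
  if (!is.matrix(midline) || nrow(midline) < 5)
    stop("midline must be a matrix with at least 5 points")
  p <- resample_polyline(midline, 21L)
  v <- diff(p)                      # 20 interval vectors
  ang <- vapply(1:18, function(j) {
    a <- v[j, ]; b <- v[j + 2, ]
    atan2(a[2] * b[1] - a[1] * b[2], a[1] * b[1] + a[2] * b[2])
  }, 0)
  structure(list(angles = ang, frame_time = frame_time),
            class = "worm_angles")
}

#' Most posterior relative body angle
#'
#' The angle between the two most posterior next-nearest-neighbor intervals
#' of the 20-interval representation (the first of the 18 relative angles).
#' Its sign follows the convention of [midline_angles]; mirror-reflecting
#' the posture negates it.
#'
#' @param angles a \code{worm_angles} object or a numeric vector of 18
#'   angles.
#' @return signed angle in radians.
#' @export
posterior_body_angle <- function(angles) {
  a <- if (inherits(angles, "worm_angles")) angles$angles else angles
  stopifnot(length(a) == 18)
  a[1]
}

#' Detect anterior and posterior coils
#'
#' A frame shows an anterior coil when the head is within
#' \code{fraction} of the midline length (Euclidean distance) of any body
#' point whose arc-length distance from the head exceeds
#' \code{exclusion} of the midline length; posterior coils are defined
#' symmetrically for the tail. The two flags are not mutually exclusive.
#' The bend direction is reported from the sign of the total body turning
#' when a dorsoventral convention is supplied (\code{ventral_sign = +1}
#' declares positive turning ventral), otherwise \code{"unknown"}.
#'
#' @param midline matrix of midline points, tail first, head last.
#' @param fraction proximity threshold as a fraction of midline length
#'   (default 0.05).
#' @param exclusion arc-length exclusion zone around the endpoint, as a
#'   fraction of midline length (default 0.15).
#' @param ventral_sign \code{+1}, \code{-1} or \code{NA} (unknown).
#' @return An object of class \code{worm_coils}: list with \code{anterior},
#'   \code{posterior} (logicals) and \code{direction}
#'   (\code{"dorsal"}, \code{"ventral"} or \code{"unknown"}).
#' @export
detect_coils <- function(midline, fraction = 0.05, exclusion = 0.15,
                         ventral_sign = NA) {
  dense <- resample_polyline(midline, 201L)
  s <- arc_length(dense)
  L <- s[length(s)]
  head_pt <- dense[nrow(dense), ]
  tail_pt <- dense[1, ]
  near <- function(endpoint, arc_from_end) {
    ok <- arc_from_end > exclusion * L
    if (!any(ok)) return(FALSE)
    d <- sqrt((dense[ok, 1] - endpoint[1])^2 + (dense[ok, 2] - endpoint[2])^2)
    min(d) < fraction * L
  }
  anterior <- near(head_pt, L - s)
  posterior <- near(tail_pt, s)
  direction <- "unknown"
  if (!is.na(ventral_sign) && (anterior || posterior)) {
    turning <- sum(midline_angles(midline)$angles)
    direction <- if (sign(turning) == sign(ventral_sign)) "ventral" else "dorsal"
  }
  structure(list(anterior = anterior, posterior = posterior,
                 direction = direction),
            class = "worm_coils")
}

#' Classify locomotion states from posture dynamics
#'
#' Directed locomotion is identified from the propagation of body bends
#' along the 18-angle representation: within a sliding window, the lagged
#' correlation between each relative angle and its more anterior neighbor
#' is averaged over the body, and the lag with the highest mean correlation
#' gives the propagation direction. Bends moving from anterior to posterior
#' (peak at negative lag with tail-to-head angle ordering) are scored
#' forward, the reverse backward. Frames whose mean absolute angle change
#' falls below \code{quiescence_threshold} are quiescent; windows without
#' coherent propagation (peak correlation below \code{min_cor}, or a
#' zero-lag peak) are dwelling.
#'
#' @param angle_series numeric matrix (frames x 18), tail-to-head columns.
#' @param fps frames per second.
#' @param window window length in seconds (default 2).
#' @param maxlag maximum propagation lag in seconds (default 0.5).
#' @param min_cor minimum peak mean correlation for directed locomotion.
#' @param quiescence_threshold mean |angle change| per frame, radians.
#' @return factor vector (one state per frame) with levels
#'   \code{forward, backward, dwell, quiescent}.
#' @export
classify_locomotion <- function(angle_series, fps, window = 2,
                                maxlag = 0.5, min_cor = 0.5,
                                quiescence_threshold = 0.005) {
  stopifnot(is.matrix(angle_series), ncol(angle_series) == 18)
  T_ <- nrow(angle_series)
  W <- max(5L, round(window * fps))
  if (T_ < W) stop("series shorter than the analysis window")
  L <- max(1L, round(maxlag * fps))
  half <- W %/% 2L

  dmean <- c(0, rowMeans(abs(diff(angle_series))))
  states <- character(T_)
  lags <- (-L):L

  score_window <- function(idx) {
    a <- angle_series[idx, , drop = FALSE]
    n <- nrow(a)
    best <- -Inf; best_lag <- 0L
    for (tau in lags) {
      if (tau >= 0) { i1 <- 1:(n - tau); i2 <- (1 + tau):n }
      else { i1 <- (1 - tau):n; i2 <- 1:(n + tau) }
      if (length(i1) < 4) next
      cc <- vapply(1:17, function(j) {
        x <- a[i1, j]; y <- a[i2, j + 1]
        if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
        cor(x, y)
      }, 0)
      m <- mean(cc, na.rm = TRUE)
      if (is.finite(m) && m > best) { best <- m; best_lag <- tau }
    }
    list(best = best, lag = best_lag)
  }

  for (t in seq_len(T_)) {
    lo <- clamp(t - half, 1L, T_ - W + 1L)
    idx <- lo:(lo + W - 1L)
    if (mean(dmean[idx]) < quiescence_threshold) {
      states[t] <- "quiescent"
      next
    }
    sc <- score_window(idx)
    states[t] <- if (!is.finite(sc$best) || sc$best < min_cor || sc$lag == 0)
      "dwell"
    else if (sc$lag < 0) "forward" else "backward"
  }
  factor(states, levels = c("forward", "backward", "dwell", "quiescent"))
}

#' Eigenworm decomposition of posture ensembles
#'
#' Mean-centered principal component analysis of 18-angle posture vectors.
#' The modes ("eigenworms") are orthonormal; the per-frame amplitudes are
#' the projections onto them; explained-variance fractions are
#' non-increasing and sum to one. Reconstruction from all modes is exact.
#'
#' @param angle_matrix numeric matrix (frames x 18) of posture angles (at
#'   least 19 frames).
#' @return An object of class \code{worm_eigen}: list with \code{modes}
#'   (18 x 18, columns are eigenworms), \code{amplitudes} (frames x 18),
#'   \code{center} and \code{explained_variance}.
#' @export
eigenworms <- function(angle_matrix) {
  stopifnot(is.matrix(angle_matrix), ncol(angle_matrix) == 18)
  if (nrow(angle_matrix) < 19)
    stop("need at least 19 frames for a full decomposition")
  pc <- prcomp(angle_matrix, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(modes = pc$rotation,
                 amplitudes = pc$x,
                 center = pc$center,
                 explained_variance = ev / sum(ev)),
            class = "worm_eigen")
}

#' @export
print.worm_eigen <- function(x, ...) {
  cum <- cumsum(x$explained_variance)
  cat(sprintf("worm_eigen: %d frames, 18 modes\n", nrow(x$amplitudes)))
  cat(sprintf("  leading modes explain: %s\n",
              paste(sprintf("%.1f%%", 100 * cum[1:6]), collapse = ", ")))
  invisible(x)
}

#' @export
predict.worm_eigen <- function(object, newdata, ...) {
  if (inherits(newdata, "worm_angles")) newdata <- matrix(newdata$angles, 1)
  if (is.vector(newdata)) newdata <- matrix(newdata, 1)
  sweep(newdata, 2, object$center) %*% object$modes
}

#' @export
plot.worm_eigen <- function(x, n_modes = 4, ...) {
  opar <- par(mfrow = c(1, 2)); on.exit(par(opar))
  plot(100 * cumsum(x$explained_variance), type = "b",
       xlab = "mode", ylab = "cumulative variance explained (%)", ...)
  graphics::matplot(x$modes[, seq_len(n_modes)], type = "l", lty = 1,
                    xlab = "angle index (tail to head)", ylab = "mode loading")
  invisible(x)
}

#' Classify spooled postures from leading-mode amplitudes
#'
#' A spool is any posture whose product of the two leading eigenworm
#' amplitudes exceeds unity (anterior and posterior curvature sufficiently
#' high and in the same direction); products above 4 mark severe spools,
#' and products below -4 figure-8-like postures where the two curvatures
#' have opposite signs.
#'
#' @param a1,a2 numeric vectors of leading-mode amplitudes.
#' @return factor with levels
#'   \code{neither, spool, severe_spool, figure8}.
#' @export
classify_spool <- function(a1, a2) {
  p <- a1 * a2
  out <- ifelse(p > 4, "severe_spool",
                ifelse(p > 1, "spool",
                       ifelse(p < -4, "figure8", "neither")))
  factor(out, levels = c("neither", "spool", "severe_spool", "figure8"))
}

#' Cluster postures in amplitude space
#'
#' K-means clustering of mode amplitudes with a redundancy of independent
#' restarts; the solution with the lowest total within-cluster sum of
#' squares is kept. Centroids are returned with population counts so that
#' the most populated clusters can be selected and reconstructed.
#'
#' @param amplitudes numeric matrix (frames x modes).
#' @param k number of clusters (default 50; 25 is typical for restricted
#'   spool sets).
#' @param redundancy number of restarts with distinct seeds (default 5).
#' @param seed base random seed.
#' @return list with \code{centroids}, \code{assignments}, \code{sizes},
#'   \code{inertia} and \code{k}.
#' @export
cluster_postures <- function(amplitudes, k = 50L, redundancy = 5L, seed = 1L) {
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) < k)
    stop("need at least k postures to form k clusters")
  # MacQueen updates converge monotonically on the near-duplicate posture
  # sets recordings produce; the degenerate k = n case uses Lloyd
  algo <- if (k >= nrow(amplitudes)) "Lloyd" else "MacQueen"
  best <- NULL
  for (r in seq_len(redundancy)) {
    km <- with_seed(seed + r, kmeans(amplitudes, centers = k, nstart = 1,
                                     iter.max = 500, algorithm = algo))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(centroids = best$centers,
       assignments = best$cluster,
       sizes = as.integer(best$size),
       inertia = best$tot.withinss,
       k = k)
}

#' Weibull fit of event durations
#'
#' Maximum-likelihood Weibull fit via the profile likelihood: for a given
#' shape the scale has the closed form \code{mean(x^shape)^(1/shape)}, and
#' the shape is found by 1-D optimization. Fixing \code{shape = 1} reduces
#' the fit to an exponential with scale equal to the sample mean.
#'
#' @param x positive durations.
#' @param shape optional fixed shape parameter.
#' @return list with \code{shape}, \code{scale} and \code{loglik}.
#' @export
fit_weibull <- function(x, shape = NULL) {
  stopifnot(length(x) >= 2, all(x > 0))
  prof_scale <- function(k) mean(x^k)^(1 / k)
  ll <- function(k) sum(stats::dweibull(x, shape = k, scale = prof_scale(k),
                                        log = TRUE))
  if (is.null(shape)) {
    opt <- optimize(function(lk) ll(exp(lk)), interval = log(c(0.05, 50)),
                    maximum = TRUE, tol = 1e-8)
    shape <- exp(opt$maximum)
  }
  scale <- prof_scale(shape)
  list(shape = shape, scale = scale, loglik = ll(shape))
}

#' Coil event statistics
#'
#' Extracts maximal runs of coil-positive frames per coil type, and fits
#' durations with a Weibull distribution to obtain the characteristic coil
#' duration (the fitted scale). Durations shorter than \code{min_frames}
#' frames are excluded from the fit (censoring at frame resolution); fits
#' are skipped with a flag when fewer than 5 events are available.
#'
#' @param annotations data frame or list with logical vectors
#'   \code{anterior} and \code{posterior} (one entry per frame).
#' @param fps frames per second.
#' @param min_frames minimum event length in frames to enter the fit.
#' @return list with \code{events} (data frame: type, start, end, duration),
#'   \code{frequency} (events per second, per type) and \code{fits} (per
#'   type: shape/scale or \code{fitted = FALSE}).
#' @export
coil_event_stats <- function(annotations, fps, min_frames = 2L) {
  types <- c("anterior", "posterior")
  T_ <- length(annotations$anterior)
  events <- do.call(rbind, lapply(types, function(tp) {
    flags <- as.logical(annotations[[tp]])
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (length(on) == 0) return(NULL)
    data.frame(type = tp, start = starts[on], end = ends[on],
               duration = r$lengths[on] / fps)
  }))
  if (is.null(events))
    events <- data.frame(type = character(), start = integer(),
                         end = integer(), duration = numeric())
  total_time <- T_ / fps
  frequency <- vapply(types, function(tp)
    sum(events$type == tp) / total_time, 0)
  fits <- lapply(types, function(tp) {
    d <- events$duration[events$type == tp]
    d <- d[d >= min_frames / fps]
    if (length(d) < 5) return(list(fitted = FALSE, n = length(d)))
    f <- fit_weibull(d)
    list(fitted = TRUE, n = length(d), shape = f$shape, scale = f$scale,
         characteristic_duration = f$scale)
  })
  names(fits) <- types
  list(events = events, frequency = frequency, fits = fits)
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end)
runs_of <- function(flags) {
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  data.frame(start = starts[on], end = ends[on])
}

#' Transition-aligned locomotion summaries
#'
#' Summarizes the relation between coiling and directed locomotion:
#' \describe{
#'   \item{aligned}{per-offset probabilities of each locomotion state in a
#'     window around coil-event entries and exits, per coil type, and
#'     around dwell-event entries and exits split by whether an anterior
#'     coil began shortly after the dwell onset.}
#'   \item{fraction_within}{the fraction of coil events that started within
#'     \code{window} seconds of the initiation of forward or backward
#'     locomotion.}
#'   \item{propensity}{the probability of each directed state during
#'     coiling, next to its baseline outside coiling.}
#' }
#'
#' @param states factor vector of per-frame locomotion states (levels as in
#'   [classify_locomotion]).
#' @param annotations per-frame coil flags (list or data frame with
#'   \code{anterior} and \code{posterior}).
#' @param fps frames per second.
#' @param window alignment half-window and initiation window, seconds
#'   (default 5).
#' @param split_window seconds after a dwell onset within which a coil must
#'   begin for the dwell event to count as coil-associated (default 2).
#' @return list with elements \code{aligned}, \code{fraction_within},
#'   \code{propensity} and \code{n_events}; empty inputs yield flagged
#'   empty summaries.
#' @export
transition_summaries <- function(states, annotations, fps, window = 5,
                                 split_window = 2) {
  states <- factor(states, levels = c("forward", "backward", "dwell",
                                      "quiescent"))
  T_ <- length(states)
  W <- round(window * fps)
  offsets <- (-W):W
  lv <- levels(states)

  align_at <- function(anchors) {
    if (length(anchors) == 0)
      return(matrix(NA_real_, length(offsets), length(lv),
                    dimnames = list(offsets, lv)))
    probs <- sapply(lv, function(s) {
      vapply(offsets, function(o) {
        at <- anchors + o
        at <- at[at >= 1 & at <= T_]
        if (length(at) == 0) return(NA_real_)
        mean(states[at] == s)
      }, 0)
    })
    rownames(probs) <- offsets
    probs
  }

  coil_any <- as.logical(annotations$anterior) | as.logical(annotations$posterior)
  aligned <- list()
  n_events <- list()
  for (tp in c("anterior", "posterior")) {
    ev <- runs_of(annotations[[tp]])
    n_events[[tp]] <- nrow(ev)
    aligned[[paste0(tp, "_entry")]] <- align_at(ev$start)
    aligned[[paste0(tp, "_exit")]] <- align_at(ev$end)
  }

  # dwell events split by whether anterior coiling follows the onset
  dw <- runs_of(states == "dwell")
  if (nrow(dw) > 0) {
    sw <- round(split_window * fps)
    coil_after <- vapply(seq_len(nrow(dw)), function(i) {
      idx <- dw$start[i]:min(T_, dw$start[i] + sw)
      any(annotations$anterior[idx])
    }, TRUE)
    aligned$dwell_entry_coil <- align_at(dw$start[coil_after])
    aligned$dwell_exit_coil <- align_at(dw$end[coil_after])
    aligned$dwell_entry_nocoil <- align_at(dw$start[!coil_after])
    aligned$dwell_exit_nocoil <- align_at(dw$end[!coil_after])
  }
  n_events$dwell <- nrow(dw)

  # fraction of coil events starting within `window` of a forward/backward
  # initiation
  init_frames <- which(diff(as.integer(states %in% c("forward", "backward"))) == 1) + 1L
  is_dir <- states %in% c("forward", "backward")
  if (length(is_dir) > 0 && is_dir[1]) init_frames <- c(1L, init_frames)
  coil_starts <- runs_of(coil_any)$start
  fraction_within <- if (length(coil_starts) == 0) NA_real_ else {
    mean(vapply(coil_starts, function(cs)
      any(init_frames >= cs - W & init_frames <= cs), TRUE))
  }

  propensity <- sapply(lv, function(s) {
    c(during_coil = if (any(coil_any)) mean(states[coil_any] == s) else NA_real_,
      baseline = if (any(!coil_any)) mean(states[!coil_any] == s) else NA_real_)
  })

  list(aligned = aligned, fraction_within = fraction_within,
       propensity = propensity, n_events = n_events,
       has_events = any(coil_any))
}
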