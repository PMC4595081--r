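# Coarse MAP detection of the midline on the coarse grid: a head-first beam
# search over admissible lattice curves under the feature data model and the
# squared-length prior.

#' Admissible extensions of a coarse instantiation
#'
#' Consecutive midline points are 8-neighbors on the coarse grid and the
#' direction may change by at most 45 degrees per step, so given the last
#' two points there are at most three positions for the next one. Points
#' already in the instantiation are excluded (the midline is self-avoiding),
#' and so are points 8-adjacent to any non-recent path point: the body has
#' nonzero width, so at quarter-worm-width grid resolution two distinct
#' stretches of midline can never occupy neighboring cells (even tightly
#' pressed body segments keep their midlines a full worm width, four cells,
#' apart). The last two path points are exempt so maximal-curvature turns
#' remain admissible.
#'
#' @param points integer matrix (n x 2, n >= 2) of coarse-grid coordinates.
#' @param grid_dim coarse grid dimensions \code{c(Hr, Hc)}.
#' @return Integer matrix (0-3 rows x 2) of candidate next points.
#' @export
admissible_extensions <- function(points, grid_dim) {
  n <- nrow(points)
  if (n < 2) stop("instantiation must have at least 2 points")
  last <- points[n, ]; prev <- points[n - 1, ]
  code <- dir_code(last[1] - prev[1], last[2] - prev[2])
  cand_codes <- (code + c(-1L, 0L, 1L)) %% 8L
  cand <- matrix(rep(last, each = 3), ncol = 2) + .dirs8[cand_codes + 1L, ]
  ok <- cand[, 1] >= 1 & cand[, 1] <= grid_dim[1] &
    cand[, 2] >= 1 & cand[, 2] <= grid_dim[2]
  if (any(ok) && n > 2) {
    older <- points[seq_len(n - 2L), , drop = FALSE]
    for (k in which(ok)) {
      cheb <- pmax(abs(older[, 1] - cand[k, 1]), abs(older[, 2] - cand[k, 2]))
      if (any(cheb <= 1L)) ok[k] <- FALSE
    }
  }
  cand[ok, , drop = FALSE]
}

#' Log length prior
#'
#' The unnormalized log prior on the number of coarse midline points,
#' \code{-A * (n - lambda)^2}.
#'
#' @param n number of points (>= 2).
#' @param params a \code{worm_config} (or any list with \code{A} and
#'   \code{lambda}).
#' @return log prior value.
#' @export
log_length_prior <- function(n, params) {
  stopifnot(n >= 2)
  -params$A * (n - params$lambda)^2
}

#' Beam-search tolerance DIFF
#'
#' \code{DIFF} is \code{alpha} times the difference in log-likelihood ratio
#' between a perfect additional point (matching feature present on the point
#' and both orthogonal neighbors) and a worst-case one (absent at all
#' three). Candidates within DIFF of the best posterior are retained.
#'
#' @param params a \code{worm_config}.
#' @return positive scalar.
#' @export
diff_value <- function(params) {
  with(params, alpha * ((log(p_high) + 2 * log(p_med) - 3 * log(p_low)) -
                          (log(1 - p_high) + 2 * log(1 - p_med) -
                             3 * log(1 - p_low))))
}

# orthogonal neighbor offsets for an orientation code
orth_offsets <- function(o) {
  switch(o + 1L,
         rbind(c(1L, 0L), c(-1L, 0L)),   # horizontal axis -> vertical orth
         rbind(c(1L, -1L), c(-1L, 1L)),  # 45 axis -> other diagonal
         rbind(c(0L, 1L), c(0L, -1L)),   # vertical axis -> horizontal orth
         rbind(c(1L, 1L), c(-1L, -1L)))
}

#' Log-likelihood-ratio increment for one added point
#'
#' The change in the data log-likelihood, relative to the all-background
#' model, from adding a point to a coarse instantiation: the feature type
#' parallel to the incoming direction contributes a
#' \code{p_high}-vs-\code{p_low} term at the point itself and
#' \code{p_med}-vs-\code{p_low} terms at its two orthogonal coarse
#' neighbors. All other feature types have background probability under
#' both models and cancel. Orthogonal neighbors outside the grid carry no
#' data and contribute zero.
#'
#' @param orientation orientation code 0..3 of the incoming direction.
#' @param point integer coarse coordinates (length 2) of the new point.
#' @param fmap logical feature array \code{Hr x Hc x 4} for the relevant
#'   stage (head or body), indexed by orientation code.
#' @param params a \code{worm_config}.
#' @return scalar log-likelihood-ratio increment.
#' @export
point_log_lr <- function(orientation, point, fmap, params) {
  dm <- dim(fmap)
  if (point[1] < 1 || point[1] > dm[1] || point[2] < 1 || point[2] > dm[2])
    stop("point outside the coarse grid")
  lr_hi_on <- log(params$p_high / params$p_low)
  lr_hi_off <- log((1 - params$p_high) / (1 - params$p_low))
  lr_md_on <- log(params$p_med / params$p_low)
  lr_md_off <- log((1 - params$p_med) / (1 - params$p_low))
  on <- fmap[point[1], point[2], orientation + 1L]
  total <- if (on) lr_hi_on else lr_hi_off
  for (k in 1:2) {
    q <- point + orth_offsets(orientation)[k, ]
    if (q[1] >= 1 && q[1] <= dm[1] && q[2] >= 1 && q[2] <= dm[2])
      total <- total + if (fmap[q[1], q[2], orientation + 1L])
        lr_md_on else lr_md_off
  }
  total
}

# ---- set-based incremental scoring ----------------------------------------
# The likelihood is a product over grid locations: points on the midline
# carry p_high terms, their orthogonal neighbors p_med terms, everything
# else background. Each location contributes once, so the incremental score
# of a new point only counts locations not already claimed by the
# instantiation (a location upgrades from neighbor to on-midline when the
# path passes through it). This is what stops the search from re-harvesting
# the same features by snaking alongside itself.

lr_terms <- function(params) {
  list(hi_on = log(params$p_high / params$p_low),
       hi_off = log((1 - params$p_high) / (1 - params$p_low)),
       md_on = log(params$p_med / params$p_low),
       md_off = log((1 - params$p_med) / (1 - params$p_low)))
}

# add one point to an instantiation's claimed-cell ledger; returns the
# updated candidate fields and the score increment
claim_point <- function(cells, contrib, role, orientation, point, fmap,
                        terms, Hr) {
  dm <- dim(fmap)
  delta <- 0
  key <- point[1] + (point[2] - 1L) * Hr
  on <- fmap[point[1], point[2], orientation + 1L]
  term <- if (on) terms$hi_on else terms$hi_off
  idx <- match(key, cells)
  if (is.na(idx)) {
    cells <- c(cells, key); contrib <- c(contrib, term); role <- c(role, 1L)
    delta <- delta + term
  } else if (role[idx] == 2L) {
    delta <- delta + term - contrib[idx]
    contrib[idx] <- term; role[idx] <- 1L
  }
  for (k in 1:2) {
    q <- point + orth_offsets(orientation)[k, ]
    if (q[1] < 1 || q[1] > dm[1] || q[2] < 1 || q[2] > dm[2]) next
    qkey <- q[1] + (q[2] - 1L) * Hr
    if (!is.na(match(qkey, cells))) next
    qterm <- if (fmap[q[1], q[2], orientation + 1L]) terms$md_on else terms$md_off
    cells <- c(cells, qkey); contrib <- c(contrib, qterm); role <- c(role, 2L)
    delta <- delta + qterm
  }
  list(cells = cells, contrib = contrib, role = role, delta = delta)
}

# build a scored seed instantiation from a start pair
seed_inst <- function(p1, p2, fmap, params, head_len = 2L) {
  terms <- lr_terms(params)
  Hr <- dim(fmap)[1]
  o <- dir_code(p2[1] - p1[1], p2[2] - p1[2]) %% 4L
  st <- claim_point(integer(0), numeric(0), integer(0), o, p1, fmap, terms, Hr)
  st2 <- claim_point(st$cells, st$contrib, st$role, o, p2, fmap, terms, Hr)
  inst <- new_coarse_inst(rbind(p1, p2), st$delta + st2$delta, head_len)
  inst$cells <- st2$cells; inst$contrib <- st2$contrib; inst$role <- st2$role
  inst
}

#' Find candidate head start pairs
#'
#' Clusters coarse cells with any head feature by 8-connectivity. For each
#' cluster (largest first) the cell with the most head-feature support is
#' the first start point, and each neighboring cell consistent with a fired
#' head orientation in the cluster yields a start pair. Retaining one
#' candidate set per cluster (rather than choosing the single most likely
#' one) lets the downstream search resolve false positive head detections.
#'
#' @param features a \code{worm_features} object.
#' @return List of clusters; each has \code{cells} (matrix of member cells),
#'   \code{size}, and \code{seeds} (list of 2 x 2 matrices, rows theta1 and
#'   theta2). Raises an error of class \code{worm_no_head} if no head
#'   feature fired anywhere.
#' @export
find_head_candidates <- function(features) {
  stopifnot(inherits(features, "worm_features"))
  hmap <- features$arrays[, , 1:4, drop = FALSE]
  support <- hmap[, , 1] + hmap[, , 2] + hmap[, , 3] + hmap[, , 4]
  on <- which(support > 0, arr.ind = TRUE)
  if (nrow(on) == 0)
    stop(structure(class = c("worm_no_head", "error", "condition"),
                   list(message = "no head detected", call = sys.call(-1))))
  # 8-connected components over the head-positive cells
  Hr <- dim(support)[1]
  keys <- on[, 1] + (on[, 2] - 1L) * Hr
  comp <- integer(nrow(on)); names(keys) <- NULL
  key_set <- new.env(hash = TRUE)
  for (i in seq_along(keys)) assign(as.character(keys[i]), i, envir = key_set)
  cid <- 0L
  for (i in seq_along(keys)) {
    if (comp[i] > 0) next
    cid <- cid + 1L
    queue <- i; comp[i] <- cid
    while (length(queue) > 0) {
      j <- queue[[1]]; queue <- queue[-1]
      for (k in 0:7) {
        nb <- on[j, ] + .dirs8[k + 1L, ]
        nb_key <- as.character(nb[1] + (nb[2] - 1L) * Hr)
        idx <- key_set[[nb_key]]
        if (!is.null(idx) && comp[idx] == 0) {
          comp[idx] <- cid
          queue <- c(queue, idx)
        }
      }
    }
  }
  clusters <- lapply(seq_len(cid), function(ci) {
    cells <- on[comp == ci, , drop = FALSE]
    sup <- support[cells]
    seed_cell <- cells[order(-sup, cells[, 1], cells[, 2])[1], ]
    # orientations fired anywhere in the cluster
    fired_o <- which(vapply(1:4, function(s)
      any(hmap[, , s][cells]), TRUE)) - 1L
    dirs <- sort(unique(c(fired_o, fired_o + 4L)))
    seeds <- list()
    for (d in dirs) {
      p2 <- seed_cell + .dirs8[d + 1L, ]
      if (p2[1] >= 1 && p2[1] <= dim(support)[1] &&
          p2[2] >= 1 && p2[2] <= dim(support)[2])
        seeds[[length(seeds) + 1]] <- rbind(seed_cell, p2)
    }
    list(cells = cells, size = nrow(cells), seeds = seeds)
  })
  clusters <- clusters[vapply(clusters, function(cl) length(cl$seeds) > 0, TRUE)]
  if (length(clusters) == 0)
    stop(structure(class = c("worm_no_head", "error", "condition"),
                   list(message = "no head detected", call = sys.call(-1))))
  clusters[order(-vapply(clusters, `[[`, 0L, "size"))]
}

new_coarse_inst <- function(points, llr, head_len = nrow(points)) {
  list(points = points, llr = llr, head_len = head_len)
}

inst_posterior <- function(inst, params) {
  inst$llr + log_length_prior(nrow(inst$points), params)
}

#' Beam search for the MAP coarse instantiation
#'
#' Grows instantiations one point at a time from the given seeds, keeping
#' track of multiple candidates: after each extension round, candidates
#' whose log posterior falls below the running best minus \code{DIFF} are
#' dropped, and of several candidates sharing an endpoint only the best
#' (earliest-created on ties) is retained. The search stops once the best
#' posterior has not improved for a stage-specific number of consecutive
#' iterations (2 for the head search, 3 for the body search), which lets it
#' pass through regions with missing features. The head stage scores against
#' head features only; the body stage against body and (by default)
#' double-body features.
#'
#' @param seeds list of instantiations (as returned internally; each a list
#'   with \code{points}, \code{llr}, \code{head_len}).
#' @param fmap logical \code{Hr x Hc x 4} stage feature array.
#' @param params a \code{worm_config}.
#' @param stage \code{"head"} or \code{"body"}.
#' @param max_len hard cap on the number of points (default
#'   \code{2 * lambda + 8}).
#' @param diff_override optional beam tolerance overriding [diff_value]
#'   (e.g. \code{Inf} for an exhaustive beam on small grids).
#' @return The best instantiation found: list with \code{points},
#'   \code{llr}, \code{head_len} and \code{log_post}.
#' @export
beam_search <- function(seeds, fmap, params, stage = c("body", "head"),
                        max_len = NULL, diff_override = NULL) {
  stage <- match.arg(stage)
  stop_n <- if (stage == "head") params$head_stop else params$body_stop
  DIFF <- if (is.null(diff_override)) diff_value(params) else diff_override
  if (is.null(max_len)) max_len <- ceiling(2 * params$lambda) + 8L
  seeds <- lapply(seeds, function(sd) {
    sd$points <- matrix(as.integer(sd$points), ncol = 2)
    sd$cells <- as.integer(sd$cells)
    sd$role <- as.integer(sd$role)
    sd$head_len <- as.integer(sd$head_len)
    sd
  })
  res <- beam_search_cpp(seeds, as.logical(fmap), dim(fmap),
                         params$p_high, params$p_med, params$p_low,
                         params$A, params$lambda, stage == "body",
                         as.integer(stop_n),
                         if (is.finite(DIFF)) DIFF else 1e300,
                         as.integer(max_len))
  best <- new_coarse_inst(res$points, res$llr, res$head_len)
  best$cells <- res$cells; best$contrib <- res$contrib; best$role <- res$role
  best$log_post <- res$log_post
  best
}

#' Coarse detection of the full midline
#'
#' Runs edge extraction, feature detection, head-candidate clustering, a
#' head beam search per cluster, and body beam searches continuing from
#' both ends of each detected head sub-instantiation. The full
#' instantiation with the highest posterior is the solution; its points are
#' ordered head-tip first and its \code{head_len} records the length of the
#' winning head sub-instantiation.
#'
#' @param image numeric intensity matrix.
#' @param params a \code{worm_config}.
#' @param masks optional precomputed mask list.
#' @param features optional precomputed \code{worm_features} (skips edge and
#'   feature extraction).
#' @return An object of class \code{worm_coarse}: list with \code{points}
#'   (n x 2 coarse coordinates, head first), \code{head_len},
#'   \code{log_post}, \code{head_cluster} (index of the winning cluster),
#'   \code{n_clusters} and \code{status} (\code{"ok"} or
#'   \code{"low_confidence"} for the body-only fallback).
#' @export
detect_coarse <- function(image, params = worm_config(), masks = NULL,
                          features = NULL) {
  if (is.null(features)) {
    if (is.null(masks))
      masks <- build_masks(params$worm_width, params$feature_threshold_frac)
    edges <- detect_edges(image, params$edge_threshold)
    features <- detect_features(edges, masks, params$coarse_unit)
  }
  hmap <- features$arrays[, , 1:4, drop = FALSE]
  bmap <- features$arrays[, , 5:8, drop = FALSE]
  if (isTRUE(params$use_double_body))
    bmap <- bmap | features$arrays[, , 9:12, drop = FALSE]

  clusters <- tryCatch(find_head_candidates(features),
                       worm_no_head = function(e) NULL)
  status <- "ok"
  if (is.null(clusters)) {
    # fallback: body-only search seeded at the strongest body-feature cell
    bsup <- bmap[, , 1] + bmap[, , 2] + bmap[, , 3] + bmap[, , 4]
    if (all(bsup == 0))
      stop(structure(class = c("worm_no_head", "error", "condition"),
                     list(message = "no head detected and no body features",
                          call = sys.call())))
    cell <- which(bsup == max(bsup), arr.ind = TRUE)[1, ]
    seeds <- list()
    for (d in 0:7) {
      p2 <- cell + .dirs8[d + 1L, ]
      if (p2[1] >= 1 && p2[1] <= dim(bsup)[1] &&
          p2[2] >= 1 && p2[2] <= dim(bsup)[2])
        seeds[[length(seeds) + 1]] <- seed_inst(cell, p2, bmap, params)
    }
    clusters <- list(list(cells = matrix(cell, 1), size = 1L,
                          seeds_prebuilt = seeds))
    status <- "low_confidence"
  }
  if (!isTRUE(params$multi_head) && length(clusters) > 1)
    clusters <- clusters[1]

  best <- NULL
  best_cluster <- NA_integer_
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    if (!is.null(cl$seeds_prebuilt)) {
      head_inst <- beam_search(cl$seeds_prebuilt, bmap, params, stage = "body")
    } else {
      seeds <- lapply(cl$seeds, function(sp)
        seed_inst(sp[1, ], sp[2, ], hmap, params))
      head_inst <- beam_search(seeds, hmap, params, stage = "head")
      head_inst$head_len <- nrow(head_inst$points)
    }
    # continue the body from either end of the head sub-instantiation; the
    # claimed-cell ledger travels with it so the body search cannot
    # re-harvest head-stage locations
    reversed <- head_inst
    reversed$points <- head_inst$points[nrow(head_inst$points):1, , drop = FALSE]
    starts <- list(head_inst, reversed)
    for (st in starts) {
      full <- beam_search(list(st), bmap, params, stage = "body")
      if (is.null(best) || full$log_post > best$log_post) {
        best <- full
        best_cluster <- ci
      }
    }
  }
  # the body search only ever extends the tail-ward end; finish by letting
  # the head end grow too (the head beam used head features alone and stops
  # short of the tip, where body features still carry signal)
  rev_best <- best
  rev_best$points <- best$points[nrow(best$points):1, , drop = FALSE]
  polished <- beam_search(list(rev_best), bmap, params, stage = "body")
  if (polished$log_post > best$log_post) {
    polished$points <- polished$points[nrow(polished$points):1, , drop = FALSE]
    best <- polished
  }
  # order points head-tip first: the search extends the tail-ward end, so
  # the head occupies the first head_len points already
  structure(list(points = best$points, head_len = best$head_len,
                 log_post = best$log_post, head_cluster = best_cluster,
                 n_clusters = length(clusters), status = status,
                 coarse_unit = features$coarse_unit,
                 grid_dim = features$dim),
            class = "worm_coarse")
}

#' @export
print.worm_coarse <- function(x, ...) {
  cat(sprintf(
    "worm_coarse: %d points (head sub-instantiation %d), log-posterior %.2f\n",
    nrow(x$points), x$head_len, x$log_post))
  cat(sprintf("  head cluster %d of %d, status: %s\n",
              x$head_cluster, x$n_clusters, x$status))
  invisible(x)
}

# check the hard constraints on a coarse instantiation; used by tests and
# assertions: 8-connected steps, turns of at most 45 degrees, no repeats
coarse_inst_valid <- function(points) {
  n <- nrow(points)
  if (n < 2) return(FALSE)
  steps <- diff(points)
  if (any(abs(steps) > 1) || any(steps[, 1] == 0 & steps[, 2] == 0))
    return(FALSE)
  codes <- vapply(seq_len(n - 1), function(i)
    dir_code(steps[i, 1], steps[i, 2]), 0L)
  if (n > 2 && any(dir_circ_dist(codes[-1], codes[-(n - 1)]) > 1))
    return(FALSE)
  keys <- points[, 1] * 1e6 + points[, 2]
  !anyDuplicated(keys)
}
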