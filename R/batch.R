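# Batch orchestration: per-frame detection over file sets or in-memory
# scenes (embarrassingly parallel), JSON-lines records, analytics tables and
# benchmark evaluation against ground truth.

detection_record <- function(frame_id, det = NULL, error = NULL) {
  if (!is.null(error))
    return(list(frame = frame_id, status = "error", message = error))
  list(frame = frame_id,
       status = det$status,
       length = det$length,
       head = as.numeric(det$head),
       tail = as.numeric(det$tail),
       midline_r = as.numeric(det$midline[, 1]),
       midline_c = as.numeric(det$midline[, 2]),
       log_post_coarse = det$log_post_coarse,
       log_post_fine = det$log_post_fine)
}

#' Batch detection over frames
#'
#' Runs [detect_posture] independently on every input frame. Inputs are
#' either file paths (processed in filename order) or a list of intensity
#' matrices / \code{worm_scene} objects. Per-frame failures yield error
#' records and never abort the batch; output order is deterministic and
#' identical for any worker count (frames share no state).
#'
#' @param inputs character vector of paths, or list of matrices or
#'   \code{worm_scene} objects.
#' @param config a [worm_config].
#' @param workers parallel workers (forked; 1 = sequential).
#' @return list of detection records (class \code{worm_detections}).
#' @export
detect_frames <- function(inputs, config = worm_config(),
                          workers = config$workers) {
  if (is.character(inputs)) {
    inputs <- sort(inputs)
    ids <- basename(inputs)
    getter <- function(i) read_frame(inputs[[i]])
  } else {
    ids <- names(inputs)
    if (is.null(ids)) ids <- sprintf("frame_%04d", seq_along(inputs))
    getter <- function(i) {
      x <- inputs[[i]]
      if (inherits(x, "worm_scene")) x$image else x
    }
  }
  masks <- build_masks(config$worm_width, config$feature_threshold_frac)
  one <- function(i) {
    tryCatch({
      img <- getter(i)
      det <- detect_posture(img, config, masks = masks)
      detection_record(ids[[i]], det)
    }, error = function(e) detection_record(ids[[i]], error = conditionMessage(e)))
  }
  recs <- if (workers > 1)
    parallel::mclapply(seq_along(ids), one, mc.cores = workers)
  else lapply(seq_along(ids), one)
  structure(recs, class = "worm_detections")
}

#' @export
print.worm_detections <- function(x, ...) {
  st <- table(vapply(x, `[[`, "", "status"))
  cat(sprintf("worm_detections: %d frames\n", length(x)))
  print(st)
  invisible(x)
}

#' Read / write detection records as JSON lines
#'
#' One JSON object per line, streamable and order-preserving.
#'
#' @param records a \code{worm_detections} list.
#' @param path output file.
#' @export
write_detections_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname write_detections_jsonl
#' @export
read_detections_jsonl <- function(path) {
  lines <- readLines(path)
  structure(lapply(lines, function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE)),
    class = "worm_detections")
}

record_midline <- function(rec) cbind(rec$midline_r, rec$midline_c)

#' Posture analytics over a detection batch
#'
#' Computes the per-frame angle representation, coil annotations,
#' locomotion states (for time-ordered recordings), the eigenworm
#' decomposition with leading-mode amplitudes, coil-event statistics and
#' posture clusters. Stages without enough data are skipped with flags
#' rather than failing.
#'
#' @param records a \code{worm_detections} list (time-ordered for state and
#'   event analyses).
#' @param fps frames per second of the recording.
#' @param config a [worm_config].
#' @return list with \code{frames} (data frame), \code{events},
#'   \code{pca}, \code{clusters}, \code{summary} and \code{flags}.
#' @export
analyze_detections <- function(records, fps = 10, config = worm_config()) {
  ok <- vapply(records, function(r) r$status %in% c("ok", "low_confidence"),
               TRUE)
  flags <- character(0)
  if (!any(ok)) {
    warning("no usable detections")
    return(list(frames = data.frame(), events = NULL, pca = NULL,
                clusters = NULL, summary = list(n_frames = 0),
                flags = "empty_input"))
  }
  usable <- records[ok]
  mids <- lapply(usable, record_midline)
  angs <- t(vapply(mids, function(m) midline_angles(m)$angles, numeric(18)))
  coils <- lapply(mids, function(m)
    detect_coils(m, config$coil_fraction, config$coil_exclusion))
  frames <- data.frame(
    frame = vapply(usable, `[[`, "", "frame"),
    length = vapply(usable, `[[`, 0, "length"),
    anterior = vapply(coils, `[[`, TRUE, "anterior"),
    posterior = vapply(coils, `[[`, TRUE, "posterior"),
    posterior_angle = angs[, 1],
    total_turning = rowSums(angs))

  pca <- NULL; clusters <- NULL; events <- NULL; states <- NULL
  if (nrow(angs) >= 19) {
    pca <- eigenworms(angs)
    frames$a1 <- pca$amplitudes[, 1]
    frames$a2 <- pca$amplitudes[, 2]
    frames$spool_class <- classify_spool(frames$a1, frames$a2)
  } else flags <- c(flags, "pca_skipped")

  if (nrow(angs) >= max(5, round(config$loco_window * fps))) {
    states <- classify_locomotion(angs, fps, config$loco_window,
                                  config$loco_maxlag, config$loco_min_cor,
                                  config$quiescence_threshold)
    frames$state <- states
    events <- coil_event_stats(list(anterior = frames$anterior,
                                    posterior = frames$posterior), fps)
  } else flags <- c(flags, "events_skipped")

  if (!is.null(pca) && nrow(angs) >= config$kmeans_k) {
    clusters <- cluster_postures(pca$amplitudes[, 1:6, drop = FALSE],
                                 k = config$kmeans_k,
                                 redundancy = config$kmeans_redundancy,
                                 seed = config$seed)
  } else flags <- c(flags, "clustering_skipped")

  transitions <- if (!is.null(states))
    transition_summaries(states, list(anterior = frames$anterior,
                                      posterior = frames$posterior), fps)
  else NULL

  list(frames = frames, events = events, pca = pca, clusters = clusters,
       transitions = transitions,
       summary = list(n_frames = nrow(frames),
                      coil_fraction = mean(frames$anterior | frames$posterior)),
       flags = flags)
}

#' Evaluate detections against ground truth
#'
#' Per-frame success requires the detected midline arc length to lie within
#' 10\% of the ground-truth length and the symmetric Hausdorff distance
#' between detected and true midlines to stay below one worm width;
#' head-identity accuracy checks that the detected head lies closer to the
#' true head than to the true tail. Rates are aggregated overall and per
#' posture family.
#'
#' @param dataset output of [generate_dataset] (or a list with
#'   \code{scenes} and \code{manifest}).
#' @param records matching \code{worm_detections}.
#' @param config a [worm_config].
#' @return list with \code{per_frame} (data frame), \code{success_rate},
#'   \code{length_success_rate}, \code{head_accuracy} and
#'   \code{by_family}.
#' @export
evaluate_detections <- function(dataset, records, config = worm_config()) {
  n <- length(dataset$scenes)
  if (length(records) != n) stop("manifest and detections do not match")
  rows <- lapply(seq_len(n), function(i) {
    truth <- dataset$scenes[[i]]$truth
    rec <- records[[i]]
    if (!rec$status %in% c("ok", "low_confidence"))
      return(data.frame(frame = dataset$manifest$frame[i],
                        family = truth$family, detected = FALSE,
                        length_ok = FALSE, hausdorff = NA_real_,
                        success = FALSE, head_ok = FALSE))
    mid <- record_midline(rec)
    len_ratio <- rec$length / truth$length
    length_ok <- len_ratio >= 0.9 && len_ratio <= 1.1
    hd <- hausdorff_dist(resample_polyline(mid, 100L),
                         resample_polyline(truth$midline21, 100L))
    head_det <- c(rec$head[1], rec$head[2])
    d_head <- sqrt(sum((head_det - truth$head)^2))
    d_tail <- sqrt(sum((head_det - truth$tail)^2))
    data.frame(frame = dataset$manifest$frame[i], family = truth$family,
               detected = TRUE, length_ok = length_ok, hausdorff = hd,
               success = length_ok && hd < config$worm_width,
               head_ok = d_head < d_tail)
  })
  per_frame <- do.call(rbind, rows)
  by_family <- vapply(split(per_frame$success, per_frame$family), mean, 0)
  list(per_frame = per_frame,
       success_rate = mean(per_frame$success),
       length_success_rate = mean(per_frame$length_ok),
       head_accuracy = mean(per_frame$head_ok),
       by_family = by_family)
}
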