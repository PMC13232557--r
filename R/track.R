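#' Tracker parameters
#'
#' @param max_displacement_um maximum allowed distance (um) of a detection
#'   from its track's first-frame anchor (5 um by default).
#' @param require_full_length drop tracks missing any frame?
#' @param frame_count expected number of frames.
#' @param match_to match candidates against the `"anchor"` (first-frame
#'   position, the default displacement rule) or the `"previous"` frame's
#'   position (for comparison).
#' @return a `tracker_params` list.
#' @export
tracker_params <- function(max_displacement_um = 5.0,
                           require_full_length = TRUE,
                           frame_count = 5L,
                           match_to = c("anchor", "previous")) {
  if (max_displacement_um <= 0) stop("max_displacement_um must be positive")
  structure(list(max_displacement_um = max_displacement_um,
                 require_full_length = require_full_length,
                 frame_count = as.integer(frame_count),
                 match_to = match.arg(match_to)),
            class = "tracker_params")
}

#' Link per-frame detections into tracks
#'
#' Tracks are seeded from the first frame. In each later frame, candidate
#' (track, detection) pairs within the maximum displacement of the track's
#' first-frame anchor are assigned greedily in ascending distance order,
#' one-to-one; ties closer than 1e-9 um break on the lower detection index.
#' Unmatched detections start no new tracks. With `require_full_length`,
#' tracks missing any frame are dropped.
#'
#' @param per_frame_detections list of detection data frames, one per frame
#'   (already passed through [video_filter()]).
#' @param params a [tracker_params()].
#' @return list of tracks; each track is a list with `track_id`, `anchor_um`,
#'   `members` (data frame `frame`, `det_index`, centroid, `cls`),
#'   `class_sequence` and `dynamic`.
#' @export
link_tracks <- function(per_frame_detections, params = tracker_params()) {
  nfr <- length(per_frame_detections)
  if (nfr != params$frame_count)
    stop(sprintf("got %d frames, params expect %d", nfr, params$frame_count))
  f0 <- per_frame_detections[[1]]
  if (nrow(f0) == 0) return(list())
  tracks <- lapply(seq_len(nrow(f0)), function(i) {
    list(track_id = i,
         anchor_um = c(f0$centroid_x_um[i], f0$centroid_y_um[i]),
         members = data.frame(frame = 1L, det_index = i,
                              centroid_x_um = f0$centroid_x_um[i],
                              centroid_y_um = f0$centroid_y_um[i],
                              cls = f0$cls[i]))
  })
  for (fr in seq_len(nfr)[-1]) {
    det <- per_frame_detections[[fr]]
    if (nrow(det) == 0) next
    ref <- t(vapply(tracks, function(tr) {
      if (params$match_to == "anchor") tr$anchor_um
      else unlist(tr$members[nrow(tr$members), c("centroid_x_um", "centroid_y_um")],
                  use.names = FALSE)
    }, numeric(2)))
    # candidate pairs within the displacement rule
    dmat <- outer(ref[, 1], det$centroid_x_um, `-`)^2 +
      outer(ref[, 2], det$centroid_y_um, `-`)^2
    dmat <- sqrt(dmat)
    cand <- which(dmat <= params$max_displacement_um, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      dist <- dmat[cand]
      ord <- order(dist, cand[, 2])   # ascending distance, ties on det index
      used_tr <- logical(length(tracks)); used_det <- logical(nrow(det))
      for (k in ord) {
        ti <- cand[k, 1]; di <- cand[k, 2]
        if (used_tr[ti] || used_det[di]) next
        used_tr[ti] <- TRUE; used_det[di] <- TRUE
        tracks[[ti]]$members <- rbind(tracks[[ti]]$members, data.frame(
          frame = fr, det_index = di,
          centroid_x_um = det$centroid_x_um[di],
          centroid_y_um = det$centroid_y_um[di],
          cls = det$cls[di]))
      }
    }
  }
  if (params$require_full_length)
    tracks <- Filter(function(tr) nrow(tr$members) == nfr, tracks)
  lapply(tracks, function(tr) {
    tr$class_sequence <- tr$members$cls
    tr$dynamic <- classify_dynamics_seq(tr$class_sequence)
    tr
  })
}

classify_dynamics_seq <- function(cls) {
  cls <- cls[!is.na(cls)]
  any(cls == 1L) && any(cls == 2L)
}

#' Call static versus dynamic behavior for a track
#'
#' A track is dynamic when its class sequence contains both class 1
#' (reporter off the membrane) and class 2 (reporter on the membrane) --
#' a class change across the time lapse reveals a dynamic event.
#'
#' @param track a track from [link_tracks()], or a bare class sequence.
#' @return `"dynamic"` or `"static"`.
#' @export
classify_dynamics <- function(track) {
  cls <- if (is.list(track)) track$class_sequence else track
  if (length(cls) == 0) stop("empty class sequence")
  if (classify_dynamics_seq(cls)) "dynamic" else "static"
}

#' Select photostimulation targets
#'
#' In `center_only` policy, returns at most one target per FOV: the
#' qualifying object nearest the FOV center, within radius `rho_um`. In
#' `anywhere` policy all qualifying objects are returned. Qualifying objects
#' are dynamic tracks (video mode) or, for detection input, class-2 or all
#' threshold-passing detections depending on `qualify`.
#'
#' @param x a list of tracks from [link_tracks()] or a detection data frame.
#' @param policy `"center_only"` or `"anywhere"`.
#' @param fov_um FOV side (um); the center is at `fov_um/2`.
#' @param rho_um center-policy capture radius (um).
#' @param qualify for detection input: `"all"` (threshold-passing, intensity
#'   selection) or `"class2"` (membrane-localized reporter).
#' @return data frame of stimulation coordinates `x_um`, `y_um` with a
#'   `reason` column and the source index.
#' @export
select_targets <- function(x, policy = c("center_only", "anywhere"),
                           fov_um = 128, rho_um = 20,
                           qualify = c("all", "class2")) {
  policy <- match.arg(policy)
  qualify <- match.arg(qualify)
  if (is.data.frame(x)) {
    q <- if (qualify == "class2") which(!is.na(x$cls) & x$cls == 2L)
         else seq_len(nrow(x))
    pts <- data.frame(x_um = x$centroid_x_um[q], y_um = x$centroid_y_um[q],
                      source = q,
                      reason = rep(if (qualify == "class2") "class2" else "threshold",
                                   length(q)))
  } else {
    q <- which(vapply(x, function(tr) isTRUE(tr$dynamic), logical(1)))
    pts <- data.frame(
      x_um = vapply(x[q], function(tr) tr$anchor_um[1], 0),
      y_um = vapply(x[q], function(tr) tr$anchor_um[2], 0),
      source = q,
      reason = rep("dynamic", length(q)))
  }
  if (nrow(pts) == 0) return(pts)
  if (policy == "center_only") {
    ctr <- fov_um / 2
    d <- sqrt((pts$x_um - ctr)^2 + (pts$y_um - ctr)^2)
    ok <- which(d <= rho_um)
    if (length(ok) == 0) return(pts[0, , drop = FALSE])
    pts <- pts[ok[which.min(d[ok])], , drop = FALSE]
  }
  rownames(pts) <- NULL
  pts
}

#' Write tracks as CSV and a JSON summary
#'
#' @param tracks list of tracks from [link_tracks()].
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, the flat track table.
#' @export
write_tracks <- function(tracks, csv_path = NULL, json_path = NULL) {
  flat <- do.call(rbind, lapply(tracks, function(tr)
    cbind(track_id = tr$track_id, tr$members)))
  if (is.null(flat)) flat <- data.frame(track_id = integer(0))
  if (!is.null(csv_path)) write.csv(flat, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- lapply(tracks, function(tr)
      list(track_id = tr$track_id, class_sequence = tr$class_sequence,
           dynamic = tr$dynamic))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(flat)
}
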