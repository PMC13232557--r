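#' Detection parameters
#'
#' Parameters of the threshold-based liposome detector and of the
#' membrane-vs-lumen localization classifier: a 3x3 mean convolution,
#' intensity thresholding, size constraints of 3.5--20 um equivalent
#' diameter, circularity constraints of 0.3--1, and a ring-score threshold
#' for calling membrane localization.
#'
#' @param smooth_kernel side of the box smoothing kernel (px).
#' @param threshold_mode `"fixed"` (background median + 5 MAD, or
#'   `threshold_value` when given) or `"otsu"`.
#' @param threshold_value absolute threshold in counts (fixed mode only);
#'   `NULL` derives it from the image background.
#' @param min_diameter_um,max_diameter_um equivalent-diameter bounds (um).
#' @param circularity_range kept circularity interval.
#' @param ring_threshold ring-score value at or above which a detection is
#'   called class 2 (membrane-localized reporter).
#' @param detect_channel which channel the geometric detector thresholds:
#'   `"membrane"` (rings hole-filled to disks) or `"protein"` (reporter
#'   intensity selection).
#' @return a `detection_params` list.
#' @export
detection_params <- function(smooth_kernel = 3L,
                             threshold_mode = c("fixed", "otsu"),
                             threshold_value = NULL,
                             min_diameter_um = 3.5, max_diameter_um = 20,
                             circularity_range = c(0.3, 1.0),
                             ring_threshold = 1.5,
                             detect_channel = c("membrane", "protein")) {
  threshold_mode <- match.arg(threshold_mode)
  detect_channel <- match.arg(detect_channel)
  if (min_diameter_um >= max_diameter_um) stop("min diameter must be < max")
  if (circularity_range[1] < 0 || circularity_range[2] > 1)
    stop("circularity bounds must lie within [0, 1]")
  structure(list(smooth_kernel = as.integer(smooth_kernel),
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_diameter_um = min_diameter_um,
                 max_diameter_um = max_diameter_um,
                 circularity_range = circularity_range,
                 ring_threshold = ring_threshold,
                 detect_channel = detect_channel),
            class = "detection_params")
}

#' Circularity shape statistic
#'
#' `4 * pi * area / perimeter^2`, clipped to a maximum of 1 (discretized
#' contours can slightly underestimate the perimeter). 1 for a circle,
#' `pi/4` for a square.
#'
#' @param area_um2 region area (um^2).
#' @param perimeter_um region perimeter (um), must be positive.
#' @return circularity values in `[0, 1]`.
#' @export
circularity <- function(area_um2, perimeter_um) {
  if (any(perimeter_um <= 0)) stop("perimeter must be positive")
  pmin(1, 4 * pi * area_um2 / perimeter_um^2)
}

empty_detections <- function() {
  data.frame(x0 = integer(0), y0 = integer(0), x1 = integer(0), y1 = integer(0),
             centroid_x_um = numeric(0), centroid_y_um = numeric(0),
             area_um2 = numeric(0), perimeter_um = numeric(0),
             circularity = numeric(0), equiv_diameter_um = numeric(0),
             aspect_ratio = numeric(0), cls = integer(0),
             ring_score = numeric(0), confidence = numeric(0),
             skipped = logical(0))
}

#' Geometric liposome detection by thresholding
#'
#' 3x3 mean smoothing, intensity thresholding, connected-component
#' labeling, hole filling (membrane rings become disks), and per-component
#' morphometry; components outside the diameter or circularity bounds and
#' components touching the image border are removed. The perimeter is
#' measured on the component contour polygon.
#'
#' @param image single-channel image matrix (rows = y) with a `px_um`
#'   attribute, as produced by [render_frame()].
#' @param params a [detection_params()].
#' @return data frame of detections: half-open pixel bounding box
#'   `x0,y0,x1,y1` (0-based), intensity-weighted centroid (um), area (um^2),
#'   perimeter (um), circularity, equivalent diameter (um), aspect ratio
#'   (bbox width/height), plus empty classification columns.
#' @export
threshold_detect <- function(image, params = detection_params()) {
  px <- attr(image, "px_um")
  if (is.null(px)) stop("image must carry a px_um attribute")
  m <- t(unclass(image))                       # [x, y] for EBImage
  k <- matrix(1, params$smooth_kernel, params$smooth_kernel)
  sm <- EBImage::filter2(m, k / sum(k))
  thr <- switch(params$threshold_mode,
    fixed = if (!is.null(params$threshold_value)) params$threshold_value
            else {
              # noise-adaptive; a noise-free image (MAD exactly 0) is
              # thresholded at half its dynamic range instead
              med <- median(sm); madv <- mad(sm)
              spread <- max(sm) - med
              if (madv > 1e-6 * spread) med + 5 * madv
              else med + 0.5 * spread
            },
    otsu = {
      maxv <- max(sm)
      EBImage::otsu(EBImage::Image(sm / maxv), range = c(0, 1)) * maxv
    })
  mask <- sm > thr
  if (mean(mask) >= 0.99)
    stop("degenerate input: image saturated above threshold")
  if (!any(mask)) return(empty_detections())
  lab <- EBImage::fillHull(EBImage::bwlabel(mask))
  labs <- sort(unique(as.integer(lab[lab > 0])))
  contours <- EBImage::ocontour(lab)
  npx <- nrow(m)
  rows <- lapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)       # [x, y] 1-based
    area_px <- nrow(idx)
    x0 <- min(idx[, 1]) - 1L; x1 <- max(idx[, 1])  # half-open, 0-based
    y0 <- min(idx[, 2]) - 1L; y1 <- max(idx[, 2])
    if (x0 == 0L || y0 == 0L || x1 == npx || y1 == npx) return(NULL)  # border
    ct <- if (!is.null(names(contours)) && as.character(l) %in% names(contours))
      contours[[as.character(l)]] else contours[[l]]
    per_px <- if (!is.null(ct) && nrow(ct) > 1) {
      d <- sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), , drop = FALSE])^2))
      sum(d)
    } else 4  # single-pixel fallback
    w <- sm[idx]
    if (sum(w) <= 0) w <- rep(1, area_px)
    cx <- sum((idx[, 1] - 0.5) * w) / sum(w) * px
    cy <- sum((idx[, 2] - 0.5) * w) / sum(w) * px
    area <- area_px * px^2
    per <- per_px * px
    eq_d <- 2 * sqrt(area / pi)
    data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
               centroid_x_um = cx, centroid_y_um = cy,
               area_um2 = area, perimeter_um = per,
               circularity = circularity(area, per),
               equiv_diameter_um = eq_d,
               aspect_ratio = (x1 - x0) / (y1 - y0),
               cls = NA_integer_, ring_score = NA_real_,
               confidence = NA_real_, skipped = FALSE)
  })
  det <- do.call(rbind, rows)
  if (is.null(det)) return(empty_detections())
  keep <- det$equiv_diameter_um >= params$min_diameter_um &
    det$equiv_diameter_um <= params$max_diameter_um &
    det$circularity >= params$circularity_range[1] &
    det$circularity <= params$circularity_range[2]
  det <- det[keep, , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Classify membrane-vs-lumen reporter localization
#'
#' Computes the ring score `R`: mean background-subtracted reporter
#' intensity in the annulus `[0.75 r, 1.05 r]` around the detection centroid
#' divided by the same quantity in the central disk `[0, 0.6 r]`, with the
#' image median as background. Class 2 (reporter at least partly on the
#' membrane) is called when `R >= ring_threshold`, class 1 otherwise;
#' confidence is `plogis(2 * log(R / ring_threshold))`. When both annulus and
#' disk signals lie below three image MADs there is no localization
#' information and `R` defaults to 1 (class 1). Detections whose annulus
#' falls outside the image are flagged as skipped.
#'
#' @param membrane_img membrane-channel image (used only for geometry
#'   context; may be `NULL`).
#' @param protein_img reporter-channel image matrix with `px_um` attribute.
#' @param det one or more detection rows from [threshold_detect()].
#' @param params a [detection_params()].
#' @return `det` with `cls`, `ring_score`, `confidence`, `skipped` filled in.
#' @export
classify_localization <- function(membrane_img, protein_img, det,
                                  params = detection_params()) {
  if (nrow(det) == 0) return(det)
  px <- attr(protein_img, "px_um")
  img <- unclass(protein_img)                 # [row(y), col(x)]
  bg <- median(img)
  sig_floor <- 3 * mad(img)  # below this, no localization information
  npx_y <- nrow(img); npx_x <- ncol(img)
  eps <- 1e-9
  for (i in seq_len(nrow(det))) {
    r <- det$equiv_diameter_um[i] / 2
    cx <- det$centroid_x_um[i]; cy <- det$centroid_y_um[i]
    ext <- 1.05 * r
    c0 <- floor((cx - ext) / px) + 1L; c1 <- ceiling((cx + ext) / px)
    r0 <- floor((cy - ext) / px) + 1L; r1 <- ceiling((cy + ext) / px)
    if (c0 < 1L || r0 < 1L || c1 > npx_x || r1 > npx_y) {
      det$skipped[i] <- TRUE
      next
    }
    cols <- c0:c1; rows <- r0:r1
    xs <- (cols - 0.5) * px; ys <- (rows - 0.5) * px
    dist <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
    sub <- img[rows, cols]
    ann <- dist >= 0.75 * r & dist <= 1.05 * r
    disk <- dist <= 0.6 * r
    if (!any(ann) || !any(disk)) {
      det$skipped[i] <- TRUE
      next
    }
    ann_s <- mean(sub[ann]) - bg
    disk_s <- mean(sub[disk]) - bg
    R <- if (ann_s <= sig_floor && disk_s <= sig_floor) 1  # no signal to localize
         else if (disk_s <= eps) Inf
         else max(0, ann_s) / disk_s
    det$ring_score[i] <- R
    det$cls[i] <- if (R >= params$ring_threshold) 2L else 1L
    det$confidence[i] <- if (is.infinite(R)) 1
                         else if (R <= 0) 0
                         else plogis(2 * log(R / params$ring_threshold))
  }
  det
}

#' Filter detections for video tracking
#'
#' Keeps detections with a bounding-box aspect ratio in `[0.7, 1.3]` and an
#' area of at least 37 um^2 (elongated boxes are typically edge artifacts;
#' small liposomes drift out of focus between frames).
#'
#' @param dets detection data frame.
#' @param aspect_range kept aspect-ratio interval.
#' @param min_area_um2 minimum area (um^2).
#' @return the kept detections.
#' @export
video_filter <- function(dets, aspect_range = c(0.7, 1.3), min_area_um2 = 37) {
  keep <- dets$aspect_ratio >= aspect_range[1] &
    dets$aspect_ratio <= aspect_range[2] &
    dets$area_um2 >= min_area_um2
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect and classify liposomes in one frame pair
#'
#' Runs [threshold_detect()] on the configured detection channel and
#' [classify_localization()] on the reporter channel. Any detector that
#' returns the same columns (bbox, class, confidence) can substitute for
#' this one downstream.
#'
#' @param membrane_img,protein_img channel images from [render_frame()].
#' @param params a [detection_params()].
#' @return classified detection data frame.
#' @export
detect_frame <- function(membrane_img, protein_img,
                         params = detection_params()) {
  src <- if (params$detect_channel == "membrane") membrane_img else protein_img
  det <- threshold_detect(src, params)
  classify_localization(membrane_img, protein_img, det, params)
}

#' Write detections as CSV
#'
#' @param dets detection data frame (optionally with `fov`/`frame` columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(dets, path) {
  write.csv(dets, path, row.names = FALSE)
  invisible(path)
}

#' Write detections in YOLO-style normalized text format
#'
#' One line per detection: `class cx cy w h confidence`, with box center and
#' size normalized to the image side, for interoperability with learned
#' detectors.
#'
#' @param dets detection data frame.
#' @param path output file.
#' @param image_px image side in pixels.
#' @return `path`, invisibly.
#' @export
write_detections_yolo <- function(dets, path, image_px = 512L) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f %.4f",
                   ifelse(is.na(dets$cls), 0L, dets$cls),
                   (dets$x0 + dets$x1) / 2 / image_px,
                   (dets$y0 + dets$y1) / 2 / image_px,
                   (dets$x1 - dets$x0) / image_px,
                   (dets$y1 - dets$y0) / image_px,
                   ifelse(is.na(dets$confidence), 0, dets$confidence))
  writeLines(lines, path)
  invisible(path)
}
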