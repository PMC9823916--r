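#' Pipeline configuration
#'
#' Collects every tunable of the model-building and mapping pipeline in
#' one place. The defaults are the operating values of the method: 2 mm
#' ray-gap and depth-median windows, truncation thresholds 1 mm then
#' 0.5 mm, eyeball radius 12 mm, IoU consensus threshold 0.5.
#'
#' @param gap_max,norm_window triangulation filter thresholds, mm
#'   (see [filter_points()]).
#' @param r eyeball radius, mm.
#' @param fit a [robust_fit_config()].
#' @param points which rectangle points to triangulate (see
#'   [triangulate_pairs()]).
#' @param pair_interval pairing interval, seconds.
#' @param iou_min consensus IoU threshold.
#' @param n_consecutive consecutive disagreeing frames that invalidate the
#'   model.
#' @param validation_period run the RGB validation detector every this
#'   many frames.
#' @param min_points minimum filtered points required to fit.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gap_max = 2, norm_window = 2, r = 12,
                            fit = robust_fit_config(),
                            points = c("all", "center"),
                            pair_interval = 1,
                            iou_min = 0.5, n_consecutive = 10L,
                            validation_period = 10L,
                            min_points = 10L) {
  points <- match.arg(points)
  stopifnot(gap_max > 0, norm_window > 0, r > 0, pair_interval > 0,
            iou_min > 0, iou_min <= 1, n_consecutive >= 1,
            validation_period >= 1, min_points >= 4)
  structure(list(gap_max = gap_max, norm_window = norm_window, r = r,
                 fit = fit, points = points, pair_interval = pair_interval,
                 iou_min = iou_min, n_consecutive = as.integer(n_consecutive),
                 validation_period = as.integer(validation_period),
                 min_points = as.integer(min_points)),
            class = "pipeline_config")
}

#' Build a per-user eyeball model from stereo detections
#'
#' The full model-building flow: pair the IR and RGB detection streams by
#' timestamp, triangulate the paired rectangle points, filter outliers by
#' the ray-gap and depth-median rules, and fit the eyeball sphere with the
#' two-pass robust M-estimator.
#'
#' @param rig a [stereo_rig()].
#' @param ir_detections,rgb_detections detection data frames.
#' @param config a [pipeline_config()].
#' @return A list of class `eyeball_fit_report`: `model` (the fitted
#'   [eyeball_model()]), `n_pairs`, `counts` (per-filter-stage rows in /
#'   rows out), and `points` (the retained 3D points).
#' @export
build_eyeball <- function(rig, ir_detections, rgb_detections,
                          config = pipeline_config()) {
  pairs <- pair_detections(ir_detections, rgb_detections,
                           one_per_interval = config$pair_interval)
  tri <- triangulate_pairs(rig, pairs, points = config$points)
  kept <- filter_points(tri, gap_max = config$gap_max,
                        norm_window = config$norm_window)
  model <- fit_eyeball(kept, r = config$r, config = config$fit,
                       min_points = config$min_points)
  structure(list(model = model, n_pairs = NROW(pairs),
                 counts = attr(kept, "filter_counts"), points = kept),
            class = "eyeball_fit_report")
}

#' @export
print.eyeball_fit_report <- function(x, ...) {
  cat("Eyeball model fit\n")
  cat(sprintf("  %d frame pairs -> %d triangulated points\n",
              x$n_pairs, x$counts[["input"]]))
  cat(sprintf("  filtered: %d negative-depth, %d ray-gap, %d depth-median; %d kept\n",
              x$counts[["negative_depth"]], x$counts[["gap"]],
              x$counts[["depth_median"]], x$counts[["kept"]]))
  print(x$model)
  invisible(x)
}

#' Fixture pupil detector (noisy oracle)
#'
#' A pluggable stand-in for a trained pupil detector, for tests and demos:
#' it reads the exact label sidecar written next to each rendered image
#' and perturbs it with Gaussian pixel noise, missing a detection with
#' probability `miss_rate`. Real detectors plug in through the same
#' contract: a function of `(image_path, camera)` returning a one-row
#' detection data frame or `NULL`.
#'
#' @param noise_sigma pixel noise added to every reported coordinate.
#' @param miss_rate probability of returning no detection.
#' @param score reported confidence of emitted detections.
#' @return A detector function `(image_path, camera) -> detection | NULL`.
#' @export
make_fixture_detector <- function(noise_sigma = 0, miss_rate = 0, score = 1) {
  function(image_path, camera) {
    if (stats::runif(1) < miss_rate) return(NULL)
    lab <- jsonlite::read_json(sub("\\.[a-zA-Z]+$", ".json", image_path),
                               simplifyVector = TRUE)
    nz <- function(x) x + stats::rnorm(1, 0, noise_sigma)
    x1 <- nz(lab$x1); y1 <- nz(lab$y1); x2 <- nz(lab$x2); y2 <- nz(lab$y2)
    if (x1 >= x2 || y1 >= y2) return(NULL)
    detection_record(lab$timestamp, camera, x1, y1, x2, y2,
                     cx = min(max(nz(lab$cx), x1), x2),
                     cy = min(max(nz(lab$cy), y1), y2), score = score)
  }
}

#' External-command pupil detector
#'
#' Wraps a detector shipped outside R (e.g. a trained CNN) behind the
#' plug-in contract: the command is invoked with the image path and the
#' camera tag as arguments and must print either nothing (no detection)
#' or one line `timestamp,x1,y1,x2,y2,cx,cy,score` to stdout.
#'
#' @param command executable to run.
#' @return A detector function `(image_path, camera) -> detection | NULL`.
#' @export
make_command_detector <- function(command) {
  force(command)
  function(image_path, camera) {
    out <- suppressWarnings(system2(command, c(shQuote(image_path), camera),
                                    stdout = TRUE))
    out <- out[nzchar(out)]
    if (!length(out)) return(NULL)
    v <- as.numeric(strsplit(out[[1]], ",")[[1]])
    if (length(v) != 8L || anyNA(v)) {
      stop("detector command produced an unparseable line: ", out[[1]],
           call. = FALSE)
    }
    detection_record(v[1], camera, v[2], v[3], v[4], v[5],
                     cx = v[6], cy = v[7], score = v[8])
  }
}

#' Run a detector over images and collect accepted detections
#'
#' Applies the detector to every image and keeps only detections whose
#' confidence reaches `min_score` (default 0.9 — only high-confidence
#' bounding rectangles are accepted as the pupil boundary).
#'
#' @param detector a detector function (see [make_fixture_detector()]).
#' @param image_paths character vector of image files.
#' @param camera camera tag passed through to the detector.
#' @param min_score acceptance threshold on the detector score.
#' @return Detection data frame (possibly empty).
#' @export
run_detector <- function(detector, image_paths, camera, min_score = 0.9) {
  dets <- lapply(image_paths, detector, camera = camera)
  dets <- dets[!vapply(dets, is.null, logical(1))]
  out <- do.call(rbind, dets)
  if (is.null(out)) {
    out <- detection_record(0, camera, 0, 0, 1, 1)[0, ]
  }
  out <- out[out$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate a mapped session against ground truth
#'
#' Joins a simulated session's truth table with the mapping of its IR
#' detections through a fitted model, and computes the per-frame
#' evaluation metrics: angular gaze error (estimated vs true gaze
#' direction), pixel gaze error (mapped vs ground-truth RGB pupil
#' center), IoU of the mapped rectangle against the ground-truth RGB
#' rectangle, IoU of the RGB detector rectangle against ground truth, and
#' consensus between mapped and detector rectangles.
#'
#' @param session a `sim_session` (see [simulate_session()]).
#' @param model a fitted [eyeball_model()].
#' @param frames which frames (row indices of `session$truth`) to
#'   evaluate; defaults to all.
#' @param iou_min consensus threshold.
#' @return A data frame: one row per frame with the
#'   [evaluate_session()] input columns plus the raw per-frame values.
#' @export
evaluate_synthetic <- function(session, model, frames = NULL, iou_min = 0.5) {
  truth <- session$truth
  if (is.null(frames)) frames <- seq_len(nrow(truth))
  rig <- session$rig
  rows <- lapply(frames, function(i) {
    det_ir <- session$ir[i, ]
    det_rgb <- session$rgb[i, ]
    m <- map_point_ir_to_rgb(rig, model, c(det_ir$cx, det_ir$cy))
    mrect <- map_rect_ir_to_rgb(rig, model,
                                c(det_ir$x1, det_ir$y1, det_ir$x2, det_ir$y2))
    gt_rect <- as.numeric(truth[i, c("rx1", "ry1", "rx2", "ry2")])
    det_rect <- as.numeric(det_rgb[c("x1", "y1", "x2", "y2")])
    true_g <- as.numeric(truth[i, c("gx", "gy", "gz")])
    data.frame(
      frame = truth$frame[i], flag = truth$flag[i],
      ir_detected = TRUE, gt_present = TRUE,
      gaze_error_deg = angular_error(m$gaze$direction, true_g),
      gaze_error_px = sqrt((m$p_rgb[1] - truth$rgb_cx0[i])^2 +
                             (m$p_rgb[2] - truth$rgb_cy0[i])^2),
      iou_auto_gt = rect_iou(mrect, gt_rect),
      iou_dl_gt = rect_iou(det_rect, gt_rect),
      consensus = rect_iou(mrect, det_rect) >= iou_min,
      mx1 = mrect[1], my1 = mrect[2], mx2 = mrect[3], my2 = mrect[4],
      dx1 = det_rect[1], dy1 = det_rect[2], dx2 = det_rect[3],
      dy2 = det_rect[4])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
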