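#' Intersect a viewing ray with the eyeball sphere
#'
#' For a unit direction `v` from the ray origin `o`, solves
#' `||o + alpha v - C||^2 = r^2`, i.e.
#' `alpha^2 - 2 (v . (C - o)) alpha + (||C - o||^2 - r^2) = 0`.
#' With two real roots the smaller positive one is returned — the near
#' surface of the eyeball, facing the camera. A negative discriminant
#' (ray misses the sphere, typically from detector noise or model error)
#' is approximated by the real part of the conjugate roots,
#' `alpha = v . (C - o)`, and flagged so consumers can weight such frames.
#' The tangent case is two equal roots; it gets no separate branch.
#'
#' @param ray a `ray` (see [backproject()]); for gaze mapping the origin is
#'   the IR camera center at the world origin.
#' @param model an [eyeball_model()].
#' @return List: `point` (length-3, mm), `alpha` (mm along the ray) and
#'   `kind` (`"two_roots"` or `"approximated_complex"`).
#' @export
intersect_ray_sphere <- function(ray, model) {
  v <- ray$direction
  stopifnot(abs(sqrt(sum(v^2)) - 1) < 1e-9)
  w <- model$C - ray$origin
  b <- sum(v * w)                      # v . (C - o)
  cc <- sum(w^2) - model$r^2
  disc <- b^2 - cc
  if (disc >= 0) {
    s <- sqrt(disc)
    roots <- c(b - s, b + s)
    pos <- roots[roots > 0]
    if (!length(pos)) {
      stop("both intersection roots are negative: the sphere lies behind the ",
           "camera, which signals a broken eyeball model", call. = FALSE)
    }
    alpha <- min(pos)
    kind <- "two_roots"
  } else {
    alpha <- b
    if (alpha <= 0) {
      stop("closest approach lies behind the camera: broken eyeball model",
           call. = FALSE)
    }
    kind <- "approximated_complex"
  }
  list(point = ray$origin + alpha * v, alpha = alpha, kind = kind)
}

#' Map an IR pixel to the RGB image plane through the eyeball
#'
#' The point-to-point stereo transform at the heart of the pipeline:
#' back-project the IR pupil pixel, intersect the viewing ray with the
#' fitted eyeball sphere to recover the 3D pupil point `P_w`, then project
#' `P_w` into the RGB camera with the perspective matrix `M_rgb`. The 3D
#' gaze ray starts at the eyeball center and passes through `P_w` out to
#' the world (the optical-axis gaze proxy).
#'
#' @param rig a [stereo_rig()].
#' @param model an [eyeball_model()].
#' @param p_ir pixel `c(x, y)` in the IR image.
#' @return A list of class `mapping_result`: `p_rgb` (pixel), `P_w` (mm),
#'   `intersection_kind`, and `gaze` (list with `origin`, unit `direction`,
#'   `pupil_point`).
#' @export
map_point_ir_to_rgb <- function(rig, model, p_ir) {
  ray <- backproject(rig, p_ir, "ir")
  hit <- intersect_ray_sphere(ray, model)
  P_w <- hit$point
  p_rgb <- project(rig, P_w, "rgb")
  g <- P_w - model$C
  gaze <- list(origin = model$C, direction = g / sqrt(sum(g^2)),
               pupil_point = P_w)
  structure(list(p_rgb = p_rgb, P_w = P_w, intersection_kind = hit$kind,
                 gaze = gaze),
            class = "mapping_result")
}

#' Map an IR bounding rectangle to the RGB image plane
#'
#' Transforms the two defining corners (top-left and bottom-right)
#' independently with [map_point_ir_to_rgb()] and re-normalizes so the
#' output corners remain top-left/bottom-right. The mapped rectangle is
#' the corneal-image crop region in the RGB frame.
#'
#' @param rig a [stereo_rig()].
#' @param model an [eyeball_model()].
#' @param rect length-4 numeric `c(x1, y1, x2, y2)` in IR pixels.
#' @return Length-4 numeric `c(x1, y1, x2, y2)` in RGB pixels, with
#'   attribute `intersection_kinds` (the two corners' kinds).
#' @export
map_rect_ir_to_rgb <- function(rig, model, rect) {
  rect <- as.numeric(rect)
  stopifnot(length(rect) == 4L)
  tl <- map_point_ir_to_rgb(rig, model, rect[1:2])
  br <- map_point_ir_to_rgb(rig, model, rect[3:4])
  xs <- sort(c(tl$p_rgb[1], br$p_rgb[1]))
  ys <- sort(c(tl$p_rgb[2], br$p_rgb[2]))
  structure(c(xs[1], ys[1], xs[2], ys[2]),
            intersection_kinds = c(tl$intersection_kind, br$intersection_kind))
}

#' Validate the eyeball model against occasional RGB detections
#'
#' The model is built once per wearing; it silently degrades when the
#' headset shifts. Every so often the RGB detector runs and its rectangle
#' is compared (IoU) with the rectangle mapped from the IR side. The model
#' is declared invalid as soon as `n_consecutive` successive frames with a
#' detector rectangle all disagree (IoU < `iou_min`). Frames without a
#' detector rectangle neither break nor extend a disagreement run.
#'
#' @param frames data frame, time-ordered, with columns `mx1,my1,mx2,my2`
#'   (mapped rectangle) and `dx1,dy1,dx2,dy2` (detector rectangle, `NA`
#'   when the detector produced nothing).
#' @param iou_min consensus threshold (default 0.5).
#' @param n_consecutive number of successive disagreeing frames that
#'   invalidates the model.
#' @return `"valid"` or `"invalid"`, with attribute `first_invalid_frame`
#'   (row index ending the first fatal run, `NA` when valid).
#' @export
validate_model <- function(frames, iou_min = 0.5, n_consecutive = 10L) {
  run <- 0L
  for (i in seq_len(NROW(frames))) {
    if (is.na(frames$dx1[i])) next      # no detector output: run unchanged
    iou_i <- rect_iou(as.numeric(frames[i, c("mx1", "my1", "mx2", "my2")]),
                      as.numeric(frames[i, c("dx1", "dy1", "dx2", "dy2")]))
    run <- if (iou_i < iou_min) run + 1L else 0L
    if (run >= n_consecutive) {
      return(structure("invalid", first_invalid_frame = i))
    }
  }
  structure("valid", first_invalid_frame = NA_integer_)
}

#' Export self-supervised pupil labels
#'
#' While a user wears the device, every RGB frame in which the detector
#' fired yields a candidate label: the rectangle mapped from the IR
#' detection. A label is accepted exactly when the mapped and detected
#' rectangles agree with IoU >= `iou_min`; frames without detector output
#' produce no label (nothing to corroborate against). Accepted labels form
#' a training set for future RGB pupil detectors with no manual labeling.
#'
#' @param frames data frame as in [validate_model()], optionally with a
#'   `frame` id column.
#' @param iou_min acceptance threshold (default 0.5).
#' @return Data frame of class `self_labels`: `frame`, the mapped and
#'   detector rectangles, `iou` and `accepted`.
#' @export
export_self_labels <- function(frames, iou_min = 0.5) {
  has_det <- !is.na(frames$dx1)
  idx <- which(has_det)
  iou <- vapply(idx, function(i) {
    rect_iou(as.numeric(frames[i, c("mx1", "my1", "mx2", "my2")]),
             as.numeric(frames[i, c("dx1", "dy1", "dx2", "dy2")]))
  }, numeric(1))
  out <- data.frame(
    frame = if ("frame" %in% names(frames)) frames$frame[idx] else idx,
    mx1 = frames$mx1[idx], my1 = frames$my1[idx],
    mx2 = frames$mx2[idx], my2 = frames$my2[idx],
    dx1 = frames$dx1[idx], dy1 = frames$dy1[idx],
    dx2 = frames$dx2[idx], dy2 = frames$dy2[idx],
    iou = iou,
    accepted = iou >= iou_min
  )
  class(out) <- c("self_labels", class(out))
  out
}

#' Map a session of IR detections through a fitted model
#'
#' Runs [map_point_ir_to_rgb()] on the center and [map_rect_ir_to_rgb()]
#' on the rectangle of every IR detection.
#'
#' @param rig a [stereo_rig()].
#' @param model an [eyeball_model()].
#' @param ir_detections detection data frame for the IR camera.
#' @return Data frame with one row per detection: `timestamp`, mapped
#'   center `p_rgb_x,p_rgb_y`, pupil 3D point `Pw_x,Pw_y,Pw_z`, unit gaze
#'   direction `gx,gy,gz`, `intersection_kind`, and the mapped rectangle
#'   `mx1,my1,mx2,my2`.
#' @export
map_session <- function(rig, model, ir_detections) {
  n <- NROW(ir_detections)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    det <- ir_detections[i, ]
    m <- map_point_ir_to_rgb(rig, model, c(det$cx, det$cy))
    rect <- map_rect_ir_to_rgb(rig, model, c(det$x1, det$y1, det$x2, det$y2))
    rows[[i]] <- data.frame(
      timestamp = det$timestamp,
      p_rgb_x = m$p_rgb[1], p_rgb_y = m$p_rgb[2],
      Pw_x = m$P_w[1], Pw_y = m$P_w[2], Pw_z = m$P_w[3],
      gx = m$gaze$direction[1], gy = m$gaze$direction[2],
      gz = m$gaze$direction[3],
      intersection_kind = m$intersection_kind,
      mx1 = rect[1], my1 = rect[2], mx2 = rect[3], my2 = rect[4])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a mapped session as JSON lines
#'
#' One JSON object per frame:
#' `{"t", "p_ir", "p_rgb", "P_w", "gaze_dir", "intersection_kind"}`.
#'
#' @param mapped output of [map_session()].
#' @param ir_detections the IR detections that were mapped (for `p_ir`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mapping_jsonl <- function(mapped, ir_detections, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(NROW(mapped))) {
    rec <- list(
      t = mapped$timestamp[i],
      p_ir = c(ir_detections$cx[i], ir_detections$cy[i]),
      p_rgb = c(mapped$p_rgb_x[i], mapped$p_rgb_y[i]),
      P_w = c(mapped$Pw_x[i], mapped$Pw_y[i], mapped$Pw_z[i]),
      gaze_dir = c(mapped$gx[i], mapped$gy[i], mapped$gz[i]),
      intersection_kind = mapped$intersection_kind[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
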