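#' Rectangle intersection-over-union (Jaccard index)
#'
#' Area of overlap divided by area of union for two axis-aligned
#' rectangles given as `c(x1, y1, x2, y2)` with continuous coordinates.
#' Disjoint rectangles score 0; by convention a zero-area rectangle also
#' scores 0.
#'
#' @param a,b rectangles `c(x1, y1, x2, y2)`, `x1 < x2`, `y1 < y2`.
#' @return IoU in `[0, 1]`.
#' @export
rect_iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  area_a <- max(0, a[3] - a[1]) * max(0, a[4] - a[2])
  area_b <- max(0, b[3] - b[1]) * max(0, b[4] - b[2])
  if (area_a == 0 || area_b == 0) return(0)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

#' Angle between two gaze vectors, in degrees
#'
#' The gaze-direction error metric: the angle between two 3D vectors,
#' invariant to their scaling. The dot product is clamped to `[-1, 1]`
#' before `acos` to absorb rounding.
#'
#' @param g1,g2 non-zero length-3 vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angular_error <- function(g1, g2) {
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  n1 <- sqrt(sum(g1^2)); n2 <- sqrt(sum(g2^2))
  if (n1 == 0 || n2 == 0) stop("gaze vectors must be non-zero", call. = FALSE)
  d <- sum(g1 * g2) / (n1 * n2)
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Summarize one session of frame-pair evaluations
#'
#' A frame pair is a *valid test pair* when the IR pupil was detected and
#' an RGB ground-truth label exists; metrics are defined only on valid
#' pairs. Per-metric medians are taken over the valid pairs (the median
#' filters out outlier measurements); rates are computed over all frames:
#' the fraction with an IR detection, the fraction of valid pairs, and the
#' consensus fraction (mapped vs detector rectangle IoU above threshold)
#' among frames where the RGB detector fired.
#'
#' @param frames data frame with logical columns `ir_detected`,
#'   `gt_present`, `consensus` (`NA` when the RGB detector produced
#'   nothing) and numeric metric columns `gaze_error_deg`,
#'   `gaze_error_px`, `iou_auto_gt`, `iou_dl_gt` (may be `NA` on invalid
#'   frames).
#' @return A one-row data frame: `n_frames`, `n_valid`, median metrics
#'   (`NA` when no valid frames), `rate_ir_detected`, `rate_valid`,
#'   `rate_consensus` (fractions, not percentages).
#' @export
evaluate_session <- function(frames) {
  valid <- frames$ir_detected & frames$gt_present
  med <- function(col) {
    x <- frames[[col]][valid]
    x <- x[!is.na(x)]
    if (length(x)) stats::median(x) else NA_real_
  }
  n <- NROW(frames)
  with_det <- !is.na(frames$consensus)
  data.frame(
    n_frames = n,
    n_valid = sum(valid),
    gaze_error_deg = med("gaze_error_deg"),
    gaze_error_px = med("gaze_error_px"),
    iou_auto_gt = med("iou_auto_gt"),
    iou_dl_gt = med("iou_dl_gt"),
    rate_ir_detected = if (n) mean(frames$ir_detected) else 0,
    rate_valid = if (n) mean(valid) else 0,
    rate_consensus = if (any(with_det)) mean(frames$consensus[with_det]) else 0
  )
}

#' Cohort summary: median of participants' medians
#'
#' Aggregates per-session summaries across a cohort the way multi-user eye
#' tracking studies report accuracy: each participant is first reduced to
#' the median of their session values per metric, then the cohort value is
#' the median of those participant medians — so no single prolific or
#' poorly tracked participant dominates. The same reduction is repeated
#' within each session type (e.g. indoors / near windows / outdoors).
#'
#' @param sessions data frame with columns `participant`, `session_type`
#'   and the metric columns of [evaluate_session()].
#' @param metrics character vector of metric columns to aggregate.
#' @return A data frame with one row per scope (`"overall"` plus each
#'   session type), the cohort median of each metric, and `n_participants`.
#' @export
summarize_cohort <- function(sessions,
                             metrics = c("gaze_error_deg", "gaze_error_px",
                                         "iou_auto_gt", "iou_dl_gt",
                                         "rate_ir_detected", "rate_valid",
                                         "rate_consensus")) {
  stopifnot(NROW(sessions) >= 1L)
  metrics <- intersect(metrics, names(sessions))
  med_of_med <- function(df) {
    vapply(metrics, function(m) {
      per_part <- tapply(df[[m]], df$participant,
                         function(x) stats::median(x, na.rm = TRUE))
      stats::median(unlist(per_part), na.rm = TRUE)
    }, numeric(1))
  }
  scopes <- c("overall", sort(unique(as.character(sessions$session_type))))
  rows <- lapply(scopes, function(sc) {
    df <- if (sc == "overall") sessions else sessions[sessions$session_type == sc, ]
    vals <- med_of_med(df)
    cbind(data.frame(scope = sc,
                     n_participants = length(unique(df$participant))),
          as.data.frame(as.list(vals)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
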