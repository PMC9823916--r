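#' Pupil detection records
#'
#' A detection record is one time-stamped pupil bounding rectangle with its
#' center, in the pixel plane of one camera. Records are kept in a plain
#' data frame with columns `timestamp` (seconds), `camera` (`"ir"` or
#' `"rgb"`), `x1,y1` (top-left), `x2,y2` (bottom-right), `cx,cy` (center)
#' and `score` (detector confidence in `[0,1]`).
#'
#' @param timestamp seconds on a monotonic clock.
#' @param camera `"ir"` or `"rgb"`.
#' @param x1,y1,x2,y2 bounding rectangle corners, pixels; the top-left
#'   corner must be strictly above-left of the bottom-right one.
#' @param cx,cy rectangle/pupil center, pixels, inside the rectangle.
#' @param score detector confidence in `[0,1]`.
#' @return A one-row `data.frame` of class `detection_record` stackable
#'   with `rbind`.
#' @export
detection_record <- function(timestamp, camera, x1, y1, x2, y2,
                             cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                             score = 1) {
  camera <- match.arg(camera, c("ir", "rgb"))
  if (!(x1 < x2 && y1 < y2)) {
    stop("rectangle top-left must be strictly above-left of bottom-right",
         call. = FALSE)
  }
  if (cx < x1 || cx > x2 || cy < y1 || cy > y2) {
    stop("center must lie inside the rectangle", call. = FALSE)
  }
  if (score < 0 || score > 1) stop("score must be in [0,1]", call. = FALSE)
  df <- data.frame(timestamp = timestamp, camera = camera,
                   x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                   cx = cx, cy = cy, score = score)
  class(df) <- c("detection_record", class(df))
  df
}

#' Read / write detection records
#'
#' Detections travel as plain CSV with columns
#' `timestamp,camera,x1,y1,x2,y2,cx,cy,score` — the dialect both the
#' simulator writes and the pipeline reads.
#'
#' @param path CSV file path.
#' @return [read_detections()] returns the detection data frame;
#'   [write_detections()] returns `path` invisibly.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "camera", "x1", "y1", "x2", "y2", "cx", "cy", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("detections file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' @rdname read_detections
#' @param detections detection data frame.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair synchronized IR/RGB detections by timestamp
#'
#' The two eye cameras free-run, so frames are never exactly simultaneous.
#' Within every interval of `one_per_interval` seconds (default 1 s — one
#' usable pair per second is enough for model building) the single IR/RGB
#' couple with the closest timestamps is kept. Interval membership is by
#' `floor(timestamp / one_per_interval)` for both streams; ties on
#' `|dt|` are broken toward the earlier RGB frame, then the earlier IR
#' frame, so pairing is deterministic.
#'
#' @param ir_stream,rgb_stream detection data frames (see
#'   [detection_record()]), each time-sorted.
#' @param one_per_interval pairing interval in seconds.
#' @return A data frame with one row per retained pair: the IR columns
#'   prefixed `ir_`, the RGB columns prefixed `rgb_`, plus `dt` (the
#'   signed `rgb - ir` timestamp difference). Rows are time-sorted.
#' @export
pair_detections <- function(ir_stream, rgb_stream, one_per_interval = 1) {
  stopifnot(one_per_interval > 0)
  empty <- function() {
    cols <- c(paste0("ir_", names(ir_stream)), paste0("rgb_", names(rgb_stream)), "dt")
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  if (NROW(ir_stream) == 0L || NROW(rgb_stream) == 0L) return(empty())
  bin_ir <- floor(ir_stream$timestamp / one_per_interval)
  bin_rgb <- floor(rgb_stream$timestamp / one_per_interval)
  out <- lapply(sort(unique(bin_ir)), function(b) {
    i <- which(bin_ir == b)
    j <- which(bin_rgb == b)
    if (!length(j)) return(NULL)
    # exhaustive min |dt| over the interval's cross product
    dt <- outer(ir_stream$timestamp[i], rgb_stream$timestamp[j], "-")
    adt <- abs(dt)
    best <- which(adt == min(adt), arr.ind = TRUE)
    if (nrow(best) > 1L) {
      ord <- order(rgb_stream$timestamp[j][best[, 2]],
                   ir_stream$timestamp[i][best[, 1]])
      best <- best[ord, , drop = FALSE]
    }
    bi <- i[best[1, 1]]; bj <- j[best[1, 2]]
    row <- cbind(stats::setNames(ir_stream[bi, , drop = FALSE],
                                 paste0("ir_", names(ir_stream))),
                 stats::setNames(rgb_stream[bj, , drop = FALSE],
                                 paste0("rgb_", names(rgb_stream))))
    row$dt <- rgb_stream$timestamp[bj] - ir_stream$timestamp[bi]
    row
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty())
  out <- out[order(out$ir_timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Triangulate one IR/RGB pixel pair
#'
#' Back-projects both pixels and finds the pair of ray parameters
#' `(alpha_ir, alpha_rgb)` minimizing the distance between the two ray
#' points — the linear least-squares closest-approach solution of
#' `C_ir + alpha_ir * N - C_rgb - alpha_rgb * N' = 0`. The estimated 3D
#' pupil point `S` is the midpoint of the two closest points and `d` the
#' residual gap between them; for rays that truly intersect `d = 0` and `S`
#' is the intersection.
#'
#' @param rig a [stereo_rig()].
#' @param p_ir,p_rgb pixels `c(x, y)` in the IR and RGB image planes.
#' @return A list of class `triangulated_point`: `S` (mm, world frame), `d`
#'   (mm gap), `alpha_ir`, `alpha_rgb` (signed ray depths, mm; the ray
#'   directions are unit so these are also the ray-segment norms).
#' @export
triangulate_pair <- function(rig, p_ir, p_rgb) {
  ray_ir <- backproject(rig, p_ir, "ir")
  ray_rgb <- backproject(rig, p_rgb, "rgb")
  n1 <- ray_ir$direction; n2 <- ray_rgb$direction
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  if (sqrt(sum(cr^2)) < 1e-12) {
    stop("degenerate geometry: the two viewing rays are parallel", call. = FALSE)
  }
  A <- cbind(n1, -n2)
  b <- ray_rgb$origin - ray_ir$origin
  alpha <- as.numeric(qr.solve(A, b))   # least-squares for the 3x2 system
  P1 <- ray_ir$origin + alpha[1] * n1
  P2 <- ray_rgb$origin + alpha[2] * n2
  structure(list(S = (P1 + P2) / 2,
                 d = sqrt(sum((P1 - P2)^2)),
                 alpha_ir = alpha[1], alpha_rgb = alpha[2]),
            class = "triangulated_point")
}

#' Triangulate paired detections
#'
#' Applies [triangulate_pair()] to every paired frame. By default the
#' top-left corner, center and bottom-right corner of the bounding
#' rectangles are each triangulated as independent samples (all three lie
#' near the corneal surface and feed the sphere fit); `points = "center"`
#' restricts to the centers.
#'
#' @param rig a [stereo_rig()].
#' @param pairs output of [pair_detections()].
#' @param points `"all"` (top-left, center, bottom-right) or `"center"`.
#' @return A data frame with one row per triangulated sample: `pair` (row
#'   index into `pairs`), `part` (`"tl"`, `"c"` or `"br"`), `Sx,Sy,Sz`,
#'   `d`, `alpha_ir`, `alpha_rgb`.
#' @export
triangulate_pairs <- function(rig, pairs, points = c("all", "center")) {
  points <- match.arg(points)
  parts <- if (points == "all") c("tl", "c", "br") else "c"
  px <- list(tl = c("x1", "y1"), c = c("cx", "cy"), br = c("x2", "y2"))
  rows <- vector("list", NROW(pairs) * length(parts))
  k <- 0L
  for (i in seq_len(NROW(pairs))) {
    for (part in parts) {
      p_ir <- as.numeric(pairs[i, paste0("ir_", px[[part]])])
      p_rgb <- as.numeric(pairs[i, paste0("rgb_", px[[part]])])
      tp <- tryCatch(triangulate_pair(rig, p_ir, p_rgb), error = function(e) NULL)
      if (is.null(tp)) next
      k <- k + 1L
      rows[[k]] <- data.frame(pair = i, part = part,
                              Sx = tp$S[1], Sy = tp$S[2], Sz = tp$S[3],
                              d = tp$d, alpha_ir = tp$alpha_ir,
                              alpha_rgb = tp$alpha_rgb)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (is.null(out)) {
    out <- data.frame(pair = integer(), part = character(),
                      Sx = numeric(), Sy = numeric(), Sz = numeric(),
                      d = numeric(), alpha_ir = numeric(), alpha_rgb = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Filter triangulated pupil points
#'
#' Two rules remove pairs where either detector erred or the concurrent
#' capture failed: (1) the ray gap `d` must not exceed `gap_max` (2 mm) for
#' the rays to count as intersecting; (2) each point's ray depths must lie
#' within `norm_window` (2 mm) of the per-camera median ray depth.
#' Points with a negative ray depth in either camera (behind a camera —
#' geometrically impossible for an eye in front of the rig) are dropped
#' before the medians are taken. Input order is preserved.
#'
#' @param points data frame from [triangulate_pairs()] (needs columns `d`,
#'   `alpha_ir`, `alpha_rgb`).
#' @param gap_max maximum ray gap, mm.
#' @param norm_window half-width of the depth-median band, mm.
#' @return The retained subset, with attribute `filter_counts` recording
#'   how many rows each rule removed. Warns if everything is filtered out.
#' @export
filter_points <- function(points, gap_max = 2, norm_window = 2) {
  if (NROW(points) == 0L) stop("no triangulated points to filter", call. = FALSE)
  pos <- points$alpha_ir > 0 & points$alpha_rgb > 0
  kept <- points[pos, , drop = FALSE]
  gap_ok <- kept$d <= gap_max
  med_ir <- stats::median(kept$alpha_ir)
  med_rgb <- stats::median(kept$alpha_rgb)
  norm_ok <- abs(kept$alpha_ir - med_ir) <= norm_window &
    abs(kept$alpha_rgb - med_rgb) <= norm_window
  out <- kept[gap_ok & norm_ok, , drop = FALSE]
  attr(out, "filter_counts") <- c(
    input = NROW(points),
    negative_depth = sum(!pos),
    gap = sum(!gap_ok),
    depth_median = sum(gap_ok & !norm_ok),
    kept = NROW(out)
  )
  if (NROW(out) == 0L) {
    warning("all triangulated points were filtered out; the eyeball fit cannot proceed",
            call. = FALSE)
  }
  out
}
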