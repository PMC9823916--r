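#' Synthetic stereo eye-tracking session configuration
#'
#' Describes a simulated head-mounted rig and recording session with full
#' ground truth. The default geometry mimics a compact eye-camera mount:
#' both sensors 1280x960 px, the eyeball center about 30 mm in front of
#' the IR camera, a 20 mm stereo baseline with the RGB camera toed in to
#' aim at the eye, and one usable frame pair per second. Gaze directions
#' are drawn uniformly from a cone about the camera-facing direction
#' (25 degree half-angle, a natural free-viewing range).
#'
#' Failure modes of real capture are injected per frame: `outlier_rate`
#' frames replace one camera's detection with a uniform random in-image
#' rectangle (a detector failure), and `desync_rate` frames recompute one
#' camera's detection from a different gaze sample (a synchronization
#' failure — the two cameras caught different moments of a saccade).
#'
#' @param focal_px focal length, px (both cameras).
#' @param image_size `c(width, height)`, px.
#' @param baseline_mm distance of the RGB camera from the IR camera along
#'   +x, mm.
#' @param toe_in_deg RGB camera rotation toward the eye about the y axis,
#'   degrees; `NULL` aims the RGB camera at `eye_center`.
#' @param eye_center true eyeball center, mm, IR frame.
#' @param r eyeball radius, mm.
#' @param pupil_radius_mm pupil radius on the eyeball surface, mm; sets
#'   the bounding-rectangle scale.
#' @param n_frames frames (seconds) per session.
#' @param gaze_cone_half_angle_deg gaze cone half-angle, degrees.
#' @param pixel_noise_sigma detector noise sigma, px, applied
#'   independently to every detected coordinate.
#' @param outlier_rate,desync_rate per-frame corruption probabilities in
#'   `[0, 1]` (mutually exclusive per frame).
#' @param seed master seed; every random sub-stream derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(focal_px = 1000, image_size = c(1280, 960),
                       baseline_mm = 20, toe_in_deg = NULL,
                       eye_center = c(0, 0, 30), r = 12,
                       pupil_radius_mm = 2,
                       n_frames = 150, gaze_cone_half_angle_deg = 25,
                       pixel_noise_sigma = 1,
                       outlier_rate = 0, desync_rate = 0,
                       seed = 1L) {
  stopifnot(n_frames > 0, focal_px > 0, baseline_mm != 0, r > 0,
            pupil_radius_mm > 0, pupil_radius_mm < r,
            gaze_cone_half_angle_deg > 0, gaze_cone_half_angle_deg < 90,
            pixel_noise_sigma >= 0,
            outlier_rate >= 0, outlier_rate <= 1,
            desync_rate >= 0, desync_rate <= 1,
            outlier_rate + desync_rate <= 1)
  structure(list(focal_px = focal_px, image_size = as.numeric(image_size),
                 baseline_mm = baseline_mm, toe_in_deg = toe_in_deg,
                 eye_center = as.numeric(eye_center), r = r,
                 pupil_radius_mm = pupil_radius_mm,
                 n_frames = as.integer(n_frames),
                 gaze_cone_half_angle_deg = gaze_cone_half_angle_deg,
                 pixel_noise_sigma = pixel_noise_sigma,
                 outlier_rate = outlier_rate, desync_rate = desync_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the stereo rig described by a simulation config
#'
#' IR camera at the world origin looking along +z; RGB camera at
#' `(baseline_mm, 0, 0)`, rotated about the y axis by the toe-in angle so
#' it faces the eye.
#'
#' @param config a [sim_config()].
#' @return A [stereo_rig()].
#' @export
sim_rig <- function(config) {
  K <- matrix(c(config$focal_px, 0, config$image_size[1] / 2,
                0, config$focal_px, config$image_size[2] / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  cam <- camera_intrinsics(K, config$image_size[1], config$image_size[2])
  c0 <- c(config$baseline_mm, 0, 0)
  toe <- config$toe_in_deg
  if (is.null(toe)) {
    # aim at the eye center
    d <- config$eye_center - c0
    toe <- atan2(-d[1], d[3]) * 180 / pi
  }
  phi <- -toe * pi / 180
  # columns are the RGB camera axes in the world frame
  R_cam <- matrix(c(cos(phi), 0, sin(phi),
                    0, 1, 0,
                    -sin(phi), 0, cos(phi)), 3, 3, byrow = TRUE)
  R <- t(R_cam)
  T <- as.numeric(-R %*% c0)
  stereo_rig(ir = cam, rgb = cam, R = R, T = T)
}

# orthonormal tangent basis at unit direction g, e1 ~ image x, e2 ~ image y
tangent_basis <- function(g) {
  xhat <- c(1, 0, 0)
  e1 <- xhat - sum(xhat * g) * g
  if (sqrt(sum(e1^2)) < 1e-9) e1 <- c(0, 1, 0) - g[2] * g
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e1[2] * g[3] - e1[3] * g[2],
          e1[3] * g[1] - e1[1] * g[3],
          e1[1] * g[2] - e1[2] * g[1])   # cross(e1, g): ~ +y (down)
  list(e1 = e1, e2 = e2)
}

#' Simulate a stereo eye-tracking session
#'
#' Draws one gaze direction per frame from the configured cone, places the
#' true pupil center and its boundary extremes on the eyeball sphere,
#' projects them into both cameras, and corrupts the detections with
#' Gaussian pixel noise plus the configured outlier and desync failures.
#' The pupil bounding rectangle of a clean frame is the projection of the
#' 3D pupil boundary, so at zero noise its corners are exactly
#' stereo-consistent points on the eyeball surface.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_session`: `ir` and `rgb` detection data
#'   frames (the CSV dialect [read_detections()] uses), `truth` (one row
#'   per frame: timestamps, `flag`, true gaze direction `gx,gy,gz`, true
#'   pupil point `Px,Py,Pz`, and the noiseless RGB center
#'   `rgb_cx0,rgb_cy0` and rectangle `rx1,ry1,rx2,ry2` serving as ground
#'   truth labels), `model` (the ground-truth [eyeball_model()]), `rig`
#'   and `config`. Deterministic given `config$seed`.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rig <- sim_rig(config)
  C <- config$eye_center
  r <- config$r
  model <- eyeball_model(C, r)
  set.seed(config$seed)
  n <- config$n_frames
  # camera-facing base gaze direction: from the eye center toward the IR camera
  n0 <- -C / sqrt(sum(C^2))
  cone_cos <- cos(config$gaze_cone_half_angle_deg * pi / 180)
  draw_gaze <- function() {
    ct <- stats::runif(1, cone_cos, 1)
    ph <- stats::runif(1, 0, 2 * pi)
    st <- sqrt(1 - ct^2)
    tb <- tangent_basis(n0)
    d <- ct * n0 + st * (cos(ph) * tb$e1 + sin(ph) * tb$e2)
    d / sqrt(sum(d^2))
  }
  pupil_geometry <- function(g) {
    P <- C + r * g
    tb <- tangent_basis(g)
    s <- config$pupil_radius_mm / r
    unit <- function(v) v / sqrt(sum(v^2))
    tl <- C + r * unit(g + s * (-tb$e1 - tb$e2))
    br <- C + r * unit(g + s * (tb$e1 + tb$e2))
    list(P = P, tl = tl, br = br)
  }
  proj_det <- function(geo, camera, sigma) {
    ctr <- project(rig, geo$P, camera)
    tl <- project(rig, geo$tl, camera)
    br <- project(rig, geo$br, camera)
    noisy <- function(p) p + stats::rnorm(2, 0, sigma)
    if (sigma > 0) { ctr <- noisy(ctr); tl <- noisy(tl); br <- noisy(br) }
    x1 <- min(tl[1], br[1]); x2 <- max(tl[1], br[1])
    y1 <- min(tl[2], br[2]); y2 <- max(tl[2], br[2])
    c(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
      cx = min(max(ctr[1], x1), x2), cy = min(max(ctr[2], y1), y2))
  }
  random_rect <- function(camera) {
    cam <- rig[[camera]]
    w <- stats::runif(1, 30, 200); h <- stats::runif(1, 30, 200)
    cx <- stats::runif(1, w / 2, cam$width - w / 2)
    cy <- stats::runif(1, h / 2, cam$height - h / 2)
    c(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2,
      cx = cx, cy = cy)
  }
  u_flag <- stats::runif(n)
  flags <- ifelse(u_flag < config$outlier_rate, "outlier",
                  ifelse(u_flag < config$outlier_rate + config$desync_rate,
                         "desynced", "clean"))
  ir_rows <- vector("list", n); rgb_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    t_ir <- (i - 1) + stats::runif(1, 0.30, 0.70)
    t_rgb <- t_ir + stats::runif(1, -0.02, 0.02)
    g <- draw_gaze()
    geo <- pupil_geometry(g)
    # noiseless RGB projection is the ground-truth label for evaluation
    gt_ctr <- project(rig, geo$P, "rgb")
    gt_tl <- project(rig, geo$tl, "rgb")
    gt_br <- project(rig, geo$br, "rgb")
    det_ir <- proj_det(geo, "ir", config$pixel_noise_sigma)
    det_rgb <- proj_det(geo, "rgb", config$pixel_noise_sigma)
    if (flags[i] == "outlier") {
      if (stats::runif(1) < 0.5) det_ir <- random_rect("ir")
      else det_rgb <- random_rect("rgb")
    } else if (flags[i] == "desynced") {
      # one camera caught a different instant of a saccade
      g2 <- draw_gaze()
      geo2 <- pupil_geometry(g2)
      if (stats::runif(1) < 0.5) {
        det_ir <- proj_det(geo2, "ir", config$pixel_noise_sigma)
      } else {
        det_rgb <- proj_det(geo2, "rgb", config$pixel_noise_sigma)
      }
    }
    ir_rows[[i]] <- data.frame(timestamp = t_ir, camera = "ir",
                               t(det_ir), score = 1)
    rgb_rows[[i]] <- data.frame(timestamp = t_rgb, camera = "rgb",
                                t(det_rgb), score = 1)
    truth_rows[[i]] <- data.frame(
      frame = i, t_ir = t_ir, t_rgb = t_rgb, flag = flags[i],
      gx = g[1], gy = g[2], gz = g[3],
      Px = geo$P[1], Py = geo$P[2], Pz = geo$P[3],
      rgb_cx0 = gt_ctr[1], rgb_cy0 = gt_ctr[2],
      rx1 = min(gt_tl[1], gt_br[1]), ry1 = min(gt_tl[2], gt_br[2]),
      rx2 = max(gt_tl[1], gt_br[1]), ry2 = max(gt_tl[2], gt_br[2]))
  }
  ir <- do.call(rbind, ir_rows); rgb <- do.call(rbind, rgb_rows)
  truth <- do.call(rbind, truth_rows)
  # setup validity: the clean noiseless eye geometry must be visible in both
  in_bounds <- function(det, cam) {
    all(det[c("x1", "x2", "cx")] >= 0) && all(det[c("y1", "y2", "cy")] >= 0) &&
      all(det[c("x1", "x2", "cx")] <= cam$width) &&
      all(det[c("y1", "y2", "cy")] <= cam$height)
  }
  clean <- flags == "clean"
  vis <- vapply(which(clean), function(i) {
    in_bounds(unlist(truth[i, c("rx1", "ry1", "rx2", "ry2",
                                "rgb_cx0", "rgb_cy0")])[c(1, 3, 5, 2, 4, 6)] |>
                stats::setNames(c("x1", "x2", "cx", "y1", "y2", "cy")),
              rig$rgb)
  }, logical(1))
  if (any(clean) && !all(vis)) {
    stop("simulation config error: the eye leaves the RGB field of view; ",
         "adjust baseline, toe-in or gaze cone", call. = FALSE)
  }
  structure(list(ir = ir, rgb = rgb, truth = truth, model = model,
                 rig = rig, config = config),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("Synthetic stereo session: %d frames (%s)\n",
              nrow(x$truth),
              paste(names(table(x$truth$flag)), table(x$truth$flag),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  true eyeball center (%.1f, %.1f, %.1f) mm, r = %g mm, seed %d\n",
              x$model$C[1], x$model$C[2], x$model$C[3], x$model$r,
              x$config$seed))
  invisible(x)
}

#' Write a simulated session to disk
#'
#' Detections go to `ir.csv` / `rgb.csv` in the dialect the pipeline
#' reads; ground truth (per-frame truth table, true model, config echo)
#' goes to sidecar files `truth.csv`, `model.json` and
#' `calibration.yaml`.
#'
#' @param session a `sim_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_detections(session$ir, file.path(dir, "ir.csv"))
  write_detections(session$rgb, file.path(dir, "rgb.csv"))
  utils::write.csv(session$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_eyeball_model(session$model, file.path(dir, "model.json"))
  save_calibration(session$rig, file.path(dir, "calibration.yaml"))
  invisible(dir)
}

#' Render simple synthetic eye images for a session
#'
#' Draws a schematic eye per frame — dark pupil ellipse filling the
#' detection rectangle, an iris disc around it, a bright sclera
#' background, optionally one or two specular reflection blobs — and an
#' exact label sidecar. The images exercise detector plug-ins; they make
#' no attempt at photorealism. Requires the `png` package.
#'
#' @param session a `sim_session`.
#' @param dir output directory.
#' @param camera which camera's frames to render.
#' @param scale down-scaling factor applied to the image size (rendering
#'   full sensor resolution for every frame is rarely needed in tests).
#' @param reflections add specular blobs.
#' @return Data frame of written image paths with their label rows
#'   (center and rectangle in the rendered pixel scale).
#' @export
render_eye_images <- function(session, dir, camera = c("ir", "rgb"),
                              scale = 1, reflections = FALSE) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("render_eye_images requires the 'png' package", call. = FALSE)
  }
  camera <- match.arg(camera)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- session[[camera]]
  cam <- session$rig[[camera]]
  w <- round(cam$width * scale); h <- round(cam$height * scale)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)   # 0-based centers
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  labels <- vector("list", nrow(det))
  for (i in seq_len(nrow(det))) {
    d <- det[i, ]
    cx <- d$cx * scale; cy <- d$cy * scale
    ax <- pmax((d$x2 - d$x1) * scale / 2, 1)
    ay <- pmax((d$y2 - d$y1) * scale / 2, 1)
    img <- matrix(0.88, h, w)
    iris <- ((xs - cx) / (2.0 * ax))^2 + ((ys - cy) / (2.0 * ay))^2 <= 1
    img[iris] <- 0.45
    pupil <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
    img[pupil] <- 0.05
    if (reflections) {
      gx <- cx + 0.6 * ax; gy <- cy - 0.6 * ay
      blob <- ((xs - gx) / (0.25 * ax))^2 + ((ys - gy) / (0.25 * ay))^2 <= 1
      img[blob] <- 1
    }
    path <- file.path(dir, sprintf("%s_%08.3f.png", camera, d$timestamp))
    png::writePNG(img, path)
    lab <- data.frame(path = path, timestamp = d$timestamp,
                      cx = cx, cy = cy,
                      x1 = d$x1 * scale, y1 = d$y1 * scale,
                      x2 = d$x2 * scale, y2 = d$y2 * scale)
    jsonlite::write_json(as.list(lab), sub("\\.png$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
    labels[[i]] <- lab
  }
  out <- do.call(rbind, labels)
  rownames(out) <- NULL
  out
}
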