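#' Pinhole camera intrinsics
#'
#' Construct and validate the intrinsic description of one eye camera: the
#' upper-triangular 3x3 intrinsic matrix `K` (in pixels) and the sensor size.
#' Pixel coordinates are continuous, 0-based, origin at the top-left corner,
#' x to the right and y down.
#'
#' @param K 3x3 numeric intrinsic matrix with `K[3,3] == 1`, positive focal
#'   entries and the principal point inside the image bounds.
#' @param width,height image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(K, width, height) {
  K <- as.matrix(K)
  storage.mode(K) <- "double"
  if (!all(dim(K) == c(3L, 3L))) {
    stop("K must be a 3x3 matrix", call. = FALSE)
  }
  if (abs(K[3, 3] - 1) > 1e-12 || any(abs(K[3, 1:2]) > 1e-12) ||
      abs(K[2, 1]) > 1e-12) {
    stop("K must be upper triangular with K[3,3] = 1", call. = FALSE)
  }
  if (K[1, 1] <= 0 || K[2, 2] <= 0) {
    stop("focal entries of K must be positive", call. = FALSE)
  }
  width <- as.numeric(width); height <- as.numeric(height)
  if (width <= 0 || height <= 0) {
    stop("image size must be positive", call. = FALSE)
  }
  if (K[1, 3] < 0 || K[1, 3] > width || K[2, 3] < 0 || K[2, 3] > height) {
    stop("principal point must lie inside the image bounds", call. = FALSE)
  }
  structure(list(K = K, width = width, height = height),
            class = "camera_intrinsics")
}

#' Stereo eye-camera rig
#'
#' Combines the intrinsics of the IR and RGB eye cameras with their relative
#' pose. The IR camera frame is the world frame: the IR camera sits at the
#' origin with identity rotation, and all 3D quantities are expressed in
#' millimetres in this frame.
#'
#' The pose follows the projection-matrix convention: a world point `X`
#' projects into the RGB camera as `K_rgb %*% (R %*% X + T)` (with
#' homogeneous division), i.e. `M_rgb = K_rgb [R | T]`. Consequently the RGB
#' camera center is `C_rgb = -t(R) %*% T` and the world direction of an RGB
#' pixel `p` is `t(R) %*% solve(K_rgb) %*% p`.
#'
#' @param ir,rgb [camera_intrinsics()] of the two cameras.
#' @param R 3x3 rotation matrix (orthonormal, `det(R) = +1` within `tol`).
#' @param T length-3 translation vector in millimetres.
#' @param tol orthonormality tolerance for `R`.
#' @return An object of class `stereo_rig` with derived fields `C_rgb`
#'   (RGB camera center, mm, world frame) and `M_rgb` (3x4 perspective
#'   matrix of the RGB camera).
#' @export
stereo_rig <- function(ir, rgb, R, T, tol = 1e-6) {
  stopifnot(inherits(ir, "camera_intrinsics"), inherits(rgb, "camera_intrinsics"))
  R <- as.matrix(R); storage.mode(R) <- "double"
  T <- as.numeric(T)
  if (!all(dim(R) == c(3L, 3L)) || length(T) != 3L) {
    stop("R must be 3x3 and T length 3", call. = FALSE)
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("R is not orthonormal (tolerance ", tol, ")", call. = FALSE)
  }
  if (det(R) < 0) {
    stop("R must be a proper rotation (det(R) = +1); reflections are invalid",
         call. = FALSE)
  }
  C_rgb <- as.numeric(-crossprod(R, T))  # -t(R) %*% T
  M_rgb <- rgb$K %*% cbind(R, T)
  structure(list(ir = ir, rgb = rgb, R = R, T = T,
                 C_ir = c(0, 0, 0), C_rgb = C_rgb, M_rgb = M_rgb),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat("Stereo eye-camera rig (units: mm; world frame = IR camera)\n")
  cat(sprintf("  IR : %gx%g px, focal (%.1f, %.1f)\n",
              x$ir$width, x$ir$height, x$ir$K[1, 1], x$ir$K[2, 2]))
  cat(sprintf("  RGB: %gx%g px, focal (%.1f, %.1f)\n",
              x$rgb$width, x$rgb$height, x$rgb$K[1, 1], x$rgb$K[2, 2]))
  cat(sprintf("  baseline |C_rgb| = %.2f mm, C_rgb = (%.2f, %.2f, %.2f)\n",
              sqrt(sum(x$C_rgb^2)), x$C_rgb[1], x$C_rgb[2], x$C_rgb[3]))
  invisible(x)
}

camera_slot <- function(rig, camera = c("ir", "rgb")) {
  camera <- match.arg(camera)
  rig[[camera]]
}

#' Load / save a stereo calibration file
#'
#' Calibration files are flat YAML (or JSON, which YAML parses) documents
#' with fields `ir.K`, `ir.size`, `rgb.K`, `rgb.size`, `R`, `T` and an
#' explicit `units: mm`. Matrices are stored row-major as lists of rows.
#' The chessboard calibration producing these numbers is an offline,
#' device-level step performed elsewhere; this package only consumes its
#' output.
#'
#' @param path path to the calibration file.
#' @return [load_calibration()] returns a validated [stereo_rig()];
#'   [save_calibration()] writes `rig` to `path` and returns `path`
#'   invisibly.
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  need <- c("ir", "rgb", "R", "T", "units")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop("calibration file is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(tolower(doc$units), "mm")) {
    stop("calibration file must declare 'units: mm'", call. = FALSE)
  }
  as_mat3 <- function(x, what) {
    m <- do.call(rbind, lapply(x, as.numeric))
    if (!all(dim(m) == c(3L, 3L))) stop("field ", what, " must be 3x3", call. = FALSE)
    m
  }
  read_cam <- function(cam, what) {
    if (is.null(cam$K) || is.null(cam$size)) {
      stop("camera block '", what, "' needs fields K and size", call. = FALSE)
    }
    camera_intrinsics(as_mat3(cam$K, paste0(what, ".K")),
                      width = as.numeric(cam$size[[1]]),
                      height = as.numeric(cam$size[[2]]))
  }
  stereo_rig(ir = read_cam(doc$ir, "ir"), rgb = read_cam(doc$rgb, "rgb"),
             R = as_mat3(doc$R, "R"), T = as.numeric(doc$T))
}

#' @rdname load_calibration
#' @param rig a [stereo_rig()].
#' @export
save_calibration <- function(rig, path) {
  stopifnot(inherits(rig, "stereo_rig"))
  mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  doc <- list(
    units = "mm",
    pixel_convention = "0-based, origin top-left, x right, y down",
    ir = list(K = mat_rows(rig$ir$K), size = c(rig$ir$width, rig$ir$height)),
    rgb = list(K = mat_rows(rig$rgb$K), size = c(rig$rgb$width, rig$rgb$height)),
    R = mat_rows(rig$R),
    T = as.numeric(rig$T)
  )
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Back-project a pixel to a world ray
#'
#' Returns the 3D viewing ray of a pixel: origin at the camera center,
#' unit direction in the world (IR) frame. For the IR camera the direction
#' is `solve(K_ir) %*% p`; for the RGB camera it is additionally rotated
#' into the world frame by `t(R)`.
#'
#' @param rig a [stereo_rig()].
#' @param p pixel as a length-2 numeric `c(x, y)`.
#' @param camera `"ir"` or `"rgb"`.
#' @return A list with class `ray`: `origin` (mm) and unit `direction`.
#' @export
backproject <- function(rig, p, camera = c("ir", "rgb")) {
  camera <- match.arg(camera)
  p <- as.numeric(p)
  stopifnot(length(p) == 2L, all(is.finite(p)))
  cam <- camera_slot(rig, camera)
  d <- solve(cam$K, c(p, 1))
  if (camera == "rgb") d <- as.numeric(crossprod(rig$R, d))
  d <- d / sqrt(sum(d^2))
  origin <- if (camera == "ir") rig$C_ir else rig$C_rgb
  structure(list(origin = origin, direction = d), class = "ray")
}

#' Project a world point to a pixel
#'
#' Perspective projection of a 3D world point (mm, IR frame) into one of the
#' cameras, with homogeneous division. For the RGB camera this equals
#' `M_rgb %*% c(P, 1)` followed by division.
#'
#' @param rig a [stereo_rig()].
#' @param P world point, length-3 numeric (mm).
#' @param camera `"ir"` or `"rgb"`.
#' @return Pixel as a length-2 numeric `c(x, y)`.
#' @export
project <- function(rig, P, camera = c("ir", "rgb")) {
  camera <- match.arg(camera)
  P <- as.numeric(P)
  stopifnot(length(P) == 3L, all(is.finite(P)))
  cam <- camera_slot(rig, camera)
  Pc <- if (camera == "ir") P else as.numeric(rig$R %*% P + rig$T)
  if (Pc[3] <= 0) {
    stop("point has non-positive depth in the ", camera, " camera", call. = FALSE)
  }
  h <- as.numeric(cam$K %*% Pc)
  h[1:2] / h[3]
}
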