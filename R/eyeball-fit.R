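#' Eyeball model
#'
#' A fitted eyeball: sphere center `C` in millimetres in the world (IR
#' camera) frame and fixed radius `r`. The anatomical average eyeball
#' radius of 12 mm is used throughout; it is never re-estimated from data
#' (the override exists for sensitivity analysis only).
#'
#' @param C sphere center, length-3 numeric, mm.
#' @param r radius, mm.
#' @param n_points,fit_residual optional fit metadata.
#' @return An object of class `eyeball_model`.
#' @export
eyeball_model <- function(C, r = 12, n_points = NA_integer_,
                          fit_residual = NA_real_) {
  C <- as.numeric(C)
  stopifnot(length(C) == 3L, all(is.finite(C)), r > 0)
  structure(list(C = C, r = r, n_points = n_points,
                 fit_residual = fit_residual),
            class = "eyeball_model")
}

#' @export
print.eyeball_model <- function(x, ...) {
  cat(sprintf("Eyeball model: C = (%.3f, %.3f, %.3f) mm, r = %g mm\n",
              x$C[1], x$C[2], x$C[3], x$r))
  if (!is.na(x$n_points)) {
    cat(sprintf("  fitted from %d points, mean robust residual %.4f mm\n",
                x$n_points, x$fit_residual))
  }
  invisible(x)
}

#' Read / write an eyeball model file
#'
#' Models are stored as JSON: `{"C": [x,y,z], "r": 12, "units": "mm",
#' "n_points": ..., "fit_residual": ...}`.
#'
#' @param path JSON file path.
#' @return [read_eyeball_model()] returns an [eyeball_model()];
#'   [write_eyeball_model()] returns `path` invisibly.
#' @export
read_eyeball_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(tolower(doc$units), "mm")) {
    stop("model file must declare units \"mm\"", call. = FALSE)
  }
  eyeball_model(doc$C, doc$r,
                n_points = if (is.null(doc$n_points)) NA_integer_ else doc$n_points,
                fit_residual = if (is.null(doc$fit_residual)) NA_real_ else doc$fit_residual)
}

#' @rdname read_eyeball_model
#' @param model an [eyeball_model()].
#' @export
write_eyeball_model <- function(model, path) {
  stopifnot(inherits(model, "eyeball_model"))
  jsonlite::write_json(
    list(C = model$C, r = model$r, units = "mm",
         n_points = model$n_points, fit_residual = model$fit_residual),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Robust fit configuration
#'
#' Controls the two-pass truncated M-estimator refinement of the sphere
#' center: refinement is run once per truncation threshold in `deltas`, in
#' order — first a loose pass (1 mm) to improve the initial center, then a
#' tight pass (0.5 mm).
#'
#' @param deltas strictly decreasing positive truncation thresholds, mm.
#' @param max_iterations iteration cap per pass.
#' @param tolerance convergence tolerance on the center, mm.
#' @return An object of class `robust_fit_config`.
#' @export
robust_fit_config <- function(deltas = c(1.0, 0.5), max_iterations = 500L,
                              tolerance = 1e-6) {
  deltas <- as.numeric(deltas)
  if (length(deltas) < 1L || any(deltas <= 0) ||
      any(diff(deltas) >= 0)) {
    stop("deltas must be strictly decreasing and positive", call. = FALSE)
  }
  stopifnot(max_iterations >= 1, tolerance > 0)
  structure(list(deltas = deltas, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance), class = "robust_fit_config")
}

#' Truncated robust distance to the sphere surface
#'
#' The loss of the sphere-center M-estimator: the absolute distance of a
#' point to the sphere surface, `| ||P - C|| - r |`, truncated at `delta` so
#' that far outliers all contribute the same bounded penalty.
#'
#' @param P one point (length-3) or an n x 3 matrix of points, mm.
#' @param C sphere center, mm.
#' @param delta truncation threshold, mm (> 0).
#' @param r sphere radius, mm.
#' @return Numeric vector of robust distances, each in `[0, delta]`.
#' @export
robust_distance <- function(P, C, delta, r = 12) {
  stopifnot(delta > 0)
  P <- if (is.matrix(P)) P else matrix(P, ncol = 3L)
  dev <- abs(sqrt(rowSums(sweep(P, 2L, C)^2)) - r)
  pmin(dev, delta)
}

#' Initial sphere-center approximation from near-coplanar surface points
#'
#' Pupil points all sit on a small cap of the eyeball, so they are close to
#' a plane tangent to the sphere. The plane normal is the right singular
#' vector of the centered point matrix with the smallest singular value;
#' the center approximation is the mean point plus `r` along that normal,
#' with the sign chosen toward larger depth (the eyeball center is farther
#' from the cameras than the pupil points, since the cameras face the eye).
#'
#' @param points n x 3 matrix of 3D points, mm (n >= 3, non-collinear).
#' @param r sphere radius, mm.
#' @return Length-3 center approximation, mm.
#' @export
init_center <- function(points, r = 12) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  Pbar <- colMeans(points)
  X <- sweep(points, 2L, Pbar)
  sv <- svd(X)
  if (sv$d[2] < 1e-9) {
    stop("degenerate geometry: points are collinear, no unique plane",
         call. = FALSE)
  }
  N <- sv$v[, 3L]
  if (N[3] < 0) N <- -N    # toward larger depth (+z in the IR frame)
  Pbar + r * N
}

#' Refine the sphere center with a truncated M-estimator
#'
#' Minimizes `sum(robust_distance(P, C, delta))` over the center `C`
#' starting from `C0`, using a derivative-free Nelder-Mead simplex search
#' (the truncated objective is only piecewise smooth). The returned center
#' never has a larger objective than `C0`.
#'
#' @param points n x 3 matrix of 3D points, mm (n >= 4).
#' @param C0 starting center, mm.
#' @param r sphere radius, mm.
#' @param delta truncation threshold, mm.
#' @param config a [robust_fit_config()] (its `max_iterations` and
#'   `tolerance` are used; `delta` is passed explicitly).
#' @return The refined center, with attributes `objective` (final sum of
#'   robust distances) and `converged` (logical; `FALSE` with a warning if
#'   the iteration cap was hit).
#' @export
refine_center <- function(points, C0, r = 12, delta = 0.5,
                          config = robust_fit_config()) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, all(is.finite(C0)))
  if (nrow(points) < 4L) stop("need at least 4 points", call. = FALSE)
  obj <- function(C) sum(robust_distance(points, C, delta, r))
  # simplex search with restarts: a restarted simplex recovers from premature
  # shrinkage on the piecewise-smooth objective; stop when the center moves
  # less than the tolerance between restarts
  C <- C0
  value <- obj(C0)
  converged <- FALSE
  for (round in 1:5) {
    # optimize the offset from the current center so the initial simplex
    # scale is independent of where the eye sits in the world frame
    fit <- stats::optim(c(0, 0, 0), function(x) obj(C + x),
                        method = "Nelder-Mead",
                        control = list(maxit = config$max_iterations,
                                       reltol = 1e-12))
    moved <- sqrt(sum(fit$par^2))
    C <- C + fit$par
    value <- fit$value
    if (fit$convergence == 0L || moved < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("center refinement hit the iteration cap; returning best iterate",
            call. = FALSE)
  }
  # Nelder-Mead never moves uphill from the start, but guard regardless
  if (value > obj(C0)) {
    C <- C0
    value <- obj(C0)
  }
  structure(C, objective = value, converged = converged)
}

#' Fit the eyeball sphere to filtered pupil points
#'
#' Two phases: approximation ([init_center()]) then optimization — one
#' [refine_center()] pass per truncation threshold in `config$deltas`
#' (default 1 mm then 0.5 mm). The radius is fixed; only the center is
#' estimated.
#'
#' @param points n x 3 matrix (or a data frame with `Sx,Sy,Sz` columns as
#'   produced by [triangulate_pairs()]) of 3D pupil points, mm.
#' @param r sphere radius, mm.
#' @param config a [robust_fit_config()].
#' @param min_points refuse to fit with fewer points than this (guards the
#'   SVD plane estimate).
#' @return An [eyeball_model()].
#' @export
fit_eyeball <- function(points, r = 12, config = robust_fit_config(),
                        min_points = 10L) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("Sx", "Sy", "Sz")])
  }
  points <- as.matrix(points)
  colnames(points) <- NULL
  if (nrow(points) < min_points) {
    stop("only ", nrow(points), " points after filtering; at least ",
         min_points, " are required for a reliable fit", call. = FALSE)
  }
  C <- init_center(points, r)
  for (delta in config$deltas) {
    C <- refine_center(points, C, r = r, delta = delta, config = config)
  }
  resid <- attr(C, "objective") / nrow(points)
  eyeball_model(as.numeric(C), r = r, n_points = nrow(points),
                fit_residual = resid)
}

#' Naive least-squares sphere fit (no robustness, no truncation)
#'
#' Baseline for comparison: minimizes the plain sum of squared surface
#' deviations `sum((||P - C|| - r)^2)` over the center, starting from the
#' same plane/SVD initialization, with no outlier handling. Used to
#' quantify what the robust two-pass fit buys on contaminated data.
#'
#' @inheritParams fit_eyeball
#' @return An [eyeball_model()].
#' @export
fit_sphere_lsq <- function(points, r = 12) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("Sx", "Sy", "Sz")])
  }
  points <- as.matrix(points)
  colnames(points) <- NULL
  C0 <- init_center(points, r)
  obj <- function(C) sum((sqrt(rowSums(sweep(points, 2L, C)^2)) - r)^2)
  fit <- stats::optim(C0, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000L, reltol = 1e-14))
  eyeball_model(fit$par, r = r, n_points = nrow(points),
                fit_residual = fit$value / nrow(points))
}
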