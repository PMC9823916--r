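# shared fixtures: small rigs and random-geometry generators used across files

simple_K <- function(f = 800, cx = 400, cy = 300) {
  matrix(c(f, 0, cx, 0, f, cy, 0, 0, 1), 3, 3, byrow = TRUE)
}

# IR at origin, RGB at (20,0,0) toed in toward an eye ~30 mm out
test_rig <- function(baseline = 20, toe_in_deg = NULL) {
  sim_rig(sim_config(baseline_mm = baseline, toe_in_deg = toe_in_deg))
}

# rotation matrix about a random axis (Rodrigues)
random_rotation <- function(max_angle_deg = 40) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  th <- stats::runif(1, 0, max_angle_deg * pi / 180)
  Kx <- matrix(c(0, -axis[3], axis[2],
                 axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
}

random_rig <- function() {
  stereo_rig(
    ir = camera_intrinsics(simple_K(stats::runif(1, 500, 1500)), 800, 600),
    rgb = camera_intrinsics(simple_K(stats::runif(1, 500, 1500)), 800, 600),
    R = random_rotation(20),
    T = stats::rnorm(3, 0, 10)
  )
}

# axis-aligned rectangle with integer corners inside [0, lim]^2
random_int_rect <- function(lim = 60) {
  x <- sort(sample(0:lim, 2))
  y <- sort(sample(0:lim, 2))
  while (x[1] == x[2]) x <- sort(sample(0:lim, 2))
  while (y[1] == y[2]) y <- sort(sample(0:lim, 2))
  c(x[1], y[1], x[2], y[2])
}

# IoU by counting unit cells: exact for integer-corner rectangles
raster_iou <- function(a, b, lim = 200) {
  cells <- function(r) {
    g <- expand.grid(x = seq(0, lim - 1), y = seq(0, lim - 1))
    g$x >= r[1] & g$x < r[3] & g$y >= r[2] & g$y < r[4]
  }
  ca <- cells(a); cb <- cells(b)
  inter <- sum(ca & cb); uni <- sum(ca | cb)
  if (uni == 0) 0 else inter / uni
}

center_error <- function(model, truth) sqrt(sum((model$C - truth$C)^2))
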