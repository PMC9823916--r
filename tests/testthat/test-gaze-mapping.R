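axial_ray <- function(v = c(0, 0, 1)) {
  structure(list(origin = c(0, 0, 0), direction = v / sqrt(sum(v^2))),
            class = "ray")
}

test_that("ray-sphere intersection returns the smaller positive root", {
  hit <- intersect_ray_sphere(axial_ray(), eyeball_model(c(0, 0, 30), 12))
  expect_equal(hit$alpha, 18)
  expect_equal(hit$point, c(0, 0, 18))
  expect_equal(hit$kind, "two_roots")
})

test_that("a missing intersection falls back to the real part of the roots", {
  # symbolic solution: for ||v|| = 1 the conjugate roots share real part v.C
  hit <- intersect_ray_sphere(axial_ray(), eyeball_model(c(13, 0, 30), 12))
  expect_equal(hit$kind, "approximated_complex")
  expect_equal(hit$alpha, 30)
  expect_equal(hit$point, c(0, 0, 30))
})

test_that("a sphere behind the camera is reported as a broken model", {
  expect_error(intersect_ray_sphere(axial_ray(), eyeball_model(c(0, 0, -30), 12)),
               "broken")
})

test_that("intersection matches a dense sampling oracle on random cases", {
  set.seed(8)
  worst <- 0
  for (rep in 1:1000) {
    C <- c(stats::rnorm(2, 0, 6), stats::runif(1, 20, 45))
    r <- stats::runif(1, 8, 14)
    v <- c(stats::rnorm(2, 0, 0.2), 1)
    v <- v / sqrt(sum(v^2))
    model <- eyeball_model(C, r)
    hit <- intersect_ray_sphere(axial_ray(v), model)
    if (hit$kind == "two_roots") {
      # first surface crossing along the ray, 1e-3 mm steps
      alphas <- seq(0, sqrt(sum(C^2)) + r, by = 1e-3)
      inside <- (outer(alphas, v[1]) - C[1])^2 +
        (outer(alphas, v[2]) - C[2])^2 +
        (outer(alphas, v[3]) - C[3])^2 <= r^2
      first <- alphas[which(inside)[1]]
      worst <- max(worst, abs(first - hit$alpha))
    } else {
      # dense sampling confirms the ray never enters the sphere
      alphas <- seq(0, sqrt(sum(C^2)) + r, by = 1e-2)
      d2 <- (alphas * v[1] - C[1])^2 + (alphas * v[2] - C[2])^2 +
        (alphas * v[3] - C[3])^2
      expect_gt(min(d2), r^2)
    }
  }
  expect_lt(worst, 2e-3)
})

test_that("mapping an IR projection reproduces the RGB projection", {
  s <- simulate_session(sim_config(pixel_noise_sigma = 0, n_frames = 40,
                                   seed = 2))
  for (i in seq_len(10)) {
    m <- map_point_ir_to_rgb(s$rig, s$model,
                             c(s$ir$cx[i], s$ir$cy[i]))
    expect_lt(sqrt(sum((m$p_rgb - c(s$truth$rgb_cx0[i], s$truth$rgb_cy0[i]))^2)),
              0.5)
    # mapping is deterministic
    m2 <- map_point_ir_to_rgb(s$rig, s$model, c(s$ir$cx[i], s$ir$cy[i]))
    expect_identical(m$p_rgb, m2$p_rgb)
  }
})

test_that("the axial mapping case and gaze-ray invariants hold", {
  rig <- test_rig()
  model <- eyeball_model(c(0, 0, 30), 12)
  p0 <- c(rig$ir$K[1, 3], rig$ir$K[2, 3])   # principal point
  m <- map_point_ir_to_rgb(rig, model, p0)
  expect_equal(m$P_w, c(0, 0, 18), tolerance = 1e-9)
  expect_equal(m$gaze$origin, model$C)
  expect_equal(sqrt(sum(m$gaze$direction^2)), 1, tolerance = 1e-12)
  expect_equal(m$gaze$direction, (m$P_w - model$C) / 12, tolerance = 1e-9)
  expect_equal(sqrt(sum((m$P_w - model$C)^2)), 12, tolerance = 1e-6)
})

test_that("gaze ray, pupil point and RGB pixel stay mutually consistent", {
  set.seed(12)
  rig <- test_rig()
  model <- eyeball_model(c(0.5, -0.3, 31), 12)
  for (rep in 1:50) {
    p_ir <- c(stats::runif(1, 500, 780), stats::runif(1, 350, 610))
    m <- map_point_ir_to_rgb(rig, model, p_ir)
    if (m$intersection_kind != "two_roots") next
    # re-derive the RGB pixel from the gaze ray's sphere crossing
    P_again <- model$C + model$r * m$gaze$direction
    expect_equal(P_again, m$P_w, tolerance = 1e-9)
    expect_identical(project(rig, m$P_w, "rgb"), m$p_rgb)
  }
})

test_that("pulling the model away from the camera keeps the axial hit real", {
  model <- eyeball_model(c(3, 1, 25), 12)
  hit25 <- intersect_ray_sphere(axial_ray(), model)
  expect_equal(hit25$kind, "two_roots")
  for (z in c(30, 40, 60, 100)) {
    hit <- intersect_ray_sphere(axial_ray(), eyeball_model(c(3, 1, z), 12))
    expect_equal(hit$kind, "two_roots")
  }
})

test_that("rectangle mapping preserves corner order and degenerate rects", {
  set.seed(13)
  rig <- test_rig()
  model <- eyeball_model(c(0, 0, 30), 12)
  for (rep in 1:500) {
    x <- sort(stats::runif(2, 400, 880)); y <- sort(stats::runif(2, 280, 680))
    rect <- c(x[1], y[1], x[2], y[2])
    out <- map_rect_ir_to_rgb(rig, model, rect)
    expect_true(out[1] <= out[3] && out[2] <= out[4])
  }
  # a 1x1 px rect maps consistently with the point mapping
  rect <- c(640, 480, 641, 481)
  out <- map_rect_ir_to_rgb(rig, model, rect)
  tl <- map_point_ir_to_rgb(rig, model, rect[1:2])$p_rgb
  br <- map_point_ir_to_rgb(rig, model, rect[3:4])$p_rgb
  expect_equal(sort(c(out[1], out[3])), sort(c(tl[1], br[1])))
  expect_equal(sort(c(out[2], out[4])), sort(c(tl[2], br[2])))
})

test_that("mapped rects overlap ground truth strongly at zero noise", {
  s <- simulate_session(sim_config(pixel_noise_sigma = 0, n_frames = 30,
                                   seed = 3))
  fit <- build_eyeball(s$rig, s$ir, s$rgb)
  ious <- sapply(seq_len(30), function(i) {
    mrect <- map_rect_ir_to_rgb(s$rig, fit$model,
                                as.numeric(s$ir[i, c("x1", "y1", "x2", "y2")]))
    rect_iou(mrect, as.numeric(s$truth[i, c("rx1", "ry1", "rx2", "ry2")]))
  })
  expect_gt(min(ious), 0.8)
})

test_that("validate_model flags exactly the configured disagreement runs", {
  mk_frames <- function(ious, present = rep(TRUE, length(ious))) {
    # build mapped/detector rect pairs realizing the requested IoUs:
    # unit-height rects [0,1]x[0,w] against [0,1]x[0,1] give IoU w
    n <- length(ious)
    data.frame(mx1 = 0, my1 = 0, mx2 = 1, my2 = 1,
               dx1 = ifelse(present, 0, NA),
               dy1 = ifelse(present, 0, NA),
               dx2 = ifelse(present, ifelse(ious > 0, ious, 2), NA),
               dy2 = ifelse(present, ifelse(ious > 0, 1, 2), NA))
  }
  expect_equal(as.character(validate_model(mk_frames(rep(0.9, 30)))), "valid")
  v <- validate_model(mk_frames(rep(0.2, 5)), n_consecutive = 5)
  expect_equal(as.character(v), "invalid")
  expect_equal(attr(v, "first_invalid_frame"), 5L)
  # 4 bad frames do not trigger a 5-frame rule
  expect_equal(as.character(validate_model(mk_frames(rep(0.2, 4)),
                                           n_consecutive = 5)), "valid")
  # a present agreeing frame breaks a disagreement run ...
  ious <- c(0.2, 0.2, 0.9, 0.2, 0.2, 0.2)
  expect_equal(as.character(validate_model(mk_frames(ious),
                                           n_consecutive = 5)), "valid")
  # ... but the same frame with no detector output does not
  present <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(as.character(validate_model(mk_frames(ious, present),
                                           n_consecutive = 5)), "invalid")
  ious2 <- c(0.2, 0.2, 0.1, 0.2, 0.2)
  present2 <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(as.character(validate_model(mk_frames(ious2, present2),
                                           n_consecutive = 4)), "invalid")
})

test_that("validation agrees with a literal scan-for-run oracle", {
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    ious <- stats::runif(n)
    present <- stats::runif(n) < 0.8
    ncons <- sample(2:6, 1)
    frames <- data.frame(mx1 = 0, my1 = 0, mx2 = 1, my2 = 1,
                         dx1 = ifelse(present, 0, NA),
                         dy1 = ifelse(present, 0, NA),
                         dx2 = ifelse(present, pmax(ious, 1e-6), NA),
                         dy2 = ifelse(present, 1, NA))
    got <- as.character(validate_model(frames, iou_min = 0.5,
                                       n_consecutive = ncons))
    # oracle: drop absent frames, look for any window of ncons all < 0.5
    seq_present <- ious[present] < 0.5
    bad <- FALSE
    if (length(seq_present) >= ncons) {
      runs <- rle(seq_present)
      bad <- any(runs$lengths[runs$values] >= ncons)
    }
    expect_equal(got, if (bad) "invalid" else "valid")
  }
})

test_that("self-labels accept exactly the IoU >= 0.5 frames", {
  frames <- data.frame(frame = 1:4,
                       mx1 = 0, my1 = 0, mx2 = 10, my2 = 10,
                       dx1 = c(0, 20, 0, NA), dy1 = c(0, 20, 5, NA),
                       dx2 = c(10, 30, 10, NA), dy2 = c(10, 30, 15, NA))
  labels <- export_self_labels(frames)
  expect_equal(nrow(labels), 3L)           # the detector-less frame is dropped
  expect_equal(labels$iou[1], 1)
  expect_true(labels$accepted[1])
  expect_equal(labels$iou[2], 0)           # disjoint
  expect_false(labels$accepted[2])
  expect_equal(labels$accepted, labels$iou >= 0.5)
})

test_that("mapping JSONL export round-trips frame records", {
  s <- simulate_session(sim_config(pixel_noise_sigma = 0, n_frames = 12,
                                   seed = 4))
  mapped <- map_session(s$rig, s$model, s$ir)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_mapping_jsonl(mapped, s$ir, path)
  lines <- readLines(path)
  expect_length(lines, 12L)
  rec <- jsonlite::fromJSON(lines[[1]])
  expect_equal(rec$t, mapped$timestamp[1])
  expect_equal(rec$p_rgb, c(mapped$p_rgb_x[1], mapped$p_rgb_y[1]))
  expect_equal(rec$intersection_kind, mapped$intersection_kind[1])
})
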