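test_that("spline interpolates nodes with C1 continuity", {
  set.seed(11)
  for (rep in 1:5) {
    sp <- random_spline(n_nodes = 4 + rep)
    n_seg <- nrow(sp$a0)
    # endpoint conditions
    for (i in seq_len(n_seg)) {
      expect_lt(max(abs(spline_eval(sp, i, 0) - sp$nodes[i, ])), 1e-9)
      expect_lt(max(abs(spline_eval(sp, i, 1) - sp$nodes[i + 1, ])), 1e-9)
    }
    # first derivatives agree at shared nodes
    for (i in seq_len(n_seg - 1)) {
      expect_lt(max(abs(spline_eval(sp, i, 1, deriv = 1) -
                        spline_eval(sp, i + 1, 0, deriv = 1))), 1e-9)
    }
  }
})

test_that("collinear and two-node inputs reproduce straight segments", {
  sp <- fit_spline(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  tt <- seq(0, 1, by = 0.1)
  for (seg in 1:2) {
    expect_lt(max(abs(spline_eval(sp, seg, tt, deriv = 2))), 1e-12)
    p <- spline_eval(sp, seg, tt)
    expect_lt(max(abs(p[, 2:3])), 1e-12)
  }
  two <- fit_spline(rbind(c(1, 2, 3), c(4, 6, 3)))
  expect_lt(max(abs(two$a2)), 1e-12)
  expect_lt(max(abs(two$a3)), 1e-12)
  expect_error(fit_spline(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "duplicate")
  expect_error(fit_spline(rbind(c(0, 0, 0))), "at least 2")
})

test_that("spline through parabola samples stays close to the curve", {
  xs <- seq(0, 2, by = 0.5)
  sp <- fit_spline(cbind(xs, xs^2, 0))
  xf <- seq(-0.5, 2.5, length.out = 20001)
  ref <- cbind(xf, xf^2)
  tt <- seq(0, 1, by = 0.005)
  for (seg in 2:3) {   # interior segments, away from one-sided end tangents
    p <- spline_eval(sp, seg, tt)
    dmin <- vapply(seq_len(nrow(p)), function(i)
      min(sqrt((ref[, 1] - p[i, 1])^2 + (ref[, 2] - p[i, 2])^2)), 0.0)
    expect_lt(max(dmin), 1e-2)
  }
})

test_that("Frenet frame of a parabola matches the analytic triad", {
  sp <- parabola_segment_spline()     # exactly c(t) = (t, t^2, 0)
  fr <- frenet_frame(sp, 1, 0)
  expect_equal(fr$axis_z, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$axis_x, c(0, 0, 1), tolerance = 1e-12)  # unit binormal
  expect_equal(fr$axis_y, c(0, -1, 0), tolerance = 1e-12) # negated normal
  expect_equal(fr$origin, c(0, 0, 0))
  # affine columns are the axes and origin
  expect_equal(fr$affine[1:3, 1], fr$axis_x)
  expect_equal(fr$affine[1:3, 4], fr$origin)
  expect_equal(fr$affine[4, ], c(0, 0, 0, 1))
})

test_that("frames are orthonormal and rigid to 1e-9", {
  set.seed(23)
  for (rep in 1:5) {
    sp <- random_spline()
    for (t in c(0, 0.3, 0.7, 1)) {
      fr <- frenet_frame(sp, sample(nrow(sp$a0), 1), t)
      expect_orthonormal(fr, 1e-9)
      # rigid transform: in-plane distances preserved in world space
      uv <- matrix(runif(10, -20, 20), 5)
      w <- slice_to_world(fr, uv, size_px = 49, pixel_size_mm = 0.5)
      d_uv <- as.matrix(dist(uv)) * 0.5
      d_w <- as.matrix(dist(w))
      expect_lt(max(abs(d_uv - d_w)), 1e-9)
    }
  }
})

test_that("straight splines fall back to a constant transported frame", {
  sp <- fit_spline(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  frames <- frames_along(sp, 2)
  ref <- frames[[1]]
  for (fr in frames) {
    expect_orthonormal(fr)
    expect_equal(fr$axis_x, ref$axis_x, tolerance = 1e-12)
    expect_equal(fr$axis_z, c(1, 0, 0), tolerance = 1e-12)
  }
  degenerate <- structure(list(nodes = rbind(c(0, 0, 0), c(1, 0, 0)),
                               a0 = rbind(c(0, 0, 0)),
                               a1 = rbind(c(0, 0, 0)),
                               a2 = rbind(c(0, 0, 0)),
                               a3 = rbind(c(0, 0, 0))),
                          class = "centerline_spline")
  expect_error(frenet_frame(degenerate, 1, 0.5), "degenerate|tangent")
})

test_that("reversing node order reverses tangents, keeps the point set", {
  nodes <- cbind(c(0, 10, 20, 30), c(0, 5, -5, 0), c(0, 0, 5, 5))
  sp <- fit_spline(nodes)
  rv <- fit_spline(nodes[4:1, ])
  f1 <- frenet_frame(sp, 1, 0)
  f2 <- frenet_frame(rv, 3, 1)
  expect_equal(f2$axis_z, -f1$axis_z, tolerance = 1e-9)
  # step dividing the total length: arc positions coincide from either end
  step <- arc_length(sp) / 10
  o1 <- t(vapply(frames_along(sp, step), `[[`, numeric(3), "origin"))
  o2 <- t(vapply(frames_along(rv, step), `[[`, numeric(3), "origin"))
  expect_equal(o1, o2[nrow(o2):1, ], tolerance = 1e-6)
})

test_that("consecutive frames do not flip on gently curved centerlines", {
  th <- seq(0, pi / 2, length.out = 7)
  sp <- fit_spline(cbind(20 * cos(th), 20 * sin(th), 0))  # 20 mm curvature
  frames <- frames_along(sp, 2)
  for (i in seq_along(frames)[-1]) {
    ang <- acos(min(1, sum(frames[[i]]$axis_x * frames[[i - 1]]$axis_x)))
    expect_lt(ang, 30 * pi / 180)
  }
})

test_that("arc length matches analytic and polyline oracles", {
  expect_equal(arc_length(fit_spline(rbind(c(0, 0, 0), c(3, 4, 0)))), 5,
               tolerance = 1e-9)
  xs <- seq(0, 2, by = 0.5)
  sp <- fit_spline(cbind(xs, xs^2, 0))
  # dense polyline oracle over the same piecewise cubic
  tt <- seq(0, 1, length.out = 250001)
  poly <- 0
  for (seg in 1:4) {
    p <- spline_eval(sp, seg, tt)
    poly <- poly + sum(sqrt(rowSums(diff(p)^2)))
  }
  expect_equal(arc_length(sp), poly, tolerance = 1e-4)
  # additivity across collinear segments
  sp2 <- fit_spline(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(arc_length(sp2), 2, tolerance = 1e-9)
})

test_that("cross sections step at fixed arc spacing with centered origin", {
  sp <- fit_spline(rbind(c(0, 70, 70), c(100, 70, 70)))
  st <- image_stack(array(5, c(8, 8, 8)), c(20, 20, 20))
  xs <- resample_cross_sections(st, sp, step_mm = 1.04, size_px = 9,
                                pixel_size_mm = 1)
  expect_length(xs$images, floor(100 / 1.04) + 1)   # 97 frames
  o <- t(vapply(xs$frames, `[[`, numeric(3), "origin"))
  expect_equal(diff(o[, 1]), rep(1.04, 96), tolerance = 1e-9)
  # constant stack -> constant sections (inside the volume)
  expect_true(all(abs(xs$images[[50]] - 5) < 1e-12))
  # center pixel equals the trilinear sample at the centerline point
  expect_equal(xs$images[[50]][5, 5], sample_world(st, rbind(o[50, ])))
})

test_that("a straight tube appears as a centered disk in cross section", {
  ph <- small_cylinder(shape = c(48L, 48L, 20L), radius = 8, noise_sd = 0,
                       blur_sd = 0)
  xs <- resample_cross_sections(ph$stack, ph$spline, step_mm = 2,
                                size_px = 61, pixel_size_mm = 0.5)
  img <- xs$images[[5]]
  mid <- mean(range(img))
  inside <- img < mid                  # dark lumen
  n_in <- sum(inside)
  r_px <- 8 / 0.5
  expect_lt(abs(n_in - pi * r_px^2), 2 * pi * r_px + 4) # 1 px boundary band
  # boundary is a circle: lumen pixels all within r + 1 px of the center
  idx <- which(inside, arr.ind = TRUE) - 1
  rr <- sqrt((idx[, 1] - 30)^2 + (idx[, 2] - 30)^2)
  expect_lt(max(rr), r_px + 1)
})

test_that("centerline JSON round-trips node lists", {
  path <- withr::local_tempfile(fileext = ".json")
  nodes <- cbind(c(0, 10, 20), c(1, 2, 3), c(4, 5, 6))
  jsonlite::write_json(unname(apply(nodes, 1, as.list)), path,
                       auto_unbox = TRUE, digits = NA)
  expect_equal(read_centerline_json(path), nodes)
  expect_error(read_centerline_json("nope.json"), "not found")
})
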