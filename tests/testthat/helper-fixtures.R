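# Shared fixtures, all generated in code.

# 2-D image of a dark disk (lumen) in a bright wall, with optional border
# blur -- the canonical single-slice snake target.
disk_image <- function(n = 128, radius = 23, lumen = 0, wall = 100,
                       blur = 1) {
  ctr <- (n - 1) / 2
  xi <- matrix(rep(0:(n - 1), n), n)
  yi <- t(xi)
  img <- ifelse(sqrt((xi - ctr)^2 + (yi - ctr)^2) < radius, lumen, wall)
  if (blur > 0)
    img <- vtseg:::.gaussian_blur3(array(img, c(n, n, 1)), blur,
                                   c(1, 1, 1))[, , 1]
  img
}

# small straight-tube phantom for fast end-to-end tests
small_cylinder <- function(shape = c(40L, 40L, 24L), radius = 6,
                           noise_sd = 0, blur_sd = 0.5, seed = 0) {
  generate_phantom(phantom_spec(centerline_kind = "straight",
                                radius_mm = radius, noise_sd = noise_sd,
                                blur_sd = blur_sd, shape = shape),
                   seed = seed)
}

# random general-position spline for property-style checks
random_spline <- function(n_nodes = 5) {
  nodes <- cbind(cumsum(runif(n_nodes, 5, 15)),
                 cumsum(runif(n_nodes, -5, 5)),
                 cumsum(runif(n_nodes, -5, 5)))
  fit_spline(nodes)
}

# spline whose single segment is exactly c(t) = (t, t^2, 0)
parabola_segment_spline <- function() {
  structure(list(nodes = rbind(c(0, 0, 0), c(1, 1, 0)),
                 a0 = rbind(c(0, 0, 0)), a1 = rbind(c(1, 0, 0)),
                 a2 = rbind(c(0, 1, 0)), a3 = rbind(c(0, 0, 0))),
            class = "centerline_spline")
}

expect_orthonormal <- function(frame, tol = 1e-9) {
  A <- cbind(frame$axis_x, frame$axis_y, frame$axis_z)
  expect_lt(max(abs(crossprod(A) - diag(3))), tol)
}
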