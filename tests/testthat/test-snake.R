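test_that("init_circle places equally spaced nodes counter-clockwise", {
  ct <- init_circle(c(50, 50), 10, n_nodes = 8)
  r <- sqrt(rowSums(sweep(ct$nodes, 2, c(50, 50))^2))
  expect_equal(r, rep(10, 8), tolerance = 1e-12)
  ang <- atan2(ct$nodes[, 2] - 50, ct$nodes[, 1] - 50)
  expect_equal(diff(ang[1:5]), rep(pi / 4, 4), tolerance = 1e-12)
  # shoelace sign positive = counter-clockwise
  p <- ct$nodes; q <- p[c(2:8, 1), ]
  expect_gt(sum(p[, 1] * q[, 2] - q[, 1] * p[, 2]), 0)
  # sizing rule: spacing about 2 * s_min
  ct2 <- init_circle(c(0, 0), 10, s_min = 3)
  expect_equal(nrow(ct2$nodes), ceiling(2 * pi * 10 / 6))
  # polygon area of a dense circle approaches the analytic value
  ct3 <- init_circle(c(0, 0), 10, n_nodes = 64)
  expect_lt(abs(contour_area(ct3) - pi * 100) / (pi * 100), 0.005)
})

test_that("node energy reduces to the printed terms in raw mode", {
  grad <- matrix(0, 20, 20)
  ct <- snake_contour(rbind(c(10, 10), c(13, 10), c(13, 13), c(10, 13)))
  prev <- snake_contour(rbind(c(2, 10), c(2, 13), c(4, 12)))
  # deviation only: nearest previous node at distance 2 -> delta * 2^4
  p <- snake_params(alpha = 0, beta = 0, gamma = 0, delta = 1,
                    normalize = FALSE)
  expect_equal(node_energy(ct, 1, c(4, 10), grad, prev, p), 16)
  # without a previous contour the deviation term vanishes
  expect_equal(node_energy(ct, 1, c(4, 10), grad, NULL, p), 0)
  # continuity: squared forward difference to the next node
  p2 <- snake_params(alpha = 1, beta = 0, gamma = 0, delta = 0,
                     normalize = FALSE)
  expect_equal(node_energy(ct, 1, c(10, 10), grad, NULL, p2), 9) # |13-10|^2
  # curvature: squared second difference
  p3 <- snake_params(alpha = 0, beta = 1, gamma = 0, delta = 0,
                     normalize = FALSE)
  v <- c(10, 10)
  expect_equal(node_energy(ct, 1, v, grad, NULL, p3),
               sum((ct$nodes[2, ] - 2 * v + ct$nodes[4, ])^2))
  # out-of-bounds candidates can never win
  expect_equal(node_energy(ct, 1, c(-5, 10), grad, NULL, p2), Inf)
})

test_that("uniform images leave the choice to the internal terms", {
  grad <- gradient_image(matrix(42, 30, 30))
  expect_true(all(grad == 0))
  ct <- init_circle(c(15, 15), 5, n_nodes = 8)
  p_only_ext <- snake_params(alpha = 0, beta = 0, gamma = 2, delta = 0)
  # with only the external term on a featureless image, nothing moves
  expect_equal(greedy_iterate(ct, grad, NULL, p_only_ext)$moved, 0)
})

test_that("greedy pass is a fixed point on a strong closed edge", {
  # square ridge of gradient with the contour exactly on it
  grad <- matrix(0, 41, 41)
  ring <- abs(pmax(abs(row(grad) - 21), abs(col(grad) - 21)) - 10) == 0
  grad[ring] <- 100
  nodes <- rbind(c(10, 10), c(10, 16), c(10, 22), c(10, 28),
                 c(16, 30), c(22, 30), c(28, 30),
                 c(30, 24), c(30, 18), c(30, 12),
                 c(24, 10), c(18, 10))
  ct <- snake_contour(nodes)
  p <- snake_params(alpha = 0, beta = 0, gamma = 1.5, delta = 0)
  st <- greedy_iterate(ct, grad, NULL, p)
  expect_equal(st$moved, 0)
  expect_equal(st$contour$nodes, nodes)
})

test_that("nodes climb a gradient ramp by one pixel per pass", {
  grad <- matrix(rep(seq_len(30), 30), 30)   # increases along first index
  ct <- snake_contour(rbind(c(10, 10), c(10, 15), c(10, 20)))
  p <- snake_params(alpha = 0, beta = 0, gamma = 1, delta = 0)
  st <- greedy_iterate(ct, grad, NULL, p)
  expect_equal(st$moved, 3)
  expect_equal(st$contour$nodes[, 1], c(11, 11, 11))  # straight up-gradient
  expect_equal(st$contour$nodes[, 2], c(10, 15, 20))  # tie-break: no drift
})

test_that("after convergence no window candidate beats the chosen node", {
  set.seed(5)
  grad <- matrix(runif(50 * 50, 0, 100), 50)
  prev <- init_circle(c(25, 25), 8, n_nodes = 10)
  ct <- init_circle(c(25, 25), 7, n_nodes = 10)
  p <- snake_params(alpha = 0.1, beta = 0.1, gamma = 1, delta = 0.01,
                    normalize = FALSE)
  for (it in 1:200) {
    st <- greedy_iterate(ct, grad, prev, p)
    ct <- st$contour
    if (st$moved == 0) break
  }
  expect_equal(st$moved, 0)
  offs <- vtseg:::.window_offsets(p$window)
  for (i in seq_len(nrow(ct$nodes))) {
    e0 <- node_energy(ct, i, ct$nodes[i, ], grad, prev, p)
    for (j in seq_len(nrow(offs))) {
      e <- node_energy(ct, i, ct$nodes[i, ] + offs[j, ], grad, prev, p)
      expect_gte(e, e0 - 1e-12)
    }
  }
})

test_that("node resampling enforces the spacing bounds", {
  p <- snake_params(s_min = 3, s_max = 12)
  # a 13 px edge is split at its midpoint
  ct <- snake_contour(rbind(c(0, 0), c(13, 0), c(13, 9), c(0, 9)))
  out <- resample_nodes(ct, p)
  expect_true(any(apply(out$nodes, 1, function(v)
    isTRUE(all.equal(v, c(6.5, 0))))))
  # a 2 px pair loses its second node
  ct2 <- snake_contour(rbind(c(0, 0), c(2, 0), c(8, 0), c(4, 6)))
  out2 <- resample_nodes(ct2, p)
  expect_equal(nrow(out2$nodes), 3)
  expect_false(any(out2$nodes[, 1] == 2 & out2$nodes[, 2] == 0))
  # a compliant contour is untouched
  ct3 <- init_circle(c(0, 0), 10, n_nodes = 12)
  expect_equal(resample_nodes(ct3, p)$nodes, ct3$nodes)
  # property: spacings end within bounds (or the 3-node floor binds)
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(4:40, 1)
    ct <- snake_contour(cbind(cumsum(runif(n, 0.5, 20)), runif(n, 0, 30)))
    out <- resample_nodes(ct, p)
    m <- nrow(out$nodes)
    sp <- sqrt(rowSums((out$nodes[c(2:m, 1), ] - out$nodes)^2))
    expect_true(all(sp <= p$s_max + 1e-9))
    expect_true(m == 3 || all(sp >= p$s_min - 1e-9))
  }
})

test_that("the snake converges onto a disk boundary within one pixel", {
  img <- disk_image(n = 128, radius = 23)
  ct <- init_circle(c(63.5, 63.5), 6, s_min = 3)
  res <- segment_slice(img, ct, params = snake_params())
  r <- sqrt(rowSums(sweep(res$nodes, 2, c(63.5, 63.5))^2))
  expect_true(all(abs(r - 23) <= 1.5))
  expect_lt(abs(contour_area(res) - pi * 23^2) / (pi * 23^2), 0.05)
  # radius of the contour grows monotonically until the edge
  ct2 <- init_circle(c(63.5, 63.5), 6, s_min = 3)
  g <- gradient_image(img)
  p <- snake_params()
  rmean <- numeric(0)
  for (it in 1:30) {
    st <- greedy_iterate(ct2, g, NULL, p)
    ct2 <- resample_nodes(st$contour, p)
    rmean <- c(rmean,
               mean(sqrt(rowSums(sweep(ct2$nodes, 2, c(63.5, 63.5))^2))))
    if (st$moved == 0) break
  }
  growing <- rmean[rmean < 21]
  expect_true(all(diff(growing) > -1e-9))
})

test_that("iteration cap and convergence reporting behave as stated", {
  img <- disk_image(n = 64, radius = 15)
  ct <- init_circle(c(31.5, 31.5), 5, s_min = 3)
  res1 <- segment_slice(img, ct, params = snake_params(max_iter = 1))
  expect_equal(attr(res1, "iterations"), 1L)
  # an already-converged contour returns after its first no-move pass
  grad <- matrix(0, 41, 41)
  ring <- abs(pmax(abs(row(grad) - 21), abs(col(grad) - 21)) - 10) == 0
  grad[ring] <- 100
  nodes <- rbind(c(10, 16), c(10, 22), c(16, 30), c(22, 30), c(30, 24),
                 c(30, 18), c(24, 10), c(18, 10))
  p <- snake_params(alpha = 0, beta = 0, gamma = 1, delta = 0)
  res2 <- segment_slice(matrix(0, 41, 41), snake_contour(nodes),
                        params = p, grad = grad)
  expect_equal(attr(res2, "iterations"), 1L)
  expect_true(attr(res2, "converged"))
})

test_that("segmentation is deterministic", {
  img <- disk_image(n = 64, radius = 15)
  ct <- init_circle(c(31.5, 31.5), 5, s_min = 3)
  r1 <- segment_slice(img, ct, params = snake_params())
  r2 <- segment_slice(img, ct, params = snake_params())
  expect_identical(r1$nodes, r2$nodes)
})

test_that("stack propagation recovers a straight cylinder", {
  ph <- small_cylinder(shape = c(48L, 48L, 26L), radius = 7,
                       noise_sd = 2, blur_sd = 0.5)
  stack <- anisotropic_diffusion(ph$stack, 5, 10, 0.2)
  xs <- resample_cross_sections(stack, ph$spline, step_mm = 1.04,
                                size_px = 61, pixel_size_mm = 0.5)
  cs <- segment_stack(xs, c(30, 30), snake_params())
  expect_equal(sum(cs$failed), 0)
  af <- area_function(cs)
  inner <- 3:(length(af$areas) - 2)     # clear of the volume faces
  expect_true(all(abs(af$areas[inner] - pi * 49) / (pi * 49) < 0.1))
})

test_that("overrides replace slices verbatim and masks forbid regions", {
  ph <- small_cylinder(shape = c(40L, 40L, 16L), radius = 6, noise_sd = 0)
  xs <- resample_cross_sections(ph$stack, ph$spline, step_mm = 2,
                                size_px = 49, pixel_size_mm = 0.5)
  manual <- init_circle(c(24, 24), 4, n_nodes = 12)
  cs <- segment_stack(xs, c(24, 24), snake_params(),
                      overrides = list("3" = manual))
  expect_equal(cs$contours[[3]]$nodes, manual$nodes)
  # forbidden mask outside radius 8 px confines the contour
  d <- dim(xs$images[[1]])
  ctr <- (d[1] - 1) / 2
  mask <- sqrt((row(xs$images[[1]]) - 1 - ctr)^2 +
               (col(xs$images[[1]]) - 1 - ctr)^2) > 8
  cs2 <- segment_stack(xs, c(24, 24), snake_params(), mask = mask)
  for (ct in cs2$contours) {
    r <- sqrt(rowSums(sweep(ct$nodes, 2, c(ctr, ctr))^2))
    expect_true(all(r <= 8 + 1))
  }
})

test_that("strong inter-slice coupling locks consecutive contours together", {
  img <- disk_image(n = 96, radius = 18)
  ct <- init_circle(c(47.5, 47.5), 6, s_min = 3)
  first <- segment_slice(img, ct, params = snake_params())
  p <- snake_params(delta = 25)
  nxt <- segment_slice(img, snake_contour(first$nodes), prev = first,
                       params = p)
  # symmetric Hausdorff distance below one pixel
  dab <- vtseg:::.dist_to_prev(nxt$nodes, first$nodes)
  dba <- vtseg:::.dist_to_prev(first$nodes, nxt$nodes)
  expect_lt(max(c(dab, dba)), 1)
})

test_that("contours survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  cts <- list(init_circle(c(10, 10), 5, n_nodes = 7, slice_index = 1L),
              init_circle(c(12, 12), 6, n_nodes = 9, slice_index = 4L))
  write_contours(cts, path, pixel_size_mm = 0.35)
  back <- read_contours(path)
  expect_named(back, c("1", "4"))
  expect_equal(back[["4"]]$nodes, cts[[2]]$nodes)
})
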