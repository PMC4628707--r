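#' Specification of a synthetic curved-tube phantom
#'
#' Describes an image stack containing a tube of known geometry: a
#' centerline (straight, circular arc, or user-supplied spline nodes), a
#' radius profile along arc length, lumen/wall intensities, Gaussian border
#' blur emulating partial-volume softening, and additive Gaussian noise.
#' The defaults describe the reference test object used throughout the
#' package: a 128^3 voxel stack at 1 mm spacing holding an 8 mm tube bent
#' along a 40 mm-radius quarter arc, dark lumen in a bright wall (air is
#' dark in MRI), 0.5 mm border blur, and noise at 5% of the lumen/wall
#' contrast.
#'
#' @param centerline_kind `"arc"`, `"straight"`, or `"spline-nodes"`.
#' @param radius_mm tube radius (mm); start radius for varying profiles.
#' @param radius_profile `"constant"`, `"linear-taper"`, or `"sinusoidal"`.
#' @param radius_end_mm end radius for the linear taper.
#' @param sin_amp_mm,sin_cycles amplitude (mm) and cycle count of the
#'   sinusoidal profile.
#' @param curvature_radius_mm arc radius of the `"arc"` centerline (mm).
#' @param arc_span_deg angular span of the arc (degrees).
#' @param nodes n x 3 node matrix for `"spline-nodes"` (world mm).
#' @param lumen,wall intensities inside and outside the tube (distinct).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param blur_sd border smoothing standard deviation (mm).
#' @param shape voxel grid size, length 3.
#' @param spacing voxel spacing (mm), length 3.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(centerline_kind = c("arc", "straight",
                                             "spline-nodes"),
                         radius_mm = 8, radius_profile = c("constant",
                                                           "linear-taper",
                                                           "sinusoidal"),
                         radius_end_mm = radius_mm, sin_amp_mm = 1,
                         sin_cycles = 2, curvature_radius_mm = 40,
                         arc_span_deg = 90, nodes = NULL,
                         lumen = 0, wall = 100, noise_sd = 5,
                         blur_sd = 0.5, shape = c(128L, 128L, 128L),
                         spacing = c(1, 1, 1)) {
  centerline_kind <- match.arg(centerline_kind)
  radius_profile <- match.arg(radius_profile)
  shape <- rep_len(as.integer(shape), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(shape < 8L)) stop("grid too small", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (lumen == wall)
    stop("lumen and wall intensities must be distinct", call. = FALSE)
  rmin <- min(radius_mm, radius_end_mm,
              if (radius_profile == "sinusoidal") radius_mm - sin_amp_mm
              else radius_mm)
  if (rmin <= 2 * max(spacing))
    stop("tube radius must exceed twice the voxel spacing everywhere ",
         "(unresolvable lumen)", call. = FALSE)
  if (centerline_kind == "spline-nodes" && is.null(nodes))
    stop("spline-nodes phantom requires nodes", call. = FALSE)
  structure(list(centerline_kind = centerline_kind, radius_mm = radius_mm,
                 radius_profile = radius_profile,
                 radius_end_mm = radius_end_mm, sin_amp_mm = sin_amp_mm,
                 sin_cycles = sin_cycles,
                 curvature_radius_mm = curvature_radius_mm,
                 arc_span_deg = arc_span_deg, nodes = nodes,
                 lumen = lumen, wall = wall, noise_sd = noise_sd,
                 blur_sd = blur_sd, shape = shape, spacing = spacing),
            class = "phantom_spec")
}

# evaluate expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.radius_fn <- function(spec, total_len) {
  r0 <- spec$radius_mm
  switch(spec$radius_profile,
         constant = function(s) rep(r0, length(s)),
         `linear-taper` = function(s)
           r0 + (spec$radius_end_mm - r0) * pmin(pmax(s / total_len, 0), 1),
         sinusoidal = function(s)
           r0 + spec$sin_amp_mm *
             sin(2 * pi * spec$sin_cycles * pmin(pmax(s / total_len, 0), 1)))
}

# separable Gaussian blur with replicated edges; sigma in mm
.gaussian_blur3 <- function(vox, sigma_mm, spacing) {
  for (axis in 1:3) {
    sv <- sigma_mm / spacing[axis]
    if (sv <= 0) next
    h <- max(1L, ceiling(3 * sv))
    w <- exp(-((-h:h)^2) / (2 * sv^2))
    w <- w / sum(w)
    acc <- 0
    for (j in seq_along(w)) acc <- acc + w[j] * .axshift(vox, axis, j - h - 1L)
    vox <- acc
  }
  vox
}

#' Generate a synthetic tube phantom with analytic ground truth
#'
#' Builds the voxel stack described by a [phantom_spec()]: intensity is the
#' lumen value where the distance to the centerline is below the local tube
#' radius and the wall value outside, then the border is blurred and seeded
#' Gaussian noise added. The returned centerline spline (fitted through
#' landmark nodes on the analytic curve, the way an operator would place
#' them) and the analytic area function are the ground truth for the
#' segmentation pipeline. Deterministic for a given `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the noise generator.
#' @param truth_step_mm arc-length sampling step of the returned analytic
#'   area function.
#' @return list with `stack` (an [image_stack()]), `spline` (a
#'   [fit_spline()] through the landmark `nodes`), `truth` (an
#'   `area_function` with the analytic areas), `radius_at` (function of arc
#'   length, mm), `length_mm`, and `nodes`.
#' @export
generate_phantom <- function(spec, seed = 0L, truth_step_mm = 1.04) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  ext <- (d - 1) * sp
  nvox <- prod(d)
  xv <- rep(seq_len(d[1]) - 1, times = d[2] * d[3]) * sp[1]
  yv <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]) * sp[2]
  zv <- rep(seq_len(d[3]) - 1, each = d[1] * d[2]) * sp[3]
  margin <- 2 * spec$blur_sd

  if (spec$centerline_kind == "straight") {
    cx <- ext[1] / 2; cy <- ext[2] / 2
    total_len <- ext[3]
    rfun <- .radius_fn(spec, total_len)
    rmax <- max(rfun(seq(0, total_len, length.out = 101)))
    if (cx - rmax - margin < 0 || cy - rmax - margin < 0)
      stop("tube exits the grid", call. = FALSE)
    dist <- sqrt((xv - cx)^2 + (yv - cy)^2)
    s <- zv
    landmarks <- cbind(cx, cy, seq(0, total_len, length.out = 5))
  } else if (spec$centerline_kind == "arc") {
    R <- spec$curvature_radius_mm
    span <- spec$arc_span_deg * pi / 180
    cy <- ext[2] / 2
    ox <- ext[1] / 2 - R / 2
    oz <- ext[3] / 2 - R / 2
    total_len <- R * span
    rfun <- .radius_fn(spec, total_len)
    th_dense <- seq(0, span, length.out = 181)
    cl <- cbind(ox + R * cos(th_dense), cy, oz + R * sin(th_dense))
    rmax <- max(rfun(R * th_dense))
    lo <- apply(cl, 2L, min) - rmax - margin
    hi <- apply(cl, 2L, max) + rmax + margin
    if (any(lo < 0) || any(hi > ext)) stop("tube exits the grid",
                                           call. = FALSE)
    rho <- sqrt((xv - ox)^2 + (zv - oz)^2)
    th <- atan2(zv - oz, xv - ox)
    s <- pmin(pmax(R * th, 0), total_len)
    dist <- sqrt((rho - R)^2 + (yv - cy)^2)
    inr <- th >= 0 & th <= span
    if (!all(inr)) {   # beyond the arc ends: spherical caps at endpoints
      e0 <- c(ox + R, cy, oz)
      e1 <- c(ox + R * cos(span), cy, oz + R * sin(span))
      d0 <- sqrt((xv - e0[1])^2 + (yv - e0[2])^2 + (zv - e0[3])^2)
      d1 <- sqrt((xv - e1[1])^2 + (yv - e1[2])^2 + (zv - e1[3])^2)
      dist[!inr] <- pmin(d0, d1)[!inr]
    }
    n_nodes <- max(5L, ceiling(spec$arc_span_deg / 15) + 1L)
    th_n <- seq(0, span, length.out = n_nodes)
    landmarks <- cbind(ox + R * cos(th_n), cy, oz + R * sin(th_n))
  } else {   # spline-nodes: distance by dense sampling with local boxes
    spl <- fit_spline(spec$nodes)
    total_len <- arc_length(spl)
    rfun <- .radius_fn(spec, total_len)
    ds <- min(sp) / 2
    ns <- max(2L, ceiling(total_len / ds) + 1L)
    svals <- seq(0, total_len, length.out = ns)
    seg_lengths <- vapply(seq_len(nrow(spl$a0)),
                          function(i) .segment_length(spl, i), 0.0)
    pts <- t(vapply(svals, function(si) {
      p <- .arc_to_param(spl, si, seg_lengths)
      drop(spline_eval(spl, p$segment, p$t, 0L))
    }, numeric(3)))
    rmax <- max(rfun(svals))
    if (any(apply(pts, 2L, min) - rmax - margin < 0) ||
        any(apply(pts, 2L, max) + rmax + margin > ext))
      stop("tube exits the grid", call. = FALSE)
    dist2 <- rep(Inf, nvox)
    s <- rep(0, nvox)
    box <- rmax + margin + min(sp)
    for (j in seq_len(ns)) {
      ir <- lapply(1:3, function(a) {
        lo <- max(0L, floor((pts[j, a] - box) / sp[a]))
        hi <- min(d[a] - 1L, ceiling((pts[j, a] + box) / sp[a]))
        lo:hi
      })
      li <- as.vector(outer(outer(ir[[1]] + 1L, ir[[2]] * d[1], "+"),
                            ir[[3]] * d[1] * d[2], "+"))
      dd <- (xv[li] - pts[j, 1])^2 + (yv[li] - pts[j, 2])^2 +
            (zv[li] - pts[j, 3])^2
      upd <- dd < dist2[li]
      dist2[li[upd]] <- dd[upd]
      s[li[upd]] <- svals[j]
    }
    dist <- sqrt(dist2)
    landmarks <- spec$nodes
  }

  dimnames(landmarks) <- NULL
  vox <- ifelse(dist < rfun(s), spec$lumen, spec$wall)
  dim(vox) <- d
  if (spec$blur_sd > 0) vox <- .gaussian_blur3(vox, spec$blur_sd, sp)
  if (spec$noise_sd > 0)
    vox <- vox + .with_seed(seed,
                            array(stats::rnorm(nvox, 0, spec$noise_sd), d))
  stack <- image_stack(vox, sp)
  spline <- fit_spline(landmarks)
  truth_pos <- seq(0, total_len, by = truth_step_mm)
  truth <- structure(list(positions = truth_pos,
                          areas = pi * rfun(truth_pos)^2,
                          step_mm = truth_step_mm),
                     class = "area_function", interpolated = integer(0))
  list(stack = stack, spline = spline, truth = truth, radius_at = rfun,
       length_mm = total_len, nodes = landmarks)
}
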