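#' Piecewise-cubic centerline through landmark nodes
#'
#' Interpolates an ordered list of user-defined 3-D landmark points with one
#' cubic per segment, `c_i(t) = a3 t^3 + a2 t^2 + a1 t + a0`, `t in [0, 1]`.
#' Coefficients are fixed by the node positions at `t = 0, 1` and by
#' equalizing first derivatives at shared nodes (C1 continuity). Node
#' tangents are Catmull-Rom finite differences, `(P[i+1] - P[i-1]) / 2`, with
#' one-sided differences at the ends, so the fit is local and needs no global
#' solve.
#'
#' @param nodes n x 3 matrix (or list of length-3 vectors) of world
#'   coordinates in mm, ordered along the structure; n >= 2, consecutive
#'   nodes distinct.
#' @return An object of class `centerline_spline` with fields `nodes` and the
#'   per-segment coefficient arrays `a0 .. a3` (each `(n-1) x 3`).
#' @examples
#' sp <- fit_spline(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
#' spline_eval(sp, segment = 1, t = 0.5)
#' @export
fit_spline <- function(nodes) {
  if (is.list(nodes)) nodes <- do.call(rbind, lapply(nodes, as.numeric))
  nodes <- matrix(as.numeric(nodes), ncol = 3L)
  n <- nrow(nodes)
  if (n < 2L) stop("need at least 2 centerline nodes", call. = FALSE)
  if (any(!is.finite(nodes))) stop("nodes must be finite", call. = FALSE)
  seg <- diff(nodes)
  if (any(sqrt(rowSums(seg^2)) == 0))
    stop("duplicate consecutive centerline nodes", call. = FALSE)
  # Catmull-Rom tangents, one-sided at the ends
  m <- matrix(0, n, 3L)
  m[1, ] <- nodes[2, ] - nodes[1, ]
  m[n, ] <- nodes[n, ] - nodes[n - 1, ]
  if (n > 2L) m[2:(n - 1), ] <- (nodes[3:n, ] - nodes[1:(n - 2), ]) / 2
  d <- seg                                    # P[i+1] - P[i], per segment
  mi <- m[-n, , drop = FALSE]                 # tangent at segment start
  mo <- m[-1, , drop = FALSE]                 # tangent at segment end
  structure(list(nodes = nodes,
                 a0 = nodes[-n, , drop = FALSE],
                 a1 = mi,
                 a2 = 3 * d - 2 * mi - mo,
                 a3 = -2 * d + mi + mo),
            class = "centerline_spline")
}

#' @export
print.centerline_spline <- function(x, ...) {
  cat(sprintf("<centerline_spline> %d nodes, %d cubic segments, length %.2f mm\n",
              nrow(x$nodes), nrow(x$nodes) - 1L, arc_length(x)))
  invisible(x)
}

#' Evaluate a centerline spline or its derivatives
#'
#' @param spline a [fit_spline()] result.
#' @param segment segment index (1-based), vectorized.
#' @param t parameter in \[0, 1\] within the segment, vectorized.
#' @param deriv 0 (position), 1 or 2 (derivatives with respect to `t`).
#' @return n x 3 matrix of points (mm) or derivative vectors.
#' @export
spline_eval <- function(spline, segment, t, deriv = 0L) {
  stopifnot(inherits(spline, "centerline_spline"))
  n <- max(length(segment), length(t))
  segment <- rep_len(as.integer(segment), n)
  t <- rep_len(as.numeric(t), n)
  if (any(segment < 1L | segment > nrow(spline$a0)))
    stop("segment index out of range", call. = FALSE)
  a0 <- spline$a0[segment, , drop = FALSE]
  a1 <- spline$a1[segment, , drop = FALSE]
  a2 <- spline$a2[segment, , drop = FALSE]
  a3 <- spline$a3[segment, , drop = FALSE]
  if (deriv == 0L) a3 * t^3 + a2 * t^2 + a1 * t + a0
  else if (deriv == 1L) 3 * a3 * t^2 + 2 * a2 * t + a1
  else if (deriv == 2L) 6 * a3 * t + 2 * a2
  else stop("deriv must be 0, 1 or 2", call. = FALSE)
}

# speed of the parameterization ||c'(t)|| on one segment, vectorized in t
.spline_speed <- function(spline, segment, t) {
  d1 <- spline_eval(spline, segment, t, deriv = 1L)
  sqrt(rowSums(d1^2))
}

.segment_length <- function(spline, segment, upto = 1) {
  if (upto <= 0) return(0)
  stats::integrate(function(t) .spline_speed(spline, segment, t),
                   0, upto, rel.tol = 1e-9, abs.tol = 0,
                   subdivisions = 200L)$value
}

#' Total arc length of a centerline spline
#'
#' Adaptive Gauss-Kronrod quadrature of the parameter speed on each segment.
#'
#' @param spline a [fit_spline()] result.
#' @return length in mm (relative error < 1e-6).
#' @export
arc_length <- function(spline) {
  stopifnot(inherits(spline, "centerline_spline"))
  sum(vapply(seq_len(nrow(spline$a0)),
             function(i) .segment_length(spline, i), 0.0))
}

# Map an arc-length position s (mm from the spline start) to (segment, t).
.arc_to_param <- function(spline, s, seg_lengths = NULL) {
  if (is.null(seg_lengths))
    seg_lengths <- vapply(seq_len(nrow(spline$a0)),
                          function(i) .segment_length(spline, i), 0.0)
  ends <- cumsum(seg_lengths)
  total <- ends[length(ends)]
  s <- min(max(s, 0), total)
  seg <- which(s <= ends + 1e-12)[1]
  s0 <- if (seg > 1L) ends[seg - 1L] else 0
  target <- s - s0
  if (target <= 0) return(list(segment = seg, t = 0))
  if (target >= seg_lengths[seg]) return(list(segment = seg, t = 1))
  f <- function(t) .segment_length(spline, seg, t) - target
  t <- stats::uniroot(f, c(0, 1), tol = 1e-10)$root
  list(segment = seg, t = t)
}

#' Local slice frame of the centerline
#'
#' Builds the orthonormal frame used to orient a cross-section plane: the
#' slice z-axis is the unit tangent, the x-axis the unit binormal
#' `(c' x c'') / ||c' x c''||`, and the y-axis the negated unit normal (so
#' that in-plane axes form a right-handed triad with the tangent; the
#' negation absorbs the left-handed raster convention of image stacks). Where
#' the curve is locally straight (`||c' x c''||` below `eps * ||c'||^2`) the
#' binormal is undefined and the frame is parallel-transported from `prev`;
#' a straight start with no `prev` uses a fixed arbitrary perpendicular.
#' When `prev` is given, the binormal sign minimizing the angle to the
#' previous x-axis is chosen, preventing 180-degree frame flips between
#' adjacent slices.
#'
#' @param spline a [fit_spline()] result.
#' @param segment segment index (1-based).
#' @param t parameter in \[0, 1\].
#' @param prev optional previous `slice_frame` for parallel transport and
#'   sign continuity.
#' @param eps relative degeneracy threshold.
#' @return A `slice_frame`: fields `origin`, `axis_x`, `axis_y`, `axis_z`
#'   (unit 3-vectors) and `affine`, the 4 x 4 matrix whose columns map
#'   in-plane mm coordinates to world mm.
#' @export
frenet_frame <- function(spline, segment, t, prev = NULL, eps = 1e-8) {
  origin <- drop(spline_eval(spline, segment, t, 0L))
  d1 <- drop(spline_eval(spline, segment, t, 1L))
  d2 <- drop(spline_eval(spline, segment, t, 2L))
  speed <- sqrt(sum(d1^2))
  if (speed == 0)
    stop("degenerate curve: zero tangent at query point", call. = FALSE)
  tz <- d1 / speed
  b <- .cross3(d1, d2)
  bn <- sqrt(sum(b^2))
  if (bn < eps * speed^2) {
    ax <- .transport_x(tz, prev)
  } else {
    ax <- b / bn
    if (!is.null(prev) && sum(ax * prev$axis_x) < 0) ax <- -ax
  }
  ay <- .cross3(tz, ax)  # = -(Frenet normal) when ax is the unit binormal
  slice_frame(origin, ax, ay, tz)
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# x-axis for a degenerate (straight) region: project the previous x-axis
# into the plane normal to the new tangent; without a previous frame, use a
# fixed perpendicular to the tangent.
.transport_x <- function(tz, prev) {
  if (!is.null(prev)) {
    for (cand in list(prev$axis_x, prev$axis_y)) {
      x <- cand - sum(cand * tz) * tz
      if (sqrt(sum(x^2)) > 1e-8) return(x / sqrt(sum(x^2)))
    }
  }
  e <- c(0, 0, 0)
  e[which.min(abs(tz))] <- 1
  x <- e - sum(e * tz) * tz
  x / sqrt(sum(x^2))
}

#' Construct a slice frame from origin and axes
#'
#' @param origin 3-vector, world mm.
#' @param axis_x,axis_y,axis_z orthonormal unit 3-vectors (checked to 1e-9).
#' @return A `slice_frame` with the 4 x 4 affine whose columns are
#'   `axis_x, axis_y, axis_z, origin`.
#' @export
slice_frame <- function(origin, axis_x, axis_y, axis_z) {
  A <- cbind(axis_x, axis_y, axis_z)
  if (max(abs(crossprod(A) - diag(3))) > 1e-9)
    stop("slice frame axes are not orthonormal", call. = FALSE)
  affine <- rbind(cbind(A, origin), c(0, 0, 0, 1))
  dimnames(affine) <- NULL
  structure(list(origin = as.numeric(origin), axis_x = as.numeric(axis_x),
                 axis_y = as.numeric(axis_y), axis_z = as.numeric(axis_z),
                 affine = affine),
            class = "slice_frame")
}

#' Place slice frames at equal arc-length steps along a spline
#'
#' Frames are positioned at `s = 0, step_mm, 2 step_mm, ...` up to the total
#' arc length (so `floor(L / step_mm) + 1` frames), each oriented by
#' [frenet_frame()] with the previous frame passed for parallel transport and
#' sign continuity.
#'
#' @param spline a [fit_spline()] result.
#' @param step_mm center-to-center distance between frames (mm), > 0.
#' @return list of `slice_frame` objects.
#' @export
frames_along <- function(spline, step_mm) {
  if (!is.numeric(step_mm) || step_mm <= 0)
    stop("step_mm must be positive", call. = FALSE)
  seg_lengths <- vapply(seq_len(nrow(spline$a0)),
                        function(i) .segment_length(spline, i), 0.0)
  total <- sum(seg_lengths)
  positions <- seq(0, total, by = step_mm)
  frames <- vector("list", length(positions))
  prev <- NULL
  for (i in seq_along(positions)) {
    p <- .arc_to_param(spline, positions[i], seg_lengths)
    frames[[i]] <- frenet_frame(spline, p$segment, p$t, prev = prev)
    prev <- frames[[i]]
  }
  frames
}

#' Resample an image stack into centerline-orthogonal cross sections
#'
#' Curved planar reformation: places frames at fixed arc-length spacing along
#' the centerline and samples the stack trilinearly on a square in-plane grid
#' in each frame, producing one true cross-section image per frame. Pixel
#' `(u, v)` (0-based) of an image lies at world position
#' `origin + (u - cx) * pixel_size * axis_x + (v - cy) * pixel_size * axis_y`
#' with `(cx, cy)` the image center `(size_px - 1) / 2`; for odd `size_px`
#' the central pixel therefore samples the stack exactly at the centerline
#' point. Samples outside the stack take the fill value 0.
#'
#' @param stack an [image_stack()].
#' @param spline a [fit_spline()] result, in the stack's world coordinates.
#' @param step_mm distance between section centers along the curve (mm).
#' @param size_px side of the square section image in pixels.
#' @param pixel_size_mm in-plane sample spacing of the section images (mm).
#' @return A `cross_section_stack`: `images` (list of `size_px` x `size_px`
#'   matrices, first index along `axis_x`), `frames` (matching
#'   `slice_frame`s), `pixel_size`, `step`.
#' @export
resample_cross_sections <- function(stack, spline, step_mm = 1.04,
                                    size_px = 97L, pixel_size_mm = 0.35) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(spline, "centerline_spline"))
  if (!is.numeric(step_mm) || step_mm <= 0)
    stop("step_mm must be positive", call. = FALSE)
  if (size_px < 1L || pixel_size_mm <= 0)
    stop("size_px and pixel_size_mm must be positive", call. = FALSE)
  frames <- frames_along(spline, step_mm)
  ctr <- (size_px - 1) / 2
  off <- (seq_len(size_px) - 1 - ctr) * pixel_size_mm
  uu <- rep(off, times = size_px)   # first image index, along axis_x
  vv <- rep(off, each = size_px)    # second image index, along axis_y
  images <- lapply(frames, function(fr) {
    pts <- cbind(fr$origin[1] + uu * fr$axis_x[1] + vv * fr$axis_y[1],
                 fr$origin[2] + uu * fr$axis_x[2] + vv * fr$axis_y[2],
                 fr$origin[3] + uu * fr$axis_x[3] + vv * fr$axis_y[3])
    matrix(sample_world(stack, pts), size_px, size_px)
  })
  structure(list(images = images, frames = frames,
                 pixel_size = pixel_size_mm, step = step_mm),
            class = "cross_section_stack")
}

#' @export
print.cross_section_stack <- function(x, ...) {
  cat(sprintf("<cross_section_stack> %d sections of %d x %d px (%.3g mm/px), step %.3g mm\n",
              length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
              x$pixel_size, x$step))
  invisible(x)
}

#' Convert between slice pixel coordinates and world coordinates
#'
#' `slice_to_world` maps 0-based in-plane pixel coordinates `(u, v)` of a
#' cross-section image to world mm via the frame affine; `world_to_slice` is
#' its exact inverse for in-plane points.
#'
#' @param frame a `slice_frame`.
#' @param uv n x 2 matrix of pixel coordinates.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @param size_px side of the section image in pixels.
#' @param pixel_size_mm in-plane pixel size (mm).
#' @return n x 3 world points, or n x 2 pixel coordinates.
#' @export
slice_to_world <- function(frame, uv, size_px, pixel_size_mm) {
  uv <- matrix(as.numeric(uv), ncol = 2L)
  ctr <- (size_px - 1) / 2
  du <- (uv[, 1] - ctr) * pixel_size_mm
  dv <- (uv[, 2] - ctr) * pixel_size_mm
  cbind(frame$origin[1] + du * frame$axis_x[1] + dv * frame$axis_y[1],
        frame$origin[2] + du * frame$axis_x[2] + dv * frame$axis_y[2],
        frame$origin[3] + du * frame$axis_x[3] + dv * frame$axis_y[3])
}

#' @rdname slice_to_world
#' @export
world_to_slice <- function(frame, xyz, size_px, pixel_size_mm) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  rel <- sweep(xyz, 2L, frame$origin)
  ctr <- (size_px - 1) / 2
  cbind(rel %*% frame$axis_x / pixel_size_mm + ctr,
        rel %*% frame$axis_y / pixel_size_mm + ctr)
}

#' Read centerline nodes from JSON
#'
#' Expects a JSON array of `[x, y, z]` world-mm triples.
#'
#' @param path JSON file path.
#' @return n x 3 numeric matrix of node coordinates.
#' @export
read_centerline_json <- function(path) {
  if (!file.exists(path))
    stop("centerline file not found: ", path, call. = FALSE)
  nodes <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(nodes)) nodes <- do.call(rbind, nodes)
  nodes <- matrix(as.numeric(nodes), ncol = 3L)
  if (nrow(nodes) < 2L)
    stop("centerline JSON must contain at least 2 [x,y,z] nodes",
         call. = FALSE)
  nodes
}

#' Export a cross-section stack as multi-page TIFF plus JSON sidecar
#'
#' The sidecar records the pixel size, step, and every frame's origin and
#' axes, so the geometry can be reassociated with the pages.
#'
#' @param xsecs a `cross_section_stack`.
#' @param path output `.tif` path; the sidecar goes to `<path>.frames.json`.
#' @return `path`, invisibly.
#' @export
write_cross_sections <- function(xsecs, path) {
  stopifnot(inherits(xsecs, "cross_section_stack"))
  vox <- array(unlist(xsecs$images),
               c(dim(xsecs$images[[1]]), length(xsecs$images)))
  write_stack(image_stack(vox, c(xsecs$pixel_size, xsecs$pixel_size,
                                 xsecs$step)),
              path, format = "tiff")
  meta <- list(pixel_size_mm = xsecs$pixel_size, step_mm = xsecs$step,
               frames = lapply(xsecs$frames, function(fr)
                 list(origin = fr$origin, axis_x = fr$axis_x,
                      axis_y = fr$axis_y, axis_z = fr$axis_z)))
  jsonlite::write_json(meta, paste0(path, ".frames.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
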