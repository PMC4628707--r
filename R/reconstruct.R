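#' Cross-sectional area of a closed contour
#'
#' Shoelace formula on the closed node polygon, scaled by the squared pixel
#' size; orientation-independent. A self-intersecting polygon triggers a
#' warning but the signed-area magnitude is still returned.
#'
#' @param contour a [snake_contour()].
#' @param pixel_size_mm in-plane pixel size (mm).
#' @return area in mm^2.
#' @export
contour_area <- function(contour, pixel_size_mm = 1) {
  stopifnot(inherits(contour, "snake_contour"))
  p <- contour$nodes
  n <- nrow(p)
  q <- p[c(2:n, 1L), , drop = FALSE]
  a <- abs(sum(p[, 1] * q[, 2] - q[, 1] * p[, 2])) / 2
  if (!.polygon_simple(p))
    warning("self-intersecting contour; area magnitude returned",
            call. = FALSE)
  a * pixel_size_mm^2
}

# proper-crossing test between all non-adjacent edge pairs
.polygon_simple <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(TRUE)
  q <- p[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    d1 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[js, 1], p[js, 2])
    d2 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[js, 1], q[js, 2])
    d3 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2],
                rep(p[i, 1], length(js)), rep(p[i, 2], length(js)))
    d4 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2],
                rep(q[i, 1], length(js)), rep(q[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Cross-sectional area function along the centerline
#'
#' One area per slice at arc-length position `(slice - 1) * step_mm`. Failed
#' slices (`NULL` contours) yield missing areas; a missing area flanked by
#' valid neighbours is linearly interpolated and flagged in the
#' `interpolated` attribute, otherwise it stays `NA`.
#'
#' @param contours list of [snake_contour()]s (or a `contour_set`), ordered
#'   by slice.
#' @param step_mm distance between slices along the centerline (mm).
#' @param pixel_size_mm in-plane pixel size (mm).
#' @return An `area_function`: fields `positions` (mm) and `areas` (mm^2),
#'   with attribute `interpolated` (slice indices filled by interpolation).
#' @export
area_function <- function(contours, step_mm, pixel_size_mm = 1) {
  if (inherits(contours, "contour_set")) {
    step_mm <- contours$step
    pixel_size_mm <- contours$pixel_size
    contours <- contours$contours
  }
  n <- length(contours)
  areas <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (!is.null(contours[[k]]) && !all(is.na(contours[[k]]$nodes)))
      areas[k] <- contour_area(contours[[k]], pixel_size_mm)
  }
  interpolated <- integer(0)
  miss <- which(is.na(areas))
  if (length(miss) && sum(!is.na(areas)) >= 2L) {
    ok <- which(!is.na(areas))
    fillable <- miss[miss > min(ok) & miss < max(ok)]
    if (length(fillable)) {
      areas[fillable] <- stats::approx(ok, areas[ok], xout = fillable)$y
      interpolated <- fillable
    }
  }
  structure(list(positions = (seq_len(n) - 1) * step_mm, areas = areas,
                 step_mm = step_mm),
            class = "area_function", interpolated = interpolated)
}

#' @export
print.area_function <- function(x, ...) {
  cat(sprintf("<area_function> %d slices, step %.3g mm, area %.1f-%.1f mm^2\n",
              length(x$areas), x$step_mm,
              suppressWarnings(min(x$areas, na.rm = TRUE)),
              suppressWarnings(max(x$areas, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.data.frame.area_function <- function(x, ...) {
  data.frame(position_mm = x$positions, area_mm2 = x$areas)
}

#' @export
plot.area_function <- function(x, ...) {
  graphics::plot(x$positions, x$areas, type = "l",
                 xlab = "distance along centerline (mm)",
                 ylab = expression(area ~ (mm^2)), ...)
}

#' Write an area function as CSV
#'
#' Two columns, `position_mm,area_mm2` -- directly usable as a 1-D acoustic
#' model input.
#'
#' @param af an [area_function()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_function <- function(af, path) {
  utils::write.csv(as.data.frame(af), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Volume of a centerline compartment
#'
#' Superposes slice areas over an index range: rectangle rule
#' `sum(area) * step` by default, matching a stack of slabs of thickness
#' `step`; the trapezoidal rule is available as an option. Missing areas in
#' the range are an error.
#'
#' @param af an [area_function()].
#' @param from_index,to_index 1-based slice range, `from_index <= to_index`.
#' @param method `"rectangle"` (default) or `"trapezoid"`.
#' @return volume in mm^3.
#' @export
volume_between <- function(af, from_index = 1L,
                           to_index = length(af$areas),
                           method = c("rectangle", "trapezoid")) {
  stopifnot(inherits(af, "area_function"))
  method <- match.arg(method)
  n <- length(af$areas)
  if (from_index < 1L || to_index > n)
    stop("index range out of bounds", call. = FALSE)
  if (from_index > to_index)
    stop("reversed index range: from_index must be <= to_index",
         call. = FALSE)
  a <- af$areas[from_index:to_index]
  if (any(is.na(a)))
    stop("missing areas in the requested range", call. = FALSE)
  if (method == "rectangle") return(sum(a) * af$step_mm)
  if (length(a) < 2L) return(a * af$step_mm)
  sum((a[-1] + a[-length(a)]) / 2) * af$step_mm
}

#' Transform contours back to world coordinates
#'
#' Maps each contour node `(u, v)` from its cross-section pixel coordinates
#' to world mm through the slice frame:
#' `origin + (u - cx) * pixel_size * axis_x + (v - cy) * pixel_size *
#' axis_y`, with `(cx, cy)` the image center. This inverts the resampling
#' convention of [resample_cross_sections()], so slice -> world -> slice is
#' the identity for in-plane points. Failed slices (`NULL`) yield `NULL`
#' polygons.
#'
#' @param contours list of [snake_contour()]s or a `contour_set`.
#' @param frames matching list of `slice_frame`s.
#' @param pixel_size_mm in-plane pixel size (mm).
#' @param size_px side of the cross-section images in pixels.
#' @return list of n x 3 world polygons (mm), one per slice.
#' @export
back_transform <- function(contours, frames, pixel_size_mm, size_px) {
  if (inherits(contours, "contour_set")) {
    pixel_size_mm <- contours$pixel_size
    contours <- contours$contours
  }
  if (length(contours) != length(frames))
    stop("contours and frames differ in length", call. = FALSE)
  lapply(seq_along(contours), function(k) {
    ct <- contours[[k]]
    if (is.null(ct)) return(NULL)
    slice_to_world(frames[[k]], ct$nodes, size_px, pixel_size_mm)
  })
}

# uniform arc-length resampling of a closed 3-D ring to m vertices
.resample_ring <- function(ring, m) {
  n <- nrow(ring)
  closed <- rbind(ring, ring[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[n + 1L]
  target <- total * (seq_len(m) - 1L) / m
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx <- pmin(idx, n)
  f <- (target - s[idx]) / pmax(seg[idx], 1e-300)
  closed[idx, , drop = FALSE] +
    (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE]) * f
}

.ring_normal <- function(ring) {  # Newell's method
  n <- nrow(ring)
  q <- ring[c(2:n, 1L), , drop = FALSE]
  c(sum((ring[, 2] - q[, 2]) * (ring[, 3] + q[, 3])),
    sum((ring[, 3] - q[, 3]) * (ring[, 1] + q[, 1])),
    sum((ring[, 1] - q[, 1]) * (ring[, 2] + q[, 2])))
}

#' Loft a triangle surface over a stack of world-space contours
#'
#' Rings are resampled to a common vertex count (the maximum over the
#' stack), oriented consistently, and each adjacent pair is rotationally
#' aligned by the cyclic shift minimizing the total inter-ring edge length
#' (minimal twist) before stitching with two triangles per quad. Identical
#' adjacent rings therefore connect vertex-to-vertex. Degenerate rings
#' (fewer than 3 points) are skipped with a warning; optional end caps are
#' triangle fans around the ring centroid, making the mesh watertight.
#'
#' @param world_polygons list of n x 3 matrices from [back_transform()].
#' @param caps close the tube ends with centroid fans (default `TRUE`).
#' @return A `surface_mesh`: `vertices` (v x 3, mm) and `faces` (f x 3,
#'   1-based vertex indices).
#' @export
loft_mesh <- function(world_polygons, caps = TRUE) {
  rings <- Filter(Negate(is.null), world_polygons)
  bad <- vapply(rings, function(r) nrow(r) < 3L, TRUE)
  if (any(bad)) {
    warning(sum(bad), " degenerate ring(s) skipped", call. = FALSE)
    rings <- rings[!bad]
  }
  if (length(rings) < 2L)
    stop("need at least 2 rings to loft a surface", call. = FALSE)
  m <- max(vapply(rings, nrow, 1L))
  rings <- lapply(rings, .resample_ring, m = m)
  # consistent orientation: flip rings whose normal opposes the previous one
  for (i in seq_along(rings)[-1]) {
    if (sum(.ring_normal(rings[[i]]) * .ring_normal(rings[[i - 1]])) < 0)
      rings[[i]] <- rings[[i]][c(1L, m:2L), , drop = FALSE]
  }
  # minimal-twist alignment: cyclic shift minimizing total inter-ring length
  for (i in seq_along(rings)[-1]) {
    a <- rings[[i - 1]]
    b <- rings[[i]]
    cost <- vapply(0:(m - 1L), function(s) {
      idx <- ((seq_len(m) - 1L + s) %% m) + 1L
      sum(sqrt(rowSums((a - b[idx, , drop = FALSE])^2)))
    }, 0.0)
    s <- which.min(cost) - 1L
    if (s > 0L) rings[[i]] <- b[((seq_len(m) - 1L + s) %% m) + 1L, ,
                                drop = FALSE]
  }
  nr <- length(rings)
  vertices <- do.call(rbind, rings)
  faces <- vector("list", nr - 1L)
  j2 <- c(2:m, 1L)
  for (i in seq_len(nr - 1L)) {
    a0 <- (i - 1L) * m
    b0 <- i * m
    faces[[i]] <- rbind(cbind(a0 + seq_len(m), b0 + seq_len(m), a0 + j2),
                        cbind(a0 + j2, b0 + seq_len(m), b0 + j2))
  }
  faces <- do.call(rbind, faces)
  if (caps) {
    c1 <- colMeans(rings[[1]])
    c2 <- colMeans(rings[[nr]])
    vertices <- rbind(vertices, c1, c2)
    i1 <- nrow(vertices) - 1L
    i2 <- nrow(vertices)
    last0 <- (nr - 1L) * m
    faces <- rbind(faces,
                   cbind(rep(i1, m), seq_len(m), j2),          # start cap
                   cbind(rep(i2, m), last0 + j2, last0 + seq_len(m)))
  }
  rownames(vertices) <- NULL
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem (signed tetrahedron) sum; meaningful for watertight
#' meshes such as capped lofts.
#'
#' @param mesh a `surface_mesh`.
#' @return absolute enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  det <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
         v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
         v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  abs(sum(det)) / 6
}

#' Write a surface mesh to PLY or OBJ
#'
#' Plain ASCII writers for the two common triangle-mesh interchange formats.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path; `write_mesh` picks the format from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  if (grepl("\\.obj$", path, ignore.case = TRUE)) .write_obj(mesh, path)
  else .write_ply(mesh, path)
  invisible(path)
}

.write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y",
               "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  writeLines(apply(format(mesh$vertices, trim = TRUE, digits = 17), 1L,
                   paste, collapse = " "), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v",
                   format(mesh$vertices[, 1], trim = TRUE, digits = 17),
                   format(mesh$vertices[, 2], trim = TRUE, digits = 17),
                   format(mesh$vertices[, 3], trim = TRUE, digits = 17)),
             con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
             con)
}

#' Write world-space contour polygons as JSON
#'
#' @param polygons list of n x 3 matrices from [back_transform()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_world_polygons <- function(polygons, path) {
  recs <- lapply(seq_along(polygons), function(k) {
    if (is.null(polygons[[k]])) return(list(slice = k, nodes = list()))
    list(slice = k, nodes = unname(apply(polygons[[k]], 1L, as.list)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
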