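#' Image stacks
#'
#' An `image_stack` is the carrier of all volumetric image data in vtseg: a
#' 3-D array of grayscale voxel intensities plus the physical voxel size in mm
#' along each array axis. Voxel indexing is 0-based in world terms: the world
#' coordinate (mm) of voxel `(i, j, k)` (0-based) is `(i, j, k) * spacing`,
#' right-handed. `axis_order` documents which anatomical direction each array
#' axis indexes; it is metadata only and is never used in computation.
#'
#' @param voxels 3-D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, voxel size in mm per array axis; all > 0.
#' @param axis_order character length-3 naming the anatomical direction of
#'   each array axis. Default assumes sagittal slices stacked along axis 3
#'   with an in-plane (coronal, axial) raster.
#' @return An object of class `image_stack` with fields `voxels`, `spacing`,
#'   `axis_order`.
#' @examples
#' s <- image_stack(array(0, c(4, 4, 3)), spacing = c(1.04, 1.04, 1.8))
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, spacing,
                        axis_order = c("coronal", "axial", "sagittal")) {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("voxel values must all be finite", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing,
                 axis_order = as.character(axis_order)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  intensity range [%g, %g], axes (%s)\n",
              min(x$voxels), max(x$voxels),
              paste(x$axis_order, collapse = ", ")))
  invisible(x)
}

.stack_format <- function(path, format = c("auto", "nifti", "tiff")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  stop("cannot infer stack format from path: ", path, call. = FALSE)
}

#' Read a 3-D image stack from NIfTI or multi-page TIFF
#'
#' NIfTI spacing is taken from the header (`pixdim`). TIFF carries no
#' trustworthy spacing, so it must be supplied via `spacing_mm` or found in
#' the JSON sidecar written by [write_stack()]; otherwise the read fails with
#' a configuration error.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.tif` or `.tiff` file.
#' @param format `"auto"` (by extension), `"nifti"` or `"tiff"`.
#' @param spacing_mm optional explicit voxel spacing in mm (overrides
#'   header/sidecar).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, format = c("auto", "nifti", "tiff"),
                       spacing_mm = NULL) {
  format <- .stack_format(path, format)
  if (!file.exists(path))
    stop("cannot read image stack: no such file: ", path, call. = FALSE)
  if (format == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("failed to parse NIfTI file ",
                                             path, ": ", conditionMessage(e),
                                             call. = FALSE))
    vox <- as.array(img)
    d <- dim(vox)
    if (length(d) > 3L) d <- d[1:3]
    vox <- array(as.vector(vox), d)   # shed niftiImage attributes
    sp <- if (is.null(spacing_mm)) RNifti::pixdim(img)[1:3] else spacing_mm
    return(image_stack(vox, sp))
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("failed to parse TIFF file ",
                                             path, ": ", conditionMessage(e),
                                             call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)), 1L) != 2L))
    stop("multi-channel TIFF not supported; expected grayscale pages",
         call. = FALSE)
  vox <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else NULL
  if (!is.null(meta) && !is.null(meta$intensity_range)) {
    r <- as.numeric(meta$intensity_range)
    vox <- vox * (r[2] - r[1]) + r[1]
  }
  sp <- spacing_mm
  if (is.null(sp) && !is.null(meta)) sp <- meta$spacing_mm
  if (is.null(sp))
    stop("TIFF stack has no voxel spacing: pass spacing_mm or provide a ",
         path, ".json sidecar (configuration error)", call. = FALSE)
  image_stack(vox, sp)
}

#' Write a 3-D image stack to NIfTI or multi-page TIFF
#'
#' NIfTI is written with double-precision voxels and the spacing in `pixdim`,
#' so a read/write round trip is voxel-identical. TIFF pages are 32-bit
#' samples in \[0, 1\]; intensities outside that range are linearly mapped
#' into it and the mapping, together with the spacing, is recorded in a
#' `<path>.json` sidecar that [read_stack()] undoes. A TIFF round trip is
#' exact to one part in 2^32 (the sample quantization).
#'
#' @inheritParams read_stack
#' @param stack an [image_stack()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("auto", "nifti", "tiff")) {
  stopifnot(inherits(stack, "image_stack"))
  format <- .stack_format(path, format)
  if (format == "nifti") {
    img <- RNifti::asNifti(stack$voxels)
    RNifti::pixdim(img) <- stack$spacing
    RNifti::writeNifti(img, path, datatype = "double")
    return(invisible(path))
  }
  vox <- stack$voxels
  rng <- range(vox)
  meta <- list(spacing_mm = stack$spacing)
  if (rng[1] < 0 || rng[2] > 1) {
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    vox <- (vox - rng[1]) / span
    meta$intensity_range <- c(rng[1], rng[1] + span)
  }
  pages <- lapply(seq_len(dim(vox)[3]), function(k) vox[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Shift a 3-D array by `by` voxels along `axis` with replicated (Neumann)
# edges, so boundary differences vanish.
.axshift <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Trilinear interpolation of a 3-D array at continuous 0-based voxel indices.
# `pts` is n x 3. Out-of-bounds points take `fill` unless `clamp`, in which
# case coordinates are clamped to the grid (border replication).
.trilinear <- function(vox, pts, fill = 0, clamp = FALSE) {
  d <- dim(vox)
  pts <- matrix(as.numeric(pts), ncol = 3L)
  if (clamp) {
    for (a in 1:3) pts[, a] <- pmin(pmax(pts[, a], 0), d[a] - 1L)
  }
  inside <- pts[, 1] >= 0 & pts[, 1] <= d[1] - 1L &
            pts[, 2] >= 0 & pts[, 2] <= d[2] - 1L &
            pts[, 3] >= 0 & pts[, 3] <= d[3] - 1L
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  i0 <- pmin(floor(p[, 1]), d[1] - 2L); if (d[1] == 1L) i0 <- rep(0, nrow(p))
  j0 <- pmin(floor(p[, 2]), d[2] - 2L); if (d[2] == 1L) j0 <- rep(0, nrow(p))
  k0 <- pmin(floor(p[, 3]), d[3] - 2L); if (d[3] == 1L) k0 <- rep(0, nrow(p))
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  s1 <- 1L; s2 <- d[1]; s3 <- d[1] * d[2]
  base <- 1L + i0 * s1 + j0 * s2 + k0 * s3
  dx <- if (d[1] > 1L) s1 else 0L
  dy <- if (d[2] > 1L) s2 else 0L
  dz <- if (d[3] > 1L) s3 else 0L
  v000 <- vox[base];                v100 <- vox[base + dx]
  v010 <- vox[base + dy];           v110 <- vox[base + dx + dy]
  v001 <- vox[base + dz];           v101 <- vox[base + dx + dz]
  v011 <- vox[base + dy + dz];      v111 <- vox[base + dx + dy + dz]
  out[inside] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out
}

#' Sample a stack trilinearly at world coordinates
#'
#' @param stack an [image_stack()].
#' @param points_mm n x 3 matrix of world coordinates in mm.
#' @param fill value for samples outside the voxel grid.
#' @return numeric vector of n interpolated intensities.
#' @export
sample_world <- function(stack, points_mm, fill = 0) {
  pts <- matrix(as.numeric(points_mm), ncol = 3L)
  idx <- sweep(pts, 2L, stack$spacing, "/")
  .trilinear(stack$voxels, idx, fill = fill)
}

#' Resample a stack to isotropic (cubic) voxels
#'
#' The target voxel edge is the in-plane pixel size (axis 1) divided by
#' `scale_factor`; all three axes are resampled trilinearly onto that cubic
#' grid, so after this call all spacing components are equal. The voxel count
#' along each axis is the physical extent divided by the new edge, rounded to
#' the nearest integer. Resampling uses the voxel-center convention with
#' border replication, so a constant image stays constant and `scale_factor =
#' 1` on an already-isotropic stack is the identity.
#'
#' @param stack an [image_stack()].
#' @param scale_factor positive in-plane magnification (e.g. 3.0 turns a
#'   1.04 mm pixel into a 0.3467 mm cubic voxel).
#' @return An isotropic [image_stack()].
#' @seealso [isotropy_report()] for the slice-count/pixel-size arithmetic.
#' @export
make_isotropic <- function(stack, scale_factor) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      !is.finite(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be a positive number", call. = FALSE)
  edge <- stack$spacing[1] / scale_factor
  d <- dim(stack$voxels)
  dn <- pmax(round(d * stack$spacing / edge), 1L)
  # voxel-center alignment: new center (i + .5) * edge lives in old index
  # space at ((i + .5) * edge) / s_old - .5
  ax <- lapply(1:3, function(a)
    ((seq_len(dn[a]) - 0.5) * edge) / stack$spacing[a] - 0.5)
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- .trilinear(stack$voxels, grid, clamp = TRUE)
  image_stack(array(vals, dn), rep(edge, 3), stack$axis_order)
}

#' Slice-count and pixel-size arithmetic of in-plane rescaling
#'
#' Reports the numbers implied by rescaling a slice stack by a given factor:
#' the in-plane pixel size after scaling, the image count after scaling every
#' axis by the factor (the count a slice-wise scale step produces), and the
#' number of through-plane planes once the volume is resampled to cubic
#' voxels at the scaled pixel size. For a 52-slice stack with 1.04 mm pixels
#' and 1.8 mm slice thickness at factor 3.0 this yields 156 scaled images
#' with 0.35 mm (0.3467 mm) pixels, and 270 isotropic planes.
#'
#' @param n_slices number of acquired slices.
#' @param in_plane_mm acquired in-plane pixel size (mm).
#' @param thickness_mm slice thickness (mm).
#' @param scale_factor in-plane magnification.
#' @return list with `pixel_size_mm`, `n_scaled_images`,
#'   `n_isotropic_planes`.
#' @export
isotropy_report <- function(n_slices, in_plane_mm, thickness_mm,
                            scale_factor) {
  px <- in_plane_mm / scale_factor
  list(pixel_size_mm = px,
       n_scaled_images = round(n_slices * scale_factor),
       n_isotropic_planes = round(n_slices * thickness_mm / px))
}

#' Edge-preserving anisotropic diffusion (Perona-Malik)
#'
#' Explicit scalar diffusion on the 6-connected 3-D stencil with conductance
#' `g(s) = exp(-(s / kappa)^2)` evaluated on each neighbour difference.
#' Smooths within near-homogeneous regions while preserving strong edges,
#' sharpening the air--tissue gradient that the snake's external energy
#' detects. Boundary handling is Neumann (zero flux).
#'
#' @param stack an [image_stack()].
#' @param n_iter number of iterations; 0 returns the input unchanged.
#' @param kappa conduction threshold in intensity units: differences well
#'   below `kappa` diffuse freely, differences well above are preserved.
#' @param step integration time step; must be <= 0.25 for stability of the
#'   explicit 6-neighbour scheme (default 1/7).
#' @return The smoothed [image_stack()], same shape and spacing.
#' @export
anisotropic_diffusion <- function(stack, n_iter = 10L, kappa = 10,
                                  step = 1 / 7) {
  stopifnot(inherits(stack, "image_stack"))
  n_iter <- as.integer(n_iter)
  if (n_iter < 0L) stop("n_iter must be >= 0", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0)
    stop("kappa must be positive", call. = FALSE)
  if (!is.finite(step) || step <= 0 || step > 0.25)
    stop("step must be in (0, 0.25] for a stable explicit scheme",
         call. = FALSE)
  if (n_iter == 0L) return(stack)
  u <- stack$voxels
  inv_k2 <- 1 / kappa^2
  for (it in seq_len(n_iter)) {
    flux <- 0
    for (axis in 1:3) {
      dp <- .axshift(u, axis, 1L) - u   # forward neighbour difference
      dm <- .axshift(u, axis, -1L) - u  # backward neighbour difference
      flux <- flux + exp(-(dp * dp) * inv_k2) * dp +
                     exp(-(dm * dm) * inv_k2) * dm
    }
    u <- u + step * flux
  }
  image_stack(u, stack$spacing, stack$axis_order)
}
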