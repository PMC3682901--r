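#' 3D image volume with physical geometry
#'
#' Container for a scalar voxel grid (CT in Hounsfield units or dose in Gy)
#' together with its physical geometry in DICOM patient coordinates (LPS, mm).
#' Voxel indices are 0-based in the index<->physical mapping; the origin is the
#' physical position of the *center* of voxel (0,0,0). The voxel array is
#' stored with x (column) fastest, i.e. `dim(voxels) = c(nx, ny, nz)`.
#'
#' @param voxels 3D numeric array, dimensions `c(nx, ny, nz)`.
#' @param origin numeric length 3, physical position (mm) of the center of
#'   voxel (0,0,0).
#' @param spacing numeric length 3, per-axis voxel size in mm; strictly
#'   positive.
#' @param orientation 3x3 matrix whose columns are the unit direction cosines
#'   of the three voxel axes; must be orthonormal within 1e-6.
#' @param frame_of_reference opaque frame-of-reference identifier string.
#' @return An object of class `ImageVolume`.
#' @export
image_volume <- function(voxels, origin, spacing, orientation = diag(3),
                         frame_of_reference = "") {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("`origin` and `spacing` must have length 3")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive on all axes")
  orientation <- matrix(as.numeric(orientation), 3L, 3L)
  gram <- crossprod(orientation)
  if (max(abs(gram - diag(3))) > 1e-6)
    stop("`orientation` must be orthonormal (within 1e-6)")
  structure(list(
    voxels = voxels,
    origin = origin,
    spacing = spacing,
    orientation = orientation,
    frame_of_reference = as.character(frame_of_reference)
  ), class = "ImageVolume")
}

#' @export
print.ImageVolume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<ImageVolume> ", paste(d, collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm\n", sep = "")
  cat("  origin  (", paste(format(round(x$origin, 3)), collapse = ", "),
      ") mm  [center of voxel (0,0,0)]\n", sep = "")
  cat("  range   [", format(min(x$voxels)), ", ", format(max(x$voxels)),
      "]\n", sep = "")
  if (nzchar(x$frame_of_reference))
    cat("  frame of reference:", x$frame_of_reference, "\n")
  invisible(x)
}

#' @export
dim.ImageVolume <- function(x) dim(x$voxels)

#' Map 0-based voxel indices to physical coordinates (mm)
#'
#' @param vol an `ImageVolume` (only its geometry is used).
#' @param ijk numeric matrix n x 3 of 0-based voxel indices (may be
#'   fractional).
#' @return n x 3 matrix of physical LPS coordinates in mm.
#' @export
index_to_phys <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(ijk %*% t(vol$orientation * rep(vol$spacing, each = 3L)),
        2L, vol$origin, "+")
}

#' Map physical coordinates (mm) to 0-based (fractional) voxel indices
#'
#' Inverse of [index_to_phys()].
#' @inheritParams index_to_phys
#' @param xyz numeric matrix n x 3 of physical coordinates in mm.
#' @export
phys_to_index <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  centered <- sweep(xyz, 2L, vol$origin, "-")
  # orientation is orthonormal: inverse is the transpose
  sweep(centered %*% vol$orientation, 2L, vol$spacing, "/")
}

#' Physical coordinates of every voxel center
#'
#' @param geom an `ImageVolume` or any list with `voxels` (or `occupancy`),
#'   `origin`, `spacing`, `orientation`.
#' @return n x 3 matrix, rows in array storage order (x fastest).
#' @export
voxel_centers <- function(geom) {
  d <- grid_dim(geom)
  ijk <- cbind(
    rep.int(seq_len(d[1L]) - 1, d[2L] * d[3L]),
    rep.int(rep(seq_len(d[2L]) - 1, each = d[1L]), d[3L]),
    rep(seq_len(d[3L]) - 1, each = d[1L] * d[2L])
  )
  index_to_phys(geom, ijk)
}

# grid dims for ImageVolume or VoxelMask alike
grid_dim <- function(geom) {
  if (!is.null(geom$voxels)) dim(geom$voxels) else dim(geom$occupancy)
}

#' Volume of one voxel in ml
#' @param geom object with a `spacing` field (mm per axis).
#' @export
voxel_volume_ml <- function(geom) prod(geom$spacing) / 1000

#' Trilinear (or nearest) interpolation of a volume at physical points
#'
#' Points outside the voxel lattice evaluate to `fill` and are reported via
#' the `outside` attribute.
#'
#' @param vol an `ImageVolume`.
#' @param xyz n x 3 matrix of physical coordinates (mm).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill value for points outside the grid.
#' @return numeric vector length n with logical attribute `outside`.
#' @export
interp_volume <- function(vol, xyz, interpolation = c("linear", "nearest"),
                          fill = NA_real_) {
  interpolation <- match.arg(interpolation)
  d <- dim(vol$voxels)
  idx <- phys_to_index(vol, xyz)
  if (interpolation == "nearest") {
    i <- round(idx[, 1L]); j <- round(idx[, 2L]); k <- round(idx[, 3L])
    outside <- i < 0 | i > d[1L] - 1 | j < 0 | j > d[2L] - 1 |
      k < 0 | k > d[3L] - 1
    i <- pmin(pmax(i, 0), d[1L] - 1)
    j <- pmin(pmax(j, 0), d[2L] - 1)
    k <- pmin(pmax(k, 0), d[3L] - 1)
    out <- vol$voxels[1L + i + d[1L] * (j + d[2L] * k)]
  } else {
    outside <- idx[, 1L] < 0 | idx[, 1L] > d[1L] - 1 |
      idx[, 2L] < 0 | idx[, 2L] > d[2L] - 1 |
      idx[, 3L] < 0 | idx[, 3L] > d[3L] - 1
    cl <- pmin(pmax(idx, 0), rep(d - 1, each = nrow(idx)))
    i0 <- pmin(floor(cl[, 1L]), d[1L] - 2); i0 <- pmax(i0, 0)
    j0 <- pmin(floor(cl[, 2L]), d[2L] - 2); j0 <- pmax(j0, 0)
    k0 <- pmin(floor(cl[, 3L]), d[3L] - 2); k0 <- pmax(k0, 0)
    if (d[1L] < 2) i0 <- rep(0, nrow(cl))
    if (d[2L] < 2) j0 <- rep(0, nrow(cl))
    if (d[3L] < 2) k0 <- rep(0, nrow(cl))
    fx <- cl[, 1L] - i0; fy <- cl[, 2L] - j0; fz <- cl[, 3L] - k0
    i1 <- pmin(i0 + 1, d[1L] - 1); j1 <- pmin(j0 + 1, d[2L] - 1)
    k1 <- pmin(k0 + 1, d[3L] - 1)
    v <- vol$voxels
    at <- function(i, j, k) v[1L + i + d[1L] * (j + d[2L] * k)]
    out <-
      at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
      at(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
      at(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
      at(i1, j1, k0) * fx       * fy       * (1 - fz) +
      at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
      at(i1, j0, k1) * fx       * (1 - fy) * fz +
      at(i0, j1, k1) * (1 - fx) * fy       * fz +
      at(i1, j1, k1) * fx       * fy       * fz
  }
  out[outside] <- fill
  attr(out, "outside") <- outside
  out
}
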