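# Isodose-volume extraction, recurrence/region overlap, physical margin
# expansion of the boost, location classification and maximal-extension
# measurement -- the pattern-of-failure geometry.

#' Isodose volume as a binary mask
#'
#' Voxels receiving at least `pct`% of `reference_dose_gy`. The reference is
#' the analyzed plan's prescribed dose by default (the cut-off line is tied
#' to prescription coverage); pass the grid maximum to switch convention.
#'
#' @param dose an [image_volume()] in Gy.
#' @param pct isodose level in percent, in (0, 100].
#' @param reference_dose_gy reference dose in Gy (> 0).
#' @return A binary [voxel_mask()] on the dose grid.
#' @export
isodose_mask <- function(dose, pct, reference_dose_gy) {
  if (pct <= 0 || pct > 100) stop("`pct` must be in (0, 100]")
  if (reference_dose_gy <= 0) stop("`reference_dose_gy` must be positive")
  thr <- pct / 100 * reference_dose_gy
  if (thr <= min(dose$voxels))
    warning(sprintf(
      "isodose threshold %.2f Gy is at or below the grid minimum; %s",
      thr, "mask covers the whole grid"))
  if (thr > max(dose$voxels))
    warning(sprintf("isodose threshold %.2f Gy exceeds the grid maximum; %s",
                    thr, "mask is empty"))
  voxel_mask((dose$voxels >= thr) * 1, dose$origin, dose$spacing,
             dose$orientation)
}

same_grid <- function(a, b) {
  identical(grid_dim(a), grid_dim(b)) &&
    max(abs(a$origin - b$origin)) < 1e-6 &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$orientation - b$orientation)) < 1e-9
}

#' Overlap of a recurrence mask with a region mask
#'
#' Fractional-occupancy intersection: `overlap_ml` is the voxelwise
#' `min(occ_rec, occ_region)` times voxel volume; `overlap_pct` is the
#' percentage of the recurrence volume inside the region.
#'
#' @param recurrence,region [voxel_mask()] objects on the same grid.
#' @param region_label label carried into the result.
#' @return An object of class `OverlapResult`.
#' @export
overlap <- function(recurrence, region, region_label = "region") {
  if (!same_grid(recurrence, region))
    stop("masks are not on the same grid geometry")
  rec_vol <- mask_volume_ml(recurrence)
  if (rec_vol <= 0) stop("recurrence mask has zero volume")
  ov <- sum(pmin(recurrence$occupancy, region$occupancy)) *
    voxel_volume_ml(recurrence)
  structure(list(region_label = region_label,
                 overlap_ml = ov,
                 overlap_pct = 100 * ov / rec_vol,
                 recurrence_vol_ml = rec_vol),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("<OverlapResult> %.2f of %.2f ml (%.1f%%) inside '%s'\n",
              x$overlap_ml, x$recurrence_vol_ml, x$overlap_pct,
              x$region_label))
  invisible(x)
}

# offsets of the anisotropic "ball" structuring element: offset o (voxels)
# included iff the Euclidean center-to-center distance in physical mm is
# <= margin_mm -- the same criterion a Euclidean distance transform on the
# voxel lattice thresholded at margin_mm yields.
ball_kernel_offsets <- function(margin_mm, spacing) {
  k <- pmax(floor(margin_mm / spacing), 0)
  ox <- -k[1L]:k[1L]; oy <- -k[2L]:k[2L]; oz <- -k[3L]:k[3L]
  g <- expand.grid(ox = ox, oy = oy, oz = oz)
  d <- sqrt((g$ox * spacing[1L])^2 + (g$oy * spacing[2L])^2 +
              (g$oz * spacing[3L])^2)
  g[d <= margin_mm + 1e-9, , drop = FALSE]
}

#' Expand a mask by a physical margin
#'
#' Binary morphological dilation in physical mm with anisotropic voxel
#' spacing respected: a voxel enters the expanded mask iff its center lies
#' within `margin_mm` of a voxel center of the binarized (occupancy >= 0.5)
#' input -- the criterion a Euclidean distance transform thresholded at the
#' margin yields. Implemented as an FFT convolution with the anisotropic
#' ball structuring element, which is exact for this criterion at the grid
#' resolution; sub-voxel accuracy therefore comes from the grid, not the
#' operator (see the methods vignette).
#'
#' @param mask a [voxel_mask()].
#' @param margin_mm non-negative margin in mm.
#' @return A binary [voxel_mask()] on the same grid.
#' @export
expand_margin <- function(mask, margin_mm) {
  if (margin_mm < 0) stop("`margin_mm` must be non-negative")
  bin <- (mask$occupancy >= 0.5) * 1
  if (margin_mm == 0 || sum(bin) == 0)
    return(voxel_mask(bin, mask$origin, mask$spacing, mask$orientation,
                      mask$level))
  off <- ball_kernel_offsets(margin_mm, mask$spacing)
  d <- dim(bin)
  kmax <- c(max(abs(off$ox)), max(abs(off$oy)), max(abs(off$oz)))
  p <- d + 2L * kmax
  mp <- array(0, dim = p)
  mp[seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L])] <- bin
  kp <- array(0, dim = p)
  kp[cbind((off$ox %% p[1L]) + 1L,
           (off$oy %% p[2L]) + 1L,
           (off$oz %% p[3L]) + 1L)] <- 1
  conv <- Re(stats::fft(stats::fft(mp) * stats::fft(kp), inverse = TRUE)) /
    prod(p)
  out <- (conv[seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L])] > 0.5) * 1
  voxel_mask(out, mask$origin, mask$spacing, mask$orientation, mask$level)
}

# For each query point (n x 3, mm), distance to the nearest target voxel
# (shrunk by `half` per axis; zero half = center-to-center) and the offset
# vector to that nearest point. Chunked to bound memory.
box_distance_to_set <- function(points, target_centers, half) {
  n <- nrow(points)
  dmin <- numeric(n)
  offs <- matrix(0, n, 3L)
  chunk <- max(1L, floor(2e6 / max(1L, nrow(target_centers))))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    px <- points[s:e, 1L]; py <- points[s:e, 2L]; pz <- points[s:e, 3L]
    ddx <- pmax(abs(outer(px, target_centers[, 1L], "-")) - half[1L], 0)
    ddy <- pmax(abs(outer(py, target_centers[, 2L], "-")) - half[2L], 0)
    ddz <- pmax(abs(outer(pz, target_centers[, 3L], "-")) - half[3L], 0)
    d2 <- ddx^2 + ddy^2 + ddz^2
    jm <- max.col(-d2, ties.method = "first")
    rows <- seq_len(e - s + 1L)
    dmin[s:e] <- sqrt(d2[cbind(rows, jm)])
    sx <- px - target_centers[jm, 1L]
    sy <- py - target_centers[jm, 2L]
    sz <- pz - target_centers[jm, 3L]
    offs[s:e, ] <- cbind(sign(sx) * ddx[cbind(rows, jm)],
                         sign(sy) * ddy[cbind(rows, jm)],
                         sign(sz) * ddz[cbind(rows, jm)])
  }
  list(distance = dmin, offset = offs)
}

#' Maximal extension of a recurrence beyond the boost surface
#'
#' Distances are measured center-to-surface on the binarized masks at the
#' analysis grid resolution (the boost voxel centers represent its surface);
#' voxels inside the boost contribute 0. `"3d"` takes the
#' maximum over all recurrence voxels. `"axial"` mirrors the clinical
#' ruler-on-one-slice measurement: per axial slice containing both
#' structures, the in-plane distance to the boost portion of that same
#' slice, reporting the worst slice.
#'
#' @param recurrence,boost [voxel_mask()] objects on the same grid.
#' @param mode `"3d"` or `"axial"`.
#' @return Extension in cm.
#' @export
max_extension <- function(recurrence, boost, mode = c("3d", "axial")) {
  mode <- match.arg(mode)
  if (!same_grid(recurrence, boost))
    stop("masks are not on the same grid geometry")
  rec <- recurrence$occupancy >= 0.5
  bst <- boost$occupancy >= 0.5
  if (!any(rec)) stop("recurrence mask is empty")
  if (!any(bst)) stop("boost mask is empty")
  half <- c(0, 0, 0)
  centers <- voxel_centers(recurrence)
  if (mode == "3d") {
    qry <- centers[as.vector(rec & !bst), , drop = FALSE]
    if (nrow(qry) == 0L) return(0)
    res <- box_distance_to_set(qry, centers[as.vector(bst), , drop = FALSE],
                               half)
    return(max(res$distance) / 10)
  }
  d <- dim(recurrence$occupancy)
  worst <- 0
  for (k in seq_len(d[3L])) {
    rk <- rec[, , k]; bk <- bst[, , k]
    if (!any(rk) || !any(bk)) next
    out_k <- rk & !bk
    if (!any(out_k)) next
    base <- (k - 1L) * d[1L] * d[2L]
    qry <- centers[base + which(out_k), , drop = FALSE]
    tgt <- centers[base + which(bk), , drop = FALSE]
    res <- box_distance_to_set(qry[, 1:2, drop = FALSE] |> cbind(0),
                               tgt[, 1:2, drop = FALSE] |> cbind(0),
                               c(half[1:2], 0))
    worst <- max(worst, max(res$distance))
  }
  worst / 10
}

#' Classify recurrence location relative to the boost and its shells
#'
#' Computes the coverage fraction of the recurrence inside the boost and
#' inside each margin-expanded shell, flags membership where coverage reaches
#' `containment_threshold`, and reports the outfield volume beyond the
#' largest shell plus the maximal extension (3D and worst-axial-slice) and a
#' direction-resolved extension along the six cardinal axes. Because the
#' shells are nested, coverage fractions are non-decreasing across
#' boost, +1 cm, +1.5 cm, +2 cm -- the canonical row pattern of a
#' pattern-of-failure table.
#'
#' @param recurrence,boost [voxel_mask()] objects on the same grid.
#' @param margins_mm ascending margins in mm (default 10, 15, 20).
#' @param containment_threshold coverage fraction required to flag
#'   membership (default 0.95). The full fractions are always reported
#'   alongside the flags, since a hard "within" criterion is a convention.
#' @return An object of class `LocationClassification`.
#' @export
classify_location <- function(recurrence, boost, margins_mm = c(10, 15, 20),
                              containment_threshold = 0.95) {
  if (is.unsorted(margins_mm, strictly = TRUE))
    stop("`margins_mm` must be sorted strictly ascending")
  shells <- c(list(binarize_mask(boost)),
              lapply(margins_mm, function(m) expand_margin(boost, m)))
  labels <- c("boost", sprintf("boost+%gmm", margins_mm))
  rec_bin <- binarize_mask(recurrence)
  ovs <- mapply(function(sh, lb) overlap(rec_bin, sh, lb),
                shells, labels, SIMPLIFY = FALSE)
  coverage <- vapply(ovs, function(o) o$overlap_pct / 100, numeric(1))
  names(coverage) <- labels
  rec_vol <- mask_volume_ml(rec_bin)
  outfield <- rec_vol - ovs[[length(ovs)]]$overlap_ml
  # direction-resolved extension from the same nearest-surface offsets
  rec <- rec_bin$occupancy >= 0.5; bst <- boost$occupancy >= 0.5
  centers <- voxel_centers(rec_bin)
  qry <- centers[as.vector(rec & !bst), , drop = FALSE]
  dir_ext <- stats::setNames(numeric(6),
                             c("x+", "x-", "y+", "y-", "z+", "z-"))
  ext3d <- 0
  if (nrow(qry) > 0L && any(bst)) {
    res <- box_distance_to_set(qry, centers[as.vector(bst), , drop = FALSE],
                               c(0, 0, 0))
    ext3d <- max(res$distance) / 10
    for (ax in 1:3) {
      dir_ext[2L * ax - 1L] <- max(0, res$offset[, ax]) / 10
      dir_ext[2L * ax] <- max(0, -res$offset[, ax]) / 10
    }
  }
  structure(list(
    labels = labels,
    coverage = coverage,
    member = coverage >= containment_threshold,
    containment_threshold = containment_threshold,
    margins_mm = margins_mm,
    recurrence_vol_ml = rec_vol,
    outfield_vol_ml = outfield,
    max_extension_cm = ext3d,
    max_extension_axial_cm = if (any(bst) && any(rec))
      max_extension(rec_bin, boost, "axial") else NA_real_,
    direction_extension_cm = dir_ext
  ), class = "LocationClassification")
}

#' @export
print.LocationClassification <- function(x, ...) {
  cat("<LocationClassification>\n")
  for (i in seq_along(x$labels))
    cat(sprintf("  %-12s coverage %6.1f%%  %s\n", x$labels[i],
                100 * x$coverage[i],
                if (x$member[i]) "[within]" else ""))
  cat(sprintf("  outfield volume %.2f ml; max extension %.2f cm (3D), %s cm (worst axial slice)\n",
              x$outfield_vol_ml, x$max_extension_cm,
              formatC(x$max_extension_axial_cm, format = "f", digits = 2)))
  invisible(x)
}
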