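#' Region of interest as planar closed contours
#'
#' A named structure stored the way RT Structure Sets store it: a list of
#' closed planar polygons, each lying in a single axial plane, with ordered
#' vertices in physical mm. The last vertex connects implicitly back to the
#' first. Coordinates stay in physical mm until voxelization.
#'
#' @param name structure name.
#' @param contours list of n x 3 numeric matrices (x, y, z in mm); each must
#'   have at least 3 vertices and constant z within 1e-6 mm.
#' @param frame_of_reference frame-of-reference identifier string.
#' @param flags character vector of quality flags (e.g. `"empty"`,
#'   `"frame_mismatch"`).
#' @return An object of class `ROI`.
#' @export
roi <- function(name, contours = list(), frame_of_reference = "",
                flags = character(0)) {
  contours <- lapply(contours, function(ct) {
    ct <- matrix(as.numeric(ct), ncol = 3L)
    if (nrow(ct) < 3L)
      stop("contour of '", name, "' has fewer than 3 vertices")
    if (diff(range(ct[, 3L])) > 1e-6)
      stop("contour of '", name, "' is not planar in z")
    ct
  })
  if (length(contours) == 0L) flags <- union(flags, "empty")
  structure(list(name = as.character(name), contours = contours,
                 frame_of_reference = as.character(frame_of_reference),
                 flags = flags),
            class = "ROI")
}

#' @export
print.ROI <- function(x, ...) {
  nz <- length(unique(vapply(x$contours, function(ct) ct[1L, 3L], numeric(1))))
  cat("<ROI> '", x$name, "': ", length(x$contours), " contour(s) on ",
      nz, " plane(s)", sep = "")
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

# distinct contour plane positions, ascending
roi_planes <- function(r) {
  sort(unique(vapply(r$contours, function(ct) ct[1L, 3L], numeric(1))))
}

#' Circle-approximating polygon contour
#'
#' Convenience constructor used by the phantom generator: a regular polygon
#' inscribed-to-circumscribed compromise is avoided by sampling the circle
#' itself; with enough vertices the polygon area converges to the disc area.
#'
#' @param center length-2, circle center (x, y) in mm.
#' @param radius radius in mm.
#' @param z axial plane position in mm.
#' @param n_vertices vertex count.
#' @return n x 3 vertex matrix.
#' @export
circle_contour <- function(center, radius, z, n_vertices = 96L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th), z)
}

#' Sphere ROI from stacked circular contours
#'
#' Slices a sphere at the given axial plane positions; planes cutting the
#' sphere produce circles of radius `sqrt(r^2 - dz^2)`.
#'
#' @param name structure name.
#' @param center length-3 sphere center, mm.
#' @param radius sphere radius, mm.
#' @param z_planes axial plane positions to slice at, mm.
#' @param frame_of_reference frame identifier.
#' @param n_vertices vertices per contour.
#' @export
sphere_roi <- function(name, center, radius, z_planes,
                       frame_of_reference = "", n_vertices = 96L) {
  contours <- list()
  for (z in z_planes) {
    dz <- z - center[3L]
    if (abs(dz) >= radius) next
    r_sl <- sqrt(radius^2 - dz^2)
    contours[[length(contours) + 1L]] <-
      circle_contour(center[1:2], r_sl, z, n_vertices)
  }
  roi(name, contours, frame_of_reference)
}

#' Axis-aligned box ROI from rectangular contours
#'
#' @param name structure name.
#' @param lower,upper length-3 box corners, mm.
#' @param z_planes axial plane positions to slice at, mm.
#' @param frame_of_reference frame identifier.
#' @export
box_roi <- function(name, lower, upper, z_planes, frame_of_reference = "") {
  contours <- list()
  for (z in z_planes) {
    if (z < lower[3L] || z > upper[3L]) next
    contours[[length(contours) + 1L]] <- cbind(
      c(lower[1L], upper[1L], upper[1L], lower[1L]),
      c(lower[2L], lower[2L], upper[2L], upper[2L]),
      z)
  }
  roi(name, contours, frame_of_reference)
}
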