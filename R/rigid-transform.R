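#' Nine-component rigid transform
#'
#' A proper rigid motion of physical space parameterized, as reported for each
#' registered follow-up scan, by a translation `(tx, ty, tz)` in mm, a
#' rotation point `(rpx, rpy, rpz)` in mm, and intrinsic Euler rotation angles
#' `(rx, ry, rz)` in degrees applied in z-y-x order about the rotation point:
#'
#'   T(x) = R (x - rp) + rp + t,   R = Rz(rz) Ry(ry) Rx(rx)
#'
#' In the registration pipeline a transform maps points in the fixed
#' (planning) frame to the corresponding sampling locations in the moving
#' (follow-up) frame, the usual resampling convention.
#'
#' @param tx,ty,tz translation components, mm.
#' @param rpx,rpy,rpz rotation point, mm.
#' @param rx,ry,rz rotation angles, degrees.
#' @return An object of class `RigidTransform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0,
                            rpx = 0, rpy = 0, rpz = 0,
                            rx = 0, ry = 0, rz = 0) {
  structure(list(tx = tx, ty = ty, tz = tz,
                 rpx = rpx, rpy = rpy, rpz = rpz,
                 rx = rx, ry = ry, rz = rz),
            class = "RigidTransform")
}

#' Identity transform
#' @export
rt_identity <- function() rigid_transform()

#' @export
print.RigidTransform <- function(x, ...) {
  cat("<RigidTransform> (z-y-x intrinsic Euler, degrees; mm)\n")
  cat(sprintf("  translation    (%.4f, %.4f, %.4f) mm\n", x$tx, x$ty, x$tz))
  cat(sprintf("  rotation point (%.4f, %.4f, %.4f) mm\n", x$rpx, x$rpy, x$rpz))
  cat(sprintf("  angles         (%.4f, %.4f, %.4f) deg\n", x$rx, x$ry, x$rz))
  invisible(x)
}

#' 3x3 rotation matrix of a transform
#' @param t a `RigidTransform`.
#' @export
rt_rotation <- function(t) {
  a <- t$rx * pi / 180; b <- t$ry * pi / 180; g <- t$rz * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' 4x4 homogeneous matrix of a transform
#' @param t a `RigidTransform`.
#' @export
rt_matrix <- function(t) {
  r <- rt_rotation(t)
  rp <- c(t$rpx, t$rpy, t$rpz)
  offset <- rp + c(t$tx, t$ty, t$tz) - r %*% rp
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4L] <- offset
  m
}

# z-y-x intrinsic Euler angles (degrees) from a rotation matrix
rt_angles_from_rotation <- function(r) {
  if (abs(r[3L, 1L]) < 1 - 1e-12) {
    ry <- asin(-r[3L, 1L])
    rx <- atan2(r[3L, 2L], r[3L, 3L])
    rz <- atan2(r[2L, 1L], r[1L, 1L])
  } else {
    # gimbal lock: ry = +-90 deg, split freely between rx and rz
    ry <- if (r[3L, 1L] < 0) pi / 2 else -pi / 2
    rx <- atan2(-r[1L, 2L], r[2L, 2L])
    rz <- 0
  }
  c(rx = rx, ry = ry, rz = rz) * 180 / pi
}

# RigidTransform from 3x3 rotation + offset, rotation point at origin
rt_from_matrix <- function(r, offset) {
  det3 <- det(r)
  if (abs(det3 - 1) > 1e-6)
    stop("matrix is not a proper rotation (det = ", format(det3), ")")
  ang <- rt_angles_from_rotation(r)
  rigid_transform(tx = offset[1L], ty = offset[2L], tz = offset[3L],
                  rx = ang[["rx"]], ry = ang[["ry"]], rz = ang[["rz"]])
}

#' Apply a rigid transform to points
#' @param t a `RigidTransform`.
#' @param xyz n x 3 matrix of physical points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
rt_apply <- function(t, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  m <- rt_matrix(t)
  sweep(xyz %*% t(m[1:3, 1:3]), 2L, m[1:3, 4L], "+")
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform mapping `x` to `a(b(x))`. The result
#' carries its rotation point at the origin (the parameterization is not
#' unique; the induced motion is).
#' @param a,b `RigidTransform` objects.
#' @export
rt_compose <- function(a, b) {
  m <- rt_matrix(a) %*% rt_matrix(b)
  rt_from_matrix(m[1:3, 1:3], m[1:3, 4L])
}

#' Invert a rigid transform
#' @param t a `RigidTransform`.
#' @export
rt_invert <- function(t) {
  m <- rt_matrix(t)
  r <- t(m[1:3, 1:3])
  rt_from_matrix(r, -r %*% m[1:3, 4L])
}

#' Euler angles of a transform's rotation
#'
#' The z-y-x intrinsic Euler angles (degrees) of the induced rotation,
#' independent of the rotation-point parameterization; use together with
#' [rt_effective_translation()] to compare transforms.
#' @param t a `RigidTransform`.
#' @return named numeric vector `(rx, ry, rz)` in degrees.
#' @export
rt_angles <- function(t) rt_angles_from_rotation(rt_rotation(t))

#' Effective translation with the rotation point moved to the origin
#'
#' Two transforms with different rotation points induce the same motion when
#' their rotations agree and their effective offsets agree; this canonical
#' form makes transforms comparable.
#' @param t a `RigidTransform`.
#' @return numeric length 3, the offset of the rp = 0 parameterization.
#' @export
rt_effective_translation <- function(t) as.numeric(rt_matrix(t)[1:3, 4L])

#' Write a transform to a plain-text key=value file
#'
#' The file records the nine named components plus a convention string so the
#' angles are interpretable without the package.
#' @param t a `RigidTransform`.
#' @param path output file path.
#' @export
write_transform <- function(t, path) {
  keys <- c("tx", "ty", "tz", "rpx", "rpy", "rpz", "rx", "ry", "rz")
  lines <- c(
    "# rigid transform: T(x) = R(x - rp) + rp + t",
    "convention=euler-zyx-intrinsic-degrees;units=mm;coords=LPS",
    sprintf("%s=%.10g", keys, vapply(keys, function(k) t[[k]], numeric(1)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a transform written by [write_transform()]
#' @param path file path.
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  conv <- vals[["convention"]]
  if (!is.na(conv) && !startsWith(conv, "euler-zyx-intrinsic-degrees"))
    stop("unsupported transform convention: ", conv)
  num <- function(k) if (k %in% names(vals)) as.numeric(vals[[k]]) else 0
  rigid_transform(num("tx"), num("ty"), num("tz"),
                  num("rpx"), num("rpy"), num("rpz"),
                  num("rx"), num("ry"), num("rz"))
}
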