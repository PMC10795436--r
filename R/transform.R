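#' Rigid transform: rotation about a center, then translation
#'
#' Rotations are extrinsic fixed-axes rotations in the LPS frame applied in
#' the order pitch (about x, the R-L axis), roll (about y, the A-P axis),
#' yaw (about z, the S-I axis), angles in degrees, right-hand rule. A point
#' `p` maps to `R (p - center) + center + translation`.
#'
#' @param translation length-3 numeric, mm (LPS signed).
#' @param pitch,yaw,roll rotation angles in degrees about the x, z and y
#'   axes respectively.
#' @param center length-3 numeric, rotation center in mm.
#' @return An object of class `rigid_transform`.
#' @examples
#' tf <- rigid_transform(c(1, 2, 3), pitch = 5)
#' apply_transform(cube_mesh(10), tf)
#' @export
rigid_transform <- function(translation = c(0, 0, 0), pitch = 0, yaw = 0,
                            roll = 0, center = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(translation) == 3, length(center) == 3,
            is.finite(translation), is.finite(center),
            is.finite(pitch), is.finite(yaw), is.finite(roll))
  structure(
    list(translation = translation, pitch = as.numeric(pitch),
         yaw = as.numeric(yaw), roll = as.numeric(roll), center = center),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> t = (%.3f, %.3f, %.3f) mm; pitch %.3f, yaw %.3f, roll %.3f deg; center (%.2f, %.2f, %.2f)\n",
    x$translation[1], x$translation[2], x$translation[3],
    x$pitch, x$yaw, x$roll, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param x object to test.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

# 3x3 rotation matrix: R = Rz(yaw) %*% Ry(roll) %*% Rx(pitch), degrees
rotation_matrix <- function(pitch = 0, yaw = 0, roll = 0) {
  p <- pitch * pi / 180; r <- roll * pi / 180; y <- yaw * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(p), -sin(p)), c(0, sin(p), cos(p)))
  Ry <- rbind(c(cos(r), 0, sin(r)), c(0, 1, 0), c(-sin(r), 0, cos(r)))
  Rz <- rbind(c(cos(y), -sin(y), 0), c(sin(y), cos(y), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Euler angles (pitch about x, roll about y, yaw about z) from R = Rz Ry Rx
rotation_angles <- function(R) {
  roll <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(roll)) > 1e-9) {
    pitch <- atan2(R[3, 2], R[3, 3])
    yaw <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock: fold yaw into pitch
    pitch <- atan2(-R[2, 3], R[2, 2])
    yaw <- 0
  }
  c(pitch = pitch, yaw = yaw, roll = roll) * 180 / pi
}

#' Apply a rigid transform to points or a mesh
#'
#' @param mesh a [tri_mesh()] (or, for `transform_points`, an `n x 3` matrix).
#' @param transform a [rigid_transform()].
#' @return A mesh (or matrix) with transformed vertices; topology unchanged.
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(is_tri_mesh(mesh), is_rigid_transform(transform))
  out <- mesh
  out$vertices <- transform_points(mesh$vertices, transform)
  out
}

#' @rdname apply_transform
#' @param points an `n x 3` numeric matrix.
#' @export
transform_points <- function(points, transform) {
  R <- rotation_matrix(transform$pitch, transform$yaw, transform$roll)
  centered <- sweep(points, 2, transform$center)
  sweep(centered %*% t(R), 2, transform$center + transform$translation, `+`)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform that applies `a` first and
#' then `b`; both must use the same rotation-center convention, and the
#' result is expressed about the center of `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()] equal to `b` after `a` pointwise.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  Ra <- rotation_matrix(a$pitch, a$yaw, a$roll)
  Rb <- rotation_matrix(b$pitch, b$yaw, b$roll)
  Rc <- Rb %*% Ra
  ang <- rotation_angles(Rc)
  # composed(x) = Rb Ra (x - ca) + Rb (ca + ta - cb) + cb + tb
  tc <- as.numeric(Rb %*% (a$center + a$translation - b$center)) +
    b$center + b$translation - a$center
  rigid_transform(tc, pitch = ang[["pitch"]], yaw = ang[["yaw"]],
                  roll = ang[["roll"]], center = a$center)
}

#' Inverse of a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The [rigid_transform()] undoing `transform`, about the same center.
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform$pitch, transform$yaw, transform$roll)
  Ri <- t(R)
  ang <- rotation_angles(Ri)
  # T(x) = R(x - c) + c + t  =>  T^-1(y) = Ri(y - c) + c - Ri t
  ti <- as.numeric(-Ri %*% transform$translation)
  rigid_transform(ti, pitch = ang[["pitch"]], yaw = ang[["yaw"]],
                  roll = ang[["roll"]], center = transform$center)
}
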