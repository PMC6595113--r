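#' Rigid pose (rotation + translation)
#'
#' A rigid pose maps points expressed in a body-local frame into the
#' laboratory frame: \code{p_world = R p_local + t}. Rotations must be proper
#' (right-handed, determinant +1) because all downstream mechanics assumes
#' rigid vertebrae.
#'
#' @param R 3x3 rotation matrix, orthonormal with det(R) = +1.
#' @param t length-3 translation vector, mm.
#' @param tol tolerance on orthonormality and determinant.
#' @return An object of class \code{rigid_pose} (list with \code{R}, \code{t}).
#' @export
rigid_pose <- function(R, t = c(0, 0, 0), tol = 1e-7) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(identical(dim(R), c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("rotation matrix is not orthonormal (||R'R - I|| > ", tol, ")")
  }
  if (abs(det(R) - 1) > tol) {
    stop("rotation matrix is not proper (det(R) != +1); reflections are not rigid poses")
  }
  structure(list(R = R, t = t), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("rigid_pose: angle", sprintf("%.4f", rotation_angle_deg(x$R)),
      "deg, |t| =", sprintf("%.4f", sqrt(sum(x$t^2))), "mm\n")
  invisible(x)
}

#' Identity pose
#' @return A \code{rigid_pose} with R = I, t = 0.
#' @export
identity_pose <- function() rigid_pose(diag(3), c(0, 0, 0))

#' Apply a rigid pose to points
#'
#' @param pose A \code{rigid_pose}.
#' @param pts n x 3 matrix of points (or a length-3 vector), mm.
#' @return Transformed points, same shape as input.
#' @export
apply_pose <- function(pose, pts) {
  if (is.null(dim(pts))) {
    return(as.numeric(pose$R %*% pts + pose$t))
  }
  pts <- as.matrix(pts)
  sweep(pts %*% t(pose$R), 2, -pose$t)
}

#' Compose two rigid poses
#'
#' \code{compose_pose(a, b)} returns the pose equivalent to applying \code{b}
#' first, then \code{a}.
#' @param a,b \code{rigid_pose} objects.
#' @return A \code{rigid_pose}.
#' @export
compose_pose <- function(a, b) {
  rigid_pose(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid pose
#' @param pose A \code{rigid_pose}.
#' @return The inverse \code{rigid_pose}.
#' @export
invert_pose <- function(pose) {
  rigid_pose(t(pose$R), as.numeric(-t(pose$R) %*% pose$t))
}

# Rotation about the +Y (medio-lateral) axis. theta in radians; positive is
# flexion under the package convention (+X anterior, +Z cranial).
rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, s_,
           0, 1, 0,
           -s_, 0, c_), nrow = 3, byrow = TRUE)
}

# Rodrigues rotation about an arbitrary unit axis.
rot_axis <- function(axis, theta) {
  n <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -n[3], n[2],
                n[3], 0, -n[1],
                -n[2], n[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees, in [0, 180].
#' @export
rotation_angle_deg <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  ang * 180 / pi
}

# Rotation vector (axis * angle, radians) of a rotation matrix; the matrix
# logarithm. Stable for small angles; angles near pi resolved via the
# symmetric part.
rotation_log <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) return(c(0, 0, 0))
  if (abs(pi - ang) < 1e-6) {
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    i <- which.max(axis)
    axis <- B[, i] / axis[i]
    axis <- axis / sqrt(sum(axis^2))
    return(axis * ang)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(ang)) * ang
}

# Signed rotation angle (degrees) about a given unit axis, by axis-angle
# projection of the rotation vector. Exact for rotations about that axis.
signed_angle_about_axis <- function(R, axis) {
  v <- rotation_log(R)
  sum(v * axis / sqrt(sum(axis^2))) * 180 / pi
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards, so generators are deterministic without side effects.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
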