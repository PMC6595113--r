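#' Rigid registration of one marker triangle onto another
#'
#' Constructive triangle-matching registration: (1) translate source vertex 1
#' onto target vertex 1; (2) rotate about the axis through vertex 1
#' perpendicular to the plane spanned by the two vertex-1 edges, so the 1-2
#' edge directions superimpose; (3) rotate about the now-common 1-2 edge to
#' bring vertex 3 into the target plane on the correct side. For congruent
#' triangles the vertices coincide to numerical precision; for triangles that
#' are only similar (same shape, different size), vertex 1 and the 1-2 edge
#' direction still match exactly and the vertex-3 residual is surfaced in the
#' result rather than absorbed by scaling, because downstream mechanics
#' assumes rigid bodies.
#'
#' @param source,target 3 x 3 matrices, one vertex per row, mm.
#' @return A \code{rigid_pose} with attributes \code{rms_mm} (RMS vertex
#'   residual) and \code{vertex3_residual_mm}.
#' @export
fit_rigid_triangle <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(identical(dim(source), c(3L, 3L)), identical(dim(target), c(3L, 3L)))
  check_triangle(source, "source")
  check_triangle(target, "target")

  es <- source[2, ] - source[1, ]
  et <- target[2, ] - target[1, ]
  R1 <- rotation_between(es, et)

  u <- et / sqrt(sum(et^2))
  s3 <- as.numeric(R1 %*% (source[3, ] - source[1, ]))
  t3 <- target[3, ] - target[1, ]
  a <- s3 - sum(s3 * u) * u
  b <- t3 - sum(t3 * u) * u
  if (sqrt(sum(a^2)) < 1e-9 || sqrt(sum(b^2)) < 1e-9) {
    stop("vertex 3 lies on the 1-2 edge line; triangle is degenerate")
  }
  phi <- atan2(sum(u * pracma_cross(a, b)), sum(a * b))
  R <- rot_axis(u, phi) %*% R1
  t <- target[1, ] - as.numeric(R %*% source[1, ])
  pose <- rigid_pose(R, t)
  fitted <- apply_pose(pose, source)
  attr(pose, "rms_mm") <- sqrt(mean(rowSums((fitted - target)^2)))
  attr(pose, "vertex3_residual_mm") <- sqrt(sum((fitted[3, ] - target[3, ])^2))
  pose
}

check_triangle <- function(tri, which) {
  if (triangle_area(tri) <= 1e-6) {
    stop("degenerate (collinear) ", which, " triangle: vertices ",
         paste(apply(round(tri, 3), 1, paste, collapse = ","), collapse = " / "))
  }
}

# Minimal rotation mapping direction a onto direction b.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  ax <- pracma_cross(a, b)
  s <- sqrt(sum(ax^2)); d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- pracma_cross(a, p)
    return(rot_axis(ax, pi))
  }
  rot_axis(ax / s, atan2(s, d))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Least-squares rigid registration (orthogonal Procrustes / Kabsch)
#'
#' Minimizes the (optionally weighted) sum of squared distances between
#' transformed source points and target points over proper rigid motions.
#' The reflection guard negates the smallest singular direction when the
#' optimal orthogonal matrix would be a reflection, so det(R) = +1 always.
#'
#' @param source,target n x 3 matrices, n >= 3, non-collinear.
#' @param weights Optional non-negative weights, length n.
#' @return A \code{rigid_pose} with attribute \code{rms_mm}.
#' @export
fit_rigid_procrustes <- function(source, target, weights = NULL) {
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  stopifnot(n >= 3, nrow(target) == n, ncol(source) == 3, ncol(target) == 3)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cs <- colSums(source * w); ct <- colSums(target * w)
  X <- sweep(source, 2, cs); Y <- sweep(target, 2, ct)
  if (max_triangle_area(source) <= 1e-6) {
    stop("collinear source points: rigid registration is underdetermined")
  }
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.numeric(R %*% cs)
  pose <- rigid_pose(R, t)
  fitted <- apply_pose(pose, source)
  attr(pose, "rms_mm") <- sqrt(mean(rowSums((fitted - target)^2)))
  pose
}

# Pick the best-conditioned marker triple: maximal triangle area, with a
# deterministic tie-break by label order.
best_triangle_rows <- function(pts) {
  n <- nrow(pts)
  best <- NULL; best_area <- -Inf
  for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
    a <- triangle_area(pts[c(i, j, k), , drop = FALSE])
    if (a > best_area + 1e-12) { best_area <- a; best <- c(i, j, k) }
  }
  best
}

#' Register the template model to an observed neutral frame
#'
#' For each vertebra, aligns the template's local marker coordinates to the
#' observed marker positions of the chosen (neutral) frame: the triangle
#' method on the maximal-area visible marker triple (the published matching
#' construction), or least-squares Procrustes over all visible markers.
#' Vertebrae with fewer than three visible markers are an error. A warning is
#' raised when any per-vertebra RMS residual exceeds \code{warn_rms_mm},
#' since a poor neutral match propagates into every joint angle.
#'
#' @param model A \code{spine_model}.
#' @param traj A \code{marker_trajectory}.
#' @param frame Frame index to use as the neutral position (default 1).
#' @param method \code{"triangle"} (default) or \code{"procrustes"}.
#' @param warn_rms_mm RMS threshold for the registration warning (mm).
#' @return Named list (per vertebra) of \code{rigid_pose}; each carries an
#'   \code{rms_mm} attribute, and the list carries a \code{residuals}
#'   attribute (data.frame vertebra, rms_mm, n_markers).
#' @export
register_model_to_neutral <- function(model, traj, frame = 1,
                                      method = c("triangle", "procrustes"),
                                      warn_rms_mm = 1.0) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "marker_trajectory"), frame >= 1,
            frame <= n_frames(traj))
  poses <- list()
  res <- data.frame(vertebra = character(), rms_mm = numeric(),
                    n_markers = integer(), stringsAsFactors = FALSE)
  for (v in c("C0", "C1", "C2", "C3")) {
    idx <- which(traj$labels$vertebra == v & !traj$missing[frame, ])
    if (length(idx) < 3) {
      stop("vertebra ", v, " has fewer than 3 visible markers in the neutral frame")
    }
    local <- model$vertebrae[[v]]$markers[traj$labels$marker[idx], , drop = FALSE]
    observed <- traj$positions[frame, idx, , drop = TRUE]
    observed <- matrix(observed, ncol = 3)
    if (method == "triangle") {
      rows <- best_triangle_rows(local)
      pose <- fit_rigid_triangle(local[rows, ], observed[rows, ])
      fitted <- apply_pose(pose, local)
      attr(pose, "rms_mm") <- sqrt(mean(rowSums((fitted - observed)^2)))
    } else {
      pose <- fit_rigid_procrustes(local, observed)
    }
    poses[[v]] <- pose
    res <- rbind(res, data.frame(vertebra = v, rms_mm = attr(pose, "rms_mm"),
                                 n_markers = length(idx),
                                 stringsAsFactors = FALSE))
  }
  if (any(res$rms_mm > warn_rms_mm)) {
    warning("neutral registration RMS exceeds ", warn_rms_mm, " mm for: ",
            paste(res$vertebra[res$rms_mm > warn_rms_mm], collapse = ", "))
  }
  attr(poses, "residuals") <- res
  poses
}

#' Serialize per-vertebra poses to JSON
#'
#' Rotation as a row-major 9-tuple, translation as a 3-tuple in mm.
#'
#' @param poses Named list of \code{rigid_pose}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_poses_json <- function(poses, path) {
  out <- lapply(poses, function(p) {
    list(rotation_row_major = as.numeric(t(p$R)), translation_mm = p$t)
  })
  atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, digits = NA, auto_unbox = FALSE, pretty = TRUE)
  })
  invisible(path)
}
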