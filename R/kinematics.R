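#' Per-frame rigid pose of one vertebra from a marker trajectory
#'
#' Least-squares (Procrustes) fit of the template's local marker coordinates
#' to the observed marker positions, frame by frame. Frames with fewer than
#' three visible markers are flagged missing rather than dropped, so the
#' series keeps trajectory length. Optional zero-phase low-pass smoothing
#' (second-order Butterworth, filtered forwards and backwards) is applied to
#' the marker positions before fitting; the motion is quasi-static, so a low
#' cutoff suppresses marker noise without biasing end ranges. Smoothing
#' requires a gap-free trajectory.
#'
#' @param traj A \code{marker_trajectory}.
#' @param model A \code{spine_model}.
#' @param vertebra One of \code{"C0"}, \code{"C1"}, \code{"C2"}, \code{"C3"}.
#' @param smooth Logical; apply zero-phase low-pass smoothing (default FALSE).
#' @param cutoff_hz Smoothing cutoff frequency, Hz (default 6).
#' @return A list of class \code{pose_series}: \code{vertebra}, \code{R}
#'   (array 3 x 3 x n), \code{t} (n x 3), \code{missing} (logical n),
#'   \code{time_s}.
#' @export
pose_series <- function(traj, model, vertebra, smooth = FALSE, cutoff_hz = 6) {
  stopifnot(inherits(traj, "marker_trajectory"))
  if (!vertebra %in% unique(traj$labels$vertebra)) {
    stop("vertebra ", vertebra, " is not present in the trajectory")
  }
  idx <- which(traj$labels$vertebra == vertebra)
  local_all <- model$vertebrae[[vertebra]]$markers[traj$labels$marker[idx], , drop = FALSE]
  n <- n_frames(traj)
  pos <- traj$positions[, idx, , drop = FALSE]
  miss <- traj$missing[, idx, drop = FALSE]

  if (smooth) {
    if (any(miss)) stop("smoothing requires a gap-free trajectory (no occluded markers)")
    bf <- signal::butter(2, min(0.99, cutoff_hz / (traj$rate_hz / 2)), type = "low")
    for (m in seq_along(idx)) for (d in 1:3) {
      pos[, m, d] <- zero_phase_filter(bf, pos[, m, d], traj$rate_hz, cutoff_hz)
    }
  }

  Rs <- array(NA_real_, dim = c(3, 3, n))
  ts <- matrix(NA_real_, n, 3)
  missing_frame <- logical(n)
  for (f in seq_len(n)) {
    vis <- which(!miss[f, ])
    if (length(vis) < 3) { missing_frame[f] <- TRUE; next }
    obs <- matrix(pos[f, vis, ], ncol = 3)
    p <- fit_rigid_procrustes(local_all[vis, , drop = FALSE], obs)
    Rs[, , f] <- p$R
    ts[f, ] <- p$t
  }
  structure(list(vertebra = vertebra, R = Rs, t = ts,
                 missing = missing_frame, time_s = traj$time_s),
            class = "pose_series")
}

# Zero-phase low-pass with symmetric reflection padding at both ends: the
# plain forward-backward filter starts from zero state, which on signals
# with a large DC offset (marker coordinates are tens of mm) produces edge
# transients far larger than the motion itself. Even reflection is
# transient-free here because quasi-static trials start and end at rest
# (zero velocity), and unlike point-pivot reflection it does not amplify
# the noise of the endpoint samples.
zero_phase_filter <- function(bf, x, rate_hz, cutoff_hz) {
  n <- length(x)
  npad <- min(n - 1, ceiling(3 * rate_hz / cutoff_hz))
  y <- signal::filtfilt(bf, c(x[seq(npad + 1, 2)], x, x[seq(n - 1, n - npad)]))
  y[(npad + 1):(npad + n)]
}

#' Relative sagittal joint angle series between two vertebrae
#'
#' Per frame, the relative rotation is \code{R_rel = t(R_lower) R_upper}; the
#' sagittal angle is the signed rotation component about the lower vertebra's
#' medio-lateral (+Y) axis extracted by axis-angle projection, with flexion
#' positive. The anterior-posterior translation is the anterior (+X)
#' component, in the lower body's frame, of the displacement of the upper
#' body's origin relative to its neutral position in that frame.
#'
#' @param upper,lower \code{pose_series} of the upper and lower vertebra.
#' @param model A \code{spine_model} (supplies the neutral relative offset
#'   and the medio-lateral axis).
#' @param joint Joint label for the output (default from the vertebra pair).
#' @return A data.frame of class \code{joint_angle_series}: \code{frame},
#'   \code{time_s}, \code{joint}, \code{theta_deg}, \code{ap_translation_mm},
#'   \code{missing}.
#' @export
relative_angle <- function(upper, lower, model = default_spine_model(),
                           joint = NULL) {
  n <- length(upper$missing)
  if (length(lower$missing) != n) {
    stop("upper and lower pose series have different frame counts")
  }
  if (is.null(joint)) joint <- paste0(upper$vertebra, lower$vertebra)
  axis <- model$sagittal_axis
  neutral_rel <- model$vertebrae[[upper$vertebra]]$origin -
    model$vertebrae[[lower$vertebra]]$origin
  theta <- rep(NA_real_, n)
  ap <- rep(NA_real_, n)
  miss <- upper$missing | lower$missing
  for (f in which(!miss)) {
    Rl <- lower$R[, , f]; Ru <- upper$R[, , f]
    Rrel <- crossprod(Rl, Ru)
    theta[f] <- signed_angle_about_axis(Rrel, axis)
    rel_t <- as.numeric(crossprod(Rl, upper$t[f, ] - lower$t[f, ]))
    ap[f] <- rel_t[1] - neutral_rel[1]
  }
  if (any(abs(theta[!miss]) > 90)) {
    warning("relative sagittal angle exceeds 90 degrees; check registration")
  }
  out <- data.frame(frame = seq_len(n), time_s = upper$time_s, joint = joint,
                    theta_deg = theta, ap_translation_mm = ap, missing = miss,
                    stringsAsFactors = FALSE)
  class(out) <- c("joint_angle_series", "data.frame")
  out
}

#' Range-of-motion summary over joint angle series
#'
#' Flexion end range is the maximum positive angle of the cleaned series;
#' extension end range is the magnitude of the most negative angle. Missing
#' frames are excluded from the extrema, never interpolated.
#'
#' @param ... One or more \code{joint_angle_series} data.frames (or a single
#'   list of them).
#' @param condition Optional condition label attached to the summary.
#' @return A data.frame: \code{joint}, \code{flexion_deg},
#'   \code{extension_deg}, \code{max_ap_translation_mm}, \code{condition}.
#' @export
rom_summary <- function(..., condition = NA_character_) {
  series <- list(...)
  if (length(series) == 1 && !inherits(series[[1]], "data.frame")) {
    series <- series[[1]]
  }
  if (length(series) == 0) stop("no angle series supplied")
  out <- lapply(series, function(s) {
    ok <- !s$missing & is.finite(s$theta_deg)
    if (!any(ok)) stop("angle series for joint ", s$joint[1], " is all-missing")
    th <- s$theta_deg[ok]
    data.frame(joint = s$joint[1],
               flexion_deg = max(c(th[th > 0], 0)),
               extension_deg = abs(min(c(th[th < 0], 0))),
               max_ap_translation_mm = max(abs(s$ap_translation_mm[ok])),
               condition = condition,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Radiographic instability predicate
#'
#' TRUE iff the intervertebral angle strictly exceeds the angular threshold
#' or the horizontal displacement strictly exceeds the displacement
#' threshold ("more than 11 degrees" / "exceeds 3.5 mm"): values exactly at
#' a threshold classify stable.
#'
#' @param angle_deg Intervertebral angulation, degrees.
#' @param displacement_mm Horizontal intervertebral displacement, mm.
#' @param criterion An \code{\link{instability_criterion}}.
#' @return Logical.
#' @export
classify_instability <- function(angle_deg, displacement_mm,
                                 criterion = instability_criterion()) {
  stopifnot(all(is.finite(angle_deg)), all(is.finite(displacement_mm)))
  angle_deg > criterion$angle_threshold_deg |
    displacement_mm > criterion$displacement_threshold_mm
}

#' Joint-level instability report
#'
#' Applies the radiographic criterion to a ROM summary. The angular branch
#' of the criterion comes from flexion imaging of the (sub-axial) cervical
#' spine, and physiological upper-cervical extension ranges already exceed
#' 11 degrees, so the angular test is applied to the flexion end range; the
#' displacement branch uses the largest anterior-posterior translation in
#' either direction. Extension end ranges are reported alongside, flagged as
#' outside the criterion's domain of validity.
#'
#' @param rom Output of \code{\link{rom_summary}}.
#' @param criterion An \code{\link{instability_criterion}}.
#' @return A data.frame: \code{joint}, \code{flexion_deg},
#'   \code{extension_deg}, \code{max_ap_translation_mm}, \code{unstable}
#'   (criterion verdict), \code{extension_in_criterion_domain} (FALSE).
#' @export
instability_report <- function(rom, criterion = instability_criterion()) {
  data.frame(joint = rom$joint,
             flexion_deg = rom$flexion_deg,
             extension_deg = rom$extension_deg,
             max_ap_translation_mm = rom$max_ap_translation_mm,
             unstable = classify_instability(rom$flexion_deg,
                                             rom$max_ap_translation_mm,
                                             criterion),
             extension_in_criterion_domain = FALSE,
             stringsAsFactors = FALSE)
}

#' Full kinematic pipeline: trajectory to ROM summary
#'
#' Convenience wrapper chaining neutral registration, per-vertebra pose
#' series, relative joint angles and the ROM summary for the three joints.
#'
#' @param traj A \code{marker_trajectory}.
#' @param model A \code{spine_model}.
#' @param smooth,cutoff_hz Passed to \code{\link{pose_series}}.
#' @param condition Condition label for the summary.
#' @param registration_method Passed to
#'   \code{\link{register_model_to_neutral}}.
#' @return A list: \code{registration} (per-vertebra neutral poses),
#'   \code{angles} (list of \code{joint_angle_series}), \code{rom}
#'   (ROM summary data.frame).
#' @export
kinematics_pipeline <- function(traj, model = default_spine_model(),
                                smooth = FALSE, cutoff_hz = 6,
                                condition = NA_character_,
                                registration_method = "triangle") {
  reg <- register_model_to_neutral(model, traj, method = registration_method)
  ps <- lapply(c("C0", "C1", "C2", "C3"), function(v) {
    pose_series(traj, model, v, smooth = smooth, cutoff_hz = cutoff_hz)
  })
  names(ps) <- c("C0", "C1", "C2", "C3")
  angles <- list(
    C0C1 = relative_angle(ps$C0, ps$C1, model),
    C1C2 = relative_angle(ps$C1, ps$C2, model),
    C2C3 = relative_angle(ps$C2, ps$C3, model)
  )
  list(registration = reg, poses = ps, angles = angles,
       rom = rom_summary(angles, condition = condition))
}
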