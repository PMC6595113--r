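#' Default per-joint ranges of motion
#'
#' End-range sagittal angles (degrees) per joint and direction for the two
#' study conditions. The physiological set is 3.49/8.84 degrees flexion and
#' 11.16/14.20 degrees extension at C0-C1/C1-C2; after ligament fatigue
#' (instability) the set is 5.51/13.70 flexion and 12.96/17.20 extension.
#' C2-C3 is quasi-fixed (base mounting) and defaults to zero.
#'
#' @param condition \code{"physiological"} or \code{"instability"}.
#' @return A data.frame with columns \code{joint}, \code{flexion_deg},
#'   \code{extension_deg}.
#' @export
default_rom <- function(condition = c("physiological", "instability")) {
  condition <- match.arg(condition)
  if (condition == "physiological") {
    data.frame(joint = c("C0C1", "C1C2", "C2C3"),
               flexion_deg = c(3.49, 8.84, 0),
               extension_deg = c(11.16, 14.20, 0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(joint = c("C0C1", "C1C2", "C2C3"),
               flexion_deg = c(5.51, 13.70, 0),
               extension_deg = c(12.96, 17.20, 0),
               stringsAsFactors = FALSE)
  }
}

#' Scenario configuration for the synthetic mocap generator
#'
#' Describes one simulated flexion/extension trial: condition, per-joint
#' end-range ROM, motion profile, duration, sampling rate, marker noise,
#' dropout probability, RNG seed, and a per-ligament stiffness scale
#' (multiplicative; values below 1 encode ligament fatigue and are consumed
#' by the equilibrium module, not by the kinematic generator).
#'
#' @param condition \code{"physiological"} or \code{"instability"}; selects
#'   the default ROM set.
#' @param rom Data.frame like \code{\link{default_rom}} output; overrides the
#'   condition default when supplied.
#' @param motion_profile \code{"raised_cosine"} (smooth start/stop ramps,
#'   default) or \code{"linear_ramp"}.
#' @param duration_s Trial duration, seconds.
#' @param rate_hz Sampling rate, Hz (default 500, the optical system rate).
#' @param noise_sigma_mm Isotropic iid Gaussian marker noise sd, mm
#'   (default 0.1, typical optical mocap precision).
#' @param dropout_prob Per frame-marker occlusion probability in [0, 1).
#' @param seed Integer RNG seed.
#' @param stiffness_scale Positive scalar (or named per-ligament vector).
#' @return A list of class \code{scenario_config}.
#' @export
scenario_config <- function(condition = c("physiological", "instability"),
                            rom = NULL,
                            motion_profile = c("raised_cosine", "linear_ramp"),
                            duration_s = 2.4,
                            rate_hz = 500,
                            noise_sigma_mm = 0.1,
                            dropout_prob = 0,
                            seed = 1L,
                            stiffness_scale = NULL) {
  condition <- match.arg(condition)
  motion_profile <- match.arg(motion_profile)
  if (is.null(rom)) rom <- default_rom(condition)
  if (is.null(stiffness_scale)) {
    stiffness_scale <- if (condition == "physiological") 1 else 0.5
  }
  stopifnot(all(c("joint", "flexion_deg", "extension_deg") %in% names(rom)),
            all(rom$flexion_deg >= 0), all(rom$extension_deg >= 0),
            duration_s > 0, rate_hz > 0,
            noise_sigma_mm >= 0, dropout_prob >= 0, dropout_prob < 1,
            all(stiffness_scale > 0))
  if (any(rom$flexion_deg > 90) || any(rom$extension_deg > 90)) {
    stop("ROM above 90 degrees is non-physiological for the upper cervical spine")
  }
  structure(list(condition = condition, rom = rom,
                 motion_profile = motion_profile, duration_s = duration_s,
                 rate_hz = rate_hz, noise_sigma_mm = noise_sigma_mm,
                 dropout_prob = dropout_prob, seed = as.integer(seed),
                 stiffness_scale = stiffness_scale),
            class = "scenario_config")
}

# Smooth 0 -> 1 ramp on s in [0, 1].
raised_cosine_ramp <- function(s) 0.5 * (1 - cos(pi * s))

# Motion phase over normalized time u in [0, 1]: neutral -> full flexion (+1)
# -> neutral -> full extension (-1) -> neutral, with zero end-point velocity
# at every turning point (quasi-static "slowly moving" loading).
motion_phase <- function(u, profile = "raised_cosine") {
  ramp <- if (profile == "raised_cosine") raised_cosine_ramp else function(s) s
  out <- numeric(length(u))
  seg <- pmin(floor(u * 4), 3)
  s <- u * 4 - seg
  out[seg == 0] <- ramp(s[seg == 0])
  out[seg == 1] <- 1 - ramp(s[seg == 1])
  out[seg == 2] <- -ramp(s[seg == 2])
  out[seg == 3] <- -1 + ramp(s[seg == 3])
  out
}

# Chain the per-joint sagittal rotations into world poses. theta_deg is a
# named vector (C0C1, C1C2, C2C3), flexion positive. C3 is the fixed base.
chain_poses <- function(model, theta_deg) {
  th <- theta_deg * pi / 180
  poses <- list(C3 = rigid_pose(diag(3), model$vertebrae$C3$origin))
  order_up <- c("C2", "C1", "C0")
  joints <- c(C2 = "C2C3", C1 = "C1C2", C0 = "C0C1")
  lower <- c(C2 = "C3", C1 = "C2", C0 = "C1")
  for (v in order_up) {
    jc <- model$joint_centers[[joints[[v]]]]
    pl <- poses[[lower[[v]]]]
    o_l <- model$vertebrae[[lower[[v]]]]$origin
    jc_now <- apply_pose(pl, jc - o_l)
    R <- pl$R %*% rot_y(th[[joints[[v]]]])
    # vertebra-local coordinates are relative to its own origin, which sits
    # at the joint center in the template
    off <- model$vertebrae[[v]]$origin - jc
    poses[[v]] <- rigid_pose(R, jc_now + as.numeric(R %*% off))
  }
  poses[c("C0", "C1", "C2", "C3")]
}

#' Generate a synthetic marker trajectory with known ground truth
#'
#' Emulates the optical motion-capture experiment: the base vertebra (C3) is
#' fixed in the laboratory frame, and C2, C1, C0 poses are composed from
#' prescribed smooth per-joint sagittal rotations that reach the configured
#' end-range ROM in flexion and then extension within one trial. Marker
#' positions are the posed template markers plus iid zero-mean Gaussian noise.
#' The exact prescribed relative angles are returned as ground truth so
#' downstream stages can be tested against them; identical seeds give
#' identical output.
#'
#' @param model A \code{spine_model}.
#' @param scenario A \code{scenario_config}.
#' @return A list with \code{trajectory} (class \code{marker_trajectory}) and
#'   \code{ground_truth} (data.frame: frame, time_s, joint, theta_deg).
#' @export
generate_trajectory <- function(model = default_spine_model(),
                                scenario = scenario_config()) {
  stopifnot(inherits(scenario, "scenario_config"))
  validate_spine_model(model)
  n <- max(5L, round(scenario$duration_s * scenario$rate_hz))
  # pad to a frame grid that samples the flexion/extension end ranges exactly
  n <- n + ((4L - ((n - 1L) %% 4L)) %% 4L)
  time_s <- (seq_len(n) - 1) / scenario$rate_hz
  u <- (seq_len(n) - 1) / (n - 1)
  phase <- motion_phase(u, scenario$motion_profile)
  rom <- scenario$rom
  theta <- matrix(0, nrow = n, ncol = 3,
                  dimnames = list(NULL, c("C0C1", "C1C2", "C2C3")))
  for (j in rom$joint) {
    fl <- rom$flexion_deg[rom$joint == j]
    ex <- rom$extension_deg[rom$joint == j]
    theta[, j] <- ifelse(phase >= 0, fl * phase, ex * phase)
  }

  labels <- marker_labels(model)
  n_mark <- nrow(labels)
  if (n_mark == 0) stop("model has no markers")
  pos <- array(NA_real_, dim = c(n, n_mark, 3))
  for (f in seq_len(n)) {
    poses <- chain_poses(model, theta[f, c("C0C1", "C1C2", "C2C3")])
    for (m in seq_len(n_mark)) {
      v <- labels$vertebra[m]
      pos[f, m, ] <- apply_pose(poses[[v]],
                                model$vertebrae[[v]]$markers[labels$marker[m], ])
    }
  }
  if (scenario$noise_sigma_mm > 0) {
    noise <- with_seed(scenario$seed,
                       array(stats::rnorm(n * n_mark * 3, sd = scenario$noise_sigma_mm),
                             dim = c(n, n_mark, 3)))
    pos <- pos + noise
  }
  traj <- marker_trajectory(rate_hz = scenario$rate_hz, labels = labels,
                            positions = pos,
                            missing = matrix(FALSE, n, n_mark))
  if (scenario$dropout_prob > 0) {
    traj <- apply_dropout(traj, scenario$dropout_prob, seed = scenario$seed + 1L)
  }
  gt <- data.frame(frame = rep(seq_len(n), times = ncol(theta)),
                   time_s = rep(time_s, times = ncol(theta)),
                   joint = rep(colnames(theta), each = n),
                   theta_deg = as.vector(theta),
                   stringsAsFactors = FALSE)
  list(trajectory = traj, ground_truth = gt)
}

marker_labels <- function(model) {
  do.call(rbind, lapply(c("C0", "C1", "C2", "C3"), function(v) {
    data.frame(vertebra = v, marker = rownames(model$vertebrae[[v]]$markers),
               stringsAsFactors = FALSE)
  }))
}

#' Marker trajectory container
#'
#' @param rate_hz Sampling rate, Hz.
#' @param labels Data.frame with columns \code{vertebra}, \code{marker}.
#' @param positions Array \code{[frames, markers, 3]}, mm, laboratory frame.
#' @param missing Logical matrix \code{[frames, markers]}; TRUE = occluded.
#' @return An object of class \code{marker_trajectory}.
#' @export
marker_trajectory <- function(rate_hz, labels, positions, missing = NULL) {
  stopifnot(rate_hz > 0, length(dim(positions)) == 3, dim(positions)[3] == 3,
            dim(positions)[2] == nrow(labels))
  if (is.null(missing)) {
    missing <- matrix(FALSE, dim(positions)[1], dim(positions)[2])
  }
  if (any(!is.finite(positions[!missing_expand(missing)]))) {
    stop("non-missing marker positions must be finite")
  }
  structure(list(rate_hz = rate_hz, labels = labels, positions = positions,
                 missing = missing,
                 time_s = (seq_len(dim(positions)[1]) - 1) / rate_hz),
            class = "marker_trajectory")
}

missing_expand <- function(missing) array(missing, dim = c(dim(missing), 3))

#' @export
print.marker_trajectory <- function(x, ...) {
  cat("marker_trajectory:", dim(x$positions)[1], "frames x",
      dim(x$positions)[2], "markers @", x$rate_hz, "Hz;",
      sum(x$missing), "occluded frame-markers\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A \code{marker_trajectory}.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$positions)[1]

#' Apply random marker occlusion
#'
#' Flags each frame-marker independently as missing with probability
#' \code{prob}; surviving marker positions are unchanged. Deterministic for
#' a given seed.
#'
#' @param traj A \code{marker_trajectory}.
#' @param prob Occlusion probability in [0, 1).
#' @param seed Integer RNG seed.
#' @return The trajectory with an updated \code{missing} mask.
#' @export
apply_dropout <- function(traj, prob, seed = 1L) {
  stopifnot(inherits(traj, "marker_trajectory"), prob >= 0, prob < 1)
  if (prob == 0) return(traj)
  d <- dim(traj$positions)
  mask <- with_seed(seed, matrix(stats::runif(d[1] * d[2]) < prob, d[1], d[2]))
  traj$missing <- traj$missing | mask
  traj
}
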