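#' Sagittal-plane quasi-static equilibrium model
#'
#' Desk-scale surrogate for the continuum finite-element run: three sagittal
#' rotational degrees of freedom (C0-C1, C1-C2, C2-C3) about fixed joint
#' centers, restrained by (i) the discrete tension-only spring ligaments
#' acting along their attachment lines, (ii) a per-joint aggregate torsional
#' stiffness standing in for the membranous structures (tectorial membrane,
#' atlanto-occipital membranes, disc) that are not in the 22-spring set, and
#' (iii) unilateral rotational facet stops with Coulomb friction engaging
#' past the joint clearance. No claim is made that this surrogate reproduces
#' continuum-model angles; it is validated against closed forms and
#' mechanical consistency properties.
#'
#' @param model A \code{spine_model}.
#' @param ligaments Ligament table (\code{\link{default_ligament_table}}).
#' @param joint_stiffness Named vector, aggregate torsional stiffness per
#'   joint, N.mm/degree.
#' @param stops Data.frame: \code{joint}, \code{flexion_stop_deg},
#'   \code{extension_stop_deg}, \code{k_stop} (N.mm/degree past the stop).
#' @param contact A \code{\link{contact_spec}} (friction, clearance).
#' @param facet_radius_mm Effective facet radius converting the joint
#'   clearance into a clearance angle.
#' @param preload_point_local Application point of the compressive preload,
#'   C0-local coordinates, mm (default 10 mm anterior of the C0-C1 center).
#' @return A list of class \code{equilibrium_model}.
#' @export
equilibrium_model <- function(model = default_spine_model(),
                              ligaments = default_ligament_table(model),
                              joint_stiffness = c(C0C1 = 150, C1C2 = 100, C2C3 = 200),
                              stops = data.frame(
                                joint = c("C0C1", "C1C2", "C2C3"),
                                flexion_stop_deg = c(15, 16, 12),
                                extension_stop_deg = c(18, 20, 12),
                                k_stop = 5000,
                                stringsAsFactors = FALSE),
                              contact = contact_spec(),
                              facet_radius_mm = 20,
                              preload_point_local = c(10, 0, 5)) {
  stopifnot(all(c("C0C1", "C1C2", "C2C3") %in% names(joint_stiffness)),
            all(joint_stiffness >= 0), all(stops$k_stop > 0),
            facet_radius_mm > 0)
  lig <- precompute_ligaments(model, ligaments)
  structure(list(model = model, ligaments = ligaments, lig = lig,
                 joint_stiffness = joint_stiffness, stops = stops,
                 contact = contact, facet_radius_mm = facet_radius_mm,
                 preload_point_local = as.numeric(preload_point_local)),
            class = "equilibrium_model")
}

# Resolve attachment coordinates and rest lengths once.
precompute_ligaments <- function(model, ligaments) {
  if (nrow(ligaments) == 0) return(list())
  lapply(seq_len(nrow(ligaments)), function(i) {
    s <- ligaments[i, ]
    list(name = s$name, k = s$rigidity_k,
         ov = s$origin_vertebra,
         op = model$vertebrae[[s$origin_vertebra]]$attachments[[s$origin_point]],
         iv = s$insertion_vertebra,
         ip = model$vertebrae[[s$insertion_vertebra]]$attachments[[s$insertion_point]],
         L0 = s$rest_length_L0)
  })
}

JOINTS <- c("C0C1", "C1C2", "C2C3")
# vertebrae distal to (carried by) each joint
ABOVE <- list(C0C1 = "C0", C1C2 = c("C0", "C1"), C2C3 = c("C0", "C1", "C2"))
DEG2RAD <- pi / 180

# Current world joint centers given chained poses.
joint_centers_now <- function(emod, poses) {
  m <- emod$model
  list(
    C2C3 = m$joint_centers$C2C3,
    C1C2 = apply_pose(poses$C2, m$joint_centers$C1C2 - m$vertebrae$C2$origin),
    C0C1 = apply_pose(poses$C1, m$joint_centers$C0C1 - m$vertebrae$C1$origin)
  )
}

# Full mechanical state at a configuration. Returns per-joint generalized
# moments (N.mm) of every contribution, per-ligament elongation and force,
# contact engagement, and stored elastic energy (N.mm).
mechanics_at <- function(emod, theta_deg, load, stiffness_scale = 1,
                         fric_dir = 0) {
  scale_of <- function(name) {
    if (length(stiffness_scale) == 1) return(stiffness_scale)
    if (!is.null(names(stiffness_scale)) && name %in% names(stiffness_scale)) {
      return(stiffness_scale[[name]])
    }
    1
  }
  poses <- chain_poses(emod$model, theta_deg)
  jc <- joint_centers_now(emod, poses)
  axis <- emod$model$sagittal_axis

  Q_lig <- stats::setNames(numeric(3), JOINTS)
  lig_dl <- numeric(length(emod$lig))
  lig_F <- numeric(length(emod$lig))
  E_lig <- 0
  for (i in seq_along(emod$lig)) {
    lg <- emod$lig[[i]]
    p_o <- apply_pose(poses[[lg$ov]], lg$op)
    p_i <- apply_pose(poses[[lg$iv]], lg$ip)
    d <- p_i - p_o
    L <- sqrt(sum(d^2))
    dl <- L - lg$L0
    k <- lg$k * scale_of(lg$name)
    Tf <- if (dl > 0) k * dl else 0
    lig_dl[i] <- dl; lig_F[i] <- Tf
    if (Tf > 0) {
      E_lig <- E_lig + 0.5 * k * dl^2
      u <- d / L
      for (j in JOINTS) {
        above <- ABOVE[[j]]
        # force on each endpoint attached to a vertebra carried by joint j
        if (lg$ov %in% above) {
          Q_lig[j] <- Q_lig[j] + sum(pracma_cross(p_o - jc[[j]], Tf * u) * axis)
        }
        if (lg$iv %in% above) {
          Q_lig[j] <- Q_lig[j] + sum(pracma_cross(p_i - jc[[j]], -Tf * u) * axis)
        }
      }
    }
  }

  # compressive preload at a point rigid with C0
  p_pre <- apply_pose(poses$C0, emod$preload_point_local)
  f_pre <- c(0, 0, -load$preload_F)
  Q_pre <- vapply(JOINTS, function(j) {
    sum(pracma_cross(p_pre - jc[[j]], f_pre) * axis)
  }, numeric(1))

  # aggregate torsional restraint; a scalar stiffness_scale softens the whole
  # soft-tissue envelope (ligaments and aggregate), a named vector is
  # per-ligament only
  ks <- vapply(JOINTS, function(j) emod$joint_stiffness[[j]], numeric(1))
  if (length(stiffness_scale) == 1) ks <- ks * stiffness_scale
  Q_tors <- -ks * theta_deg[JOINTS]
  E_tors <- sum(0.5 * ks * theta_deg[JOINTS]^2) * DEG2RAD

  # unilateral facet stops past the clearance angle, with Coulomb friction
  clear_deg <- emod$contact$clearance_mm / emod$facet_radius_mm / DEG2RAD
  Q_stop <- stats::setNames(numeric(3), JOINTS)
  Q_fric <- stats::setNames(numeric(3), JOINTS)
  E_stop <- 0
  engaged <- stats::setNames(logical(3), JOINTS)
  for (j in JOINTS) {
    srow <- emod$stops[emod$stops$joint == j, ]
    th <- theta_deg[[j]]
    lim <- if (th >= 0) srow$flexion_stop_deg else srow$extension_stop_deg
    excess <- abs(th) - lim - clear_deg
    if (excess > 0) {
      engaged[j] <- TRUE
      Mstop <- srow$k_stop * excess
      Q_stop[j] <- -sign(th) * Mstop
      E_stop <- E_stop + 0.5 * srow$k_stop * excess^2 * DEG2RAD
      if (fric_dir != 0) {
        Q_fric[j] <- -fric_dir * emod$contact$friction_mu * Mstop
      }
    }
  }

  M_applied <- if (load$direction == "flexion") load$moment_M else -load$moment_M
  residual <- M_applied + Q_pre + Q_lig + Q_tors + Q_stop + Q_fric
  list(residual = residual, Q_lig = Q_lig, Q_pre = Q_pre, Q_tors = Q_tors,
       Q_stop = Q_stop, Q_fric = Q_fric, lig_dl = lig_dl, lig_F = lig_F,
       engaged = engaged, E_elastic = E_lig + E_tors + E_stop,
       preload_z = p_pre[3])
}

#' Solve quasi-static sagittal equilibrium
#'
#' Finds the joint angles at which the net sagittal moment at each free joint
#' vanishes: applied moment + preload-induced moment - ligament restoring
#' moments - aggregate torsional moment - facet-stop moment (- Coulomb
#' friction when contact is engaged) = 0. Damped Newton iteration on the
#' stacked residual with a finite-difference Jacobian; falls back to
#' per-joint bisection (Gauss-Seidel sweeps) if Newton stalls. The residual
#' is monotone in each angle, so the solution is independent of the initial
#' guess in the monotone regime.
#'
#' @param emod An \code{\link{equilibrium_model}}.
#' @param load A \code{\link{load_case}}.
#' @param stiffness_scale Positive scalar (scales all ligament and aggregate
#'   joint stiffnesses; below 1 encodes soft-tissue fatigue) or named
#'   per-ligament vector.
#' @param joints Character vector of free joints (others held at 0).
#' @param theta0 Optional named initial guess, degrees.
#' @param friction Logical; include Coulomb friction at engaged stops,
#'   resisting the loading direction (default TRUE).
#' @param tol Convergence tolerance on the residual moment, N.mm.
#' @param max_iter Maximum Newton iterations.
#' @return A list of class \code{equilibrium_state}: \code{theta_deg} (named,
#'   all three joints), \code{moment_Nmm} (signed applied), \code{residual},
#'   \code{ligaments} (data.frame name, dl_mm, force_N), \code{engaged}
#'   (named logical), \code{E_elastic}, \code{preload_z}, \code{converged},
#'   \code{iterations}.
#' @export
solve_static <- function(emod, load = load_case(), stiffness_scale = 1,
                         joints = JOINTS, theta0 = NULL, friction = TRUE,
                         tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(emod, "equilibrium_model"), inherits(load, "load_case"))
  if (any(stiffness_scale <= 0)) stop("stiffness_scale must be strictly positive")
  th <- stats::setNames(numeric(3), JOINTS)
  if (!is.null(theta0)) th[names(theta0)] <- theta0
  fric_dir <- if (!friction) 0 else if (load$direction == "flexion") 1 else -1

  res_fun <- function(x) {
    th[joints] <- x
    mechanics_at(emod, th, load, stiffness_scale, fric_dir)$residual[joints]
  }
  x <- th[joints]
  r <- res_fun(x)
  iter <- 0L
  h <- 1e-4
  while (max(abs(r)) > tol && iter < max_iter) {
    iter <- iter + 1L
    J <- matrix(0, length(x), length(x))
    for (k in seq_along(x)) {
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      J[, k] <- (res_fun(xp) - res_fun(xm)) / (2 * h)
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    improved <- FALSE
    if (!is.null(step)) {
      lambda <- 1
      for (half in 1:40) {
        xn <- x + lambda * step
        rn <- res_fun(xn)
        if (max(abs(rn)) < max(abs(r))) {
          x <- xn; r <- rn; improved <- TRUE; break
        }
        lambda <- lambda / 2
      }
    }
    if (!improved) {
      # Gauss-Seidel bisection sweeps: residual_j is monotone decreasing in
      # theta_j, so a wide bracket always contains the per-joint root
      for (sweep in 1:200) {
        for (k in seq_along(x)) {
          fk <- function(v) { xx <- x; xx[k] <- v; res_fun(xx)[k] }
          lo <- -80; hi <- 80
          if (fk(lo) < 0 || fk(hi) > 0) {
            stop("equilibrium bracket failure at joint ", joints[k],
                 "; residual report: ", paste(signif(r, 6), collapse = ", "))
          }
          x[k] <- stats::uniroot(fk, c(lo, hi), tol = 1e-12)$root
        }
        r <- res_fun(x)
        if (max(abs(r)) <= tol) break
      }
      break
    }
  }
  if (max(abs(r)) > tol) {
    stop("equilibrium solver did not converge after ", iter,
         " iterations; residual (N.mm): ", paste(signif(r, 6), collapse = ", "))
  }
  th[joints] <- x
  mech <- mechanics_at(emod, th, load, stiffness_scale, fric_dir)
  lig_names <- vapply(emod$lig, `[[`, character(1), "name")
  structure(list(theta_deg = th,
                 moment_Nmm = if (load$direction == "flexion") load$moment_M else -load$moment_M,
                 residual = mech$residual,
                 ligaments = data.frame(name = lig_names, dl_mm = mech$lig_dl,
                                        force_N = mech$lig_F,
                                        stringsAsFactors = FALSE),
                 engaged = mech$engaged, E_elastic = mech$E_elastic,
                 preload_z = mech$preload_z,
                 converged = TRUE, iterations = iter),
            class = "equilibrium_state")
}

#' Quasi-static moment sweep
#'
#' Solves the equilibrium at a ramp of applied moments from 0 to
#' \code{max_moment_Nmm} (1.5 N.m default; 300 N.mm reproduces the lighter
#' literature load), warm-starting each step at the previous solution.
#'
#' @param emod An \code{\link{equilibrium_model}}.
#' @param direction \code{"flexion"} or \code{"extension"}.
#' @param n_steps Number of moment steps (>= 2).
#' @param max_moment_Nmm Final moment, N.mm.
#' @param preload_F Compressive preload, N.
#' @param stiffness_scale As in \code{\link{solve_static}}.
#' @param friction Logical; Coulomb friction at engaged stops.
#' @return A list of class \code{moment_sweep}: \code{states} (list of
#'   \code{equilibrium_state}), \code{table} (data.frame moment_Nmm,
#'   theta_C0C1_deg, theta_C1C2_deg, theta_C2C3_deg, n_engaged_contacts),
#'   \code{friction_dissipation_Nmm}, \code{direction}.
#' @export
moment_sweep <- function(emod, direction = c("flexion", "extension"),
                         n_steps = 50, max_moment_Nmm = 1500,
                         preload_F = 100, stiffness_scale = 1,
                         friction = TRUE) {
  direction <- match.arg(direction)
  stopifnot(n_steps >= 2)
  moments <- seq(0, max_moment_Nmm, length.out = n_steps)
  states <- vector("list", n_steps)
  prev <- NULL
  dissipation <- 0
  for (i in seq_len(n_steps)) {
    ld <- load_case(preload_F = preload_F, moment_M = moments[i],
                    direction = direction)
    st <- tryCatch(
      solve_static(emod, ld, stiffness_scale = stiffness_scale,
                   theta0 = if (is.null(prev)) NULL else prev$theta_deg,
                   friction = friction),
      error = function(e) stop("sweep failed at step ", i, " (moment ",
                               signif(moments[i], 6), " N.mm): ",
                               conditionMessage(e)))
    if (!is.null(prev) && friction) {
      mu <- emod$contact$friction_mu
      for (j in JOINTS) {
        if (st$engaged[[j]] || prev$engaged[[j]]) {
          Mn <- mean(c(stop_moment(emod, st, j), stop_moment(emod, prev, j)))
          dissipation <- dissipation +
            mu * Mn * abs(st$theta_deg[[j]] - prev$theta_deg[[j]]) * DEG2RAD
        }
      }
    }
    states[[i]] <- st
    prev <- st
  }
  tab <- data.frame(
    moment_Nmm = moments,
    theta_C0C1_deg = vapply(states, function(s) s$theta_deg[["C0C1"]], numeric(1)),
    theta_C1C2_deg = vapply(states, function(s) s$theta_deg[["C1C2"]], numeric(1)),
    theta_C2C3_deg = vapply(states, function(s) s$theta_deg[["C2C3"]], numeric(1)),
    n_engaged_contacts = vapply(states, function(s) 2L * sum(s$engaged), integer(1))
  )
  structure(list(states = states, table = tab,
                 friction_dissipation_Nmm = dissipation,
                 direction = direction, preload_F = preload_F),
            class = "moment_sweep")
}

# |stop moment| at a state, N.mm.
stop_moment <- function(emod, state, j) {
  srow <- emod$stops[emod$stops$joint == j, ]
  th <- state$theta_deg[[j]]
  clear_deg <- emod$contact$clearance_mm / emod$facet_radius_mm / DEG2RAD
  lim <- if (th >= 0) srow$flexion_stop_deg else srow$extension_stop_deg
  max(abs(th) - lim - clear_deg, 0) * srow$k_stop
}

#' Work-energy audit of a moment sweep
#'
#' Checks quasi-static consistency: external work done by the applied moment
#' (trapezoidal integral of M dtheta_total) plus work done by the preload
#' (drop of its application point) must equal the change in stored elastic
#' energy (ligaments + aggregate torsional + stops) plus frictional
#' dissipation.
#'
#' @param sweep A \code{\link{moment_sweep}} result.
#' @return A list: \code{work_moment_Nmm}, \code{work_preload_Nmm},
#'   \code{delta_elastic_Nmm}, \code{dissipation_Nmm},
#'   \code{imbalance_fraction} (|lhs - rhs| / max(|lhs|, |rhs|)).
#' @export
energy_audit <- function(sweep) {
  states <- sweep$states
  n <- length(states)
  th_tot <- vapply(states, function(s) sum(s$theta_deg), numeric(1)) * DEG2RAD
  M <- vapply(states, function(s) s$moment_Nmm, numeric(1))
  W_m <- sum(0.5 * (M[-1] + M[-n]) * diff(th_tot))
  z <- vapply(states, function(s) s$preload_z, numeric(1))
  # preload force is -F z-hat; its work is F * (z_initial - z_final)
  W_p <- sweep$preload_F * (z[1] - z[n])
  dE <- states[[n]]$E_elastic - states[[1]]$E_elastic
  lhs <- W_m + W_p
  rhs <- dE + sweep$friction_dissipation_Nmm
  list(work_moment_Nmm = W_m, work_preload_Nmm = W_p,
       delta_elastic_Nmm = dE, dissipation_Nmm = sweep$friction_dissipation_Nmm,
       imbalance_fraction = abs(lhs - rhs) / max(abs(lhs), abs(rhs), 1e-12))
}
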