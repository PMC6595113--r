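# Atomic file writes: write to a temp file in the target directory, then
# rename, so failed runs never leave partial outputs behind.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file onto ", path)
  ok <- TRUE
  invisible(path)
}

# Adler-32 checksum of a configuration, for output provenance headers.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  bytes <- utf8ToInt(s)
  a <- 1; b <- 0
  for (v in bytes) {
    a <- (a + v) %% 65521
    b <- (b + a) %% 65521
  }
  sprintf("%04x%04x", b, a)
}

write_metadata_header <- function(con, metadata = NULL) {
  pkg_ver <- as.character(utils::packageVersion("ucspine"))
  writeLines(paste0("# ucspine ", pkg_ver), con)
  if (!is.null(metadata)) {
    for (nm in names(metadata)) {
      writeLines(paste0("# ", nm, ": ", metadata[[nm]]), con)
    }
  }
}

#' Write a marker trajectory as a TRC file
#'
#' Standard tab-delimited motion-capture interchange format: header with
#' DataRate/NumFrames/NumMarkers/Units (mm), then one row per frame with
#' Frame#, Time and X/Y/Z triplets per marker. Positions are written with
#' four decimals; occluded frame-markers are written as empty fields.
#' Output is byte-identical for identical trajectories.
#'
#' @param traj A \code{marker_trajectory}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trc <- function(traj, path) {
  stopifnot(inherits(traj, "marker_trajectory"))
  n <- n_frames(traj)
  nm <- nrow(traj$labels)
  names_full <- paste(traj$labels$vertebra, traj$labels$marker, sep = "_")
  hdr1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  hdr2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t")
  hdr3 <- paste(fmt_num(traj$rate_hz), fmt_num(traj$rate_hz), n, nm, "mm",
                fmt_num(traj$rate_hz), 1, n, sep = "\t")
  hdr4 <- paste(c("Frame#", "Time",
                  as.vector(rbind(names_full, "", ""))), collapse = "\t")
  hdr5 <- paste(c("", "",
                  as.vector(rbind(paste0("X", seq_len(nm)),
                                  paste0("Y", seq_len(nm)),
                                  paste0("Z", seq_len(nm))))), collapse = "\t")
  rows <- vapply(seq_len(n), function(f) {
    cells <- character(3 * nm)
    for (m in seq_len(nm)) {
      idx <- (m - 1) * 3 + 1:3
      if (traj$missing[f, m]) {
        cells[idx] <- ""
      } else {
        cells[idx] <- sprintf("%.4f", traj$positions[f, m, ])
      }
    }
    paste(c(as.character(f), sprintf("%.6f", traj$time_s[f]), cells),
          collapse = "\t")
  }, character(1))
  atomic_write(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeLines(c(hdr1, hdr2, hdr3, hdr4, hdr5, "", rows), con, sep = "\n")
  })
  invisible(path)
}

fmt_num <- function(x) {
  if (x == round(x)) as.character(as.integer(x)) else as.character(x)
}

#' Read a TRC marker trajectory
#'
#' @param path TRC file path.
#' @return A \code{marker_trajectory}. Marker names of the form
#'   \code{vertebra_label} are split at the first underscore.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("malformed TRC file (fewer than 6 lines): ", path)
  meta <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  rate <- as.numeric(meta[1]); nfr <- as.integer(meta[3]); nm <- as.integer(meta[4])
  if (!is.finite(rate) || is.na(nfr) || is.na(nm)) {
    stop("malformed TRC header at line 3: ", path)
  }
  if (!identical(meta[5], "mm")) stop("TRC units must be mm, got: ", meta[5])
  name_cells <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  names_full <- name_cells[seq(3, by = 3, length.out = nm)]
  vert <- sub("_.*$", "", names_full)
  mark <- sub("^[^_]*_", "", names_full)
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) != nfr) {
    stop("TRC body has ", length(data_lines), " data rows at line ",
         5 + which(c(length(data_lines) < nfr, TRUE))[1],
         " onward but header declares ", nfr, " frames: ", path)
  }
  pos <- array(NA_real_, dim = c(nfr, nm, 3))
  miss <- matrix(FALSE, nfr, nm)
  for (f in seq_len(nfr)) {
    cells <- strsplit(data_lines[f], "\t", fixed = TRUE)[[1]]
    if (length(cells) < 2 + 3 * nm) cells <- c(cells, rep("", 2 + 3 * nm - length(cells)))
    for (m in seq_len(nm)) {
      v <- cells[2 + (m - 1) * 3 + 1:3]
      if (all(nzchar(v))) {
        pos[f, m, ] <- as.numeric(v)
      } else {
        miss[f, m] <- TRUE
      }
    }
  }
  marker_trajectory(rate_hz = rate,
                    labels = data.frame(vertebra = vert, marker = mark,
                                        stringsAsFactors = FALSE),
                    positions = pos, missing = miss)
}

#' Write a marker trajectory as long-format CSV
#'
#' Columns: frame, time_s, vertebra, marker, x, y, z, missing. Occluded
#' positions are written as NA.
#'
#' @param traj A \code{marker_trajectory}.
#' @param path Output path.
#' @param metadata Optional named vector for the comment header.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, metadata = NULL) {
  n <- n_frames(traj); nm <- nrow(traj$labels)
  df <- data.frame(
    frame = rep(seq_len(n), each = nm),
    time_s = rep(traj$time_s, each = nm),
    vertebra = rep(traj$labels$vertebra, times = n),
    marker = rep(traj$labels$marker, times = n),
    x = as.vector(t(traj$positions[, , 1])),
    y = as.vector(t(traj$positions[, , 2])),
    z = as.vector(t(traj$positions[, , 3])),
    missing = as.vector(t(traj$missing)),
    stringsAsFactors = FALSE)
  df$x[df$missing] <- NA; df$y[df$missing] <- NA; df$z[df$missing] <- NA
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    write_metadata_header(con, metadata)
    utils::write.csv(df, con, row.names = FALSE)
  })
  invisible(path)
}

#' Read a long-format trajectory CSV
#'
#' @param path CSV path (layout of \code{\link{write_trajectory_csv}}).
#' @param rate_hz Sampling rate; inferred from the time column when NULL.
#' @return A \code{marker_trajectory}.
#' @export
read_trajectory_csv <- function(path, rate_hz = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "vertebra", "marker", "x", "y", "z", "missing")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  }
  frames <- sort(unique(df$frame))
  lab <- unique(df[df$frame == frames[1], c("vertebra", "marker")])
  key <- paste(lab$vertebra, lab$marker)
  nm <- nrow(lab); n <- length(frames)
  if (is.null(rate_hz)) {
    dt <- diff(sort(unique(df$time_s)))
    rate_hz <- if (length(dt)) 1 / stats::median(dt) else 1
  }
  pos <- array(NA_real_, dim = c(n, nm, 3))
  miss <- matrix(TRUE, n, nm)
  fi <- match(df$frame, frames)
  mi <- match(paste(df$vertebra, df$marker), key)
  for (r in seq_len(nrow(df))) {
    if (isTRUE(df$missing[r]) || is.na(df$x[r])) next
    pos[fi[r], mi[r], ] <- c(df$x[r], df$y[r], df$z[r])
    miss[fi[r], mi[r]] <- FALSE
  }
  marker_trajectory(rate_hz = rate_hz, labels = lab, positions = pos,
                    missing = miss)
}

scenario_fields <- c("condition", "rom", "motion_profile", "duration_s",
                     "rate_hz", "noise_sigma_mm", "dropout_prob", "seed",
                     "stiffness_scale")

#' Write a scenario configuration as JSON
#' @param scenario A \code{scenario_config}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scenario_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_config"))
  atomic_write(path, function(tmp) {
    jsonlite::write_json(unclass(scenario), tmp, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, dataframe = "columns")
  })
  invisible(path)
}

#' Read a scenario configuration from JSON
#'
#' The schema is strict: unknown keys are rejected, so typos in
#' configuration files fail loudly instead of silently using defaults.
#'
#' @param path JSON path.
#' @return A \code{scenario_config}.
#' @export
read_scenario_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), scenario_fields)
  if (length(unknown)) {
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  }
  rom <- if (!is.null(raw$rom)) as.data.frame(raw$rom) else NULL
  scenario_config(condition = raw$condition %||% "physiological",
                  rom = rom,
                  motion_profile = raw$motion_profile %||% "raised_cosine",
                  duration_s = raw$duration_s %||% 2.4,
                  rate_hz = raw$rate_hz %||% 500,
                  noise_sigma_mm = raw$noise_sigma_mm %||% 0.1,
                  dropout_prob = raw$dropout_prob %||% 0,
                  seed = raw$seed %||% 1L,
                  stiffness_scale = raw$stiffness_scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a trial and write it to disk
#'
#' Wraps \code{\link{generate_trajectory}}: writes the TRC file and a
#' ground-truth JSON sidecar (scenario echo, seed, config hash, end-range
#' angles, full prescribed angle series) so downstream tests never have to
#' re-derive the truth.
#'
#' @param scenario A \code{scenario_config}.
#' @param out_dir Output directory (created if needed).
#' @param model A \code{spine_model}.
#' @param basename Output file stem (default \code{"trial"}).
#' @return A list with \code{trc}, \code{ground_truth_json} paths and the
#'   generated objects.
#' @export
run_generate <- function(scenario, out_dir, model = default_spine_model(),
                         basename = "trial") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_trajectory(model, scenario)
  trc_path <- file.path(out_dir, paste0(basename, ".trc"))
  write_trc(gen$trajectory, trc_path)
  gt <- gen$ground_truth
  end_ranges <- do.call(rbind, lapply(split(gt, gt$joint), function(g) {
    data.frame(joint = g$joint[1],
               flexion_deg = max(c(g$theta_deg[g$theta_deg > 0], 0)),
               extension_deg = abs(min(c(g$theta_deg[g$theta_deg < 0], 0))),
               stringsAsFactors = FALSE)
  }))
  rownames(end_ranges) <- NULL
  sidecar <- list(tool = paste("ucspine", utils::packageVersion("ucspine")),
                  seed = scenario$seed,
                  config_hash = config_hash(unclass(scenario)),
                  scenario = unclass(scenario),
                  end_ranges = end_ranges,
                  ground_truth = gt)
  gt_path <- file.path(out_dir, paste0(basename, "_ground_truth.json"))
  atomic_write(gt_path, function(tmp) {
    jsonlite::write_json(sidecar, tmp, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  })
  list(trc = trc_path, ground_truth_json = gt_path,
       trajectory = gen$trajectory, ground_truth = gt)
}

#' Analyze a recorded (or generated) trajectory end to end
#'
#' Reads a TRC or long-CSV trajectory, registers the template to the neutral
#' frame, recovers per-joint sagittal angle series and the ROM summary,
#' evaluates per-ligament length changes at the flexion and extension
#' end-range frames into state tables, applies the radiographic instability
#' criterion, and writes: angle series CSV, ROM summary CSV, ligament state
#' CSVs, instability report CSV and a validation JSON (literature
#' containment of C0-C1/C1-C2 angles). All outputs carry a metadata header
#' (tool version, seed where known, config hash).
#'
#' @param trajectory_path TRC (\code{.trc}) or CSV trajectory path.
#' @param out_dir Output directory.
#' @param model A \code{spine_model}.
#' @param condition Condition label for reports.
#' @param criterion An \code{\link{instability_criterion}}.
#' @param smooth Logical; smooth marker positions (needs gap-free data).
#' @param ligaments Ligament table.
#' @return A list: \code{rom}, \code{instability}, \code{state_tables},
#'   \code{containment}, \code{paths}.
#' @export
run_analyze <- function(trajectory_path, out_dir,
                        model = default_spine_model(),
                        condition = NA_character_,
                        criterion = instability_criterion(),
                        smooth = FALSE,
                        ligaments = default_ligament_table(model)) {
  traj <- if (grepl("\\.trc$", trajectory_path, ignore.case = TRUE)) {
    read_trc(trajectory_path)
  } else {
    read_trajectory_csv(trajectory_path)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kin <- kinematics_pipeline(traj, model, smooth = smooth,
                             condition = condition)
  meta <- c(trajectory = basename(trajectory_path),
            config_hash = config_hash(list(file = basename(trajectory_path),
                                           condition = condition)))

  angles <- do.call(rbind, kin$angles)
  angles_path <- file.path(out_dir, "angles.csv")
  atomic_write(angles_path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    write_metadata_header(con, meta)
    utils::write.csv(angles, con, row.names = FALSE)
  })

  rom_path <- file.path(out_dir, "rom_summary.csv")
  rom_tab <- data.frame(
    Movements = rep(c("Flexion", "Extension"), each = nrow(kin$rom)),
    Segment = rep(kin$rom$joint, 2),
    angle_deg = c(kin$rom$flexion_deg, kin$rom$extension_deg))
  atomic_write(rom_path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    write_metadata_header(con, meta)
    utils::write.csv(rom_tab, con, row.names = FALSE)
  })

  # per-ligament state at the end-range frames
  state_tables <- list()
  for (dir_lab in c("flexion", "extension")) {
    dl <- ligament_dl_at_endrange(kin, model, ligaments, dir_lab)
    st <- build_state_table(dl, ligaments, condition, dir_lab)
    state_tables[[dir_lab]] <- st
    write_state_table_csv(st, file.path(out_dir, paste0("ligaments_", dir_lab, ".csv")),
                          metadata = meta)
  }

  inst <- instability_report(kin$rom, criterion)
  inst_path <- file.path(out_dir, "instability.csv")
  atomic_write(inst_path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    write_metadata_header(con, meta)
    utils::write.csv(inst, con, row.names = FALSE)
  })
  for (i in seq_len(nrow(inst))) {
    message(sprintf("[ucspine] %s: flexion %.2f deg, AP %.2f mm -> %s",
                    inst$joint[i], inst$flexion_deg[i],
                    inst$max_ap_translation_mm[i],
                    if (inst$unstable[i]) "UNSTABLE" else "stable"))
  }

  contain <- range_check(kin$rom[kin$rom$joint %in% c("C0C1", "C1C2"), ])
  val_path <- file.path(out_dir, "validation.json")
  validation_report(containment = contain, path = val_path,
                    metadata = as.list(meta))

  list(rom = kin$rom, instability = inst, state_tables = state_tables,
       containment = contain,
       paths = list(angles = angles_path, rom = rom_path,
                    instability = inst_path, validation = val_path))
}

# Ligament length changes between the neutral frame and the end-range frame
# of the given direction, from the fitted pose series.
ligament_dl_at_endrange <- function(kin, model, ligaments, direction) {
  total <- rowSums(vapply(kin$angles, function(a) {
    ifelse(a$missing, 0, a$theta_deg)
  }, numeric(nrow(kin$angles[[1]]))))
  f_end <- if (direction == "flexion") which.max(total) else which.min(total)
  pose_at <- function(v, f) {
    ps <- pose_series_cache(kin, v)
    rigid_pose(ps$R[, , f], ps$t[f, ])
  }
  dl <- numeric(nrow(ligaments))
  names(dl) <- ligaments$name
  for (i in seq_len(nrow(ligaments))) {
    s <- ligaments[i, ]
    len <- ligament_length(pose_at(s$origin_vertebra, f_end),
                           pose_at(s$insertion_vertebra, f_end), s, model)
    dl[i] <- len - s$rest_length_L0
  }
  dl
}

pose_series_cache <- function(kin, v) kin$poses[[v]]
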