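# Trajectory planning and the simulated positioning workflow: the microdrive
# is first rotated until its tool axis is parallel to the planned trajectory,
# then translated until the perpendicular distance from the planned target to
# the tool axis is minimised, and only then advanced along the penetration
# axis. The simulation emulates the live rotational/translational offset
# readouts an operator minimises, with quantised micromanipulator moves.

#' Plan an electrode trajectory from entry and target points
#'
#' The entry point is the planned final location of the guide-tube tip; the
#' target point is the planned location of the electrode tip. The trajectory
#' axis is the unit vector from entry to target and the depth is their
#' separation.
#'
#' @param entry,target Points in mm (world frame); must differ.
#' @returns A `trajectory` with `entry`, `target`, `axis`, `depth_mm`.
#' @export
plan_trajectory <- function(entry, target) {
  entry <- as_point3(entry, "entry")
  target <- as_point3(target, "target")
  v <- target - entry
  depth <- sqrt(sum(v^2))
  if (depth < 1e-9) {
    rlang::abort("Entry and target points coincide; trajectory undefined.",
                 class = "stereonav_degenerate_direction")
  }
  structure(list(entry = entry, target = target, axis = v / depth,
                 depth_mm = depth),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> depth:", signif(x$depth_mm, 6), "mm\n")
  cat("  entry :", paste(signif(x$entry, 6), collapse = ", "), "\n")
  cat("  target:", paste(signif(x$target, 6), collapse = ", "), "\n")
  cat("  axis  :", paste(signif(x$axis, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Live alignment readout for a device pose against a planned trajectory
#'
#' Reproduces the navigation display: the rotational offset between the
#' current tool axis and the planned trajectory in each anatomical plane,
#' the perpendicular "tool axis to target" distance from the planned target
#' to the current tool axis, and the distance from the tool tip to the
#' planned entry point. Degenerate in-plane projections are flagged as `NA`,
#' never raised.
#'
#' @param pose A [device_pose()].
#' @param traj A [plan_trajectory()] result.
#' @returns A one-row tibble: `rot_coronal_deg`, `rot_sagittal_deg`,
#'   `rot_axial_deg`, `angle_total_deg`, `axis_to_target_mm`,
#'   `tip_to_entry_mm`.
#' @export
compute_readout <- function(pose, traj) {
  assert_pose(pose)
  axis <- device_axis_world(pose)
  tip <- device_tip_world(pose)
  ro <- rotational_offsets(traj$axis, axis)
  tibble::tibble(
    rot_coronal_deg = ro$offset_deg[ro$plane == "coronal"],
    rot_sagittal_deg = ro$offset_deg[ro$plane == "sagittal"],
    rot_axial_deg = ro$offset_deg[ro$plane == "axial"],
    angle_total_deg = angle_between_axes(axis, traj$axis),
    axis_to_target_mm = point_to_line_distance(traj$target, tip, axis),
    tip_to_entry_mm = sqrt(sum((tip - traj$entry)^2))
  )
}

#' Micromanipulator stage model
#'
#' Two rotational axes (about the world x and y axes, pivoting at the tool
#' tip) and three linear axes, with symmetric travel limits and a finite step
#' resolution to which every commanded move is quantised.
#'
#' @param travel_mm Linear travel limit per axis (+/- mm).
#' @param travel_deg Rotational travel limit per axis (+/- degrees).
#' @param step_mm Linear step resolution (mm).
#' @param step_deg Rotational step resolution (degrees).
#' @returns A `manipulator_model`.
#' @export
manipulator_model <- function(travel_mm = 100, travel_deg = 90,
                              step_mm = 0.01, step_deg = 0.01) {
  if (step_mm <= 0 || step_deg <= 0) {
    rlang::abort("Step resolutions must be positive.",
                 class = "stereonav_bad_params")
  }
  if (travel_mm < 0 || travel_deg < 0) {
    rlang::abort("Travel limits must be non-negative.",
                 class = "stereonav_bad_params")
  }
  structure(list(travel_mm = travel_mm, travel_deg = travel_deg,
                 step_mm = step_mm, step_deg = step_deg),
            class = "manipulator_model")
}

# signed in-plane angle from the device axis to the target axis under a
# rotation about world axis `k` (1 = x, 2 = y); components (i, j) span the
# rotation plane in right-handed order.
signed_plane_angle <- function(dev, tgt, k) {
  ij <- switch(k, `1` = c(2, 3), `2` = c(3, 1))
  a <- dev[ij]; b <- tgt[ij]
  if (sqrt(sum(a^2)) < 1e-9 || sqrt(sum(b^2)) < 1e-9) return(0)
  th <- atan2(b[2], b[1]) - atan2(a[2], a[1])
  th <- ((th + pi) %% (2 * pi)) - pi
  th * 180 / pi
}

#' Align the microdrive to a planned trajectory (two-phase simulation)
#'
#' Emulates the manual procedure: the tool is first rotated (per-axis greedy
#' moves, quantised to the manipulator's step resolution, pivoting at the
#' tool tip) until the angle between the tool axis and the planned trajectory
#' falls below `rot_tol_deg`; only then are the linear axes moved until the
#' perpendicular tool-axis-to-target distance falls below `trans_tol_mm`.
#' The electrode is never advanced along the penetration axis here — that is
#' [advance_to_depth()]'s job. Every accepted move strictly decreases the
#' active phase's error metric, producing an auditable move log.
#'
#' @param pose Starting [device_pose()].
#' @param traj A [plan_trajectory()] result.
#' @param manip A [manipulator_model()].
#' @param rot_tol_deg Rotational convergence tolerance (degrees).
#' @param trans_tol_mm Translational convergence tolerance (mm).
#' @param max_iter Maximum sweeps per phase.
#' @returns A list with the final `pose`, the move log tibble `moves`
#'   (phase, axis, amount, and the readout metric after the move) and the
#'   final `readout`.
#' @export
align <- function(pose, traj, manip = manipulator_model(),
                  rot_tol_deg = 0.05, trans_tol_mm = 0.01, max_iter = 100) {
  assert_pose(pose)
  moves <- list()
  used_deg <- c(rx = 0, ry = 0)
  used_mm <- c(x = 0, y = 0, z = 0)

  quantize <- function(amount, step) round(amount / step) * step
  log_move <- function(phase, axis, amount, metric) {
    moves[[length(moves) + 1L]] <<- tibble::tibble(
      phase = phase, axis = axis, amount = amount, metric_after = metric)
  }

  # --- phase 1: rotations about world x (rx) and y (ry), pivot at the tip
  for (it in seq_len(max_iter)) {
    ang <- angle_between_axes(device_axis_world(pose), traj$axis)
    if (ang < rot_tol_deg) break
    improved <- FALSE
    for (axname in c("rx", "ry")) {
      k <- if (axname == "rx") 1L else 2L
      dev <- device_axis_world(pose)
      # rotate towards the *vector* (not axis) representative nearest dev
      tgt <- if (sum(dev * traj$axis) >= 0) traj$axis else -traj$axis
      theta <- quantize(signed_plane_angle(dev, tgt, k), manip$step_deg)
      if (abs(theta) < manip$step_deg / 2) next
      if (abs(used_deg[[axname]] + theta) > manip$travel_deg) {
        rlang::abort("Target orientation unreachable: rotational travel limit hit before tolerance.",
                     class = "stereonav_unreachable")
      }
      rot <- if (k == 1L) rotation_about_x(theta) else rotation_about_y(theta)
      tip <- device_tip_world(pose)
      # pivot at the tool tip: the device origin maps to the unchanged tip
      cand <- device_pose(rigid_transform(rot %*% pose$transform$rotation, tip))
      new_ang <- angle_between_axes(device_axis_world(cand), traj$axis)
      if (new_ang < ang - 1e-12) {
        pose <- cand
        used_deg[[axname]] <- used_deg[[axname]] + theta
        ang <- new_ang
        improved <- TRUE
        log_move("rotate", axname, theta, ang)
      }
    }
    if (!improved) break
  }
  ang <- angle_between_axes(device_axis_world(pose), traj$axis)
  if (ang >= rot_tol_deg) {
    rlang::abort("Rotational alignment did not reach tolerance within the manipulator model.",
                 class = "stereonav_unreachable")
  }

  # --- phase 2: linear x/y/z moves minimising the tool-axis-to-target distance
  for (it in seq_len(max_iter)) {
    tip <- device_tip_world(pose)
    axis <- device_axis_world(pose)
    dist <- point_to_line_distance(traj$target, tip, axis)
    if (dist < trans_tol_mm) break
    r <- traj$target - tip
    delta <- r - sum(r * axis) * axis  # perpendicular correction, no advance
    improved <- FALSE
    for (k in 1:3) {
      axname <- c("x", "y", "z")[k]
      step <- quantize(delta[k], manip$step_mm)
      if (abs(step) < manip$step_mm / 2) next
      if (abs(used_mm[[axname]] + step) > manip$travel_mm) {
        rlang::abort("Target unreachable: linear travel limit hit before tolerance.",
                     class = "stereonav_unreachable")
      }
      shift <- c(0, 0, 0); shift[k] <- step
      cand <- device_pose(rigid_transform(pose$transform$rotation,
                                          pose$transform$translation + shift))
      new_dist <- point_to_line_distance(traj$target, device_tip_world(cand),
                                         device_axis_world(cand))
      if (new_dist < dist - 1e-12) {
        pose <- cand
        used_mm[[axname]] <- used_mm[[axname]] + step
        dist <- new_dist
        improved <- TRUE
        log_move("translate", axname, step, dist)
      }
    }
    if (!improved) break
  }
  tip <- device_tip_world(pose)
  dist <- point_to_line_distance(traj$target, tip, device_axis_world(pose))
  if (dist >= trans_tol_mm) {
    rlang::abort("Translational alignment did not reach tolerance within the manipulator model.",
                 class = "stereonav_unreachable")
  }

  moves <- if (length(moves) > 0) dplyr::bind_rows(moves) else
    tibble::tibble(phase = character(), axis = character(),
                   amount = numeric(), metric_after = numeric())
  list(pose = pose, moves = moves, readout = compute_readout(pose, traj))
}

#' Electrode travel needed to reach the planned target depth
#'
#' Once the guide tube is positioned, the electrode is advanced out of it by
#' the distance from the guide-tube tip to the target along the trajectory
#' axis.
#'
#' @param traj A [plan_trajectory()] result.
#' @param guide_tip_world Current guide-tube tip position (mm, world frame);
#'   should lie near the planned axis.
#' @returns Electrode travel in mm.
#' @export
advance_to_depth <- function(traj, guide_tip_world) {
  tip <- as_point3(guide_tip_world, "guide_tip_world")
  travel <- sum((traj$target - tip) * traj$axis)
  if (travel <= 0) {
    rlang::abort("Guide tip lies at or beyond the target: negative electrode travel.",
                 class = "stereonav_negative_travel")
  }
  travel
}
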