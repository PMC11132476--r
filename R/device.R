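# Microdrive model: a five-guide-tube cross layout centred on guide 3, the
# device (matrix-centred) coordinate frame with its origin at the central
# guide-tube tip and -z as the penetration axis, per-guide coordinate
# corrections, and the electrolytic deposit mass from Faraday's law.

FARADAY_CONSTANT_C_PER_MOL <- 96485
IRON_MOLAR_MASS_G_PER_MOL <- 55.845

#' Five-guide-tube cross layout
#'
#' Guides 1..5 are arranged in a cross centred on guide 3; the four outer
#' guides sit one centre-to-centre spacing from the centre along +/-x and
#' +/-y of the device frame and are shorter than the central guide by their
#' `length_deficit`, so their tips sit higher (+z) by that amount. The
#' spacing defaults to the 0.305 mm outer tube diameter (tubes touching);
#' the arm assignment (1=+y, 2=+x, 4=-x, 5=-y) is configurable.
#'
#' @param spacing_mm Centre-to-centre spacing of outer guides (mm).
#' @param length_deficit_mm Length deficit of each outer guide relative to the
#'   central guide (mm); scalar (recycled over guides 1,2,4,5) or a named
#'   vector over ids "1","2","4","5". The central guide's deficit is 0.
#' @param directions Named list mapping outer guide id to its unit arm
#'   direction in the device x/y plane.
#' @param outer_diameter_mm Guide-tube outer diameter (mm).
#' @param electrode_shaft_diameter_mm Electrode shaft diameter (mm).
#' @returns A `guide_tube_layout` object.
#' @export
guide_tube_layout <- function(spacing_mm = 0.305,
                              length_deficit_mm = 0.75,
                              directions = list(`1` = c(0, 1), `2` = c(1, 0),
                                                `4` = c(-1, 0), `5` = c(0, -1)),
                              outer_diameter_mm = 0.305,
                              electrode_shaft_diameter_mm = 0.080) {
  outer_ids <- c("1", "2", "4", "5")
  if (!setequal(names(directions), outer_ids)) {
    rlang::abort("`directions` must name exactly the outer guides 1, 2, 4, 5.",
                 class = "stereonav_bad_layout")
  }
  if (length(length_deficit_mm) == 1L) {
    length_deficit_mm <- stats::setNames(rep(length_deficit_mm, 4), outer_ids)
  }
  if (!setequal(names(length_deficit_mm), outer_ids) || any(length_deficit_mm < 0)) {
    rlang::abort("`length_deficit_mm` must be non-negative, for guides 1, 2, 4, 5.",
                 class = "stereonav_bad_layout")
  }
  lat <- vapply(directions, function(d) d / sqrt(sum(d^2)), numeric(2))
  if (max(abs(rowSums(lat))) > 1e-9) {
    rlang::abort("Outer-guide arm directions must be symmetric (cross shape).",
                 class = "stereonav_bad_layout")
  }
  structure(
    list(spacing_mm = spacing_mm,
         length_deficit_mm = length_deficit_mm[outer_ids],
         directions = lapply(directions[outer_ids], function(d) d / sqrt(sum(d^2))),
         outer_diameter_mm = outer_diameter_mm,
         electrode_shaft_diameter_mm = electrode_shaft_diameter_mm),
    class = "guide_tube_layout"
  )
}

assert_guide_id <- function(guide_id) {
  if (length(guide_id) != 1L || !guide_id %in% 1:5) {
    rlang::abort("`guide_id` must be a single id in 1..5.",
                 class = "stereonav_bad_guide")
  }
  as.integer(guide_id)
}

#' Device-frame tip offset of a guide tube
#'
#' Returns the offset of guide `guide_id`'s tip from the central guide-tube
#' tip (the device-frame origin): `(0,0,0)` for the central guide 3; for the
#' outer guides, the lateral cross offset in x/y plus `+length_deficit` in z
#' (the shorter tube's tip sits higher).
#'
#' @param layout A [guide_tube_layout()].
#' @param guide_id Guide id in 1..5.
#' @returns Length-3 numeric offset (mm) in the device frame.
#' @export
guide_offset <- function(layout, guide_id) {
  guide_id <- assert_guide_id(guide_id)
  if (guide_id == 3L) return(c(0, 0, 0))
  id <- as.character(guide_id)
  d <- layout$directions[[id]]
  c(layout$spacing_mm * d, layout$length_deficit_mm[[id]])
}

#' Device pose: rigid transform from device to world frame
#'
#' The device frame has its origin at the central guide-tube tip and the
#' penetration axis along -z; `transform` maps device coordinates into the
#' world (stereotaxic) frame.
#'
#' @param transform A [rigid_transform()] (device -> world).
#' @returns A `device_pose` object.
#' @export
device_pose <- function(transform = rigid_transform()) {
  assert_transform(transform)
  structure(list(transform = transform), class = "device_pose")
}

assert_pose <- function(pose) {
  if (!inherits(pose, "device_pose")) {
    rlang::abort("`pose` must be a device_pose.", class = "stereonav_bad_pose")
  }
  pose
}

#' World position of the central guide-tube tip
#' @param pose A [device_pose()].
#' @returns Length-3 world coordinates (mm).
#' @export
device_tip_world <- function(pose) {
  assert_pose(pose)
  transform_points(pose$transform, c(0, 0, 0))
}

#' World direction of the penetration axis
#' @inheritParams device_tip_world
#' @returns Unit direction (device -z mapped to world).
#' @export
device_axis_world <- function(pose) {
  assert_pose(pose)
  transform_direction(pose$transform, c(0, 0, -1))
}

#' Convert between world and device frames
#'
#' `world_to_device()` maps world coordinates into the matrix-centred frame
#' (central guide tip at the origin, penetration axis -z); `device_to_world()`
#' is its inverse. Round trips are identity to machine precision.
#'
#' @param p Point (length-3) or n x 3 matrix of points (mm).
#' @param pose A [device_pose()].
#' @returns Coordinates in the other frame, same shape as the input.
#' @export
world_to_device <- function(p, pose) {
  assert_pose(pose)
  transform_points(transform_invert(pose$transform), p)
}

#' @rdname world_to_device
#' @export
device_to_world <- function(p, pose) {
  assert_pose(pose)
  transform_points(pose$transform, p)
}

#' Correct a planned target for the guide tube that drove the electrode
#'
#' Planned electrode-tip locations are expressed relative to the central
#' guide-tube model; a deposit made through an outer guide is systematically
#' offset by that guide's tip offset. This shifts the planned target by the
#' world-frame image of [guide_offset()]. Planned entry points are never
#' corrected: all five guide tubes advance into the tissue together, so the
#' guide choice induces no systematic entry offset.
#'
#' @param planned_target Planned target point (mm) in the world frame.
#' @param guide_id Guide id in 1..5.
#' @param layout A [guide_tube_layout()].
#' @param pose A [device_pose()] locating the device in the world frame.
#' @returns Corrected planned target (mm, world frame).
#' @export
correct_planned_for_guide <- function(planned_target, guide_id,
                                      layout = guide_tube_layout(),
                                      pose = device_pose()) {
  assert_pose(pose)
  off <- guide_offset(layout, guide_id)
  as_point3(planned_target, "planned_target") +
    as.vector(pose$transform$rotation %*% off)
}

#' Electrolytically deposited metal mass (Faraday coulometry)
#'
#' Mass deposited by an anodal direct current through a metal electrode:
#' `m = (I * t / (z * F)) * M`, returned in nanograms. Defaults model anodal
#' dissolution of iron as Fe2+ (valence 2, M = 55.845 g/mol).
#'
#' @param current_uA Current in microamperes (> 0).
#' @param duration_s Application time in seconds (> 0).
#' @param valence Ion charge number (2 for Fe2+, 3 for Fe3+).
#' @param molar_mass_g_per_mol Molar mass of the deposited metal (g/mol).
#' @param faraday_c_per_mol Faraday constant (C/mol).
#' @returns Deposited mass in ng; linear in current and duration.
#' @examples
#' deposit_mass(current_uA = 4, duration_s = 300) # ~347 ng of iron
#' @export
deposit_mass <- function(current_uA, duration_s, valence = 2,
                         molar_mass_g_per_mol = IRON_MOLAR_MASS_G_PER_MOL,
                         faraday_c_per_mol = FARADAY_CONSTANT_C_PER_MOL) {
  if (current_uA < 0 || duration_s < 0) {
    rlang::abort("Current and duration must be non-negative.",
                 class = "stereonav_bad_params")
  }
  if (!valence %in% c(2, 3)) {
    rlang::abort("`valence` must be 2 (Fe2+) or 3 (Fe3+).",
                 class = "stereonav_bad_params")
  }
  charge_c <- current_uA * 1e-6 * duration_s
  mass_g <- charge_c / (valence * faraday_c_per_mol) * molar_mass_g_per_mol
  mass_g * 1e9
}
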