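# Frame-independent 3D primitives used throughout the navigation pipeline.
# Points are length-3 numeric vectors (mm) in a right-handed R/A/S frame:
# x = Right, y = Anterior, z = Superior. Directions are unit vectors; trajectory
# axes are treated as undirected (d and -d equivalent).

DIRECTION_TOL <- 1e-9
DEGENERATE_PROJECTION_TOL <- 1e-6

as_point3 <- function(p, arg = "p") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    rlang::abort(
      paste0("`", arg, "` must be a finite length-3 numeric (x, y, z) in mm."),
      class = "stereonav_bad_point"
    )
  }
  unname(p)
}

#' Normalize a vector to a unit direction
#'
#' @param v Length-3 numeric vector.
#' @returns A unit-norm length-3 numeric vector.
#' @export
unit_vector <- function(v) {
  v <- as_point3(v, "v")
  n <- sqrt(sum(v^2))
  if (n < DIRECTION_TOL) {
    rlang::abort("Degenerate direction: vector has (near-)zero norm.",
                 class = "stereonav_degenerate_direction")
  }
  v / n
}

assert_direction <- function(d, arg = "d") {
  d <- as_point3(d, arg)
  n <- sqrt(sum(d^2))
  if (n < DIRECTION_TOL) {
    rlang::abort("Degenerate direction: vector has (near-)zero norm.",
                 class = "stereonav_degenerate_direction")
  }
  if (abs(n - 1) > 1e-6) {
    rlang::abort(paste0("`", arg, "` must be unit norm (got norm ", format(n), ")."),
                 class = "stereonav_bad_direction")
  }
  d / n
}

#' Perpendicular distance from a point to a 3D line
#'
#' The line is given by an anchor point `a` and a unit direction `d`; the
#' result is the minimum over t of ||p - (a + t d)||. This is the
#' "tool axis to target" readout: the perpendicular distance from a planned
#' target to the tracked tool axis.
#'
#' @param p Query point (mm).
#' @param a Point on the line (mm).
#' @param d Unit direction of the line.
#' @returns Distance in mm (non-negative).
#' @export
point_to_line_distance <- function(p, a, d) {
  p <- as_point3(p, "p")
  a <- as_point3(a, "a")
  d <- assert_direction(d)
  r <- p - a
  perp <- r - sum(r * d) * d
  sqrt(sum(perp^2))
}

#' Angle between two undirected axes
#'
#' Uses axis (not vector) semantics: `d` and `-d` are equivalent, so the
#' result lies in [0, 90] degrees.
#'
#' @param d1,d2 Unit directions.
#' @returns Angle in degrees.
#' @export
angle_between_axes <- function(d1, d2) {
  d1 <- assert_direction(d1, "d1")
  d2 <- assert_direction(d2, "d2")
  c_ <- min(1, abs(sum(d1 * d2)))
  acos(c_) * 180 / pi
}

#' Anatomical plane definition
#'
#' Returns the plane's unit normal in the R/A/S device frame: the coronal
#' plane's normal is the AP axis (y), the sagittal plane's normal the RL axis
#' (x), and the axial plane's normal the SI axis (z).
#'
#' @param name One of "coronal", "sagittal", "axial".
#' @returns A list with `name` and `normal`.
#' @export
anatomical_plane <- function(name = c("coronal", "sagittal", "axial")) {
  name <- match.arg(name)
  normal <- switch(name,
    coronal  = c(0, 1, 0),
    sagittal = c(1, 0, 0),
    axial    = c(0, 0, 1)
  )
  list(name = name, normal = normal)
}

#' Per-plane rotational offset between a planned and a real axis
#'
#' Projects both axes onto the requested anatomical plane (removing the
#' component along the plane normal) and returns the in-plane angle between
#' the projections, in degrees. When either projection has norm below
#' `1e-6` the in-plane angle is numerically meaningless (the axis is nearly
#' normal to the plane) and `NA_real_` is returned as a degenerate flag
#' rather than an unstable number.
#'
#' @param planned,real Unit directions (planned and tracked tool axis).
#' @param plane Plane name or an [anatomical_plane()] object.
#' @returns In-plane angle in degrees, or `NA_real_` when degenerate.
#' @export
decompose_rotational_offset <- function(planned, real, plane) {
  planned <- assert_direction(planned, "planned")
  real <- assert_direction(real, "real")
  if (is.character(plane)) plane <- anatomical_plane(plane)
  n <- plane$normal
  proj <- function(v) v - sum(v * n) * n
  p1 <- proj(planned)
  p2 <- proj(real)
  n1 <- sqrt(sum(p1^2))
  n2 <- sqrt(sum(p2^2))
  if (n1 < DEGENERATE_PROJECTION_TOL || n2 < DEGENERATE_PROJECTION_TOL) {
    return(NA_real_)
  }
  c_ <- min(1, abs(sum(p1 * p2) / (n1 * n2)))
  acos(c_) * 180 / pi
}

#' Rotational offsets in all three anatomical planes
#'
#' @inheritParams decompose_rotational_offset
#' @returns A tibble with one row per plane (`plane`, `offset_deg`).
#' @export
rotational_offsets <- function(planned, real) {
  planes <- c("coronal", "sagittal", "axial")
  tibble::tibble(
    plane = planes,
    offset_deg = purrr::map_dbl(planes, function(pl) {
      decompose_rotational_offset(planned, real, pl)
    })
  )
}

# ---- rigid transforms -------------------------------------------------------

#' Rigid transform between 3D frames
#'
#' A rotation (3x3 proper orthogonal matrix) followed by a translation (mm):
#' `x -> R x + t`.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation Length-3 numeric (mm).
#' @returns An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as_point3(translation, "translation")
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    rlang::abort("`rotation` must be a finite 3x3 matrix.",
                 class = "stereonav_bad_rotation")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    rlang::abort("`rotation` must be proper orthogonal (R'R = I, det R = +1).",
                 class = "stereonav_bad_rotation")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", paste(round(x$translation, 6), collapse = ", "), "\n")
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

assert_transform <- function(t, arg = "transform") {
  if (!is_rigid_transform(t)) {
    rlang::abort(paste0("`", arg, "` must be a rigid_transform."),
                 class = "stereonav_bad_transform")
  }
  t
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points Length-3 vector or an n x 3 matrix of points (mm).
#' @returns Transformed points, same shape as the input.
#' @export
transform_points <- function(transform, points) {
  assert_transform(transform)
  if (is.null(dim(points))) {
    return(as.vector(transform$rotation %*% as_point3(points, "points") +
                       transform$translation))
  }
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 3L)
  sweep(pts %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Apply a rigid transform to a direction (rotation only)
#'
#' @inheritParams transform_points
#' @param direction Unit direction.
#' @returns Rotated unit direction.
#' @export
transform_direction <- function(transform, direction) {
  assert_transform(transform)
  as.vector(transform$rotation %*% assert_direction(direction, "direction"))
}

#' Compose two rigid transforms
#'
#' `transform_compose(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @returns The composed `rigid_transform`.
#' @export
transform_compose <- function(a, b) {
  assert_transform(a, "a")
  assert_transform(b, "b")
  rigid_transform(
    rotation = a$rotation %*% b$rotation,
    translation = as.vector(a$rotation %*% b$translation) + a$translation
  )
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @returns The inverse `rigid_transform`.
#' @export
transform_invert <- function(transform) {
  assert_transform(transform)
  rt <- t(transform$rotation)
  rigid_transform(rotation = rt,
                  translation = as.vector(-rt %*% transform$translation))
}

#' Elementary rotation matrices (degrees)
#'
#' @param theta_deg Rotation angle in degrees.
#' @returns A 3x3 rotation matrix about the named world axis.
#' @export
rotation_about_x <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), -sin(th),
           0, sin(th), cos(th)), 3, 3, byrow = TRUE)
}

#' @rdname rotation_about_x
#' @export
rotation_about_y <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), 0, sin(th),
           0, 1, 0,
           -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
}

#' @rdname rotation_about_x
#' @export
rotation_about_z <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), -sin(th), 0,
           sin(th), cos(th), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Rotation about an arbitrary unit axis (Rodrigues)
#'
#' @param axis Unit rotation axis.
#' @param theta_deg Angle in degrees.
#' @returns A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta_deg) {
  a <- assert_direction(axis, "axis")
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Draw a random rigid transform
#'
#' Uniform random rotation (QR of a Gaussian matrix, det-corrected) and a
#' Gaussian translation. Useful for invariance checks.
#'
#' @param translation_sd Standard deviation of each translation component (mm).
#' @returns A `rigid_transform`.
#' @export
random_rigid_transform <- function(translation_sd = 10) {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d + (d == 0)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, stats::rnorm(3, sd = translation_sd))
}
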