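# Two-step co-registration: closed-form paired-point rigid registration on a
# few well-spaced fiducials, followed by iterative surface refinement (ICP)
# against a reference point cloud sampled with a tracked pointer. Accuracy is
# reported as the root-mean-square residual, mirroring the RMS readout of
# camera-based neuronavigation systems.

as_point_matrix <- function(x, arg = "points") {
  if (is.data.frame(x)) {
    cols <- intersect(c("x_mm", "y_mm", "z_mm"), names(x))
    if (length(cols) == 3L) {
      x <- as.matrix(x[, c("x_mm", "y_mm", "z_mm")])
    } else if (all(c("x", "y", "z") %in% names(x))) {
      x <- as.matrix(x[, c("x", "y", "z")])
    } else {
      rlang::abort(paste0("`", arg, "` must have columns x_mm,y_mm,z_mm (or x,y,z)."),
                   class = "stereonav_bad_points")
    }
  }
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != 3L) {
    rlang::abort(paste0("`", arg, "` must be an n x 3 matrix of mm coordinates."),
                 class = "stereonav_bad_points")
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    rlang::abort(paste0("`", arg, "` contains non-finite coordinates."),
                 class = "stereonav_bad_points")
  }
  unname(x)
}

#' Root-mean-square of residual vectors
#'
#' @param residuals An n x 3 matrix of residual vectors (mm), or a numeric
#'   vector of residual lengths.
#' @returns RMS in mm.
#' @export
rms_error <- function(residuals) {
  if (is.matrix(residuals)) {
    sq <- rowSums(residuals^2)
  } else {
    sq <- as.numeric(residuals)^2
  }
  if (length(sq) == 0L) {
    rlang::abort("Cannot compute RMS of an empty residual set.",
                 class = "stereonav_empty_input")
  }
  sqrt(mean(sq))
}

# Kabsch / orthogonal Procrustes: least-squares rigid transform mapping
# source onto target, reflection-guarded via the det sign of V U'.
kabsch <- function(source, target) {
  cs <- colMeans(source)
  ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

new_registration <- function(transform, fre_mm = NA_real_, rms_mm = NA_real_,
                             iterations = 0L, converged = TRUE,
                             method = "paired_point", rms_trace = numeric()) {
  structure(
    list(transform = transform, fre_mm = fre_mm, rms_mm = rms_mm,
         iterations = iterations, converged = converged, method = method,
         rms_trace = rms_trace),
    class = "stereonav_registration"
  )
}

#' Closed-form paired-point rigid registration
#'
#' Solves the orthogonal Procrustes problem for matched fiducial pairs:
#' the rotation is obtained from the SVD of the cross-covariance with a
#' determinant correction that excludes reflections, and the translation
#' aligns the centroids. This is the "first point-set registration" on three
#' (or more) arbitrary, well-spaced points.
#'
#' @param source Fiducials in the tracker frame: n x 3 matrix or data frame
#'   with `x_mm`,`y_mm`,`z_mm` columns; n >= 3.
#' @param target Matching fiducials in the model frame, same shape.
#' @returns A `stereonav_registration` with the fitted `transform` and the
#'   fiducial registration error `fre_mm` (RMS residual).
#' @export
paired_point_register <- function(source, target) {
  src <- as_point_matrix(source, "source")
  tgt <- as_point_matrix(target, "target")
  if (nrow(src) != nrow(tgt)) {
    rlang::abort("`source` and `target` must contain the same number of fiducials.",
                 class = "stereonav_bad_points")
  }
  if (nrow(src) < 3L) {
    rlang::abort("At least 3 fiducial correspondences are required.",
                 class = "stereonav_ill_conditioned")
  }
  sv <- svd(sweep(src, 2, colMeans(src)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12) || sv[1] < 1e-12) {
    rlang::abort("Fiducials are collinear or coincident: registration is ill-conditioned.",
                 class = "stereonav_ill_conditioned")
  }
  tr <- kabsch(src, tgt)
  res <- transform_points(tr, src) - tgt
  new_registration(tr, fre_mm = rms_error(res), method = "paired_point")
}

#' Fiducial registration error of a fitted registration
#'
#' @param result A `stereonav_registration`.
#' @param source,target The fiducial sets used for the fit.
#' @returns RMS residual over the fiducials (mm).
#' @export
fre <- function(result, source, target) {
  src <- as_point_matrix(source, "source")
  tgt <- as_point_matrix(target, "target")
  rms_error(transform_points(result$transform, src) - tgt)
}

nearest_surface_points <- function(cloud, pts) {
  # brute-force nearest neighbour; ties resolved to the lowest cloud index
  # (max.col with "first" on the negated distance matrix)
  d2 <- outer(rowSums(pts^2), rowSums(cloud^2), "+") - 2 * tcrossprod(pts, cloud)
  idx <- max.col(-d2, ties.method = "first")
  # exact distances for the matched pairs (the expanded form cancels badly
  # near zero)
  list(idx = idx,
       dist = sqrt(rowSums((pts - cloud[idx, , drop = FALSE])^2)))
}

#' Surface refinement of a registration (iterative closest point)
#'
#' Alternates nearest-neighbour correspondence between the transformed probe
#' points and the reference surface cloud with a closed-form rigid update,
#' until the change in surface RMS falls below `tol` or `max_iter` is reached.
#' This mirrors the second registration step in which a tracked pointer
#' samples larger parts of the implant surface to refine the co-registration.
#'
#' @param cloud Reference surface point cloud in the model frame (>= 10
#'   points): n x 3 matrix or data frame with `x_mm`,`y_mm`,`z_mm`.
#' @param probes Sampled probe points in the tracker frame.
#' @param init Initial `rigid_transform` (typically from
#'   [paired_point_register()]).
#' @param tol Convergence tolerance on the change in RMS (mm).
#' @param max_iter Maximum number of ICP iterations.
#' @param trim Fraction of worst-matching probes excluded from each rigid
#'   update (0 disables trimming; the default, as no outlier rejection is
#'   part of the modelled procedure).
#' @returns A `stereonav_registration` with the refined `transform`, the
#'   surface RMS `rms_mm`, the per-iteration RMS trace in `rms_trace`,
#'   `iterations` and `converged`. Non-convergence is reported via
#'   `converged = FALSE`, not an error.
#' @export
surface_refine <- function(cloud, probes, init = rigid_transform(),
                           tol = 1e-6, max_iter = 200, trim = 0) {
  cl <- as_point_matrix(cloud, "cloud")
  pr <- as_point_matrix(probes, "probes")
  if (nrow(cl) < 10L) {
    rlang::abort("Surface cloud must contain at least 10 points for refinement.",
                 class = "stereonav_empty_input")
  }
  if (nrow(pr) == 0L) {
    rlang::abort("No probe points supplied.", class = "stereonav_empty_input")
  }
  assert_transform(init, "init")
  stopifnot(trim >= 0, trim < 1)

  tr <- init
  trace <- numeric()
  prev_rms <- Inf
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    moved <- transform_points(tr, pr)
    nn <- nearest_surface_points(cl, moved)
    rms <- rms_error(nn$dist)
    trace <- c(trace, rms)
    iterations <- it
    if (rms < tol || abs(prev_rms - rms) < tol) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    keep <- seq_len(nrow(pr))
    if (trim > 0) {
      n_keep <- max(3L, ceiling((1 - trim) * nrow(pr)))
      keep <- order(nn$dist)[seq_len(n_keep)]
    }
    tr <- kabsch(pr[keep, , drop = FALSE], cl[nn$idx[keep], , drop = FALSE])
  }
  new_registration(tr, fre_mm = NA_real_, rms_mm = trace[length(trace)],
                   iterations = iterations, converged = converged,
                   method = "surface_icp", rms_trace = trace)
}

#' Surface RMS of probe points under a registration
#'
#' @param result A `stereonav_registration` (its transform is applied).
#' @param cloud Reference surface cloud.
#' @param probes Probe points in the tracker frame.
#' @returns RMS distance from the transformed probes to their nearest surface
#'   points (mm).
#' @export
surface_rms <- function(result, cloud, probes) {
  cl <- as_point_matrix(cloud, "cloud")
  pr <- as_point_matrix(probes, "probes")
  if (nrow(cl) == 0L || nrow(pr) == 0L) {
    rlang::abort("Empty cloud or probe set.", class = "stereonav_empty_input")
  }
  rms_error(nearest_surface_points(cl, transform_points(result$transform, pr))$dist)
}

#' @export
print.stereonav_registration <- function(x, ...) {
  cat("<stereonav_registration> method:", x$method, "\n")
  if (!is.na(x$fre_mm)) cat("  fiducial RMS (FRE):", signif(x$fre_mm, 6), "mm\n")
  if (!is.na(x$rms_mm)) cat("  surface RMS:", signif(x$rms_mm, 6), "mm\n")
  cat("  iterations:", x$iterations, " converged:", x$converged, "\n")
  print(x$transform)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a registration result
#'
#' @param x A `stereonav_registration`.
#' @param ... Unused.
#' @returns A tibble with one row per ICP iteration (or a single row for the
#'   closed-form fit) and the RMS at that iteration.
#' @method tidy stereonav_registration
#' @export
tidy.stereonav_registration <- function(x, ...) {
  if (length(x$rms_trace) > 0) {
    tibble::tibble(iteration = seq_along(x$rms_trace), rms_mm = x$rms_trace)
  } else {
    tibble::tibble(iteration = 0L, rms_mm = x$fre_mm)
  }
}

#' One-row summary of a registration result
#'
#' @inheritParams tidy.stereonav_registration
#' @returns A one-row tibble: method, fre_mm, rms_mm, iterations, converged.
#' @method glance stereonav_registration
#' @export
glance.stereonav_registration <- function(x, ...) {
  tibble::tibble(method = x$method, fre_mm = x$fre_mm, rms_mm = x$rms_mm,
                 iterations = x$iterations, converged = x$converged)
}

#' Read or write a surface/point cloud CSV
#'
#' Three-column CSV with mandatory header `x_mm,y_mm,z_mm`.
#'
#' @param path File path.
#' @returns `read_surface_cloud()` returns a tibble with columns
#'   `x_mm`,`y_mm`,`z_mm`.
#' @export
read_surface_cloud <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("x_mm", "y_mm", "z_mm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("Surface CSV is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "stereonav_schema_error")
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_surface_cloud
#' @param cloud Matrix or data frame of points to write.
#' @export
write_surface_cloud <- function(cloud, path) {
  m <- as_point_matrix(cloud, "cloud")
  readr::write_csv(tibble::tibble(x_mm = m[, 1], y_mm = m[, 2], z_mm = m[, 3]), path)
  invisible(path)
}
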