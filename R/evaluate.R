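# Targeting-accuracy analysis. Coordinates are analysed in the matrix-centred
# device frame (RL = x, AP = y, SI = z, penetration along -z). Deposit
# offsets are observed minus guide-corrected planned target, componentwise
# and signed (+SI = superior). Penetration-mark offsets are reported only in
# RL/AP and as the 2D distance: depth information along the penetration axis
# is discarded, since the guide-tube tip position along that axis cannot be
# inferred reliably from the images.

dataset_columns <- c(
  "record_id", "guide_id", "block_id",
  "planned_entry_x_mm", "planned_entry_y_mm", "planned_entry_z_mm",
  "planned_target_x_mm", "planned_target_y_mm", "planned_target_z_mm",
  "observed_mark_x_mm", "observed_mark_y_mm", "observed_mark_z_mm",
  "observed_deposit_x_mm", "observed_deposit_y_mm", "observed_deposit_z_mm",
  "travel_mm"
)

assert_dataset <- function(dataset) {
  missing <- setdiff(dataset_columns, names(dataset))
  if (length(missing) > 0) {
    rlang::abort(paste0("Dataset is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "stereonav_schema_error")
  }
  if (nrow(dataset) == 0L) {
    rlang::abort("Dataset is empty.", class = "stereonav_empty_input")
  }
  invisible(dataset)
}

#' Per-record targeting-error metrics
#'
#' For every deposit record, computes the signed per-axis offsets of the
#' observed deposit from its guide-corrected planned target (RL, AP, SI),
#' the 2D distance to the planned electrode axis, the 3D deviation, the
#' penetration-mark RL/AP offsets and 2D distance to the planned entry
#' (no guide correction: all guides advance together), and the angular error
#' between the planned axis and the physical axis through the projected
#' mark and the deposit.
#'
#' @param dataset A deposit-record tibble as produced by
#'   [generate_experiment()] or [read_dataset()].
#' @param model_layout The digital guide-tube model used for the planned-
#'   target correction. The default assumes all guides share the central
#'   guide's length (`length_deficit_mm = 0`), i.e. only the lateral cross
#'   offset is corrected, mirroring a digital model that is unaware of the
#'   physical length deficit. Pass a calibrated layout to also correct the
#'   deficit.
#' @param correct_for_guide Apply the guide correction to planned targets?
#' @returns The dataset with metric columns appended:
#'   `offset_rl_mm`, `offset_ap_mm`, `offset_si_mm`, `dist_2d_mm`,
#'   `dist_3d_mm`, `mark_offset_rl_mm`, `mark_offset_ap_mm`,
#'   `mark_dist_2d_mm`, `angular_error_deg`.
#' @export
record_metrics <- function(dataset,
                           model_layout = guide_tube_layout(length_deficit_mm = 0),
                           correct_for_guide = TRUE) {
  assert_dataset(dataset)
  corr <- if (correct_for_guide) {
    t(vapply(dataset$guide_id, function(id) guide_offset(model_layout, id),
             numeric(3)))
  } else {
    matrix(0, nrow(dataset), 3)
  }
  planned <- as.matrix(dataset[c("planned_target_x_mm", "planned_target_y_mm",
                                 "planned_target_z_mm")]) + corr
  observed <- as.matrix(dataset[c("observed_deposit_x_mm", "observed_deposit_y_mm",
                                  "observed_deposit_z_mm")])
  off <- unname(observed - planned)

  entry <- as.matrix(dataset[c("planned_entry_x_mm", "planned_entry_y_mm",
                               "planned_entry_z_mm")])
  mark <- as.matrix(dataset[c("observed_mark_x_mm", "observed_mark_y_mm",
                              "observed_mark_z_mm")])
  mark_off <- unname(mark[, 1:2, drop = FALSE] - entry[, 1:2, drop = FALSE])

  # physical axis: the mark projected onto the planned-entry depth plane
  # (its own depth reading is discarded) through the observed deposit
  mark_proj <- cbind(mark[, 1:2, drop = FALSE], entry[, 3])
  ang <- vapply(seq_len(nrow(dataset)), function(i) {
    v <- observed[i, ] - mark_proj[i, ]
    if (sqrt(sum(v^2)) < 1e-9) return(NA_real_)
    planned_axis <- unit_vector(planned[i, ] - (entry[i, ] + corr[i, ] * c(1, 1, 0)))
    angle_between_axes(unit_vector(v), planned_axis)
  }, numeric(1))

  dplyr::mutate(
    tibble::as_tibble(dataset),
    offset_rl_mm = off[, 1],
    offset_ap_mm = off[, 2],
    offset_si_mm = off[, 3],
    dist_2d_mm = sqrt(off[, 1]^2 + off[, 2]^2),
    dist_3d_mm = sqrt(off[, 1]^2 + off[, 2]^2 + off[, 3]^2),
    mark_offset_rl_mm = mark_off[, 1],
    mark_offset_ap_mm = mark_off[, 2],
    mark_dist_2d_mm = sqrt(mark_off[, 1]^2 + mark_off[, 2]^2),
    angular_error_deg = ang
  )
}

#' Angular error of a single trajectory
#'
#' Angle in [0, 90] degrees between the planned electrode axis and the
#' physical axis through the penetration mark (projected onto the planned
#' entry's depth plane) and the deposit. Returns `NA` (degenerate flag) when
#' the two physical points coincide.
#'
#' @param planned_axis Unit planned direction.
#' @param mark,deposit Observed mark and deposit points (mm).
#' @param entry_depth Depth-plane coordinate (device z) of the planned entry.
#' @returns Degrees, or `NA_real_` if degenerate.
#' @export
angular_error <- function(planned_axis, mark, deposit, entry_depth) {
  mark <- as_point3(mark, "mark")
  deposit <- as_point3(deposit, "deposit")
  mark_proj <- c(mark[1:2], entry_depth)
  v <- deposit - mark_proj
  if (sqrt(sum(v^2)) < 1e-9) return(NA_real_)
  angle_between_axes(unit_vector(v), assert_direction(planned_axis, "planned_axis"))
}

sample_sd0 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

#' Correlation between penetration depth and a targeting-error metric
#'
#' Two-sided Pearson correlation with its t-distribution p-value and Spearman
#' rank correlation (average-rank ties) with the t-approximation p-value
#' (`exact = FALSE`); an exact permutation p-value for the Spearman statistic
#' is available behind `exact_spearman`.
#'
#' @param dataset A deposit-record tibble.
#' @param metric Error metric to correlate against `travel_mm`:
#'   3D deviation or angular error.
#' @param exact_spearman Use the exact permutation distribution for the
#'   Spearman p-value (small n only).
#' @param ... Passed to [record_metrics()].
#' @returns A one-row tibble: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`, `metric`.
#' @export
depth_offset_correlation <- function(dataset,
                                     metric = c("dist_3d_mm", "angular_error_deg"),
                                     exact_spearman = FALSE, ...) {
  metric <- match.arg(metric)
  rec <- if (metric %in% names(dataset)) tibble::as_tibble(dataset) else
    record_metrics(dataset, ...)
  y <- rec[[metric]]
  x <- rec$travel_mm
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    rlang::abort("Need at least 3 records for a depth-offset correlation.",
                 class = "stereonav_empty_input")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    rlang::abort("Depth (or metric) is constant: correlation undefined.",
                 class = "stereonav_degenerate_correlation")
  }
  pe <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact_spearman,
                    alternative = "two.sided"))
  tibble::tibble(
    pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    n = length(x), metric = metric
  )
}

#' Summarize the targeting accuracy of a deposition experiment
#'
#' Computes the full accuracy analysis: sample means and standard deviations
#' (n-1 denominator) of per-axis deposit offsets, 2D distance to the planned
#' electrode axis, 3D deviation, penetration-mark RL/AP offsets and 2D
#' distance, angular errors; a per-guide breakdown; and the depth-offset
#' correlation. Groups with a single record report sd 0 together with an
#' `insufficient_n` flag.
#'
#' @inheritParams record_metrics
#' @param correlation_metric Metric for [depth_offset_correlation()].
#' @returns A `nav_evaluation` object with `$records` (per-record metrics),
#'   `$summary` (per-metric mean/sd tibble), `$per_guide` and
#'   `$correlation`. Use [tidy()]/[glance()]/[ggplot2::autoplot()] on it.
#' @export
evaluate_accuracy <- function(dataset,
                              model_layout = guide_tube_layout(length_deficit_mm = 0),
                              correct_for_guide = TRUE,
                              correlation_metric = c("dist_3d_mm", "angular_error_deg")) {
  correlation_metric <- match.arg(correlation_metric)
  rec <- record_metrics(dataset, model_layout = model_layout,
                        correct_for_guide = correct_for_guide)

  metric_cols <- c(
    deposit_offset_rl = "offset_rl_mm",
    deposit_offset_ap = "offset_ap_mm",
    deposit_offset_si = "offset_si_mm",
    deposit_dist_2d = "dist_2d_mm",
    deposit_dist_3d = "dist_3d_mm",
    mark_offset_rl = "mark_offset_rl_mm",
    mark_offset_ap = "mark_offset_ap_mm",
    mark_dist_2d = "mark_dist_2d_mm",
    angular_error = "angular_error_deg"
  )
  summary <- purrr::imap(metric_cols, function(col, nm) {
    x <- rec[[col]]
    ok <- sum(!is.na(x))
    tibble::tibble(metric = nm,
                   unit = if (nm == "angular_error") "deg" else "mm",
                   mean = mean(x, na.rm = TRUE), sd = sample_sd0(x),
                   n = ok, insufficient_n = ok < 2L)
  }) |> dplyr::bind_rows()

  per_guide <- rec |>
    dplyr::group_by(.data$guide_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_offset_rl_mm = mean(.data$offset_rl_mm),
      mean_offset_ap_mm = mean(.data$offset_ap_mm),
      mean_offset_si_mm = mean(.data$offset_si_mm),
      sd_offset_si_mm = sample_sd0(.data$offset_si_mm),
      mean_dist_2d_mm = mean(.data$dist_2d_mm),
      mean_dist_3d_mm = mean(.data$dist_3d_mm),
      insufficient_n = dplyr::n() < 2L,
      .groups = "drop"
    )

  correlation <- tryCatch(
    depth_offset_correlation(rec, metric = correlation_metric),
    error = function(e) tibble::tibble(
      pearson_r = NA_real_, pearson_p = NA_real_,
      spearman_rho = NA_real_, spearman_p = NA_real_,
      n = nrow(rec), metric = correlation_metric)
  )

  structure(list(records = rec, summary = summary, per_guide = per_guide,
                 correlation = correlation, n = nrow(rec),
                 correct_for_guide = correct_for_guide),
            class = "nav_evaluation")
}

#' @export
print.nav_evaluation <- function(x, ...) {
  cat("<nav_evaluation>", x$n, "deposit records\n")
  print(x$summary, n = Inf)
  cat("depth-offset correlation (", x$correlation$metric, "): Pearson r = ",
      signif(x$correlation$pearson_r, 3), " (p = ",
      signif(x$correlation$pearson_p, 3), "); Spearman rho = ",
      signif(x$correlation$spearman_rho, 3), " (p = ",
      signif(x$correlation$spearman_p, 3), ")\n", sep = "")
  invisible(x)
}

#' Tidy an accuracy evaluation
#'
#' @param x A `nav_evaluation`.
#' @param ... Unused.
#' @returns The per-metric summary tibble (metric, unit, mean, sd, n).
#' @method tidy nav_evaluation
#' @export
tidy.nav_evaluation <- function(x, ...) x$summary

#' One-row summary of an accuracy evaluation
#'
#' @inheritParams tidy.nav_evaluation
#' @returns A one-row tibble with the headline accuracy numbers.
#' @method glance nav_evaluation
#' @export
glance.nav_evaluation <- function(x, ...) {
  s <- function(m, what) x$summary[[what]][x$summary$metric == m]
  tibble::tibble(
    n = x$n,
    mean_dist_2d_mm = s("deposit_dist_2d", "mean"),
    sd_dist_2d_mm = s("deposit_dist_2d", "sd"),
    mean_dist_3d_mm = s("deposit_dist_3d", "mean"),
    sd_dist_3d_mm = s("deposit_dist_3d", "sd"),
    mean_mark_dist_2d_mm = s("mark_dist_2d", "mean"),
    mean_angular_error_deg = s("angular_error", "mean"),
    pearson_r = x$correlation$pearson_r,
    pearson_p = x$correlation$pearson_p,
    spearman_rho = x$correlation$spearman_rho,
    spearman_p = x$correlation$spearman_p
  )
}

#' Violin/box plot of targeting errors
#'
#' Per-record signed offsets (R, A, S), the 2D in-plane distance (RA) and the
#' 3D distance (RAS) for deposits, plus the penetration-mark offsets, in the
#' style of a per-axis accuracy figure.
#'
#' @param object A `nav_evaluation`.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot nav_evaluation
#' @export
autoplot.nav_evaluation <- function(object, ...) {
  long <- object$records |>
    dplyr::select(dplyr::all_of(c("record_id", "offset_rl_mm", "offset_ap_mm",
                                  "offset_si_mm", "dist_2d_mm", "dist_3d_mm",
                                  "mark_offset_rl_mm", "mark_offset_ap_mm",
                                  "mark_dist_2d_mm"))) |>
    tidyr::pivot_longer(-"record_id", names_to = "metric", values_to = "mm") |>
    dplyr::mutate(
      source = dplyr::if_else(startsWith(.data$metric, "mark_"),
                              "penetration mark", "iron deposit"),
      metric = dplyr::recode(.data$metric,
        offset_rl_mm = "R", offset_ap_mm = "A", offset_si_mm = "S",
        dist_2d_mm = "RA", dist_3d_mm = "RAS",
        mark_offset_rl_mm = "R", mark_offset_ap_mm = "A",
        mark_dist_2d_mm = "RA"),
      metric = factor(.data$metric, levels = c("R", "A", "RA", "S", "RAS"))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$mm)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~source, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "offset / distance (mm)",
                  title = "Planned-to-physical targeting error") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
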