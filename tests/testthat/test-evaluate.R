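test_that("per-record metrics follow the Pythagorean closed forms", {
  ds <- offsets_dataset(rbind(c(0.3, 0.4, 0), c(0, 0, 1), c(0, 0, 0)),
                        travel_mm = 7)
  rec <- record_metrics(ds)
  expect_equal(rec$offset_rl_mm, c(0.3, 0, 0))
  expect_equal(rec$offset_ap_mm, c(0.4, 0, 0))
  expect_equal(rec$offset_si_mm, c(0, 1, 0))
  expect_equal(rec$dist_2d_mm, c(0.5, 0, 0))
  expect_equal(rec$dist_3d_mm, c(0.5, 1, 0))
  expect_equal(rec$mark_dist_2d_mm, c(0, 0, 0))
})

test_that("a deposit superior of its plan yields a positive SI offset", {
  ds <- offsets_dataset(matrix(c(0, 0, 0.78), 1))
  rec <- record_metrics(ds)
  expect_equal(rec$offset_si_mm, 0.78)
  # antisymmetry: swapping observed and planned negates the offsets
  ds2 <- ds
  ds2$observed_deposit_z_mm <- ds$planned_target_z_mm -
    (ds$observed_deposit_z_mm - ds$planned_target_z_mm)
  expect_equal(record_metrics(ds2)$offset_si_mm, -0.78)
})

test_that("3D deviation dominates the 2D axis distance, equal iff SI is zero", {
  set.seed(61)
  ds <- generate_experiment(protocol_config("eggwhite"), seed = 61)
  rec <- record_metrics(ds)
  expect_true(all(rec$dist_3d_mm >= rec$dist_2d_mm - 1e-12))
  flat <- offsets_dataset(cbind(rnorm(5), rnorm(5), 0))
  rflat <- record_metrics(flat)
  expect_equal(rflat$dist_3d_mm, rflat$dist_2d_mm, tolerance = 1e-12)
})

test_that("angular error matches the arctangent construction and is rigid-invariant", {
  # mark and deposit on the planned axis -> 0
  expect_equal(angular_error(c(0, 0, -1), c(0, 0, 0), c(0, 0, -6), 0), 0)
  # deposit displaced 0.5 mm perpendicular at 5.8 mm depth
  expect_equal(angular_error(c(0, 0, -1), c(0, 0, 0), c(0.5, 0, -5.8), 0),
               atan(0.5 / 5.8) * 180 / pi, tolerance = 1e-9)
  expect_true(is.na(angular_error(c(0, 0, -1), c(0.2, 0.1, 0), c(0.2, 0.1, 0), 0)))
  # invariance under rotations that preserve the depth-plane convention is
  # checked through the full-axis form: angle between planned and physical
  # axes is frame-free
  set.seed(67)
  for (i in 1:10) {
    w <- random_rigid_transform()
    ax <- random_unit(); v <- random_unit()
    expect_equal(
      angle_between_axes(transform_direction(w, ax), transform_direction(w, v)),
      angle_between_axes(ax, v), tolerance = 1e-7)
  }
})

test_that("summaries equal a brute-force recomputation from the CSV", {
  ds <- generate_experiment(protocol_config("eggwhite"), seed = 71)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  ev <- evaluate_accuracy(back)
  # brute force with base R from the raw CSV columns
  raw <- utils::read.csv(path)
  lat <- t(vapply(raw$guide_id,
                  function(id) guide_offset(guide_tube_layout(length_deficit_mm = 0), id),
                  numeric(3)))
  dx <- raw$observed_deposit_x_mm - (raw$planned_target_x_mm + lat[, 1])
  dy <- raw$observed_deposit_y_mm - (raw$planned_target_y_mm + lat[, 2])
  dz <- raw$observed_deposit_z_mm - (raw$planned_target_z_mm + lat[, 3])
  s <- ev$summary
  g <- function(m, w) s[[w]][s$metric == m]
  expect_equal(g("deposit_offset_rl", "mean"), mean(dx), tolerance = 1e-9)
  expect_equal(g("deposit_offset_ap", "sd"), sd(dy), tolerance = 1e-9)
  expect_equal(g("deposit_offset_si", "mean"), mean(dz), tolerance = 1e-9)
  expect_equal(g("deposit_dist_2d", "mean"), mean(sqrt(dx^2 + dy^2)), tolerance = 1e-9)
  expect_equal(g("deposit_dist_3d", "mean"), mean(sqrt(dx^2 + dy^2 + dz^2)),
               tolerance = 1e-9)
  expect_equal(g("deposit_dist_3d", "sd"), sd(sqrt(dx^2 + dy^2 + dz^2)),
               tolerance = 1e-9)
})

test_that("a zero-noise pipeline evaluates to all-zero offsets", {
  ds <- generate_experiment(protocol_config("eggwhite"),
                            noise_model(tracking_sigma_mm = 0), seed = 3)
  ev <- evaluate_accuracy(ds)
  dep <- ev$summary[startsWith(ev$summary$metric, "deposit"), ]
  expect_true(all(abs(dep$mean) < 1e-12))
  expect_true(all(dep$sd < 1e-12))
})

test_that("single-record summaries report sd 0 with an insufficient-n flag", {
  ds <- offsets_dataset(matrix(c(0.3, 0.4, 0), 1))
  ev <- evaluate_accuracy(ds)
  row <- ev$summary[ev$summary$metric == "deposit_dist_2d", ]
  expect_equal(row$mean, 0.5)
  expect_equal(row$sd, 0)
  expect_true(row$insufficient_n)
})

test_that("depth-offset correlation recovers monotone relationships", {
  n <- 12
  travel <- seq(6, 10, length.out = n)
  ds <- tibble::tibble(travel_mm = travel, dist_3d_mm = 0.1 + 0.05 * travel)
  r <- depth_offset_correlation(ds)
  expect_equal(r$pearson_r, 1, tolerance = 1e-9)
  expect_equal(r$spearman_rho, 1, tolerance = 1e-9)
  ds2 <- tibble::tibble(travel_mm = travel, dist_3d_mm = exp(-travel))
  expect_equal(depth_offset_correlation(ds2)$spearman_rho, -1, tolerance = 1e-9)
  expect_error(
    depth_offset_correlation(tibble::tibble(travel_mm = rep(7, 5),
                                            dist_3d_mm = rnorm(5))),
    class = "stereonav_degenerate_correlation")
})

test_that("correlation p-values are uniform under an independent null", {
  set.seed(73)
  reps <- 2000
  p_pe <- numeric(reps)
  p_sp <- numeric(reps)
  for (i in seq_len(reps)) {
    ds <- tibble::tibble(travel_mm = rnorm(10), dist_3d_mm = rnorm(10))
    r <- depth_offset_correlation(ds)
    p_pe[i] <- r$pearson_p
    p_sp[i] <- r$spearman_p
  }
  expect_gt(suppressWarnings(ks.test(p_pe, "punif"))$p.value, 0.01)
  # the Spearman t-approximation is slightly conservative at n = 10; its
  # p-values must still be essentially uniform
  expect_gt(mean(p_sp < 0.05), 0.02)
  expect_lt(mean(p_sp < 0.05), 0.08)
})

test_that("uncorrected outer-guide deposits sit superior of central-guide ones", {
  proto <- protocol_config("eggwhite", n_electrodes = 5, deposits_per_electrode = 10)
  ds <- generate_experiment(proto, noise_preset("eggwhite"), seed = 77)
  ev <- evaluate_accuracy(ds) # default model assumes equal guide lengths
  pg <- ev$per_guide
  si_outer <- mean(pg$mean_offset_si_mm[pg$guide_id != 3])
  si_central <- pg$mean_offset_si_mm[pg$guide_id == 3]
  expect_gt(si_outer, si_central)
  # correcting with the physically calibrated layout removes the bias
  ev2 <- evaluate_accuracy(ds, model_layout = guide_tube_layout())
  pg2 <- ev2$per_guide
  expect_lt(abs(mean(pg2$mean_offset_si_mm[pg2$guide_id != 3])), 0.5)
})

test_that("tidy, glance and autoplot expose the evaluation results", {
  ds <- generate_experiment(protocol_config("eggwhite"), seed = 79)
  ev <- evaluate_accuracy(ds)
  td <- tidy(ev)
  expect_true(all(c("metric", "mean", "sd", "n") %in% names(td)))
  gl <- glance(ev)
  expect_equal(gl$n, 10)
  expect_true(gl$mean_dist_3d_mm >= gl$mean_dist_2d_mm)
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
})
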