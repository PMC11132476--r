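test_that("paired-point registration recovers exact transforms", {
  fid <- matrix(c(10, 0, 0,
                  0, 12, 0,
                  0, 0, 9,
                  -4, 5, 3), 4, 3, byrow = TRUE)
  # identical sets -> identity, zero residual
  r0 <- paired_point_register(fid, fid)
  expect_equal(r0$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(r0$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(r0$fre_mm, 0, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    tr <- random_rigid_transform()
    n <- sample(3:6, 1)
    src <- matrix(rnorm(3 * n, sd = 8), n, 3)
    r <- paired_point_register(src, transform_points(tr, src))
    expect_lt(max(abs(r$transform$rotation - tr$rotation)), 1e-9)
    expect_lt(max(abs(r$transform$translation - tr$translation)), 1e-9)
    expect_lt(r$fre_mm, 1e-9)
  }
})

test_that("registration is invariant to consistent fiducial permutation", {
  set.seed(5)
  src <- matrix(rnorm(15, sd = 6), 5, 3)
  tgt <- transform_points(random_rigid_transform(), src) +
    matrix(rnorm(15, sd = 0.1), 5, 3)
  r1 <- paired_point_register(src, tgt)
  perm <- sample(5)
  r2 <- paired_point_register(src[perm, ], tgt[perm, ])
  expect_equal(r1$transform$rotation, r2$transform$rotation, tolerance = 1e-9)
  expect_equal(r1$transform$translation, r2$transform$translation, tolerance = 1e-9)
  expect_equal(r1$fre_mm, r2$fre_mm, tolerance = 1e-12)
})

test_that("degenerate fiducial geometry is rejected", {
  collinear <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  expect_error(paired_point_register(collinear, collinear),
               class = "stereonav_ill_conditioned")
  coincident <- matrix(1, 3, 3)
  expect_error(paired_point_register(coincident, coincident),
               class = "stereonav_ill_conditioned")
  expect_error(paired_point_register(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               class = "stereonav_ill_conditioned")
})

test_that("Monte-Carlo fiducial residual matches the closed-form FRE expectation", {
  # with Gaussian localization noise of sd sigma on one set of N fiducials,
  # E[FRE^2] = (1 - 2/N) * 3 sigma^2; N = 3 gives sigma^2 exactly
  set.seed(11)
  S <- matrix(c(10, 0, 0, 0, 12, 0, 0, 0, 9), 3, 3, byrow = TRUE)
  sigma <- 0.1
  fre2 <- vapply(seq_len(10000), function(i) {
    paired_point_register(S, S + matrix(rnorm(9, sd = sigma), 3, 3))$fre_mm^2
  }, numeric(1))
  expect_equal(mean(fre2), (1 - 2 / 3) * 3 * sigma^2, tolerance = 0.05)
})

test_that("RMS error matches hand arithmetic and a brute-force oracle", {
  expect_equal(rms_error(matrix(0, 4, 3)), 0)
  # residual lengths 3 and 4 -> sqrt((9 + 16) / 2)
  expect_equal(rms_error(c(3, 4)), sqrt(12.5))
  expect_equal(rms_error(matrix(c(3, 0, 0, 0, 4, 0), 2, 3, byrow = TRUE)),
               sqrt(12.5))
  set.seed(8)
  res <- matrix(rnorm(30), 10, 3)
  expect_equal(rms_error(res), sqrt(mean(rowSums(res^2))), tolerance = 1e-12)
  expect_error(rms_error(numeric()), class = "stereonav_empty_input")
})

test_that("surface refinement converges with a non-increasing RMS trace", {
  cloud <- bent_sheet_cloud()
  set.seed(31)
  probes <- cloud[sample(nrow(cloud), 120), ]
  # probes already on the surface: immediate convergence at RMS 0
  r0 <- surface_refine(cloud, probes)
  expect_equal(r0$rms_mm, 0, tolerance = 1e-12)
  expect_true(r0$converged)
  # known small rigid perturbation is recovered
  pert <- rigid_transform(rotation_about_x(4) %*% rotation_about_y(-3),
                          c(1.2, -0.8, 0.6))
  displaced <- transform_points(transform_invert(pert), probes)
  r <- surface_refine(cloud, displaced)
  expect_true(r$converged)
  expect_lt(max(abs(transform_points(r$transform, displaced) - probes)), 0.05)
  ang <- acos(min(1, (sum(diag(t(r$transform$rotation) %*% pert$rotation)) - 1) / 2))
  expect_lt(ang * 180 / pi, 0.1)
  # monotone non-increasing per-iteration RMS
  expect_true(all(diff(r$rms_trace) <= 1e-9))
  expect_equal(tidy(r)$rms_mm, r$rms_trace)
})

test_that("planar clouds expose the sliding ambiguity along the normal", {
  g <- seq(-10, 10, by = 1)
  plane <- as.matrix(expand.grid(x = g, y = g))
  plane <- cbind(plane, 0)
  h <- 0.3
  probes <- plane[seq(1, nrow(plane), by = 7), ]
  probes[, 3] <- h
  r <- surface_refine(plane, probes)
  # first-iteration RMS is exactly the normal offset
  expect_equal(r$rms_trace[1], h, tolerance = 1e-9)
  # the recovered transform moves only along the plane normal
  expect_equal(r$transform$rotation, diag(3), tolerance = 1e-6)
  expect_lt(max(abs(r$transform$translation[1:2])), 1e-6)
  expect_equal(r$transform$translation[3], -h, tolerance = 1e-6)
})

test_that("surface refinement validates its inputs", {
  cloud <- bent_sheet_cloud()
  expect_error(surface_refine(cloud[1:5, ], cloud[1:5, ]),
               class = "stereonav_empty_input")
  expect_error(surface_refine(cloud, cloud[0, ]),
               class = "stereonav_empty_input")
})

test_that("surface cloud CSV round-trips and validates its header", {
  set.seed(91)
  cloud <- bent_sheet_cloud(n = 36)
  path <- withr::local_tempfile(fileext = ".csv")
  write_surface_cloud(cloud, path)
  back <- read_surface_cloud(path)
  expect_equal(as.matrix(back), cloud, ignore_attr = TRUE, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(a = 1, b = 2), bad)
  expect_error(read_surface_cloud(bad), class = "stereonav_schema_error")
})
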