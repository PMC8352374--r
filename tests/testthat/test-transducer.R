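test_that("couch geometry derives the calibrated membrane-to-home distance", {
  couch <- couch_geometry()
  expect_equal(couch$membrane_to_home,
               couch$home_below_isocentre - couch$membrane_below_isocentre)
  expect_equal(couch_home(couch), c(0, -140, 0))
  expect_error(couch_geometry(home_below_isocentre = 50,
                              membrane_below_isocentre = 72.5))
})

test_that("element layout lies on the focal sphere within the aperture", {
  td <- build_transducer()
  expect_equal(td$n_elements, 256L)
  focus <- c(0, td$focal_length, 0)  # local frame, apex at origin
  d <- sqrt(rowSums(sweep(td$element_offsets, 2, focus, "-")^2))
  expect_true(all(abs(d - 140) < 1e-9))
  expect_true(max(sqrt(td$element_offsets[, 1]^2 + td$element_offsets[, 3]^2))
              <= 65 + 1e-9)
  # deterministic layout
  expect_identical(td$element_offsets, build_transducer()$element_offsets)

  one <- build_transducer(n_elements = 1)
  expect_equal(as.numeric(one$element_offsets), c(0, 0, 0), tolerance = 1e-12)

  expect_error(build_transducer(aperture_diameter = 300, focal_length = 140),
               "non-physical")
})

test_that("pose_to_focus maps zero pose to the isocentre and tilts correctly", {
  couch <- couch_geometry()
  fa0 <- pose_to_focus(transducer_pose(), couch)
  expect_equal(fa0$focus, couch$isocentre, tolerance = 1e-12)
  expect_equal(fa0$axis, c(0, 1, 0))

  fa_t <- pose_to_focus(transducer_pose(c(10, 0, 0)), couch)
  expect_equal(fa_t$focus, couch$isocentre + c(10, 0, 0), tolerance = 1e-12)

  fa_r <- pose_to_focus(transducer_pose(tilt_lr = 10), couch)
  expect_equal(fa_r$focus[1], -140 * sin(10 * pi / 180), tolerance = 1e-9)
  expect_equal(fa_r$focus[2], -140 * (1 - cos(10 * pi / 180)), tolerance = 1e-9)
  expect_equal(fa_r$focus[3], 0)

  expect_error(pose_to_focus(transducer_pose(c(100, 0, 0)), couch,
                             limits = pose_limits()),
               "outside")
})

test_that("enumerate_poses builds the expected regular grid", {
  lim <- pose_limits(ap_toward_patient = 0, ap_away = 0, tilt_max = 2.5,
                     tilt_step = 2.5, translation_step = 4)
  poses <- enumerate_poses(lim, list(lr = c(-8, 8), is_ = c(0, 0)))
  expect_equal(nrow(poses), 5 * 1 * 1 * 3)
  expect_false(any(duplicated(poses)))
  # deterministic ordering: LR slowest, tilt fastest, all ascending
  expect_equal(unique(poses$lr), c(-8, -4, 0, 4, 8))
  expect_true(all(diff(order(poses$lr, poses$is_, poses$ap, poses$tilt)) == 1))

  # the default tilt envelope has 9 values (-10 .. 10 by 2.5)
  full <- enumerate_poses(pose_limits(), list(lr = c(0, 0), is_ = c(0, 0)))
  expect_equal(sort(unique(full$tilt)), seq(-10, 10, by = 2.5))
  expect_equal(nrow(full), 1 * 1 * 17 * 9)

  expect_warning(
    empty <- enumerate_poses(pose_limits(), list(lr = c(100, 120),
                                                 is_ = c(0, 0))),
    "no poses")
  expect_equal(nrow(empty), 0)
})

test_that("trace_beam discretizes every ray from element to focus", {
  td <- build_transducer()
  couch <- couch_geometry()
  pts <- trace_beam(transducer_pose(), td, couch)
  expect_equal(attr(pts, "points_per_ray"), 700)
  expect_equal(nrow(pts), 256 * 700)
  # first point of each ray is the element itself; last stops short of focus
  first <- pts[(0:255) * 700 + 1, ]
  dist_first <- sqrt(rowSums(sweep(first, 2, couch$isocentre, "-")^2))
  expect_true(all(abs(dist_first - 140) < 1e-9))
  last <- pts[(1:256) * 700, ]
  dist_last <- sqrt(rowSums(sweep(last, 2, couch$isocentre, "-")^2))
  expect_true(all(abs(dist_last - 0.2) < 1e-9))

  expect_equal(attr(trace_beam(transducer_pose(), td, couch, 1.0),
                    "points_per_ray"), 140)

  # translation shifts the cloud rigidly; tilt preserves ray lengths
  shifted <- trace_beam(transducer_pose(c(7, -3, 11)), td, couch)
  expect_lt(max(abs(sweep(shifted, 2, c(7, -3, 11), "-") - pts)), 1e-9)
  tilted <- trace_beam(transducer_pose(tilt_lr = 7.5), td, couch)
  fa <- pose_to_focus(transducer_pose(tilt_lr = 7.5), couch)
  tfirst <- tilted[(0:255) * 700 + 1, ]
  expect_true(all(abs(sqrt(rowSums(sweep(tfirst, 2, fa$focus, "-")^2)) - 140)
                  < 1e-9))
})

test_that("point_in_cell implements the closed ellipsoid", {
  cell <- treatment_cell(center = c(0, 0, 0), axis = c(0, 1, 0))
  expect_true(point_in_cell(c(0, 0, 0), cell))
  expect_false(point_in_cell(c(4.1, 0, 0), cell))
  expect_true(point_in_cell(c(4, 0, 0), cell))       # transverse boundary
  expect_true(point_in_cell(c(0, 10.92, 0), cell))   # long-axis boundary
  expect_false(point_in_cell(c(0, 10.93, 0), cell))
  # vectorized and axis-aware
  tilted <- treatment_cell(center = c(1, 2, 3), axis = c(1, 0, 0))
  expect_equal(point_in_cell(rbind(c(1 + 10.92, 2, 3), c(1, 2 + 4.1, 3)),
                             tilted),
               c(TRUE, FALSE))
})

test_that("Monte-Carlo cell volume matches the closed-form ellipsoid", {
  cell <- treatment_cell()
  set.seed(7)
  n <- 2e5
  box <- c(8, 8, 21.84)
  pts <- cbind(runif(n, -4, 4), runif(n, -4, 4), runif(n, -10.92, 10.92))
  pts <- pts[, c(1, 3, 2)]  # long axis along AP = cell axis
  vol_mc <- mean(point_in_cell(pts, cell)) * prod(box)
  vol_true <- 4 / 3 * pi * 4^2 * 10.92
  expect_equal(vol_mc, vol_true, tolerance = 0.02)
})

test_that("device YAML round-trips the system defaults", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "device.yaml")
  writeLines(c("n_elements: 128", "aperture_mm: 100", "focal_length_mm: 120",
               "limits:", "  tilt_max_deg: 5", "  translation_step_mm: 2",
               "couch:", "  home_below_isocentre_mm: 130"), f)
  cfg <- read_device_config(f)
  expect_equal(cfg$transducer$n_elements, 128L)
  expect_equal(cfg$transducer$focal_length, 120)
  expect_equal(cfg$limits$tilt_max, 5)
  expect_equal(cfg$limits$translation_step, 2)
  expect_equal(cfg$couch$home_below_isocentre, 130)
  expect_equal(cfg$couch$membrane_to_home, 130 - 72.5)
  expect_equal(cfg$cell$diameter, 8)
})
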