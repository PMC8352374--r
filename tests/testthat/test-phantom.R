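test_that("phantom generation is deterministic given spec and seed", {
  s <- phantom_spec(profile = "mini", tilt_deg = 12, seed = 99L)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$anatomy$image$data, b$anatomy$image$data)
  expect_identical(a$anatomy$body$data, b$anatomy$body$data)
  expect_identical(a$landmarks, b$landmarks)
  # a different seed changes the noise but not the masks
  c_ <- generate_phantom(phantom_spec(profile = "mini", tilt_deg = 12,
                                      seed = 100L))
  expect_false(identical(a$anatomy$image$data, c_$anatomy$image$data))
  expect_identical(a$anatomy$body$data, c_$anatomy$body$data)
})

test_that("phantom masks satisfy the anatomy invariants", {
  for (tilt in c(0, 22)) {
    an <- generate_phantom(phantom_spec(profile = "mini", tilt_deg = tilt))$anatomy
    expect_false(any(an$target$data & an$bone$data))
    expect_true(all(!an$target$data | an$body$data))
    expect_false(any(an$extracorporeal_air$data & an$body$data))
    expect_gt(sum(an$target$data), 0)
  }
})

test_that("voxelized tumour volume approximates the analytic ellipsoid", {
  # 17 mm spherical target on a 1 mm grid, patient-scale ~20,580 mm^3
  ph <- generate_phantom(phantom_spec(profile = "mini", tilt_deg = 0,
                                      on_couch = FALSE,
                                      dim = c(96L, 96L, 48L),
                                      spacing = c(1, 1, 1),
                                      ap_origin = -47,
                                      referral_center_ap = 0,
                                      body_is_halflength = 24,
                                      ring_z_half = 20))
  vol <- sum(ph$anatomy$target$data) * prod(ph$anatomy$image$spacing)
  expect_equal(vol, 4 / 3 * pi * 17^3, tolerance = 0.05)
})

test_that("landmarks rotate rigidly with the phantom tilt", {
  base <- generate_phantom(phantom_spec(profile = "mini", tilt_deg = 0))
  tilt <- generate_phantom(phantom_spec(profile = "mini", tilt_deg = 22))
  L0 <- as.matrix(base$landmarks[, c("x", "y", "z")])
  L1 <- as.matrix(tilt$landmarks[, c("x", "y", "z")])
  expect_gte(nrow(L0), 10)
  # landmarks are anchored to the pelvic ring centred on the isocentre, so
  # tilting rotates them rigidly about the isocentre
  R <- rot_is_deg(22)
  iso <- c(0, 0, 0)
  pred <- sweep(sweep(L0, 2, iso, "-") %*% t(R), 2, iso, "+")
  expect_lt(max(abs(pred - L1)), 1e-9)
})

test_that("the on-couch phantom encodes the deformation chain truthfully", {
  ph <- mini_phantom(tilt_deg = 10)
  tt <- ph$truth
  # skin point sits t above the bowed membrane; home 140 below isocentre
  expect_equal(tt$skin_point[2],
               -72.5 - tt$membrane_bowing + tt$gelpad_thickness)
  expect_equal(tt$home, c(0, -140, 0))
  # gel-pad voxels occupy the space between bowed membrane and skin
  gel_idx <- arrayInd(which(ph$gelpad$data), dim(ph$gelpad$data))
  gel_ap <- ph$anatomy$image$origin[2] +
    (gel_idx[, 2] - 1) * ph$anatomy$image$spacing[2]
  expect_gte(min(gel_ap), -72.5 - tt$membrane_bowing - 1e-9)
  expect_gt(sum(ph$gelpad$data), 0)
})

test_that("referral/treatment pairs carry their exact linking affine", {
  pair <- make_referral_treatment_pair(
    phantom_spec(profile = "mini", tilt_deg = 15))
  tr <- fit_landmark_affine(pair$landmarks_referral,
                            pair$landmarks_treatment)
  expect_lt(max(abs(tr$matrix - pair$true_affine$matrix)), 1e-9)
  expect_lt(max(abs(tr$translation - pair$true_affine$translation)), 1e-9)

  # zero-tilt pair: rotation part is the identity
  pair0 <- make_referral_treatment_pair(
    phantom_spec(profile = "mini", tilt_deg = 0))
  expect_equal(pair0$true_affine$matrix, diag(3), tolerance = 1e-12)

  # mapping referral landmarks through the truth lands on treatment ones
  moved <- transform_points(pair$true_affine,
                            as.matrix(pair$landmarks_referral[, c("x", "y", "z")]))
  expect_lt(max(abs(moved - as.matrix(
    pair$landmarks_treatment[, c("x", "y", "z")]))), 1e-9)
})

test_that("noisy landmarks yield a registration error at the noise scale", {
  pair <- make_referral_treatment_pair(
    phantom_spec(profile = "mini", tilt_deg = 15))
  S <- as.matrix(pair$landmarks_referral[, c("x", "y", "z")])
  D <- as.matrix(pair$landmarks_treatment[, c("x", "y", "z")])
  set.seed(21)
  errs <- replicate(100, {
    Dn <- D + matrix(rnorm(length(D), 0, 1), ncol = 3)
    tr <- fit_landmark_affine(S, Dn)
    registration_error(transform_points(tr, S), Dn)
  })
  # mean residual for sigma = 1 after a 12-parameter fit on 12 landmarks
  expect_gt(mean(errs), 0.5)
  expect_lt(mean(errs), 2)
})

test_that("invariant-violating specs are rejected", {
  # tumour pushed outside the body
  expect_error(generate_phantom(
    phantom_spec(profile = "mini", tilt_deg = 0,
                 tumor_center_world = c(0, 50, 0))),
    "outside the body")
  # tumour centre moved into the bone ring
  expect_error(generate_phantom(
    phantom_spec(profile = "mini", tilt_deg = 0,
                 tumor_center_world = c(26, 0, 0))),
    "bone")
})
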