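# Small hand-built scenes for beam clearance: grid spans the beam path
# between transducer and focus so obstructions can be placed inside it.
beam_scene <- function(bone_ix = NULL, dim = c(40, 40, 40),
                       spacing = c(2, 2, 2)) {
  origin <- c(-(dim[1] - 1) * spacing[1] / 2, -79,
              -(dim[3] - 1) * spacing[3] / 2)
  blank_anatomy(dim, spacing, origin, bone = bone_ix)
}

test_that("a beam with no obstructions is always clear", {
  an <- beam_scene()
  td <- build_transducer()
  for (pose in list(transducer_pose(), transducer_pose(c(10, -5, 20)),
                    transducer_pose(tilt_lr = -10)))
    expect_true(is_beam_clear(pose, td, an))
})

test_that("a slab across the whole aperture blocks every pose", {
  dim <- c(40, 40, 40)
  slab <- as.matrix(expand.grid(i = 1:40, j = 18:20, k = 1:40))
  an <- beam_scene(slab)
  td <- build_transducer()
  expect_false(is_beam_clear(transducer_pose(), td, an))
  expect_false(is_beam_clear(transducer_pose(tilt_lr = 10), td, an))
})

test_that("a small cube clipping only edge rays still blocks the pose", {
  # 3-voxel (6 mm) cube near the lateral beam margin, halfway down: at
  # y ~ -67 mm the beam's widest ray reaches |x| ~ 36 mm
  dims <- c(48, 40, 40)
  cube <- as.matrix(expand.grid(i = 39:41, j = 6:8, k = 19:21))  # x 29..33
  an <- beam_scene(cube, dim = dims)
  td <- build_transducer()
  pose <- transducer_pose()
  expect_false(is_beam_clear(pose, td, an))
  # agrees with a 0.01 mm fine-walk oracle (any-ray-blocked rule)
  expect_false(oracle_beam_clear(pose, td, an, step = 0.01,
                                 endpoint_rule = "fine"))
  # moving the cube outside the aperture margin frees the beam
  cube2 <- cube
  cube2[, 1] <- cube2[, 1] + 6                                   # x 41..45
  an2 <- beam_scene(cube2, dim = dims)
  expect_true(is_beam_clear(pose, td, an2))
  expect_true(oracle_beam_clear(pose, td, an2, step = 0.01,
                                endpoint_rule = "fine"))
})

test_that("accumulate_cell marks points in the posed cell, monotonically", {
  tgt <- as.matrix(expand.grid(i = 14:28, j = 14:28, k = 14:28))
  an <- blank_anatomy(c(41, 41, 41), c(1, 1, 1), c(-20, -20, -20),
                      target = tgt)
  grid <- target_grid(an$target)
  pose <- transducer_pose()
  g1 <- accumulate_cell(pose, grid)
  # brute-force enumeration of target voxel centres inside the ellipsoid
  fa <- pose_to_focus(pose, couch_geometry())
  d <- sweep(grid$points, 2, fa$focus, "-")
  w <- d %*% fa$axis
  r2 <- rowSums(d^2) - w^2
  expected <- (r2 / 16 + w^2 / 10.92^2) <= 1
  expect_identical(g1$covered, as.vector(expected))
  expect_gt(sum(g1$covered), 0)
  # the focus grid point itself is covered
  focus_row <- which(rowSums(abs(sweep(grid$points, 2, fa$focus, "-"))) == 0)
  expect_true(g1$covered[focus_row])
  # idempotent, never unsets
  g2 <- accumulate_cell(pose, g1)
  expect_identical(g2$covered, g1$covered)
})

test_that("an unobstructed in-envelope target is fully covered", {
  # 20 mm spherical target centred at the isocentre, no obstructions
  dm <- c(41, 41, 41)
  img <- voxel_volume(array(0, dm), c(1, 1, 1), c(-20, -20, -20))
  idx <- arrayInd(seq_len(prod(dm)), dm)
  w <- voxel_to_world(idx, img)
  ball <- array(rowSums(w^2) <= 10^2, dm)
  an <- labelled_anatomy(img, body = label_mask(array(TRUE, dm), geometry = img),
                         bone = label_mask(array(FALSE, dm), geometry = img),
                         target = label_mask(ball, geometry = img))
  cov <- compute_coverage(an, limits = pose_limits(translation_step = 2))
  expect_equal(cov$tvc_pat, 100.0)
  expect_equal(cov$covered_volume, cov$total_target_volume)
  expect_equal(cov$n_poses_clear, cov$n_poses_tested)
})

test_that("a target enclosed in a thick bone shell has zero coverage", {
  # the shell must be thicker than the cell half-length: rays are only
  # tested up to the focus, so the cell can reach a short way past an
  # obstruction from a focus positioned outside it
  dm <- c(47, 47, 47)
  img <- voxel_volume(array(0, dm), c(1, 1, 1), c(-23, -23, -23))
  idx <- arrayInd(seq_len(prod(dm)), dm)
  w <- voxel_to_world(idx, img)
  r <- sqrt(rowSums(w^2))
  an <- labelled_anatomy(img, body = label_mask(array(TRUE, dm), geometry = img),
                         bone = label_mask(array(r > 12 & r <= 22, dm),
                                           geometry = img),
                         target = label_mask(array(r <= 8, dm),
                                             geometry = img))
  cov <- compute_coverage(an, limits = pose_limits(translation_step = 4))
  expect_equal(cov$tvc_pat, 0.0)
})

test_that("compute_coverage matches the naive sweep oracle exactly", {
  ph <- mini_phantom(tilt_deg = 0, gap_half_angle_deg = 45)
  an <- ph$anatomy
  td <- build_transducer()
  lim <- pose_limits(ap_toward_patient = 4, ap_away = 4, tilt_step = 10,
                     translation_step = 8)
  bounds <- list(lr = c(-8, 8), is_ = c(-8, 8))
  cov <- compute_coverage(an, td, lim, bounds)
  ora <- oracle_coverage(an, td, lim, bounds)
  expect_identical(which(cov$covered_mask$data), ora$lin[ora$covered])
  expect_equal(cov$n_poses_clear, sum(ora$clear))
  # the scenario must be discriminative: some poses blocked, some clear
  expect_gt(cov$n_poses_clear, 0)
  expect_lt(cov$n_poses_clear, cov$n_poses_tested)
  expect_gt(cov$tvc_pat, 0)
  expect_lt(cov$tvc_pat, 100)
})

test_that("coverage is monotone in the obstruction set", {
  ph <- mini_phantom(tilt_deg = 0, gap_half_angle_deg = 45)
  an <- ph$anatomy
  lim <- pose_limits(ap_toward_patient = 4, ap_away = 4, tilt_step = 10,
                     translation_step = 8)
  base <- compute_coverage(an, limits = lim)
  # removing obstruction voxels never decreases coverage
  set.seed(11)
  bone_ix <- which(an$bone$data)
  fewer <- an$bone$data
  fewer[sample(bone_ix, length(bone_ix) %/% 2)] <- FALSE
  an_fewer <- labelled_anatomy(an$image, an$body,
                               label_mask(fewer, geometry = an$image),
                               an$target, an$extracorporeal_air, an$oar,
                               an$couch)
  expect_gte(compute_coverage(an_fewer, limits = lim)$tvc_pat, base$tvc_pat)
  # adding obstruction voxels never increases coverage
  soft <- which(an$body$data & !an$target$data & !an$bone$data)
  more <- an$bone$data
  more[soft[seq(1, length(soft), by = 97)]] <- TRUE
  an_more <- labelled_anatomy(an$image, an$body,
                              label_mask(more, geometry = an$image),
                              an$target, an$extracorporeal_air, an$oar,
                              an$couch)
  expect_lte(compute_coverage(an_more, limits = lim)$tvc_pat, base$tvc_pat)
})

test_that("tvc_pat and tvc_vol implement their defining ratios", {
  expect_equal(tvc_pat(250, 1000), 25.0)
  expect_equal(tvc_pat(1000, 1000), 100.0)
  expect_equal(tvc_pat(0, 1000), 0.0)
  expect_error(tvc_pat(1, 0), "must be > 0")
  expect_error(tvc_pat(2, 1), "CV")

  a <- array(FALSE, c(5, 5, 5)); a[1:4, 1, 1] <- TRUE
  b <- array(FALSE, c(5, 5, 5)); b[1:5, 1, 1] <- TRUE
  expect_equal(tvc_vol(a, a), 100.0)
  expect_equal(tvc_vol(a, b), 100 * 4 / 5)
  expect_equal(tvc_vol(array(FALSE, c(5, 5, 5)), b), 0.0)
  expect_error(tvc_vol(b, array(FALSE, c(5, 5, 5))), "empty")
  # invariant to voxels outside the treatment covered set
  a2 <- a; a2[1, 5, 5] <- TRUE
  expect_equal(tvc_vol(a2, b), tvc_vol(a, b))
})

test_that("target_search_bounds spans the target extents about home", {
  dm <- c(21, 21, 21)
  img <- voxel_volume(array(0, dm), c(1, 1, 1), c(-10, -10, -10))
  one <- array(FALSE, dm); one[11, 11, 11] <- TRUE
  m <- label_mask(one, geometry = img)
  home <- c(0, -140, 0)
  b <- target_search_bounds(m, home)
  expect_equal(b$lr, c(0, 0))
  expect_equal(b$is_, c(0, 0))
  expect_equal(target_search_bounds(m, home, margin = 8)$lr, c(-8, 8))

  box <- array(FALSE, dm); box[3:16, 11, 6:11] <- TRUE
  b2 <- target_search_bounds(label_mask(box, geometry = img), home)
  expect_equal(b2$lr, c(-8, 5))
  expect_equal(b2$is_, c(-5, 0))
})
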