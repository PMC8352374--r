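#' Digital pelvis phantom specification
#'
#' Parameters of the deterministic synthetic phantom: an elliptic-cylinder
#' body resting (when on the couch) on a compressed gel-pad over the bowed
#' membrane, a pelvic-ring bone shell with one angular gap emulating the
#' acoustic window at the sciatic notch, an ellipsoidal tumour target near
#' the magnetic isocentre, optional organ-at-risk ellipsoids, optional
#' lens-shaped air defects at the skin/gel-pad interface, and a pelvic tilt
#' about the IS axis. Intensities are class means plus seeded Gaussian
#' noise.
#'
#' Two profiles are provided: `"desk"` (192 x 160 x 96 voxels at 1.5 mm,
#' the default working scale) and `"mini"` (48^3 at 3 mm, for
#' oracle-equivalence tests).
#'
#' @param profile `"desk"` or `"mini"`.
#' @param tilt_deg pelvic tilt about the IS axis (degrees); the study
#'   treatment angles spanned 6-33 degrees.
#' @param on_couch logical: treatment-style phantom on the gel-pad (`TRUE`)
#'   or supine referral-style phantom (`FALSE`).
#' @param gelpad_thickness,membrane_bowing compressed pad thickness t and
#'   bowing b (mm) used to build the couch-side geometry.
#' @param tumor_halfaxes tumour half-axes (mm); the default 17 mm sphere
#'   matches the patient-scale ~20,000 mm^3 target volume.
#' @param tumor_center_world world position of the tumour centre (treatment
#'   frame; defaults to the magnetic isocentre).
#' @param air_defects list of interface air lenses, each a list with
#'   `center_lr`, `center_is`, `radius_lr`, `radius_is`, `depth` (mm).
#' @param oars list of organ-at-risk ellipsoids, each a list with `center`
#'   (world mm) and `halfaxes` (mm).
#' @param gap_half_angle_deg half-angle of the acoustic-window gap in the
#'   bone ring, measured from the posterior (-AP) direction.
#' @param intensities named list of class mean intensities
#'   (`background`, `gelpad`, `body`, `bone`) and `noise_sd`.
#' @param seed RNG seed for the intensity noise.
#' @param ... overrides for geometry fields (`dim`, `spacing`, `ap_origin`,
#'   `body_halfaxes`, `body_is_halflength`, `ring_outer`, `ring_inner`,
#'   `ring_z_half`, `pad_half_lr`, `referral_center_ap`).
#' @return object of class `hifu_phantom_spec`.
#' @export
phantom_spec <- function(profile = c("desk", "mini"), tilt_deg = 20,
                         on_couch = TRUE,
                         gelpad_thickness = 9.8, membrane_bowing = 10.0,
                         tumor_halfaxes = c(17, 17, 17),
                         tumor_center_world = c(0, 0, 0),
                         air_defects = list(), oars = list(),
                         gap_half_angle_deg = 60,
                         intensities = list(background = 50, gelpad = 700,
                                            body = 1000, bone = 150,
                                            noise_sd = 20),
                         seed = 42L, ...) {
  profile <- match.arg(profile)
  geom <- if (profile == "desk") {
    list(dim = c(192L, 160L, 96L), spacing = c(1.5, 1.5, 1.5),
         ap_origin = -90, body_halfaxes = c(110, 95),
         body_is_halflength = 65, ring_outer = 65, ring_inner = 50,
         ring_z_half = 48, pad_half_lr = 100, referral_center_ap = 10)
  } else {
    list(dim = c(48L, 48L, 48L), spacing = c(3, 3, 3),
         ap_origin = -80, body_halfaxes = c(55, 55),
         body_is_halflength = 60, ring_outer = 30, ring_inner = 22,
         ring_z_half = 36, pad_half_lr = 60, referral_center_ap = 0)
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(geom)) stop("unknown phantom field: ", nm)
    geom[[nm]] <- over[[nm]]
  }
  stopifnot(gelpad_thickness > 0, membrane_bowing >= 0,
            all(tumor_halfaxes > 0), gap_half_angle_deg >= 0,
            gap_half_angle_deg <= 180)
  spec <- c(geom,
            list(profile = profile, tilt_deg = tilt_deg, on_couch = on_couch,
                 gelpad_thickness = gelpad_thickness,
                 membrane_bowing = membrane_bowing,
                 tumor_halfaxes = as.numeric(tumor_halfaxes),
                 tumor_center_world = as.numeric(tumor_center_world),
                 air_defects = air_defects, oars = oars,
                 gap_half_angle_deg = gap_half_angle_deg,
                 intensities = intensities, seed = as.integer(seed),
                 membrane_below_isocentre = 72.5,
                 home_below_isocentre = 140))
  class(spec) <- "hifu_phantom_spec"
  spec
}

# Half-width of the tilted body ellipse along a vertical line through its
# centre: the ellipse (a, b) rotated by phi meets x = 0 at +/- this distance.
tilted_vertical_halfwidth <- function(a, b, phi_deg) {
  phi <- phi_deg * pi / 180
  1 / sqrt(sin(phi)^2 / a^2 + cos(phi)^2 / b^2)
}

phantom_grid <- function(spec) {
  origin <- c(-(spec$dim[1] - 1) * spec$spacing[1] / 2,
              spec$ap_origin,
              -(spec$dim[3] - 1) * spec$spacing[3] / 2)
  list(origin = origin, dim = spec$dim, spacing = spec$spacing)
}

# body-frame landmark points on the bone ring mid-surface, away from the gap
ring_landmarks_body <- function(spec, ring_offset, n = 12) {
  gap <- spec$gap_half_angle_deg * pi / 180
  margin <- 8 * pi / 180
  alpha <- gap + margin + (seq_len(n) - 1) / (n - 1) * (2 * pi - 2 * (gap + margin))
  rm <- (spec$ring_outer + spec$ring_inner) / 2
  z <- rep(c(-0.5, 0.5) * spec$ring_z_half, length.out = n)
  cbind(ring_offset[1] + rm * sin(alpha),
        ring_offset[2] - rm * cos(alpha),
        ring_offset[3] + z)
}

# Voxelize one phantom dataset given its body centre, tilt and body-frame
# structure offsets. Returns masks + image + per-structure truth.
phantom_voxelize <- function(spec, center, tilt_deg, ring_offset,
                             tumor_offset, on_couch, air_defects, seed) {
  g <- phantom_grid(spec)
  dm <- g$dim
  n <- prod(dm)
  idx <- arrayInd(seq_len(n), dm)
  W <- cbind(g$origin[1] + (idx[, 1] - 1) * g$spacing[1],
             g$origin[2] + (idx[, 2] - 1) * g$spacing[2],
             g$origin[3] + (idx[, 3] - 1) * g$spacing[3])
  Rinv <- rotation_is(-tilt_deg)
  X <- sweep(W, 2, center, "-") %*% t(Rinv)
  a <- spec$body_halfaxes[1]; b <- spec$body_halfaxes[2]
  body <- (X[, 1] / a)^2 + (X[, 2] / b)^2 <= 1 &
    abs(X[, 3]) <= spec$body_is_halflength
  # bone ring with angular acoustic-window gap (gap centred on -AP, body frame)
  dx <- X[, 1] - ring_offset[1]
  dy <- X[, 2] - ring_offset[2]
  dz <- X[, 3] - ring_offset[3]
  rad <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, -dy)  # 0 at the posterior (bottom) direction
  gap <- spec$gap_half_angle_deg * pi / 180
  bone <- body & rad >= spec$ring_inner & rad <= spec$ring_outer &
    abs(dz) <= spec$ring_z_half & abs(ang) > gap
  th <- spec$tumor_halfaxes
  tum <- ((X[, 1] - tumor_offset[1]) / th[1])^2 +
    ((X[, 2] - tumor_offset[2]) / th[2])^2 +
    ((X[, 3] - tumor_offset[3]) / th[3])^2 <= 1
  if (any(tum & !body))
    stop("invalid phantom spec: tumour extends outside the body")
  if (any(tum & bone))
    stop("invalid phantom spec: tumour overlaps bone")
  oar <- rep(FALSE, n)
  for (o in spec$oars) {
    oc <- as.numeric(o$center); oh <- as.numeric(o$halfaxes)
    oar <- oar | (((W[, 1] - oc[1]) / oh[1])^2 + ((W[, 2] - oc[2]) / oh[2])^2 +
                    ((W[, 3] - oc[3]) / oh[3])^2 <= 1)
  }
  oar <- oar & !tum & !bone

  body_a <- array(body, dm)
  gel <- rep(FALSE, n)
  air <- rep(FALSE, n)
  if (on_couch) {
    bow_plane <- -spec$membrane_below_isocentre - spec$membrane_bowing
    surf <- body_under_surface(body_a)  # LR x IS matrix of AP indices
    ap_world <- g$origin[2] + (seq_len(dm[2]) - 1) * g$spacing[2]
    lr_world <- g$origin[1] + (seq_len(dm[1]) - 1) * g$spacing[1]
    is_world <- g$origin[3] + (seq_len(dm[3]) - 1) * g$spacing[3]
    gel_a <- array(FALSE, dm)
    air_a <- array(FALSE, dm)
    for (k in seq_len(dm[3])) {
      for (i in seq_len(dm[1])) {
        if (abs(lr_world[i]) > spec$pad_half_lr) next
        sj <- surf[i, k]
        top <- if (!is.na(sj)) ap_world[sj] else bow_plane + spec$gelpad_thickness
        jj <- which(ap_world >= bow_plane & ap_world < top)
        if (!is.na(sj)) jj <- jj[jj < sj]
        gel_a[i, jj, k] <- TRUE
      }
    }
    # lens-shaped air defects replace gel just beneath the local skin surface
    for (df in air_defects) {
      for (k in seq_len(dm[3])) {
        for (i in seq_len(dm[1])) {
          sj <- surf[i, k]
          if (is.na(sj)) next
          u <- ((lr_world[i] - df$center_lr) / df$radius_lr)^2 +
            ((is_world[k] - df$center_is) / df$radius_is)^2
          if (u > 1) next
          depth <- df$depth * sqrt(1 - u)
          skin_ap <- ap_world[sj]
          jj <- which(ap_world < skin_ap & ap_world >= skin_ap - depth)
          jj <- jj[gel_a[i, jj, k]]
          air_a[i, jj, k] <- TRUE
        }
      }
    }
    gel_a <- gel_a & !air_a
    gel <- as.vector(gel_a)
    air <- as.vector(air_a)
  }

  ints <- spec$intensities
  img <- rep(ints$background, n)
  img[gel] <- ints$gelpad
  img[body] <- ints$body
  img[bone] <- ints$bone
  img[air] <- ints$background
  set.seed(seed)
  img <- img + stats::rnorm(n, 0, ints$noise_sd)

  geom <- voxel_volume(array(img, dm), g$spacing, g$origin)
  list(image = geom,
       body = label_mask(array(body, dm), geometry = geom),
       bone = label_mask(array(bone, dm), geometry = geom),
       target = label_mask(array(tum, dm), geometry = geom),
       air = label_mask(array(air, dm), geometry = geom),
       oar = label_mask(array(oar, dm), geometry = geom),
       gelpad = label_mask(array(gel, dm), geometry = geom))
}

#' Generate a digital pelvis phantom
#'
#' Builds one labelled dataset from a [phantom_spec()]: the intensity image
#' (class means plus seeded Gaussian noise), exact ground-truth masks, at
#' least 10 bony landmarks on the pelvic ring, and a truth record holding
#' every generating parameter. Deterministic given the spec and seed.
#'
#' For an on-couch phantom the body is positioned so the skin point on the
#' isocentre column sits at
#' `-membrane_below_isocentre - bowing + gelpad_thickness`, i.e. resting on
#' the compressed pad over the bowed membrane, and the true home position is
#' `home_below_isocentre` beneath the isocentre.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `hifu_phantom`: `anatomy` (a `hifu_anatomy`),
#'   `landmarks` (data.frame `name,x,y,z`), and `truth` (list of generating
#'   parameters: body centre, tilt, structure offsets, skin point, home,
#'   isocentre, t, b).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "hifu_phantom_spec"))
  a <- spec$body_halfaxes[1]; b <- spec$body_halfaxes[2]
  # Structure offsets (body frame) always come from the on-couch treatment
  # configuration implied by the spec, so the supine (on_couch = FALSE)
  # phantom of a spec is the exact referral partner of its treatment phantom.
  b_eff <- tilted_vertical_halfwidth(a, b, spec$tilt_deg)
  skin_ap_couch <- -spec$membrane_below_isocentre - spec$membrane_bowing +
    spec$gelpad_thickness
  center_couch <- c(0, skin_ap_couch + b_eff, 0)
  Rinv <- rotation_is(-spec$tilt_deg)
  ring_offset <- as.numeric(Rinv %*% (c(0, 0, 0) - center_couch))
  tumor_offset <- as.numeric(Rinv %*% (spec$tumor_center_world - center_couch))
  if (spec$on_couch) {
    center <- center_couch
    skin_ap <- skin_ap_couch
    isocentre <- c(0, 0, 0)
    tilt_eff <- spec$tilt_deg
  } else {
    center <- c(0, spec$referral_center_ap, 0)
    skin_ap <- center[2] - b
    isocentre <- NULL
    tilt_eff <- 0
  }
  vox <- phantom_voxelize(spec, center, tilt_eff, ring_offset,
                          tumor_offset, spec$on_couch, spec$air_defects,
                          spec$seed)
  couch <- couch_geometry(
    isocentre = if (is.null(isocentre)) c(0, 0, 0) else isocentre,
    home_below_isocentre = spec$home_below_isocentre,
    membrane_below_isocentre = spec$membrane_below_isocentre)
  anatomy <- labelled_anatomy(vox$image, body = vox$body, bone = vox$bone,
                              target = vox$target,
                              extracorporeal_air = vox$air, oar = vox$oar,
                              couch = couch)
  lm_body <- ring_landmarks_body(spec, ring_offset)
  R <- rotation_is(tilt_eff)
  lm_world <- sweep(lm_body %*% t(R), 2, center, "+")
  landmarks <- data.frame(name = sprintf("bone_%02d", seq_len(nrow(lm_world))),
                          x = lm_world[, 1], y = lm_world[, 2],
                          z = lm_world[, 3])
  truth <- list(spec = spec, body_center = center, tilt_deg = tilt_eff,
                ring_offset = ring_offset, tumor_offset = tumor_offset,
                skin_point = c(0, skin_ap, 0),
                gelpad_thickness = spec$gelpad_thickness,
                membrane_bowing = spec$membrane_bowing,
                home = if (spec$on_couch) c(0, -spec$home_below_isocentre, 0) else NULL,
                isocentre = isocentre)
  structure(list(anatomy = anatomy, landmarks = landmarks, truth = truth,
                 gelpad = vox$gelpad),
            class = "hifu_phantom")
}

#' @export
print.hifu_phantom <- function(x, ...) {
  cat(sprintf("<hifu_phantom> tilt %g deg, %s\n", x$truth$tilt_deg,
              if (x$truth$spec$on_couch) "on couch" else "supine (referral)"))
  print(x$anatomy)
  invisible(x)
}

#' Generate a paired referral / treatment phantom
#'
#' The treatment phantom is tilted and on the couch (with gel-pad
#' compression, membrane bowing and any air defects); the referral phantom
#' is the same subject supine on a flat table. Both carry the same
#' body-frame structures and paired landmarks, and the exact affine linking
#' referral to treatment space is returned.
#'
#' @param spec a [phantom_spec()] (describes the treatment configuration).
#' @return list with `referral` and `treatment` (`hifu_phantom`s),
#'   `true_affine` (a `hifu_affine` mapping referral world coordinates to
#'   treatment world coordinates) and the paired landmark data.frames.
#' @export
make_referral_treatment_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "hifu_phantom_spec"))
  treatment <- generate_phantom(spec)
  ref_spec <- spec
  ref_spec$on_couch <- FALSE
  ref_spec$air_defects <- list()
  ref_spec$seed <- spec$seed + 1L
  referral <- generate_phantom(ref_spec)
  R <- rotation_is(spec$tilt_deg)
  true_affine <- affine_transform(
    R, treatment$truth$body_center -
      as.numeric(R %*% referral$truth$body_center))
  list(referral = referral, treatment = treatment,
       true_affine = true_affine,
       landmarks_referral = referral$landmarks,
       landmarks_treatment = treatment$landmarks)
}

#' Write a phantom to a directory
#'
#' Writes `image.nii.gz`, the mask files (`body`, `bone`, `target`,
#' `extracorporeal_air`, `oar`), `landmarks.csv` and `truth.json`.
#'
#' @param phantom a `hifu_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  an <- phantom$anatomy
  write_volume(an$image, file.path(dir, "image.nii.gz"))
  write_mask(an$body, file.path(dir, "body.nii.gz"))
  write_mask(an$bone, file.path(dir, "bone.nii.gz"))
  write_mask(an$target, file.path(dir, "target.nii.gz"))
  write_mask(an$extracorporeal_air, file.path(dir, "extracorporeal_air.nii.gz"))
  write_mask(an$oar, file.path(dir, "oar.nii.gz"))
  write_landmarks(phantom$landmarks, file.path(dir, "landmarks.csv"))
  truth <- phantom$truth
  truth$spec <- truth$spec[setdiff(names(truth$spec), character(0))]
  class(truth$spec) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
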