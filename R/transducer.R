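#' Couch geometry of the MRgHIFU system
#'
#' The transducer's home position lies a fixed distance below the magnetic
#' isocentre (140 mm for the Sonalleve V2), and the undeformed oil-bath
#' membrane lies 72.5 mm below the isocentre, so the calibrated
#' membrane-to-home distance is 67.5 mm.
#'
#' @param isocentre world position (mm) of the magnetic isocentre.
#' @param home_below_isocentre distance (mm) from isocentre down (-AP) to the
#'   transducer home position.
#' @param membrane_below_isocentre distance (mm) from isocentre down to the
#'   undeformed membrane.
#' @return object of class `hifu_couch` with derived field `membrane_to_home`.
#' @export
couch_geometry <- function(isocentre = c(0, 0, 0),
                           home_below_isocentre = 140,
                           membrane_below_isocentre = 72.5) {
  stopifnot(length(isocentre) == 3L, all(is.finite(isocentre)),
            home_below_isocentre > 0,
            membrane_below_isocentre > 0,
            home_below_isocentre > membrane_below_isocentre)
  structure(list(isocentre = as.numeric(isocentre),
                 home_below_isocentre = home_below_isocentre,
                 membrane_below_isocentre = membrane_below_isocentre,
                 membrane_to_home = home_below_isocentre - membrane_below_isocentre),
            class = "hifu_couch")
}

#' Home position of a couch
#'
#' @param couch a `hifu_couch`.
#' @return world point (mm) of the transducer home position.
#' @export
couch_home <- function(couch) {
  couch$isocentre - c(0, couch$home_below_isocentre, 0)
}

#' Phased-array transducer model
#'
#' Element centres are laid out deterministically on a spherical cap whose
#' curvature centre is the focus, so every element is exactly `focal_length`
#' from the focus and projects within `aperture_diameter / 2` of the beam
#' axis. The default layout is a Fermat (sunflower) spiral, giving
#' near-uniform area density over the cap; a concentric-ring layout is
#' available as an alternative.
#'
#' @param n_elements number of elements (default 256).
#' @param aperture_diameter aperture (mm, default 130).
#' @param focal_length focal length (mm, default 140).
#' @param frequency source frequency in MHz (metadata only).
#' @param layout `"fermat"` or `"rings"`.
#' @return object of class `hifu_transducer`; `element_offsets` is an
#'   `n_elements` x 3 matrix of offsets (mm) from the transducer apex, in a
#'   local frame whose +AP axis points from apex to focus.
#' @export
build_transducer <- function(n_elements = 256, aperture_diameter = 130,
                             focal_length = 140, frequency = 1.22,
                             layout = c("fermat", "rings")) {
  layout <- match.arg(layout)
  if (!(n_elements >= 1)) stop("n_elements must be >= 1")
  if (!(aperture_diameter > 0 && focal_length > 0))
    stop("aperture and focal length must be positive")
  if (aperture_diameter >= 2 * focal_length)
    stop("non-physical geometry: aperture must be < 2 * focal_length")
  theta_max <- asin(aperture_diameter / 2 / focal_length)
  if (n_elements == 1L) {
    theta <- 0
    phi <- 0
  } else if (layout == "fermat") {
    k <- seq_len(n_elements)
    # area-uniform in cos(theta); golden-angle azimuth
    u <- (k - 0.5) / n_elements
    theta <- acos(1 - u * (1 - cos(theta_max)))
    phi <- k * pi * (3 - sqrt(5))
  } else {
    n_rings <- max(1L, round(sqrt(n_elements / pi) * 2))
    ring <- ceiling(seq_len(n_elements) / (n_elements / n_rings))
    theta <- theta_max * ring / n_rings
    phi <- unlist(lapply(split(seq_len(n_elements), ring), function(ix)
      2 * pi * (seq_along(ix) - 1) / length(ix)), use.names = FALSE)
  }
  # direction from focus to element; apex direction is (0, -1, 0) from focus
  d <- cbind(sin(theta) * cos(phi), -cos(theta), sin(theta) * sin(phi))
  apex_from_focus <- c(0, -focal_length, 0)
  offsets <- sweep(focal_length * d, 2, apex_from_focus, "-")
  structure(list(n_elements = as.integer(n_elements),
                 aperture_diameter = aperture_diameter,
                 focal_length = focal_length,
                 frequency = frequency, layout = layout,
                 element_offsets = offsets),
            class = "hifu_transducer")
}

#' @export
print.hifu_transducer <- function(x, ...) {
  cat(sprintf("<hifu_transducer> %d elements, aperture %g mm, focal length %g mm (%s layout)\n",
              x$n_elements, x$aperture_diameter, x$focal_length, x$layout))
  invisible(x)
}

#' Mechanical pose limits of the transducer positioner
#'
#' Defaults are the Sonalleve V2 envelope: +/-72.5 mm left-right and
#' inferior-superior, 34 mm toward the patient (anterior) and 33 mm away,
#' tilt up to 10 degrees in 2.5 degree steps about the IS axis (left-right
#' tilt only). The translation step is 4 mm for whole-pelvis targets; 2 mm
#' is used for small tumour targets.
#'
#' @param lr,is_ symmetric translation limits (mm).
#' @param ap_toward_patient,ap_away anterior / posterior translation limits (mm).
#' @param tilt_max,tilt_step tilt envelope and step (degrees).
#' @param translation_step pose-grid translation step (mm).
#' @return object of class `hifu_limits`.
#' @export
pose_limits <- function(lr = 72.5, is_ = 72.5, ap_toward_patient = 34,
                        ap_away = 33, tilt_max = 10, tilt_step = 2.5,
                        translation_step = 4) {
  stopifnot(lr >= 0, is_ >= 0, ap_toward_patient >= 0, ap_away >= 0,
            tilt_max >= 0, tilt_step > 0, translation_step > 0)
  structure(list(lr = lr, is_ = is_, ap_toward_patient = ap_toward_patient,
                 ap_away = ap_away, tilt_max = tilt_max, tilt_step = tilt_step,
                 translation_step = translation_step),
            class = "hifu_limits")
}

#' One transducer pose
#'
#' @param translation `(lr, ap, is)` translation (mm) from the home position.
#' @param tilt_lr tilt (degrees) about the IS axis through the transducer apex.
#' @param limits optional `hifu_limits`; when given the pose is validated.
#' @return object of class `hifu_pose`.
#' @export
transducer_pose <- function(translation = c(0, 0, 0), tilt_lr = 0,
                            limits = NULL) {
  stopifnot(length(translation) == 3L, all(is.finite(translation)),
            is.finite(tilt_lr))
  p <- structure(list(translation = as.numeric(translation),
                      tilt_lr = as.numeric(tilt_lr)),
                 class = "hifu_pose")
  if (!is.null(limits) && !pose_within_limits(p, limits))
    stop("pose outside mechanical limits")
  p
}

pose_within_limits <- function(pose, limits, tol = 1e-9) {
  t <- pose$translation
  abs(t[1]) <= limits$lr + tol &&
    t[2] <= limits$ap_toward_patient + tol && -t[2] <= limits$ap_away + tol &&
    abs(t[3]) <= limits$is_ + tol &&
    abs(pose$tilt_lr) <= limits$tilt_max + tol
}

# Rotation about the IS (z) axis by `deg` degrees, acting on (LR, AP, IS).
rotation_is <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' Focus position and beam axis for a pose
#'
#' The transducer apex sits at `home + translation`; at zero tilt the beam
#' axis is +AP and the focus lies `focal_length` above the apex (so the zero
#' pose focuses at the magnetic isocentre). Tilt rotates the beam axis about
#' the IS axis through the apex.
#'
#' @param pose a `hifu_pose`.
#' @param couch a `hifu_couch`.
#' @param focal_length focal length (mm).
#' @param limits optional `hifu_limits` for validation.
#' @return list with `focus`, `axis` (unit vector) and `apex`, in world mm.
#' @export
pose_to_focus <- function(pose, couch, focal_length = 140, limits = NULL) {
  if (!is.null(limits) && !pose_within_limits(pose, limits))
    stop("pose outside mechanical limits")
  apex <- couch_home(couch) + pose$translation
  R <- rotation_is(pose$tilt_lr)
  axis <- as.numeric(R %*% c(0, 1, 0))
  list(focus = apex + focal_length * axis, axis = axis, apex = apex)
}

grid_values <- function(lo, hi, step) {
  if (lo > hi) return(numeric(0))
  v <- seq(ceiling(lo / step - 1e-9) * step, hi + 1e-9, by = step)
  v <- v[v <= hi + 1e-9]
  # non-empty interval containing no step multiple: fall back to its midpoint
  if (length(v) == 0L) v <- (lo + hi) / 2
  v
}

#' Enumerate the exhaustive pose grid
#'
#' Builds the regular pose grid swept by the coverage engine: LR and IS
#' translations are clipped to the intersection of the device limits and the
#' supplied search bounds (the restriction of the search to the target's
#' left-right and inferior-superior extents); AP spans its full device range;
#' tilt runs from `-tilt_max` to `+tilt_max` in `tilt_step` steps. Ordering
#' is deterministic: LR, then IS, then AP, then tilt, each ascending.
#'
#' @param limits a `hifu_limits`.
#' @param search_bounds optional list with elements `lr` and `is_`, each a
#'   length-2 interval (mm, translations from home). `NULL` means the full
#'   device range.
#' @return data.frame with columns `lr`, `is_`, `ap`, `tilt`, one row per pose.
#' @export
enumerate_poses <- function(limits, search_bounds = NULL) {
  clip <- function(device, bounds) {
    if (is.null(bounds)) return(device)
    c(max(device[1], bounds[1]), min(device[2], bounds[2]))
  }
  lr_iv <- clip(c(-limits$lr, limits$lr), search_bounds$lr)
  is_iv <- clip(c(-limits$is_, limits$is_), search_bounds$is_)
  if (lr_iv[1] > lr_iv[2] || is_iv[1] > is_iv[2]) {
    warning("search bounds do not intersect the device limits; no poses")
    return(data.frame(lr = numeric(0), is_ = numeric(0),
                      ap = numeric(0), tilt = numeric(0)))
  }
  lr <- grid_values(lr_iv[1], lr_iv[2], limits$translation_step)
  is_ <- grid_values(is_iv[1], is_iv[2], limits$translation_step)
  ap <- grid_values(-limits$ap_away, limits$ap_toward_patient,
                    limits$translation_step)
  tilt <- if (limits$tilt_max == 0) 0 else
    seq(-limits$tilt_max, limits$tilt_max, by = limits$tilt_step)
  g <- expand.grid(tilt = tilt, ap = ap, is_ = is_, lr = lr,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(lr = g$lr, is_ = g$is_, ap = g$ap, tilt = g$tilt)
}

#' Sample the discretized acoustic beam for one pose
#'
#' The beam is represented as one ray per element, from the element centre to
#' the focus. Each ray is discretized into regularly spaced points starting
#' at the element (inclusive) and ending one step short of the focus
#' (exclusive: the focus lies inside the target). Since every element lies on
#' a sphere of radius `focal_length` about the focus, each ray has exactly
#' `floor(focal_length / sample_spacing)` points.
#'
#' @param pose a `hifu_pose`.
#' @param transducer a `hifu_transducer`.
#' @param couch a `hifu_couch`.
#' @param sample_spacing point spacing along each ray (mm, default 0.2).
#' @return matrix of world points (mm) with attributes `ray` (element index
#'   per point) and `points_per_ray`.
#' @export
trace_beam <- function(pose, transducer, couch, sample_spacing = 0.2) {
  fa <- pose_to_focus(pose, couch, transducer$focal_length)
  R <- rotation_is(pose$tilt_lr)
  elements <- sweep(transducer$element_offsets %*% t(R), 2, fa$apex, "+")
  n_pts <- floor(transducer$focal_length / sample_spacing)
  dirs <- sweep(-elements, 2, fa$focus, "+") / transducer$focal_length
  s <- sample_spacing * (seq_len(n_pts) - 1)
  n_el <- nrow(elements)
  # points for ray i occupy rows ((i-1)*n_pts + 1) : (i*n_pts)
  pts <- matrix(0, n_el * n_pts, 3)
  for (ax in 1:3)
    pts[, ax] <- rep(elements[, ax], each = n_pts) +
      rep(dirs[, ax], each = n_pts) * s
  attr(pts, "ray") <- rep(seq_len(n_el), each = n_pts)
  attr(pts, "points_per_ray") <- n_pts
  pts
}

#' Ellipsoidal treatment cell
#'
#' The idealized volume ablated by one sonication: an ellipsoid with
#' transverse diameter `diameter` and long axis `length`, centred at the
#' focus with its long axis along the beam axis (default 8 x 21.84 mm).
#'
#' @param diameter transverse diameter (mm).
#' @param length long-axis length (mm).
#' @param center focus position (world mm).
#' @param axis unit beam-axis vector.
#' @return object of class `hifu_cell`.
#' @export
treatment_cell <- function(diameter = 8, length = 21.84,
                           center = c(0, 0, 0), axis = c(0, 1, 0)) {
  stopifnot(diameter > 0, length > 0)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(diameter = diameter, length = length,
                 center = as.numeric(center), axis = axis),
            class = "hifu_cell")
}

#' Point-in-treatment-cell test
#'
#' True iff the point lies inside or on the cell ellipsoid:
#' `(r_perp / (d/2))^2 + (w / (L/2))^2 <= 1`, where `w` is the coordinate
#' along the cell axis and `r_perp` the transverse distance.
#'
#' @param point length-3 world point or n x 3 matrix.
#' @param cell a `hifu_cell`.
#' @return logical, one value per point.
#' @export
point_in_cell <- function(point, cell) {
  p <- if (is.matrix(point)) point else matrix(point, 1, 3)
  d <- sweep(p, 2, cell$center, "-")
  w <- d %*% cell$axis
  r2 <- rowSums(d^2) - w^2
  r2[r2 < 0] <- 0
  a <- cell$diameter / 2
  c_ <- cell$length / 2
  val <- r2 / a^2 + (w / c_)^2
  as.vector(val <= 1)
}

#' Read a device geometry YAML configuration
#'
#' Recognised keys (all optional, defaults are the Sonalleve V2 values):
#' `n_elements`, `aperture_mm`, `focal_length_mm`, `frequency_mhz`,
#' `cell_diameter_mm`, `cell_length_mm`,
#' `limits: {lr_mm, is_mm, ap_toward_mm, ap_away_mm, tilt_max_deg,
#' tilt_step_deg, translation_step_mm}`, and
#' `couch: {isocentre, home_below_isocentre_mm, membrane_below_isocentre_mm}`.
#'
#' @param path YAML file path.
#' @return list with elements `transducer`, `limits`, `cell`, `couch`.
#' @export
read_device_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  pick <- function(x, default) if (is.null(x)) default else x
  transducer <- build_transducer(
    n_elements = pick(cfg$n_elements, 256),
    aperture_diameter = pick(cfg$aperture_mm, 130),
    focal_length = pick(cfg$focal_length_mm, 140),
    frequency = pick(cfg$frequency_mhz, 1.22))
  lim <- cfg$limits
  limits <- pose_limits(
    lr = pick(lim$lr_mm, 72.5), is_ = pick(lim$is_mm, 72.5),
    ap_toward_patient = pick(lim$ap_toward_mm, 34),
    ap_away = pick(lim$ap_away_mm, 33),
    tilt_max = pick(lim$tilt_max_deg, 10),
    tilt_step = pick(lim$tilt_step_deg, 2.5),
    translation_step = pick(lim$translation_step_mm, 4))
  cell <- treatment_cell(diameter = pick(cfg$cell_diameter_mm, 8),
                         length = pick(cfg$cell_length_mm, 21.84))
  cch <- cfg$couch
  couch <- couch_geometry(
    isocentre = pick(cch$isocentre, c(0, 0, 0)),
    home_below_isocentre = pick(cch$home_below_isocentre_mm, 140),
    membrane_below_isocentre = pick(cch$membrane_below_isocentre_mm, 72.5))
  list(transducer = transducer, limits = limits, cell = cell, couch = couch)
}
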