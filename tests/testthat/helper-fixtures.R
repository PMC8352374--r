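# Shared fixtures and independent reference (oracle) implementations.
# The oracles deliberately re-derive the beam sampling, nearest-voxel
# mapping, obstruction test and cell test with plain loops, sharing only
# the deterministic element layout with the package.

mini_phantom <- local({
  cache <- new.env()
  function(...) {
    key <- paste(deparse(list(...)), collapse = "")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_phantom(phantom_spec(profile = "mini", ...))
    cache[[key]]
  }
})

# Minimal hand-built anatomy: empty masks on a given grid, optionally with
# obstruction voxels / target voxels set.
blank_anatomy <- function(dim, spacing, origin, bone = NULL, target = NULL,
                          air = NULL, oar = NULL, couch = couch_geometry()) {
  img <- voxel_volume(array(0, dim), spacing, origin)
  mk <- function(ix) {
    a <- array(FALSE, dim)
    if (!is.null(ix)) a[ix] <- TRUE
    label_mask(a, geometry = img)
  }
  body <- label_mask(array(TRUE, dim), geometry = img)
  labelled_anatomy(img, body = body, bone = mk(bone), target = mk(target),
                   extracorporeal_air = mk(air), oar = mk(oar), couch = couch)
}

# Rotation about IS axis (z), duplicated here so oracle geometry does not
# depend on package internals.
rot_is_deg <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Naive per-ray clearance oracle: walks each ray element -> focus at a given
# (possibly much finer) step and looks up voxels one point at a time.
oracle_beam_clear <- function(pose, transducer, anatomy, step = 0.2,
                              endpoint_rule = c("package", "fine")) {
  endpoint_rule <- match.arg(endpoint_rule)
  couch <- anatomy$couch
  home <- couch$isocentre - c(0, couch$home_below_isocentre, 0)
  apex <- home + pose$translation
  R <- rot_is_deg(pose$tilt_lr)
  axis <- as.numeric(R %*% c(0, 1, 0))
  focus <- apex + transducer$focal_length * axis
  elements <- sweep(transducer$element_offsets %*% t(R), 2, apex, "+")
  obst <- anatomy$bone$data | anatomy$extracorporeal_air$data | anatomy$oar$data
  dm <- dim(obst)
  sp <- anatomy$image$spacing
  orig <- anatomy$image$origin
  for (e in seq_len(nrow(elements))) {
    L <- sqrt(sum((focus - elements[e, ])^2))
    u <- (focus - elements[e, ]) / L
    ss <- if (endpoint_rule == "package") step * (seq_len(floor(L / step)) - 1)
          else seq(0, L - 1e-9, by = step)
    for (s in ss) {
      p <- elements[e, ] + s * u
      ijk <- floor((p - orig) / sp + 0.5) + 1
      if (any(ijk < 1) || any(ijk > dm)) next
      if (obst[ijk[1], ijk[2], ijk[3]]) return(FALSE)
    }
  }
  TRUE
}

# Naive full-sweep oracle: plain-R re-implementation of the exhaustive pose
# sweep; returns the covered logical flags over the target voxels (in
# which(target) order) and the per-pose clear flags.
oracle_coverage <- function(anatomy, transducer, limits, search_bounds,
                            cell = treatment_cell(), step = 0.2) {
  couch <- anatomy$couch
  home <- couch$isocentre - c(0, couch$home_below_isocentre, 0)
  poses <- enumerate_poses(limits, search_bounds)
  lin <- which(anatomy$target$data)
  idx <- arrayInd(lin, dim(anatomy$target$data))
  sp <- anatomy$image$spacing
  orig <- anatomy$image$origin
  pts <- sweep(sweep(idx - 1, 2, sp, "*"), 2, orig, "+")
  covered <- logical(nrow(pts))
  clear <- logical(nrow(poses))
  a2 <- (cell$diameter / 2)^2
  c2 <- (cell$length / 2)^2
  for (p in seq_len(nrow(poses))) {
    pose <- transducer_pose(c(poses$lr[p], poses$ap[p], poses$is_[p]),
                            poses$tilt[p])
    ok <- oracle_beam_clear(pose, transducer, anatomy, step)
    clear[p] <- ok
    if (!ok) next
    R <- rot_is_deg(pose$tilt_lr)
    axis <- as.numeric(R %*% c(0, 1, 0))
    focus <- home + pose$translation + transducer$focal_length * axis
    for (g in seq_len(nrow(pts))) {
      if (covered[g]) next
      d <- pts[g, ] - focus
      w <- sum(d * axis)
      r2 <- max(sum(d^2) - w^2, 0)
      if (r2 / a2 + w^2 / c2 <= 1) covered[g] <- TRUE
    }
  }
  list(covered = covered, clear = clear, lin = lin)
}
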