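#' Combined acoustic-obstruction mask
#'
#' Bone, extracorporeal air and organs at risk are treated identically for
#' beam clearance: any ray crossing any of them invalidates a pose.
#'
#' @param anatomy a `hifu_anatomy`.
#' @return 3D logical array on the anatomy grid.
#' @export
obstruction_array <- function(anatomy) {
  anatomy$bone$data | anatomy$extracorporeal_air$data | anatomy$oar$data
}

# Linear (column-major) indices for an n x 3 integer index matrix; NA outside.
linear_index <- function(idx, dm) {
  inside <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
    idx[, 2] >= 1 & idx[, 2] <= dm[2] &
    idx[, 3] >= 1 & idx[, 3] <= dm[3]
  lin <- (idx[, 1] - 1) + (idx[, 2] - 1) * dm[1] +
    (idx[, 3] - 1) * dm[1] * dm[2] + 1
  lin[!inside] <- NA_integer_
  lin
}

#' Test whether the full beam clears all obstructions at a pose
#'
#' Every sampled point of every ray is mapped to its nearest voxel; the pose
#' is clear iff no point lands on an obstruction voxel (bone, extracorporeal
#' air or organ at risk). Points outside the image bounds are treated as
#' unobstructed (oil bath / couch region below the imaged volume).
#'
#' @param pose a `hifu_pose`.
#' @param transducer a `hifu_transducer`.
#' @param anatomy a `hifu_anatomy` (its couch situates the beam).
#' @param sample_spacing ray sampling step (mm).
#' @param max_blocked_fraction fraction of rays allowed to be blocked while
#'   still calling the pose clear (default 0: any blocked ray invalidates the
#'   pose, the strict rule).
#' @return logical scalar.
#' @export
is_beam_clear <- function(pose, transducer, anatomy, sample_spacing = 0.2,
                          max_blocked_fraction = 0) {
  pts <- trace_beam(pose, transducer, anatomy$couch, sample_spacing)
  obst <- obstruction_array(anatomy)
  geom <- anatomy$image
  frac <- sweep(sweep(pts, 2, geom$origin, "-"), 2, geom$spacing, "/")
  idx <- round_half_up(frac) + 1
  lin <- linear_index(idx, dim(obst))
  hit <- !is.na(lin) & obst[ifelse(is.na(lin), 1L, lin)]
  if (max_blocked_fraction <= 0) return(!any(hit))
  blocked_rays <- unique(attr(pts, "ray")[hit])
  length(blocked_rays) / transducer$n_elements <= max_blocked_fraction
}

#' Target grid: one point per target voxel
#'
#' @param target a `hifu_mask`.
#' @return object of class `hifu_grid`: world points (voxel centres) of all
#'   target voxels, their covered flags, the per-point voxel volume (mm^3)
#'   and the linear indices into the target array.
#' @export
target_grid <- function(target) {
  stopifnot(inherits(target, "hifu_mask"))
  lin <- which(target$data)
  if (length(lin) == 0L) stop("target mask is empty")
  idx <- arrayInd(lin, dim(target$data))
  structure(list(points = voxel_to_world(idx, target),
                 covered = logical(length(lin)),
                 voxel_volume = prod(target$spacing),
                 lin = lin, dim = dim(target$data)),
            class = "hifu_grid")
}

#' Mark target grid points covered by the treatment cell at one pose
#'
#' Sets the covered flag of every grid point lying inside the cell ellipsoid
#' centred at this pose's focus and aligned with its beam axis. Flags are
#' never unset (the accumulation is a pure union over poses).
#'
#' @param pose a `hifu_pose` (must already have passed [is_beam_clear()]).
#' @param grid a `hifu_grid`.
#' @param cell a `hifu_cell` (its center/axis are replaced by the pose's).
#' @param couch a `hifu_couch`.
#' @param focal_length transducer focal length (mm).
#' @return the updated `hifu_grid`.
#' @export
accumulate_cell <- function(pose, grid, cell = treatment_cell(),
                            couch = couch_geometry(), focal_length = 140) {
  fa <- pose_to_focus(pose, couch, focal_length)
  posed <- treatment_cell(cell$diameter, cell$length, fa$focus, fa$axis)
  todo <- !grid$covered
  if (any(todo))
    grid$covered[todo] <- point_in_cell(grid$points[todo, , drop = FALSE], posed)
  grid
}

#' Exhaustive pose sweep and target volume coverage
#'
#' The core planning computation: enumerates the pose grid, tests each pose's
#' beam for obstruction, and for every clear pose marks all target grid
#' points inside the treatment cell as covered. The covered count times the
#' voxel volume gives the covered volume CV; `tvc_pat = 100 * CV / TV`.
#'
#' @param anatomy a `hifu_anatomy` with a non-empty target.
#' @param transducer a `hifu_transducer`.
#' @param limits a `hifu_limits`.
#' @param search_bounds optional LR/IS search bounds (see [enumerate_poses()]);
#'   defaults to the target's LR/IS extents ([target_search_bounds()]).
#' @param cell a `hifu_cell`.
#' @param sample_spacing ray sampling step (mm).
#' @param max_blocked_fraction see [is_beam_clear()].
#' @return object of class `hifu_coverage`: the grid, `covered_volume` (CV,
#'   mm^3), `total_target_volume` (TV, mm^3), `tvc_pat` (percent),
#'   `n_poses_tested`, `n_poses_clear`, and `covered_mask` (a `hifu_mask` of
#'   covered target voxels).
#' @export
compute_coverage <- function(anatomy, transducer = build_transducer(),
                             limits = pose_limits(), search_bounds = NULL,
                             cell = treatment_cell(), sample_spacing = 0.2,
                             max_blocked_fraction = 0) {
  if (sum(anatomy$target$data) == 0L) stop("target mask is empty")
  couch <- anatomy$couch
  home <- couch_home(couch)
  if (is.null(search_bounds))
    search_bounds <- target_search_bounds(anatomy$target, home)
  poses <- enumerate_poses(limits, search_bounds)
  grid <- target_grid(anatomy$target)
  obst <- obstruction_array(anatomy)
  geom <- anatomy$image
  dm <- dim(obst)
  n_clear <- 0L

  clear <- logical(nrow(poses))
  if (nrow(poses) > 0L) {
    # Per-tilt base clouds at zero translation, in fractional (0-based)
    # voxel coordinates: a translation then only shifts them by
    # translation / spacing, so each pose costs one pass over the cloud.
    tilts <- sort(unique(poses$tilt))
    base_vox <- lapply(tilts, function(tl) {
      pts <- trace_beam(transducer_pose(c(0, 0, 0), tl), transducer, couch,
                        sample_spacing)
      sweep(sweep(pts, 2, geom$origin, "-"), 2, geom$spacing, "/")
    })
    home <- couch_home(couch)
    foci <- matrix(0, nrow(poses), 3)
    axes <- matrix(0, nrow(poses), 3)
    for (t in seq_along(tilts)) {
      sel <- poses$tilt == tilts[t]
      ax <- as.numeric(rotation_is(tilts[t]) %*% c(0, 1, 0))
      axes[sel, ] <- matrix(ax, sum(sel), 3, byrow = TRUE)
      apex <- cbind(home[1] + poses$lr[sel], home[2] + poses$ap[sel],
                    home[3] + poses$is_[sel])
      foci[sel, ] <- sweep(apex, 2, transducer$focal_length * ax, "+")
    }
    trans_vox <- cbind(poses$lr / geom$spacing[1],
                       poses$ap / geom$spacing[2],
                       poses$is_ / geom$spacing[3])
    res <- .sweep_poses(base_vox, match(poses$tilt, tilts), trans_vox,
                        as.logical(obst), dim(obst), grid$points, foci, axes,
                        (cell$diameter / 2)^2, (cell$length / 2)^2)
    grid$covered <- res$covered
    clear <- res$clear
    n_clear <- res$n_clear
  }

  cv <- sum(grid$covered) * grid$voxel_volume
  tv_tot <- length(grid$covered) * grid$voxel_volume
  covered <- array(FALSE, dm)
  covered[grid$lin[grid$covered]] <- TRUE
  structure(list(grid = grid,
                 covered_volume = cv,
                 total_target_volume = tv_tot,
                 tvc_pat = tvc_pat(cv, tv_tot),
                 n_poses_tested = nrow(poses),
                 n_poses_clear = n_clear,
                 covered_mask = label_mask(covered, geometry = geom),
                 search_bounds = search_bounds),
            class = "hifu_coverage")
}

#' @export
print.hifu_coverage <- function(x, ...) {
  cat(sprintf(paste0("<hifu_coverage> TVC = %.1f%% (CV %.0f / TV %.0f mm^3)\n",
                     "  %d / %d poses clear\n"),
              x$tvc_pat, x$covered_volume, x$total_target_volume,
              x$n_poses_clear, x$n_poses_tested))
  invisible(x)
}

#' Percentage target volume covered (per-dataset)
#'
#' `tvc_pat = 100 * CV / TV`, the covered fraction of the target in one
#' dataset.
#'
#' @param cv covered target volume (mm^3).
#' @param tv total target volume (mm^3), must be > 0.
#' @return percent in \[0, 100\].
#' @export
tvc_pat <- function(cv, tv) {
  if (!(tv > 0)) stop("total target volume must be > 0")
  if (cv < 0 || cv > tv + 1e-9) stop("CV must lie in [0, TV]")
  100 * cv / tv
}

#' Referral-vs-treatment covered-volume agreement
#'
#' `tvc_vol = 100 * |covered_regref  covered_treat| / |covered_treat|`: the
#' treatment-dataset covered set becomes the target for the registered
#' referral dataset, measuring how much of the achievable coverage the
#' referral prediction found. Both sets must be indexed on the shared
#' treatment voxel grid.
#'
#' @param covered_regref,covered_treat `hifu_mask` objects or 3D logical
#'   arrays on the same grid; `covered_treat` must be non-empty.
#' @return percent in \[0, 100\].
#' @export
tvc_vol <- function(covered_regref, covered_treat) {
  a <- if (inherits(covered_regref, "hifu_mask")) covered_regref$data else covered_regref
  b <- if (inherits(covered_treat, "hifu_mask")) covered_treat$data else covered_treat
  if (!identical(dim(a), dim(b)))
    stop("covered sets must share one voxel grid")
  nb <- sum(b)
  if (nb == 0L) stop("treatment covered set is empty")
  100 * sum(a & b) / nb
}

#' Search bounds from the target's LR/IS extents
#'
#' Restricts transducer LR and IS translation to the target's bounding box
#' (plus an optional margin), expressed as translations from the home
#' position. AP is left unrestricted (full device range).
#'
#' @param target non-empty `hifu_mask`.
#' @param home transducer home position (world mm).
#' @param margin widening of the bounds per side (mm).
#' @return list with `lr` and `is_` intervals (mm).
#' @export
target_search_bounds <- function(target, home, margin = 0) {
  lin <- which(target$data)
  if (length(lin) == 0L) stop("target mask is empty")
  idx <- arrayInd(lin, dim(target$data))
  w <- voxel_to_world(idx, target)
  list(lr = c(min(w[, 1]) - margin, max(w[, 1]) + margin) - home[1],
       is_ = c(min(w[, 3]) - margin, max(w[, 3]) + margin) - home[3])
}
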