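#' Gel-pad / membrane deformation parameters
#'
#' The compressed gel-pad thickness and membrane bowing used to estimate the
#' transducer home position under a registered-referral dataset. Defaults
#' are the volunteer-cohort averages (15 mm nominal pads compressed to
#' 9.8 mm; 10.0 mm bowing near the isocentre line).
#'
#' @param gelpad_thickness compressed gel-pad thickness t (mm, > 0).
#' @param membrane_bowing membrane bowing distance b (mm, >= 0).
#' @param nominal_gelpad nominal pad thickness (mm, metadata).
#' @return object of class `hifu_deformation`.
#' @export
deformation_params <- function(gelpad_thickness = 9.8, membrane_bowing = 10.0,
                               nominal_gelpad = 15) {
  stopifnot(gelpad_thickness > 0, membrane_bowing >= 0)
  structure(list(gelpad_thickness = gelpad_thickness,
                 membrane_bowing = membrane_bowing,
                 nominal_gelpad = nominal_gelpad),
            class = "hifu_deformation")
}

#' Skin point below the isocentre
#'
#' Draws a vertical (AP) line downward at the given LR/IS position and
#' returns the most posterior body-surface voxel centre on it — the point
#' where the line exits the skin toward the gel-pad. Optionally the skin
#' height is taken as the median over a square LR/IS neighbourhood.
#'
#' @param body a `hifu_mask`.
#' @param isocentre_lr_is length-2 `(LR, IS)` world coordinates (mm) of the
#'   vertical line.
#' @param neighborhood_mm side length of an optional LR/IS sampling
#'   neighbourhood (0 = single column, the default).
#' @return world point (mm) of the skin point.
#' @export
find_skin_point <- function(body, isocentre_lr_is, neighborhood_mm = 0) {
  dm <- dim(body$data)
  ic <- round_half_up((isocentre_lr_is[1] - body$origin[1]) / body$spacing[1]) + 1
  kc <- round_half_up((isocentre_lr_is[2] - body$origin[3]) / body$spacing[3]) + 1
  hi <- max(0, floor(neighborhood_mm / 2 / body$spacing[1]))
  hk <- max(0, floor(neighborhood_mm / 2 / body$spacing[3]))
  ii <- max(1, ic - hi):min(dm[1], ic + hi)
  kk <- max(1, kc - hk):min(dm[3], kc + hk)
  if (ic < 1 || ic > dm[1] || kc < 1 || kc > dm[3])
    stop("isocentre column lies outside the image")
  bottoms <- c()
  for (k in kk) for (i in ii) {
    col <- which(body$data[i, , k])
    if (length(col) > 0L) bottoms <- c(bottoms, col[1])
  }
  if (length(bottoms) == 0L)
    stop("the vertical line at the isocentre does not intersect the body")
  j <- stats::median(bottoms)
  c(body$origin[1] + (ic - 1) * body$spacing[1],
    body$origin[2] + (j - 1) * body$spacing[2],
    body$origin[3] + (kc - 1) * body$spacing[3])
}

#' Estimate the transducer home position from the skin point
#'
#' Walks the deformation chain downward from the skin point: down through
#' the compressed gel-pad (thickness t) to the bowed membrane, up by the
#' bowing distance b to the undeformed membrane plane, then down the
#' calibrated membrane-to-home distance:
#' `home_AP = skin_AP - t + b - membrane_to_home`.
#' LR/IS of the home position are those of the isocentre column.
#'
#' @param skin_point world point from [find_skin_point()].
#' @param params a [deformation_params()].
#' @param couch a `hifu_couch` (provides `membrane_to_home`).
#' @return world point (mm) of the estimated home position.
#' @export
estimate_home_position <- function(skin_point, params = deformation_params(),
                                   couch = couch_geometry()) {
  stopifnot(length(skin_point) == 3L, all(is.finite(skin_point)))
  c(skin_point[1],
    skin_point[2] - params$gelpad_thickness + params$membrane_bowing -
      couch$membrane_to_home,
    skin_point[3])
}

#' Isocentre implied by a home position
#'
#' The home position always lies a fixed distance below the magnetic
#' isocentre, so `isocentre = home + (0, home_below_isocentre, 0)`.
#'
#' @param home world point (mm).
#' @param couch a `hifu_couch`.
#' @return world point (mm).
#' @export
isocentre_from_home <- function(home, couch = couch_geometry()) {
  home + c(0, couch$home_below_isocentre, 0)
}

#' Couch re-anchored at an estimated home position
#'
#' Convenience for the registered-referral workflow: returns a couch whose
#' isocentre is implied by the given home position, keeping the template's
#' calibrated distances.
#'
#' @param home world point (mm).
#' @param couch template `hifu_couch`.
#' @return a `hifu_couch`.
#' @export
couch_at_home <- function(home, couch = couch_geometry()) {
  couch_geometry(isocentre = isocentre_from_home(home, couch),
                 home_below_isocentre = couch$home_below_isocentre,
                 membrane_below_isocentre = couch$membrane_below_isocentre)
}
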