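mask_array <- function(x) if (inherits(x, c("hifu_mask", "hifu_volume"))) x$data else x

#' Dice similarity coefficient
#'
#' `DSC = 2|A  B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b `hifu_mask` objects or logical arrays on a shared grid.
#' @return coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  A <- mask_array(a); B <- mask_array(b)
  if (!identical(dim(A), dim(B))) stop("masks must share one voxel grid")
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) return(1)
  2 * sum(A & B) / (na + nb)
}

# Boundary voxels: mask voxels with >= 1 face-adjacent non-mask neighbour
# (out-of-array counts as non-mask). 2D (4-connectivity) per slice or 3D
# (6-connectivity).
boundary_indices_2d <- function(sl) {
  dm <- dim(sl)
  pad <- matrix(FALSE, dm[1] + 2, dm[2] + 2)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1)] <- sl
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1)]
  nb <- pad[1:dm[1], 2:(dm[2] + 1)] & pad[3:(dm[1] + 2), 2:(dm[2] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2]] & pad[2:(dm[1] + 1), 3:(dm[2] + 2)]
  which(core & !nb, arr.ind = TRUE)
}

min_dist_to_set <- function(P, Q) {
  # per-row min distance from points P to set Q (both n x d, mm)
  apply(P, 1, function(p) sqrt(min(colSums((t(Q) - p)^2))))
}

#' Mean contour-to-contour distance
#'
#' Symmetric mean surface distance between two masks: boundary points of
#' each mask are matched to the nearest boundary point of the other, and all
#' point-to-nearest distances (both directions) are averaged. The default
#' `slicewise2d` mode extracts 2D contours per axial slice with in-plane
#' distances (the slice-based validation convention); `mode = "3d"` uses 3D
#' boundary voxels and 3D distances. A one-directional variant (`a` to `b`
#' only) is available via `symmetric = FALSE`.
#'
#' @param a,b non-empty `hifu_mask` objects on a shared grid.
#' @param mode `"slicewise2d"` (default) or `"3d"`.
#' @param symmetric average both directions (default) or `a` to `b` only.
#' @return mean distance in mm.
#' @export
mean_contour_distance <- function(a, b, mode = c("slicewise2d", "3d"),
                                  symmetric = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "hifu_mask"), inherits(b, "hifu_mask"))
  if (!same_geometry(a, b)) stop("masks must share one voxel grid")
  if (sum(a$data) == 0L || sum(b$data) == 0L)
    stop("contour distance requires two non-empty masks")
  sp <- a$spacing
  d_ab <- c(); d_ba <- c()
  if (mode == "slicewise2d") {
    for (k in seq_len(dim(a$data)[3])) {
      ba <- boundary_indices_2d(a$data[, , k])
      bb <- boundary_indices_2d(b$data[, , k])
      if (nrow(ba) == 0L || nrow(bb) == 0L) next
      Pa <- sweep(ba - 1, 2, sp[1:2], "*")
      Pb <- sweep(bb - 1, 2, sp[1:2], "*")
      d_ab <- c(d_ab, min_dist_to_set(Pa, Pb))
      if (symmetric) d_ba <- c(d_ba, min_dist_to_set(Pb, Pa))
    }
    if (length(d_ab) == 0L)
      stop("no slice contains contours of both masks")
  } else {
    bnd3 <- function(m) {
      dm <- dim(m)
      pad <- array(FALSE, dm + 2)
      pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
      inner <- pad[1:dm[1] + 1, 1:dm[2] + 1, 1:dm[3] + 1]
      nb <- pad[1:dm[1], 1:dm[2] + 1, 1:dm[3] + 1] &
        pad[1:dm[1] + 2, 1:dm[2] + 1, 1:dm[3] + 1] &
        pad[1:dm[1] + 1, 1:dm[2], 1:dm[3] + 1] &
        pad[1:dm[1] + 1, 1:dm[2] + 2, 1:dm[3] + 1] &
        pad[1:dm[1] + 1, 1:dm[2] + 1, 1:dm[3]] &
        pad[1:dm[1] + 1, 1:dm[2] + 1, 1:dm[3] + 2]
      which(inner & !nb, arr.ind = TRUE)
    }
    Pa <- sweep(bnd3(a$data) - 1, 2, sp, "*")
    Pb <- sweep(bnd3(b$data) - 1, 2, sp, "*")
    d_ab <- min_dist_to_set(Pa, Pb)
    if (symmetric) d_ba <- min_dist_to_set(Pb, Pa)
  }
  mean(c(d_ab, d_ba))
}

#' Descriptive statistics (mean, SD, range)
#'
#' Summary cells of the cohort tables: arithmetic mean, sample standard
#' deviation (n - 1 denominator; `NA` for a single value), minimum and
#' maximum. Missing values are dropped.
#'
#' @param values numeric vector with at least one finite value.
#' @return list with `mean`, `sd`, `min`, `max`, `n`.
#' @export
descriptive_stats <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) stop("no finite values")
  list(mean = mean(v),
       sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
       min = min(v), max = max(v), n = length(v))
}
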