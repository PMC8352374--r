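#' Segmentation parameters
#'
#' @param closing_radius morphological closing radius in voxels (in-plane,
#'   applied slice-wise in axial planes).
#' @param min_component_volume smallest connected component (mm^3) considered
#'   a body candidate.
#' @param air_band_height height of the band (mm) above/below the
#'   body/gel-pad interface searched for coupling air.
#' @param n_bins histogram bins for Otsu thresholding.
#' @return object of class `hifu_seg_params`.
#' @export
segmentation_params <- function(closing_radius = 2,
                                min_component_volume = 1e4,
                                air_band_height = 10,
                                n_bins = 256) {
  stopifnot(closing_radius >= 0, min_component_volume >= 0,
            air_band_height >= 0, n_bins >= 2)
  structure(list(closing_radius = closing_radius,
                 min_component_volume = min_component_volume,
                 air_band_height = air_band_height,
                 n_bins = as.integer(n_bins)),
            class = "hifu_seg_params")
}

# Otsu threshold on a numeric vector (values normalized internally).
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) <= 0) stop("cannot threshold a constant image")
  norm <- (values - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(norm, nrow = 1)),
                      range = c(0, 1), levels = n_bins)
  rng[1] + th * diff(rng)
}

# Otsu effectiveness: between-class variance at the threshold over total
# variance. Near 1 for well-separated bimodal data, ~0.64 for a single
# Gaussian; used to decide whether a histogram supports a second split.
otsu_effectiveness <- function(values, threshold) {
  lo <- values <= threshold
  p <- mean(lo)
  if (p <= 0 || p >= 1) return(0)
  vb <- p * (1 - p) * (mean(values[!lo]) - mean(values[lo]))^2
  vb / stats::var(values)
}

# 3D connected-component labels (6-connectivity) for a logical array.
# Foreground voxels become graph vertices; edges join face-adjacent pairs.
connected_components_3d <- function(mask) {
  dm <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list(labels = integer(0), voxels = fg))
  id <- integer(prod(dm))
  id[fg] <- seq_along(fg)
  edges <- list()
  strides <- c(1L, dm[1], dm[1] * dm[2])
  idx <- arrayInd(fg, dm)
  for (ax in 1:3) {
    ok <- idx[, ax] < dm[ax]
    nb <- fg[ok] + strides[ax]
    both <- mask[nb]
    if (any(both))
      edges[[ax]] <- rbind(id[fg[ok][both]], id[nb[both]])
  }
  e <- do.call(cbind, edges)
  g <- igraph::make_graph(edges = as.vector(e), n = length(fg),
                          directed = FALSE)
  comp <- igraph::components(g)
  list(labels = comp$membership, voxels = fg, sizes = comp$csize)
}

#' Automatic body-outline segmentation
#'
#' Separates the body from surrounding extracorporeal air and from the
#' gel-pad: a first Otsu threshold on the full-volume histogram splits air
#' from tissue-like intensities; a second Otsu threshold restricted to the
#' foreground splits the gel-pad from the body. Connected-components
#' labelling keeps the largest body candidate, then slice-wise morphological
#' closing and hole filling (axial planes) produce a single filled outline.
#'
#' @param image a `hifu_volume` with bimodal-ish foreground/background
#'   intensities.
#' @param params a [segmentation_params()].
#' @return a `hifu_mask`.
#' @export
segment_body_outline <- function(image, params = segmentation_params()) {
  vals <- as.numeric(image$data)
  th1 <- otsu_threshold(vals, params$n_bins)
  if (otsu_effectiveness(vals, th1) < 0.8)
    stop("segmentation failed: no bimodal foreground/background separation")
  fg <- image$data > th1
  if (!any(fg)) stop("segmentation failed: no foreground above the Otsu threshold")
  # second split separates the gel-pad from the body; only applied when the
  # foreground histogram is genuinely bimodal (a supine dataset has no pad)
  th2 <- otsu_threshold(vals[fg], params$n_bins)
  if (otsu_effectiveness(vals[fg], th2) < 0.8) th2 <- th1
  cand <- image$data > th2
  cc <- connected_components_3d(cand)
  if (length(cc$voxels) == 0L)
    stop("segmentation failed: no body candidate component")
  vox_vol <- prod(image$spacing)
  big <- which(cc$sizes * vox_vol >= params$min_component_volume)
  if (length(big) == 0L)
    stop("segmentation failed: no component above min_component_volume (",
         params$min_component_volume, " mm^3)")
  keep <- big[which.max(cc$sizes[big])]
  body <- array(FALSE, dim(image$data))
  body[cc$voxels[cc$labels == keep]] <- TRUE
  # slice-wise closing + flood-fill of internal holes, axial (LR-AP) planes
  brush <- if (params$closing_radius > 0)
    EBImage::makeBrush(2 * params$closing_radius + 1, "disc") else NULL
  for (k in seq_len(dim(body)[3])) {
    sl <- body[, , k]
    if (!any(sl)) next
    if (!is.null(brush)) sl <- EBImage::closing(sl * 1, brush) > 0
    sl <- EBImage::fillHull(sl * 1) > 0
    body[, , k] <- sl
  }
  label_mask(body, geometry = image)
}

# AP index of the most posterior body voxel, per (LR, IS) column; NA where
# the column contains no body.
body_under_surface <- function(body) {
  dm <- dim(body)
  surf <- matrix(NA_integer_, dm[1], dm[3])
  ap <- seq_len(dm[2])
  for (k in seq_len(dm[3])) {
    sl <- body[, , k]
    has <- rowSums(sl) > 0
    if (!any(has)) next
    surf[has, k] <- apply(sl[has, , drop = FALSE], 1,
                          function(r) which(r)[1])
  }
  surf
}

#' Extracorporeal (coupling) air segmentation
#'
#' Finds air at the body/gel-pad interface that would obstruct acoustic
#' coupling: voxels below the first Otsu threshold, outside the body, lying
#' below the skin under-surface within `air_band_height` of it, in columns
#' that actually contain gel-pad material within the band (columns where the
#' body overhangs plain air, beyond the pad's lateral extent, are not part
#' of the coupling interface). Air pockets connected to the exterior and air
#' trapped at the interface are both included; low-intensity regions outside
#' the band (e.g. anterior to the pelvis) are not.
#'
#' @param image a `hifu_volume`.
#' @param body the body `hifu_mask` (e.g. from [segment_body_outline()]).
#' @param gelpad_surface optional LR x IS matrix of gel-pad top surface AP
#'   indices; defaults to the body's under-surface.
#' @param params a [segmentation_params()].
#' @return a `hifu_mask` (possibly empty).
#' @export
segment_extracorporeal_air <- function(image, body, gelpad_surface = NULL,
                                       params = segmentation_params()) {
  th1 <- otsu_threshold(as.numeric(image$data), params$n_bins)
  low <- image$data <= th1 & !body$data
  dm <- dim(image$data)
  surf <- if (is.null(gelpad_surface)) body_under_surface(body$data)
          else gelpad_surface
  band_vox <- params$air_band_height / image$spacing[2]
  out <- array(FALSE, dm)
  j_idx <- seq_len(dm[2])
  for (k in seq_len(dm[3])) {
    s_k <- surf[, k]
    cols <- which(!is.na(s_k))
    if (length(cols) == 0L) next
    sl <- low[, , k]
    in_band <- outer(s_k[cols], j_idx, function(s, j) j < s & j >= s - band_vox)
    # interface columns: gel-pad material (above-threshold, non-body)
    # present somewhere in the band below the skin
    gel_sl <- image$data[, , k] > th1 & !body$data[, , k]
    has_gel <- rowSums(gel_sl[cols, , drop = FALSE] & in_band) > 0
    keep <- sl[cols, , drop = FALSE] & in_band & has_gel
    out[cols, , k] <- keep
  }
  label_mask(out, geometry = image)
}

#' Left-right extent of acoustic coupling
#'
#' The LR interval of the body's under-surface that is not overlain by
#' interface air: LR positions where at least one IS column has skin-gel
#' contact free of air immediately beneath it. Used to clip the transducer's
#' LR search bounds.
#'
#' @param air interface-air `hifu_mask` (e.g. from
#'   [segment_extracorporeal_air()]).
#' @param body body `hifu_mask` on the same grid.
#' @param gap_vox how many voxels beneath the skin to inspect for air.
#' @return length-2 numeric LR interval (world mm), or `numeric(0)` with a
#'   warning if no coupled surface exists.
#' @export
coupling_extent <- function(air, body, gap_vox = 3) {
  stopifnot(same_geometry(air, body))
  dm <- dim(body$data)
  surf <- body_under_surface(body$data)
  coupled_lr <- logical(dm[1])
  for (k in seq_len(dm[3])) {
    s_k <- surf[, k]
    cols <- which(!is.na(s_k))
    for (i in cols) {
      jj <- seq(max(1, s_k[i] - gap_vox), max(1, s_k[i] - 1))
      if (s_k[i] == 1L || !any(air$data[i, jj, k]))
        coupled_lr[i] <- TRUE
    }
  }
  if (!any(coupled_lr)) {
    warning("no coupled body surface found")
    return(numeric(0))
  }
  ii <- range(which(coupled_lr))
  body$origin[1] + (ii - 1) * body$spacing[1]
}
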