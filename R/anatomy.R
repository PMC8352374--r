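#' Voxel volume with world-space geometry
#'
#' A 3D scalar image together with its voxel geometry. The world frame is
#' right-handed, in millimetres, with axes named LR (x, array axis 1),
#' AP (y, array axis 2, positive toward anterior, i.e. "up" on the HIFU
#' couch) and IS (z, array axis 3, positive superior). The world coordinate
#' of voxel `(i, j, k)` (1-based indices, voxel-centre convention) is
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of the centre of
#'   voxel (1,1,1).
#' @return An object of class `hifu_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 axis_labels = c("LR", "AP", "IS")),
            class = "hifu_volume")
}

#' Binary label mask sharing a volume's geometry
#'
#' @param data 3D array; coerced to logical with `> 0`.
#' @param spacing,origin voxel geometry, as in [voxel_volume()]. Alternatively
#'   pass `geometry = ` a `hifu_volume`/`hifu_mask` to copy geometry from.
#' @param geometry optional object to share geometry with.
#' @return An object of class `hifu_mask`.
#' @export
label_mask <- function(data, spacing = NULL, origin = NULL, geometry = NULL) {
  if (!is.null(geometry)) {
    spacing <- geometry$spacing
    origin <- geometry$origin
  }
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  storage.mode(data) <- "double"
  m <- voxel_volume(data > 0, spacing, origin)
  class(m) <- "hifu_mask"
  m
}

#' @export
print.hifu_volume <- function(x, ...) {
  cat(sprintf("<hifu_volume> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.hifu_mask <- function(x, ...) {
  cat(sprintf("<hifu_mask> %s voxels, %d set, spacing %s mm\n",
              paste(dim(x$data), collapse = " x "), sum(x$data),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Test whether two volumes/masks share a voxel grid
#'
#' @param a,b `hifu_volume` or `hifu_mask` objects.
#' @param tol tolerance in mm on spacing and origin.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-3) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Convert voxel indices to world coordinates (voxel centres)
#'
#' @param index integer vector of length 3 or an n x 3 matrix of 1-based
#'   voxel indices.
#' @param geometry a `hifu_volume` or `hifu_mask`.
#' @return world coordinates (mm), same shape as the input.
#' @export
voxel_to_world <- function(index, geometry) {
  if (is.matrix(index)) {
    sweep(sweep(index - 1, 2, geometry$spacing, "*"), 2, geometry$origin, "+")
  } else {
    geometry$origin + (as.numeric(index) - 1) * geometry$spacing
  }
}

# Half-up rounding: deterministic nearest-voxel rule shared by the coverage
# engine and its test oracle (round() would use banker's rounding on .5 ties).
round_half_up <- function(x) floor(x + 0.5)

#' Convert world points to nearest voxel indices
#'
#' Maps each world point to the nearest voxel centre (half-voxel ties round
#' up). Out-of-bounds points are flagged, not clamped.
#'
#' @param point numeric length-3 or n x 3 matrix of world coordinates (mm).
#' @param geometry a `hifu_volume` or `hifu_mask`.
#' @return list with `index` (1-based indices, same shape as input) and
#'   `inside` (logical, whether each point falls within the array bounds).
#' @export
world_to_voxel <- function(point, geometry) {
  dm <- dim(geometry$data)
  if (is.matrix(point)) {
    frac <- sweep(sweep(point, 2, geometry$origin, "-"), 2, geometry$spacing, "/")
    idx <- round_half_up(frac) + 1
    inside <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
      idx[, 2] >= 1 & idx[, 2] <= dm[2] &
      idx[, 3] >= 1 & idx[, 3] <= dm[3]
  } else {
    idx <- round_half_up((as.numeric(point) - geometry$origin) / geometry$spacing) + 1
    inside <- all(idx >= 1 & idx <= dm)
  }
  list(index = idx, inside = inside)
}

nifti_from_geometry <- function(data, spacing, origin) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  img
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Masks are stored as uint8 (0/1); re-reading yields a voxel-identical mask.
#'
#' @param x a `hifu_volume` or `hifu_mask`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write '", path, "': directory does not exist")
  if (inherits(x, "hifu_mask")) {
    img <- nifti_from_geometry(array(as.integer(x$data), dim(x$data)),
                               x$spacing, x$origin)
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else {
    img <- nifti_from_geometry(x$data, x$spacing, x$origin)
    RNifti::writeNifti(img, path, datatype = "double")
  }
  invisible(path)
}

#' @rdname write_volume
#' @param mask a `hifu_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "hifu_mask"))
  write_volume(mask, path)
}

read_geometry <- function(img) {
  xf <- RNifti::xform(img)
  lin <- xf[1:3, 1:3]
  if (any(abs(lin - diag(diag(lin))) > 1e-6) || any(diag(lin) <= 0))
    stop("only axis-aligned volumes with positive spacing are supported")
  list(spacing = diag(lin), origin = xf[1:3, 4])
}

#' Read a NIfTI volume or mask
#'
#' @param path NIfTI file path.
#' @return a `hifu_volume` ([read_volume()]) or `hifu_mask` ([read_mask()],
#'   binarized at `> 0`).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("'", path, "' is not a 3D volume")
  g <- read_geometry(img)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  voxel_volume(dat, g$spacing, g$origin)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  label_mask(v$data, geometry = v)
}

#' Co-registered anatomy: image plus label masks
#'
#' Bundles the intensity image with the body outline, bone, extracorporeal
#' air, organ-at-risk and target masks, all on one voxel grid, plus the couch
#' geometry that situates the anatomy relative to the transducer. Enforces
#' the anatomical invariants: the target lies inside the body and does not
#' overlap bone, and extracorporeal air lies outside the body.
#'
#' @param image `hifu_volume`.
#' @param body,bone,target `hifu_mask` (required).
#' @param extracorporeal_air,oar `hifu_mask` or `NULL` (treated as empty).
#' @param couch a [couch_geometry()].
#' @return object of class `hifu_anatomy`.
#' @export
labelled_anatomy <- function(image, body, bone, target,
                             extracorporeal_air = NULL, oar = NULL,
                             couch = couch_geometry()) {
  stopifnot(inherits(image, "hifu_volume"))
  empty <- label_mask(array(FALSE, dim(image$data)), geometry = image)
  if (is.null(extracorporeal_air)) extracorporeal_air <- empty
  if (is.null(oar)) oar <- empty
  masks <- list(body = body, bone = bone, target = target,
                extracorporeal_air = extracorporeal_air, oar = oar)
  for (nm in names(masks)) {
    if (!inherits(masks[[nm]], "hifu_mask"))
      stop("'", nm, "' must be a hifu_mask")
    if (!same_geometry(image, masks[[nm]]))
      stop("mask '", nm, "' does not share the image voxel grid")
  }
  n_tb <- sum(target$data & bone$data)
  if (n_tb > 0)
    stop("target overlaps bone in ", n_tb, " voxel(s)")
  n_out <- sum(target$data & !body$data)
  if (n_out > 0)
    stop("target extends outside the body in ", n_out, " voxel(s)")
  n_air <- sum(extracorporeal_air$data & body$data)
  if (n_air > 0)
    stop("extracorporeal air overlaps the body in ", n_air, " voxel(s)")
  structure(list(image = image, body = body, bone = bone, target = target,
                 extracorporeal_air = extracorporeal_air, oar = oar,
                 couch = couch),
            class = "hifu_anatomy")
}

#' @export
print.hifu_anatomy <- function(x, ...) {
  cat(sprintf(paste0("<hifu_anatomy> %s voxels @ %s mm\n",
                     "  body %d | bone %d | air %d | oar %d | target %d voxels\n"),
              paste(dim(x$image$data), collapse = " x "),
              paste(format(x$image$spacing), collapse = " x "),
              sum(x$body$data), sum(x$bone$data),
              sum(x$extracorporeal_air$data), sum(x$oar$data),
              sum(x$target$data)))
  invisible(x)
}

#' Read a labelled anatomy from per-structure NIfTI files
#'
#' Expects one intensity image plus one single-label mask file per structure
#' (the per-structure segmentation workflow). All files must share shape,
#' spacing and origin to within 1e-3 mm.
#'
#' @param paths named list/vector with entries `image`, `body`, `bone`,
#'   `target` (required) and optionally `extracorporeal_air`, `oar`.
#'   Alternatively a directory containing `image.nii.gz`, `body.nii.gz`, ...
#' @param couch_config optional path to a couch/device YAML (see
#'   [read_device_config()]); defaults to the standard couch.
#' @return a `hifu_anatomy`.
#' @export
read_anatomy <- function(paths, couch_config = NULL) {
  if (length(paths) == 1L && is.character(paths) && dir.exists(paths)) {
    find1 <- function(stem) {
      for (ext in c(".nii.gz", ".nii")) {
        p <- file.path(paths, paste0(stem, ext))
        if (file.exists(p)) return(p)
      }
      NA_character_
    }
    paths <- sapply(c("image", "body", "bone", "target",
                      "extracorporeal_air", "oar"), find1)
    paths <- paths[!is.na(paths)]
  }
  paths <- as.list(paths)
  for (nm in c("image", "body", "bone", "target"))
    if (is.null(paths[[nm]]))
      stop("required input '", nm, "' is missing")
  image <- read_volume(paths$image)
  masks <- list()
  for (nm in c("body", "bone", "target", "extracorporeal_air", "oar")) {
    if (is.null(paths[[nm]])) next
    m <- read_mask(paths[[nm]])
    if (!same_geometry(image, m))
      stop("geometry mismatch: '", paths[[nm]],
           "' does not match the image grid (shape/spacing/origin, tol 1e-3 mm)")
    masks[[nm]] <- m
  }
  couch <- if (is.null(couch_config)) couch_geometry()
           else read_device_config(couch_config)$couch
  labelled_anatomy(image, body = masks$body, bone = masks$bone,
                   target = masks$target,
                   extracorporeal_air = masks$extracorporeal_air,
                   oar = masks$oar, couch = couch)
}

#' Read / write landmark point sets
#'
#' Landmarks are stored as CSV with columns `name,x,y,z` in world mm
#' (LR, AP, IS).
#'
#' @param path CSV file path.
#' @return data.frame with columns `name`, `x`, `y`, `z`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns name,x,y,z")
  if (nrow(df) < 1L || any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("landmark CSV must contain at least one finite point")
  df[, need]
}

#' @rdname read_landmarks
#' @param landmarks data.frame with columns `name`, `x`, `y`, `z`.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks[, c("name", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}

landmark_matrix <- function(landmarks) {
  if (is.data.frame(landmarks))
    return(as.matrix(landmarks[, c("x", "y", "z")]))
  m <- as.matrix(landmarks)
  stopifnot(ncol(m) == 3L)
  m
}
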