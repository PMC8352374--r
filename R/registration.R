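#' 3D affine transform
#'
#' Convention: `y = A x + t`, world mm.
#'
#' @param matrix 3 x 3 linear part (must be invertible).
#' @param translation length-3 vector (mm).
#' @return object of class `hifu_affine`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  stopifnot(identical(dim(matrix), c(3L, 3L)), length(translation) == 3L)
  if (abs(det(matrix)) <= 1e-12) stop("linear part is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "hifu_affine")
}

#' @export
print.hifu_affine <- function(x, ...) {
  cat("<hifu_affine> y = A x + t (world mm)\nA =\n")
  print(unname(x$matrix))
  cat("t =", format(x$translation), "\n")
  invisible(x)
}

#' Apply / invert affine transforms on points
#'
#' @param transform a `hifu_affine`.
#' @param points length-3 point or n x 3 matrix (world mm).
#' @return transformed points, same shape.
#' @export
transform_points <- function(transform, points) {
  p <- if (is.matrix(points)) points else matrix(points, 1, 3)
  out <- sweep(p %*% t(transform$matrix), 2, transform$translation, "+")
  if (is.matrix(points)) out else as.numeric(out)
}

#' @rdname transform_points
#' @export
invert_affine <- function(transform) {
  Ai <- solve(transform$matrix)
  affine_transform(Ai, -as.numeric(Ai %*% transform$translation))
}

#' Least-squares landmark affine registration
#'
#' Fits the 12-parameter affine `y = A x + t` minimizing the sum of squared
#' distances between transformed source landmarks and their paired
#' destination landmarks. Needs at least 4 non-coplanar point pairs. A rigid
#' fit (rotation + translation, Kabsch) is available for sensitivity checks.
#'
#' @param source,dest paired landmark sets: data.frames with columns
#'   `x`, `y`, `z` (e.g. from [read_landmarks()]) or n x 3 matrices, same n.
#' @param type `"affine"` (default) or `"rigid"`.
#' @return a `hifu_affine` with attributes `residuals` (per-point distances,
#'   mm), `rms` and `mean_error` (mm).
#' @export
fit_landmark_affine <- function(source, dest, type = c("affine", "rigid")) {
  type <- match.arg(type)
  S <- landmark_matrix(source)
  D <- landmark_matrix(dest)
  if (nrow(S) != nrow(D)) stop("source and dest must have the same number of points")
  if (nrow(S) < 4L) stop("at least 4 point pairs are required")
  if (type == "affine") {
    X <- cbind(S, 1)
    qx <- qr(X)
    if (qx$rank < 4L)
      stop("degenerate landmark configuration (coplanar or coincident points)")
    coef <- unname(qr.coef(qx, D))
    tr <- affine_transform(t(coef[1:3, , drop = FALSE]), coef[4, ])
  } else {
    cs <- colMeans(S); cd <- colMeans(D)
    H <- t(sweep(S, 2, cs)) %*% sweep(D, 2, cd)
    sv <- svd(H)
    R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    tr <- affine_transform(R, cd - as.numeric(R %*% cs))
  }
  res <- sqrt(rowSums((transform_points(tr, S) - D)^2))
  attr(tr, "residuals") <- res
  attr(tr, "rms") <- sqrt(mean(res^2))
  attr(tr, "mean_error") <- mean(res)
  tr
}

#' Mean Euclidean landmark distance (registration error)
#'
#' @param transformed_source,dest paired landmark sets (data.frame or
#'   matrix), same n.
#' @return mean of per-pair Euclidean distances (mm).
#' @export
registration_error <- function(transformed_source, dest) {
  A <- landmark_matrix(transformed_source)
  B <- landmark_matrix(dest)
  if (nrow(A) != nrow(B)) stop("point sets must be paired (same size)")
  mean(sqrt(rowSums((A - B)^2)))
}

#' Resample a volume or mask through an affine transform
#'
#' Maps the input onto the reference grid: each reference voxel centre is
#' pulled back through the inverse transform and the input is interpolated
#' there — trilinearly for intensity volumes, nearest-neighbour for masks
#' (keeping labels binary). Voxels mapping outside the input field of view
#' become background (0 / `FALSE`).
#'
#' @param x a `hifu_volume` or `hifu_mask` (in source space).
#' @param transform a `hifu_affine` mapping source to reference space.
#' @param reference a `hifu_volume`/`hifu_mask` defining the output grid.
#' @return resampled object of the same class as `x`, on the reference grid.
#' @export
apply_transform <- function(x, transform, reference) {
  inv <- invert_affine(transform)
  dm_out <- dim(reference$data)
  idx <- arrayInd(seq_len(prod(dm_out)), dm_out)
  w_out <- voxel_to_world(idx, reference)
  w_src <- transform_points(inv, w_out)
  # fractional (0-based) voxel coordinates in the source grid
  f <- sweep(sweep(w_src, 2, x$origin, "-"), 2, x$spacing, "/")
  dm_in <- dim(x$data)
  if (inherits(x, "hifu_mask")) {
    i <- round_half_up(f) + 1
    ok <- i[, 1] >= 1 & i[, 1] <= dm_in[1] & i[, 2] >= 1 & i[, 2] <= dm_in[2] &
      i[, 3] >= 1 & i[, 3] <= dm_in[3]
    out <- logical(prod(dm_out))
    lin <- (i[ok, 1] - 1) + (i[ok, 2] - 1) * dm_in[1] +
      (i[ok, 3] - 1) * dm_in[1] * dm_in[2] + 1
    out[ok] <- x$data[lin]
    return(label_mask(array(out, dm_out), geometry = reference))
  }
  i0 <- floor(f)
  d <- f - i0
  out <- numeric(prod(dm_out))
  ok <- i0[, 1] >= 0 & i0[, 1] <= dm_in[1] - 1 &
    i0[, 2] >= 0 & i0[, 2] <= dm_in[2] - 1 &
    i0[, 3] >= 0 & i0[, 3] <= dm_in[3] - 1
  # clamp the +1 neighbour at the upper edge so boundary voxels interpolate
  if (any(ok)) {
    i0k <- i0[ok, , drop = FALSE]
    dk <- d[ok, , drop = FALSE]
    nx <- dm_in[1]; nxy <- dm_in[1] * dm_in[2]
    ip <- pmin(i0k + 1, matrix(rep(dm_in - 1, each = nrow(i0k)), ncol = 3))
    lin000 <- i0k[, 1] + i0k[, 2] * nx + i0k[, 3] * nxy + 1
    gat <- function(a, b, cc) x$data[a + b * nx + cc * nxy + 1]
    v <- gat(i0k[, 1], i0k[, 2], i0k[, 3]) * (1 - dk[, 1]) * (1 - dk[, 2]) * (1 - dk[, 3]) +
      gat(ip[, 1], i0k[, 2], i0k[, 3]) * dk[, 1] * (1 - dk[, 2]) * (1 - dk[, 3]) +
      gat(i0k[, 1], ip[, 2], i0k[, 3]) * (1 - dk[, 1]) * dk[, 2] * (1 - dk[, 3]) +
      gat(i0k[, 1], i0k[, 2], ip[, 3]) * (1 - dk[, 1]) * (1 - dk[, 2]) * dk[, 3] +
      gat(ip[, 1], ip[, 2], i0k[, 3]) * dk[, 1] * dk[, 2] * (1 - dk[, 3]) +
      gat(ip[, 1], i0k[, 2], ip[, 3]) * dk[, 1] * (1 - dk[, 2]) * dk[, 3] +
      gat(i0k[, 1], ip[, 2], ip[, 3]) * (1 - dk[, 1]) * dk[, 2] * dk[, 3] +
      gat(ip[, 1], ip[, 2], ip[, 3]) * dk[, 1] * dk[, 2] * dk[, 3]
    out[ok] <- v
  }
  voxel_volume(array(out, dm_out), reference$spacing, reference$origin)
}

#' Write / read an affine transform as JSON
#'
#' Stored as `{matrix: 9 numbers row-major, translation: 3 numbers,
#' convention: "y = A x + t, world mm"}`.
#'
#' @param transform a `hifu_affine`.
#' @param path JSON file path.
#' @export
write_affine <- function(transform, path) {
  jsonlite::write_json(
    list(matrix = as.numeric(t(transform$matrix)),
         translation = transform$translation,
         convention = "y = A x + t, world mm"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(j$matrix, 3, 3, byrow = TRUE), j$translation)
}
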