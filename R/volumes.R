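#' Voxel volume container
#'
#' A `voxel_volume` carries a 3D grid of scalars or integer labels together
#' with its voxel spacing (mm) and an affine transform mapping 0-based grid
#' indices to scanner coordinates in millimetres. It is the common carrier
#' for binary organ masks, Couinaud label maps and quantitative MRI maps
#' (cT1, PDFF, T2*).
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0). If
#'   `transform` is given and `spacing` is `NULL`, spacing is derived from
#'   the transform column norms.
#' @param transform 4x4 affine matrix mapping homogeneous 0-based grid
#'   indices to scanner mm. Defaults to `diag(spacing)` with zero origin.
#' @param kind one of `"mask"`, `"labelmap"`, `"ct1_ms"`, `"pdff_percent"`,
#'   `"t2star_ms"`.
#' @return An object of class `voxel_volume`.
#' @examples
#' v <- voxel_volume(array(1, c(2, 2, 2)), spacing = c(1, 1, 1), kind = "mask")
#' mask_volume_ml(v)
#' @export
voxel_volume <- function(data, spacing = NULL, transform = NULL,
                         kind = c("mask", "labelmap", "ct1_ms",
                                  "pdff_percent", "t2star_ms")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (is.null(spacing) && is.null(transform)) {
    stop("supply `spacing`, `transform` or both", call. = FALSE)
  }
  if (is.null(spacing)) {
    spacing <- sqrt(colSums(transform[1:3, 1:3]^2))
  }
  spacing <- as.double(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite values (mm)",
         call. = FALSE)
  }
  if (is.null(transform)) {
    transform <- diag(c(spacing, 1))
  }
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L)) ||
      abs(det(transform)) < .Machine$double.eps^0.5) {
    stop("`transform` must be an invertible 4x4 affine", call. = FALSE)
  }
  vals <- as.vector(data)
  if (anyNA(vals) && kind %in% c("mask", "labelmap")) {
    stop("mask/labelmap volumes must not contain NA", call. = FALSE)
  }
  if (kind == "mask" && !all(vals %in% c(0, 1))) {
    stop("mask volumes must contain only {0, 1}", call. = FALSE)
  }
  if (kind == "labelmap" && (any(vals < 0) || any(vals != round(vals)))) {
    stop("label maps must contain only non-negative integers", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, transform = transform,
                 kind = kind),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> kind:", x$kind,
      " dim:", paste(dim(x$data), collapse = "x"),
      " spacing(mm):", paste(signif(x$spacing, 4), collapse = "x"), "\n")
  invisible(x)
}

voxel_volume_mm3 <- function(vol) prod(vol$spacing)

is_mask <- function(vol) inherits(vol, "voxel_volume") && vol$kind == "mask"

# mm coordinates of the centres of the voxels at 1-based index matrix `idx`
voxel_centres_mm <- function(vol, idx) {
  idx0 <- cbind(idx - 1, 1)
  (idx0 %*% t(vol$transform))[, 1:3, drop = FALSE]
}

# 1-based index matrix of foreground voxels of a mask/label volume
foreground_idx <- function(vol) {
  which(vol$data != 0, arr.ind = TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 volume (`.nii` or `.nii.gz`) into a [voxel_volume()].
#' Voxel spacing comes from the header `pixdim`; the grid-to-mm affine from
#' the sform (or qform, or pixdim) in that order of preference.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind semantic kind of the volume (caller metadata); see
#'   [voxel_volume()].
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, kind = c("mask", "labelmap", "ct1_ms",
                                       "pdff_percent", "t2star_ms")) {
  kind <- match.arg(kind)
  nii <- read_nifti(path)
  voxel_volume(nii$data, spacing = nii$spacing, transform = nii$transform,
               kind = kind)
}

#' Write a volume as NIfTI
#'
#' Masks and label maps are stored as integers, quantitative maps as
#' float64, with the affine written to the sform.
#'
#' @param vol a [voxel_volume()].
#' @param path output path; `.nii.gz` is compressed, `.nii` is not.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  write_nifti(vol$data, vol$spacing, vol$transform, path)
}

#' Volume of a binary mask in millilitres
#'
#' Foreground voxel count times the voxel volume, in mL. This is the
#' delineated liver (or lesion) volume used throughout the FLR arithmetic.
#'
#' @param mask a binary [voxel_volume()] of kind `"mask"`.
#' @return volume in mL.
#' @export
mask_volume_ml <- function(mask) {
  if (!is_mask(mask)) stop("`mask` must be a voxel_volume of kind 'mask'",
                           call. = FALSE)
  sum(mask$data) * voxel_volume_mm3(mask) / 1000
}

# logical 3D array of face voxels (on any grid boundary face)
.face_voxels <- function(d) {
  f <- array(FALSE, d)
  f[c(1, d[1]), , ] <- TRUE
  f[, c(1, d[2]), ] <- TRUE
  f[, , c(1, d[3])] <- TRUE
  f
}

# 6-neighbourhood boundary of a binary array (foreground with a background
# face neighbour); voxels on the grid faces count as boundary
.mask_boundary <- function(m) {
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  nb <- pad[i - 1, j, k] + pad[i + 1, j, k] +
        pad[i, j - 1, k] + pad[i, j + 1, k] +
        pad[i, j, k - 1] + pad[i, j, k + 1]
  m == 1 & nb < 6L
}

# Algebraic least-squares ellipsoid fit x'Ax + b'x = 1 on points (n x 3, mm).
# Returns the fitted ellipsoid volume, or NA if the quadric is not an
# ellipsoid (indefinite or degenerate).
.fit_ellipsoid_volume <- function(pts, inflate = 0) {
  ctr <- colMeans(pts)
  p <- sweep(pts, 2, ctr)
  sc <- max(apply(abs(p), 2, max))
  if (sc == 0) return(NA_real_)
  p <- p / sc
  D <- cbind(p[, 1]^2, p[, 2]^2, p[, 3]^2,
             p[, 1] * p[, 2], p[, 1] * p[, 3], p[, 2] * p[, 3],
             p[, 1], p[, 2], p[, 3])
  w <- tryCatch(qr.solve(D, rep(1, nrow(p))), error = function(e) NULL)
  if (is.null(w)) return(NA_real_)
  A <- matrix(c(w[1], w[4] / 2, w[5] / 2,
                w[4] / 2, w[2], w[6] / 2,
                w[5] / 2, w[6] / 2, w[3]), 3, 3)
  b <- w[7:9]
  ei <- eigen(A, symmetric = TRUE)
  if (any(ei$values <= 0)) return(NA_real_)
  # complete the square: y'Ay = 1 + b'A^{-1}b/4
  c0 <- 1 + sum(b * solve(A, b)) / 4
  if (c0 <= 0) return(NA_real_)
  semi <- sqrt(c0 / ei$values) * sc + inflate
  if (any(semi <= 0)) return(NA_real_)
  4 / 3 * pi * prod(semi)
}

#' Field-of-view coverage check
#'
#' Estimates the fraction of an organ truncated at the image boundary and
#' applies the exclusion rule: a case is excluded when more than 5% of the
#' organ volume lies outside the field of view. A mask that touches no grid
#' face is trivially fully covered. Otherwise the full organ volume is
#' estimated by a least-squares ellipsoid fit to the interior boundary
#' surface (face voxels excluded) and the truncated fraction is
#' `1 - observed/fitted`.
#'
#' @param mask binary [voxel_volume()].
#' @param threshold exclusion threshold on the truncated fraction
#'   (default 0.05; the rule is strictly "more than").
#' @return list with `status` (`"included"`/`"excluded"`) and `fraction`.
#' @export
check_fov_coverage <- function(mask, threshold = 0.05) {
  if (!is_mask(mask)) stop("`mask` must be a voxel_volume of kind 'mask'",
                           call. = FALSE)
  d <- dim(mask$data)
  face <- .face_voxels(d)
  if (!any(mask$data == 1 & face)) {
    return(list(status = "included", fraction = 0))
  }
  bnd <- .mask_boundary(mask$data) & !face
  idx <- which(bnd, arr.ind = TRUE)
  frac <- NA_real_
  if (nrow(idx) >= 20L) {
    pts <- voxel_centres_mm(mask, idx)
    # boundary voxel centres sit ~half a voxel inside the true surface
    v_fit <- .fit_ellipsoid_volume(pts, inflate = mean(mask$spacing) / 2)
    v_obs <- sum(mask$data) * voxel_volume_mm3(mask)
    if (is.finite(v_fit) && v_fit > 0) {
      frac <- min(max(1 - v_obs / v_fit, 0), 0.999)
    }
  }
  if (!is.finite(frac)) {
    # degenerate fit: fall back to the share of the boundary surface lying
    # on the clipped faces (a crude but monotone proxy)
    n_face <- sum(mask$data == 1 & face)
    n_bnd <- sum(.mask_boundary(mask$data))
    frac <- n_face / max(n_bnd, 1L)
  }
  list(status = .fov_status(frac, threshold), fraction = frac)
}

# strict "more than threshold" exclusion rule
.fov_status <- function(fraction, threshold = 0.05) {
  if (fraction > threshold) "excluded" else "included"
}
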