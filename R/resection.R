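# Virtual hepatectomy: anatomical segmentectomies plus atypical wedge
# resections modelled as conical frustra, and the planned future liver
# remnant (FLR) arithmetic.

#' Wedge resection specification
#'
#' An atypical (non-anatomical) resection is modelled as a conical frustrum
#' along the access axis from a liver-surface entry point to the tumour:
#' the small (deep) face is the tumour's bounding disc dilated by the
#' resection margin; the frustrum widens towards the surface with a fixed
#' half-angle.
#'
#' @param tumour_id name of the tumour mask the wedge removes.
#' @param entry_point optional mm coordinate on the liver surface; when
#'   omitted, the closest surface point to the tumour centroid is used
#'   (direct-access convention).
#' @param margin_mm radial clearance around the tumour (default 10).
#' @param half_angle_deg opening half-angle of the frustrum (default 15).
#' @return object of class `wedge_spec`.
#' @export
wedge_spec <- function(tumour_id, entry_point = NULL, margin_mm = 10,
                       half_angle_deg = 15) {
  if (margin_mm < 0) stop("`margin_mm` must be >= 0", call. = FALSE)
  if (!is.null(entry_point)) {
    entry_point <- as.double(entry_point)
    stopifnot(length(entry_point) == 3L, all(is.finite(entry_point)))
  }
  structure(list(tumour_id = as.character(tumour_id),
                 entry_point = entry_point, margin_mm = margin_mm,
                 half_angle_deg = half_angle_deg),
            class = "wedge_spec")
}

#' Resection plan
#'
#' @param segments_removed integer subset of 1..8 (Couinaud segments to
#'   remove); may be empty.
#' @param wedges list of [wedge_spec()] objects.
#' @return object of class `resection_plan`.
#' @export
resection_plan <- function(segments_removed = integer(), wedges = list()) {
  segments_removed <- as.integer(segments_removed)
  if (anyDuplicated(segments_removed)) {
    stop("`segments_removed` contains duplicates", call. = FALSE)
  }
  if (length(segments_removed) &&
      !all(segments_removed %in% 1:8)) {
    stop("`segments_removed` must be a subset of 1..8", call. = FALSE)
  }
  if (length(wedges) && !all(vapply(wedges, inherits, TRUE, "wedge_spec"))) {
    stop("`wedges` must be a list of wedge_spec objects", call. = FALSE)
  }
  structure(list(segments_removed = segments_removed, wedges = wedges),
            class = "resection_plan")
}

# surface voxels (mm centres) of a binary mask
.surface_points_mm <- function(mask) {
  bnd <- .mask_boundary(mask$data)
  voxel_centres_mm(mask, which(bnd, arr.ind = TRUE))
}

#' Voxelise a conical-frustrum wedge
#'
#' Builds the wedge mask for one tumour: the frustrum runs from the entry
#' point on the liver surface (large face) to a plane just deep to the
#' margin-dilated tumour (small face, radius = tumour bounding radius +
#' margin), is unioned with the margin-dilated tumour, and intersected with
#' the liver mask.
#'
#' @param liver binary liver [voxel_volume()].
#' @param tumour binary tumour [voxel_volume()] on the same grid, contained
#'   in the liver.
#' @param spec a [wedge_spec()].
#' @return binary [voxel_volume()] wedge mask.
#' @export
wedge_mask <- function(liver, tumour, spec) {
  stopifnot(is_mask(liver), is_mask(tumour), inherits(spec, "wedge_spec"))
  if (!all(dim(liver$data) == dim(tumour$data))) {
    stop("liver and tumour masks must share a grid", call. = FALSE)
  }
  if (any(tumour$data == 1 & liver$data == 0)) {
    stop("tumour mask is not contained in the liver mask", call. = FALSE)
  }
  t_idx <- foreground_idx(tumour)
  if (nrow(t_idx) == 0L) stop("empty tumour mask", call. = FALSE)
  t_pts <- voxel_centres_mm(tumour, t_idx)
  centroid <- colMeans(t_pts)
  r_t <- sqrt(max(rowSums(sweep(t_pts, 2, centroid)^2)))

  entry <- spec$entry_point
  if (is.null(entry)) {
    surf <- .surface_points_mm(liver)
    d2 <- rowSums(sweep(surf, 2, centroid)^2)
    entry <- surf[which.min(d2), ]
  }
  u <- centroid - entry
  if (sqrt(sum(u^2)) < 1e-6) {
    stop("entry point coincides with the tumour centroid", call. = FALSE)
  }
  u <- u / sqrt(sum(u^2))

  r_small <- r_t + spec$margin_mm
  s_far <- max(as.vector(sweep(t_pts, 2, entry) %*% u)) + spec$margin_mm
  tan_a <- tan(spec$half_angle_deg * pi / 180)

  l_idx <- foreground_idx(liver)
  l_pts <- voxel_centres_mm(liver, l_idx)
  rel <- sweep(l_pts, 2, entry)
  s <- as.vector(rel %*% u)
  rad2 <- rowSums((rel - outer(s, u))^2)
  in_frustrum <- s >= 0 & s <= s_far &
    rad2 <= (r_small + (s_far - s) * tan_a)^2

  # margin-dilated tumour, evaluated only near the tumour bounding sphere
  near <- rowSums(sweep(l_pts, 2, centroid)^2) <= (r_t + spec$margin_mm + 1e-9)^2
  in_dilated <- logical(nrow(l_pts))
  cand <- which(near & !in_frustrum)
  if (length(cand) && spec$margin_mm > 0) {
    m2 <- spec$margin_mm^2
    step <- 2000L
    for (i0 in seq(1L, length(cand), by = step)) {
      ii <- cand[i0:min(i0 + step - 1L, length(cand))]
      dx <- outer(l_pts[ii, 1], t_pts[, 1], "-")
      dy <- outer(l_pts[ii, 2], t_pts[, 2], "-")
      dz <- outer(l_pts[ii, 3], t_pts[, 3], "-")
      in_dilated[ii] <- apply(dx^2 + dy^2 + dz^2 <= m2, 1, any)
    }
  }

  out <- array(0L, dim(liver$data))
  out[l_idx[in_frustrum | in_dilated, , drop = FALSE]] <- 1L
  out[t_idx] <- 1L
  voxel_volume(out, spacing = liver$spacing, transform = liver$transform,
               kind = "mask")
}

#' Apply a resection plan and compute the planned FLR
#'
#' Removes the planned Couinaud segments and wedge volumes from the liver
#' mask and reports the future liver remnant as a percentage of the total
#' functional parenchyma. Tumour voxels are excluded from both numerator
#' and denominator: the FLR is a parenchymal fraction, since tumour tissue
#' contributes no function.
#'
#' @param liver binary liver [voxel_volume()].
#' @param labels Couinaud label map from [label_segments()] partitioning
#'   the liver.
#' @param tumours named list of binary tumour masks (may be empty).
#' @param plan a [resection_plan()].
#' @return object of class `flr_result`: list with `flr_percent`,
#'   `remnant_mask`, `resected_volume_ml`, `total_parenchyma_ml`,
#'   `lesion_volume_ml`.
#' @export
apply_plan <- function(liver, labels, tumours = list(), plan) {
  stopifnot(is_mask(liver), inherits(labels, "voxel_volume"),
            labels$kind == "labelmap", inherits(plan, "resection_plan"))
  if (!all((labels$data > 0) == (liver$data == 1))) {
    stop("label map does not partition the liver mask", call. = FALSE)
  }
  wanted <- vapply(plan$wedges, function(w) w$tumour_id, character(1))
  unknown <- setdiff(wanted, names(tumours))
  if (length(unknown)) {
    stop("plan references unknown tumour_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  resected <- array(FALSE, dim(liver$data))
  if (length(plan$segments_removed)) {
    resected <- resected |
      (labels$data %in% plan$segments_removed &
         array(TRUE, dim(liver$data)))
    dim(resected) <- dim(liver$data)
  }
  for (w in plan$wedges) {
    wm <- wedge_mask(liver, tumours[[w$tumour_id]], w)
    resected <- resected | (wm$data == 1)
  }
  resected <- resected & (liver$data == 1)

  tumour_any <- array(FALSE, dim(liver$data))
  for (tm in tumours) tumour_any <- tumour_any | (tm$data == 1)

  parench <- liver$data == 1 & !tumour_any
  remnant <- liver$data == 1 & !resected
  vx_ml <- voxel_volume_mm3(liver) / 1000

  flr <- 100 * sum(remnant & parench) / sum(parench)
  remnant_mask <- voxel_volume(array(as.integer(remnant), dim(liver$data)),
                               spacing = liver$spacing,
                               transform = liver$transform, kind = "mask")
  structure(list(flr_percent = flr,
                 remnant_mask = remnant_mask,
                 resected_volume_ml = sum(resected) * vx_ml,
                 total_parenchyma_ml = sum(parench) * vx_ml,
                 lesion_volume_ml = sum(tumour_any) * vx_ml),
            class = "flr_result")
}

#' Resected fraction of the liver
#'
#' `1 - flr_percent/100`; the eligibility filter for the statistical
#' analyses keeps patients with at least 10% of the liver removed
#' (inclusive at the boundary).
#'
#' @param result an `flr_result` from [apply_plan()], or a numeric
#'   `flr_percent`.
#' @return resected fraction in `[0, 1]`.
#' @export
resected_fraction <- function(result) {
  flr <- if (inherits(result, "flr_result")) result$flr_percent else result
  1 - flr / 100
}
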