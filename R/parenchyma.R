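# Summaries of quantitative MRI maps (cT1, PDFF, T2*) over liver regions,
# with lesion exclusion, and the cT1 normal-limit classification.

# nearest-neighbour sample of `map` at the mm centres of `region` voxels
.sample_map_at <- function(map, region, idx) {
  same_grid <- all(dim(map$data) == dim(region$data)) &&
    max(abs(map$transform - region$transform)) < 1e-6
  if (same_grid) return(map$data[idx])
  mm <- voxel_centres_mm(region, idx)
  inv <- solve(map$transform)
  gi <- round(cbind(mm, 1) %*% t(inv))[, 1:3, drop = FALSE] + 1
  d <- dim(map$data)
  ok <- gi[, 1] >= 1 & gi[, 1] <= d[1] &
        gi[, 2] >= 1 & gi[, 2] <= d[2] &
        gi[, 3] >= 1 & gi[, 3] <= d[3]
  out <- rep(NA_real_, nrow(gi))
  out[ok] <- map$data[gi[ok, , drop = FALSE]]
  out
}

#' Summarise a quantitative map over a region
#'
#' Median, interquartile range and mean of a quantitative map (cT1, PDFF or
#' T2*) over a region mask after excluding lesion voxels. The map may live
#' on a different grid (e.g. multi-slice maps against a 3D volume); it is
#' then matched by nearest-neighbour sampling in scanner mm, and region
#' voxels falling outside the map are dropped from the summary.
#'
#' @param map [voxel_volume()] of kind `"ct1_ms"`, `"pdff_percent"` or
#'   `"t2star_ms"`.
#' @param region binary [voxel_volume()] region mask (e.g. whole liver or
#'   the planned remnant).
#' @param lesions list of binary masks on the region grid to exclude.
#' @return list with `median`, `iqr` (length-2), `mean`, `n_voxels`.
#' @export
region_summary <- function(map, region, lesions = list()) {
  stopifnot(inherits(map, "voxel_volume"),
            map$kind %in% c("ct1_ms", "pdff_percent", "t2star_ms"),
            is_mask(region))
  keep <- region$data == 1
  for (les in lesions) {
    stopifnot(is_mask(les))
    keep <- keep & les$data == 0
  }
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("region is empty after lesion exclusion", call. = FALSE)
  }
  vals <- .sample_map_at(map, region, idx)
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    stop("region does not overlap the quantitative map", call. = FALSE)
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], iqr = c(q[1], q[3]), mean = mean(vals),
       n_voxels = length(vals))
}

#' Classify a liver cT1 summary against the normal limit
#'
#' The upper limit of normal for liver cT1 is 795 ms; values strictly above
#' it are classified `"elevated"` (fibroinflammation), the limit itself is
#' still `"normal"`.
#'
#' @param ct1_summary_ms patient-level cT1 in ms (scalar or vector).
#' @param threshold_ms upper limit of normal (default 795).
#' @return character vector, `"normal"` or `"elevated"`.
#' @export
classify_ct1 <- function(ct1_summary_ms, threshold_ms = 795) {
  if (any(!is.finite(ct1_summary_ms))) {
    stop("cT1 summary must be finite", call. = FALSE)
  }
  ifelse(ct1_summary_ms > threshold_ms, "elevated", "normal")
}
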