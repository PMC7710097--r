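# Couinaud subdivision of a liver mask from eight anatomical landmarks.
#
# Geometry convention: everything happens in scanner mm after applying the
# volume's affine. Each cutting plane is stored as (point, unit normal,
# anchor); the anchor is a landmark that fixes which side of the plane is
# "positive", making the half-space tests patient-independent. Voxels with
# signed distance exactly 0 are assigned to the anchor side.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("zero-length direction in plane construction",
                     call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# plane through `point` with unit `normal`, oriented so that `anchor` lies
# on the positive side
.plane <- function(point, normal, anchor, name) {
  s <- sum((anchor - point) * normal)
  if (abs(s) < 1e-9) {
    stop("degenerate geometry: orientation anchor lies on the ", name,
         " plane", call. = FALSE)
  }
  list(point = point, normal = normal * sign(s), name = name)
}

.plane_signed <- function(pts, plane) {
  (pts - matrix(plane$point, nrow(pts), 3, byrow = TRUE)) %*% plane$normal
}

#' Build Couinaud cutting planes from landmarks
#'
#' The inferior vena cava axis is `normalize(ivc_superior - ivc_inferior)`.
#' Each hepatic-vein plane contains the IVC axis (through `ivc_inferior`)
#' and its vein landmark; the portal plane passes through the midpoint of
#' the portal branches with the IVC axis as normal; the umbilical plane
#' passes through the umbilical fissure, spanned by the IVC axis and the
#' direction towards the gallbladder fossa. Sidedness anchors: the right
#' portal branch for the right/middle hepatic-vein planes, the left hepatic
#' vein landmark for the umbilical plane (its positive side is the left
#' lobe), the superior cava for the portal plane, and the gallbladder fossa
#' marks the anterior side of the middle hepatic-vein plane (used by the
#' caudate rule).
#'
#' @param landmarks a [landmark_set()].
#' @return object of class `cutting_planes`: list with `ivc_axis`,
#'   `ivc_point` and planes `portal`, `rhv`, `mhv`, `lhv`, `umbilical`,
#'   plus `mhv_anterior` (the gallbladder-anchored orientation of the MHV
#'   plane).
#' @export
build_planes <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  lm <- function(n) unname(landmarks[n, ])
  axis <- .unit(lm("ivc_superior") - lm("ivc_inferior"))
  p0 <- lm("ivc_inferior")

  vein_plane <- function(vein, anchor, name) {
    d <- lm(vein) - p0
    n <- .cross3(axis, d)
    if (sqrt(sum(n^2)) < 1e-6) {
      stop("degenerate geometry: ", vein,
           " landmark is collinear with the IVC axis (", name, " plane)",
           call. = FALSE)
    }
    .plane(p0, .unit(n), lm(anchor), name)
  }
  rhv <- vein_plane("rhv", "portal_right", "rhv")
  mhv <- vein_plane("mhv", "portal_right", "mhv")
  lhv <- vein_plane("lhv", "umbilical_fissure", "lhv")
  mhv_anterior <- .plane(p0, mhv$normal, lm("gallbladder_fossa"),
                         "mhv (anterior orientation)")

  u_dir <- lm("gallbladder_fossa") - lm("umbilical_fissure")
  u_n <- .cross3(axis, u_dir)
  if (sqrt(sum(u_n^2)) < 1e-6) {
    stop("degenerate geometry: gallbladder fossa is collinear with the IVC ",
         "axis at the umbilical fissure (umbilical plane)", call. = FALSE)
  }
  umb <- .plane(lm("umbilical_fissure"), .unit(u_n), lm("lhv"), "umbilical")

  portal_mid <- (lm("portal_left") + lm("portal_right")) / 2
  portal <- .plane(portal_mid, axis, lm("ivc_superior"), "portal")

  structure(list(ivc_axis = axis, ivc_point = p0, portal = portal,
                 rhv = rhv, mhv = mhv, lhv = lhv, umbilical = umb,
                 mhv_anterior = mhv_anterior),
            class = "cutting_planes")
}

#' Label Couinaud segments
#'
#' Partitions every foreground voxel of a binary liver mask into the eight
#' Couinaud segments by signed half-space tests at voxel centres (mm):
#' right of the RHV plane gives segments 7 (superior of the portal plane) /
#' 6 (inferior); between RHV and MHV gives 8/5; between MHV and the
#' umbilical plane gives 4 (4a/4b merged); left of the umbilical plane
#' gives 2/3. The caudate (segment 1) is modelled as a cylinder of radius
#' `r_caudate_mm` around the IVC axis on the posterior side of the MHV
#' plane, overriding the plane labels; set `caudate = FALSE` to disable.
#'
#' @param liver binary [voxel_volume()] liver mask.
#' @param planes a `cutting_planes` object from [build_planes()].
#' @param r_caudate_mm caudate cylinder radius in mm (default 15).
#' @param caudate logical, model segment 1 at all.
#' @return [voxel_volume()] of kind `"labelmap"` with labels 0 and 1-8.
#' @export
label_segments <- function(liver, planes, r_caudate_mm = 15, caudate = TRUE) {
  if (!is_mask(liver)) stop("`liver` must be a voxel_volume of kind 'mask'",
                            call. = FALSE)
  stopifnot(inherits(planes, "cutting_planes"))
  idx <- foreground_idx(liver)
  if (nrow(idx) == 0L) stop("empty liver mask", call. = FALSE)
  pts <- voxel_centres_mm(liver, idx)

  # signed distance 0 (to within float noise) goes to the anchor side
  tol <- -1e-9
  sup   <- .plane_signed(pts, planes$portal) >= tol
  r_rhv <- .plane_signed(pts, planes$rhv) >= tol
  r_mhv <- .plane_signed(pts, planes$mhv) >= tol
  l_umb <- .plane_signed(pts, planes$umbilical) >= tol

  lab <- ifelse(r_rhv, ifelse(sup, 7L, 6L),
         ifelse(r_mhv, ifelse(sup, 8L, 5L),
         ifelse(l_umb, ifelse(sup, 2L, 3L), 4L)))

  if (caudate && r_caudate_mm > 0) {
    rel <- pts - matrix(planes$ivc_point, nrow(pts), 3, byrow = TRUE)
    along <- as.vector(rel %*% planes$ivc_axis)
    radial2 <- rowSums((rel - outer(along, planes$ivc_axis))^2)
    posterior <- .plane_signed(pts, planes$mhv_anterior) < 0
    lab[radial2 <= r_caudate_mm^2 & posterior] <- 1L
  }

  out <- array(0L, dim(liver$data))
  out[idx] <- lab
  vol <- voxel_volume(out, spacing = liver$spacing,
                      transform = liver$transform, kind = "labelmap")
  attr(vol, "planes") <- planes
  vol
}

#' Per-segment volumes and liver fractions
#'
#' @param labels a Couinaud label map from [label_segments()].
#' @return data.frame with `segment` (1-8), `volume_ml` and `fraction`
#'   (of total labelled liver; fractions sum to 1 exactly).
#' @export
segment_volumes <- function(labels) {
  stopifnot(inherits(labels, "voxel_volume"), labels$kind == "labelmap")
  counts <- tabulate(labels$data[labels$data > 0], nbins = 8L)
  vml <- counts * voxel_volume_mm3(labels) / 1000
  data.frame(segment = 1:8, volume_ml = vml,
             fraction = counts / sum(counts))
}
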