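# Analytic liver phantoms: a voxelised sphere/spheroid with landmarks
# placed so that the cutting planes all pass through the "vena cava" axis
# (the z axis) at known azimuths, the portal plane at a known height, and
# closed-form per-segment volumes as an independent oracle.
#
# Geometry of the default phantom (azimuths measured in the x-y plane from
# +x, degrees):
#   RHV plane       azimuth  90  -> the x = 0 plane; right side is x >= 0
#   MHV plane       azimuth 120  -> right side is 0.5*y >= -sqrt(3)/2*x
#   umbilical plane azimuth  60  -> left side of the y = sqrt(3)*x plane
#   portal plane    z = portal_z_mm, superior above
# which yields angular sectors 7/6: (-90, 90), 8/5: (90, 120),
# 2/3: (120, 240), 4: (240, 270), and the caudate cylinder over the
# posterior half-circle (120, 300) (the posterior side of the MHV plane). The 120/60 degree fan deliberately
# avoids plane orientations that contain whole lattice sheets of voxel
# centres (a 45-degree plane on an isotropic grid does), which would make
# voxel-centre counting degenerate.

.deg2rad <- function(d) d * pi / 180

# closed-form volumes of a sphere radius r cut by the default plane fan,
# portal height zp and caudate cylinder radius rc (all mm); returns mm^3
# per segment 1..8. Requires |zp| <= sqrt(r^2 - rc^2) when rc > 0.
.sphere_segment_volumes <- function(r, zp = 0, rc = 15, caudate = TRUE) {
  stopifnot(abs(zp) < r)
  v_total <- 4 / 3 * pi * r^3
  v_above <- pi * (r - zp)^2 * (2 * r + zp) / 3
  v_below <- v_total - v_above
  if (caudate && rc > 0) {
    if (rc >= r || abs(zp) > sqrt(r^2 - rc^2)) {
      stop("caudate oracle requires rc < r and |zp| <= sqrt(r^2 - rc^2)",
           call. = FALSE)
    }
    vc <- 4 * pi / 3 * (r^3 - (r^2 - rc^2)^1.5)
    vc_above <- 2 * pi / 3 * (r^3 - (r^2 - rc^2)^1.5) - zp * pi * rc^2
    vc_below <- vc - vc_above
  } else {
    vc <- vc_above <- vc_below <- 0
  }
  f <- function(deg) deg / 360
  c(seg1 = f(180) * vc,
    seg2 = f(120) * v_above - f(120) * vc_above,
    seg3 = f(120) * v_below - f(120) * vc_below,
    seg4 = f(30) * v_total - f(30) * vc,
    seg5 = f(30) * v_below,
    seg6 = f(180) * v_below - f(30) * vc_below,
    seg7 = f(180) * v_above - f(30) * vc_above,
    seg8 = f(30) * v_above)
}

#' Analytic liver phantom with landmarks and oracle segment volumes
#'
#' Voxelises a sphere or spheroid "liver" centred at the origin, places the
#' nine landmarks so that [build_planes()] reproduces a fixed fan of
#' cutting planes through the z axis (see the package vignette for the
#' exact angles), optionally carves spherical tumours, and returns
#' closed-form per-segment volumes as an independent oracle for the
#' voxel-counting pipeline.
#'
#' @param radii_mm either a single sphere radius or `c(a, a, c)` spheroid
#'   semi-axes (the x and y semi-axes must be equal so the plane fan stays
#'   analytic); default a 50 mm sphere.
#' @param spacing_mm isotropic voxel edge length (default 1).
#' @param portal_z_mm height of the portal plane (default 0, through the
#'   centre).
#' @param r_caudate_mm caudate cylinder radius used by the oracle and
#'   intended for [label_segments()] (default 15; 0 disables).
#' @param tumours list of `list(centre = c(x, y, z), radius = r)` spheres
#'   (mm), each strictly inside the liver.
#' @param pad_mm empty margin around the liver (default 4; use a negative
#'   offset via `clip_z_mm` to study field-of-view truncation).
#' @param clip_z_mm optional scalar: grid is cut at `z > clip_z_mm`,
#'   truncating the phantom (for field-of-view tests).
#' @return list with `liver` ([voxel_volume()] mask), `landmarks`
#'   ([landmark_set()]), `tumours` (named list of masks), `analytic`
#'   (data.frame segment/volume_ml), `analytic_total_ml`, `params`.
#' @export
make_phantom <- function(radii_mm = 50, spacing_mm = 1, portal_z_mm = 0,
                         r_caudate_mm = 15, tumours = list(), pad_mm = 4,
                         clip_z_mm = NULL) {
  radii <- as.double(radii_mm)
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  stopifnot(length(radii) == 3L, all(radii > 0))
  if (abs(radii[1] - radii[2]) > 1e-9) {
    stop("x and y semi-axes must be equal (spheroid phantom)", call. = FALSE)
  }
  if (any(radii < 2 * spacing_mm)) {
    stop("radii must exceed twice the voxel spacing", call. = FALSE)
  }
  a <- radii[1]; cz <- radii[3]

  lo <- -(radii + pad_mm)
  hi <- radii + pad_mm
  if (!is.null(clip_z_mm)) hi[3] <- min(hi[3], clip_z_mm)
  n <- pmax(ceiling((hi - lo) / spacing_mm), 1)
  # voxel centre of index (0,0,0) sits at lo + spacing/2
  transform <- diag(c(rep(spacing_mm, 3), 1))
  transform[1:3, 4] <- lo + spacing_mm / 2

  xs <- lo[1] + spacing_mm * (seq_len(n[1]) - 0.5)
  ys <- lo[2] + spacing_mm * (seq_len(n[2]) - 0.5)
  zs <- lo[3] + spacing_mm * (seq_len(n[3]) - 0.5)
  ell <- outer(outer((xs / a)^2, (ys / a)^2, "+"), (zs / cz)^2, "+")
  mask <- array(as.integer(ell <= 1), n)
  liver <- voxel_volume(mask, spacing = rep(spacing_mm, 3),
                        transform = transform, kind = "mask")

  az <- function(deg, rho, z) {
    th <- .deg2rad(deg)
    c(rho * cos(th), rho * sin(th), z)
  }
  lms <- landmark_set(list(
    ivc_inferior = c(0, 0, -(cz + 2)),
    ivc_superior = c(0, 0, cz + 2),
    rhv = az(90, 0.8 * a, 0.5 * cz),
    mhv = az(120, 0.8 * a, 0.5 * cz),
    lhv = az(180, 0.8 * a, 0.5 * cz),
    umbilical_fissure = az(60, 0.4 * a, -0.2 * cz),
    gallbladder_fossa = az(60, 0.8 * a, -0.4 * cz),
    portal_left = az(180, 0.2 * a, portal_z_mm),
    portal_right = az(0, 0.2 * a, portal_z_mm)
  ))

  tum_masks <- list()
  if (length(tumours)) {
    if (is.null(names(tumours)) || any(names(tumours) == "")) {
      names(tumours) <- paste0("tumour", seq_along(tumours))
    }
    for (nm in names(tumours)) {
      tu <- tumours[[nm]]
      ctr <- as.double(tu$centre); rad <- as.double(tu$radius)
      lam <- sqrt(sum((ctr / radii)^2))
      if (lam + rad / min(radii) > 1) {
        stop("tumour '", nm, "' is not inside the phantom liver",
             call. = FALSE)
      }
      d2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"),
                  (zs - ctr[3])^2, "+")
      tm <- array(as.integer(d2 <= rad^2 & ell <= 1), n)
      tum_masks[[nm]] <- voxel_volume(tm, spacing = rep(spacing_mm, 3),
                                      transform = transform, kind = "mask")
    }
  }

  # oracle: compute on the sphere of radius a (z scaled by a/cz), rescale
  zp_s <- portal_z_mm * a / cz
  segs <- .sphere_segment_volumes(a, zp = zp_s, rc = r_caudate_mm,
                                  caudate = r_caudate_mm > 0) * (cz / a)
  analytic <- data.frame(segment = 1:8, volume_ml = unname(segs) / 1000)

  list(liver = liver, landmarks = lms, tumours = tum_masks,
       analytic = analytic,
       analytic_total_ml = 4 / 3 * pi * a^2 * cz / 1000,
       params = list(radii_mm = radii, spacing_mm = spacing_mm,
                     portal_z_mm = portal_z_mm,
                     r_caudate_mm = r_caudate_mm))
}
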