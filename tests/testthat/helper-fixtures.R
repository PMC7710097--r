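# Shared fixtures, built in code. The coarse (2 mm) phantom is cached per
# session because several files exercise the same geometry.

phantom_2mm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom(radii_mm = 50, spacing_mm = 2)
    cache
  }
})

# axis-aligned cube mask of side `side_mm` centred at the origin
cube_mask <- function(side_mm = 60, spacing_mm = 1, pad_mm = 2) {
  half <- side_mm / 2
  lo <- -(half + pad_mm)
  n <- ceiling((half + pad_mm) * 2 / spacing_mm)
  transform <- diag(c(rep(spacing_mm, 3), 1))
  transform[1:3, 4] <- rep(lo + spacing_mm / 2, 3)
  g <- lo + spacing_mm * (seq_len(n) - 0.5)
  inside <- abs(g) <= half
  m <- array(0L, rep(n, 3))
  m[inside, inside, inside] <- 1L
  voxel_volume(m, spacing = rep(spacing_mm, 3), transform = transform,
               kind = "mask")
}

# spherical mask on the grid of `vol`
sphere_on_grid <- function(vol, centre, radius) {
  idx <- which(array(TRUE, dim(vol$data)), arr.ind = TRUE)
  mm <- liverplanr:::voxel_centres_mm(vol, idx)
  d2 <- rowSums(sweep(mm, 2, centre)^2)
  m <- array(0L, dim(vol$data))
  m[idx[d2 <= radius^2, , drop = FALSE]] <- 1L
  voxel_volume(m, spacing = vol$spacing, transform = vol$transform,
               kind = "mask")
}

# random rigid rotation (3x3) from a seeded draw
random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),   2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 + c^2 - b^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),   a^2 + d^2 - b^2 - c^2
  ), 3, 3, byrow = TRUE)
}

# complete 5-day bloods data.frame in SI units
bloods_df <- function(inr, bili, creat, days = 1:5) {
  data.frame(day = days, inr = inr, bilirubin_umol_l = bili,
             creatinine_umol_l = creat)
}
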