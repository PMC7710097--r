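# Volume container, NIfTI round-trips, volume arithmetic and the
# field-of-view exclusion rule.

test_that("voxel_volume enforces its invariants", {
  arr <- array(0, c(3, 3, 3))
  expect_s3_class(voxel_volume(arr, spacing = 1, kind = "mask"),
                  "voxel_volume")
  expect_error(voxel_volume(arr, spacing = c(1, -1, 1), kind = "mask"),
               "positive")
  bad <- arr; bad[1] <- 2
  expect_error(voxel_volume(bad, spacing = 1, kind = "mask"), "\\{0, 1\\}")
  expect_error(voxel_volume(bad * -1, spacing = 1, kind = "labelmap"),
               "non-negative")
  expect_error(voxel_volume(arr, spacing = 1,
                            transform = matrix(0, 4, 4), kind = "mask"),
               "invertible")
})

test_that("mask volume arithmetic uses the voxel volume", {
  m <- array(0L, c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- 1L
  expect_equal(mask_volume_ml(voxel_volume(m, spacing = 1, kind = "mask")),
               1.0)
  expect_equal(mask_volume_ml(voxel_volume(array(0L, c(4, 4, 4)),
                                           spacing = 1, kind = "mask")), 0)
  m2 <- array(0L, c(10, 10, 10)); m2[seq_len(500)] <- 1L
  expect_equal(mask_volume_ml(voxel_volume(m2, spacing = 2, kind = "mask")),
               4.0)                           # 500 * 8 mm^3 / 1000
  # non-uniform spacing: 3 mm slices count 3 mm^3 per voxel
  m3 <- array(1L, c(5, 5, 5))
  expect_equal(mask_volume_ml(voxel_volume(m3, spacing = c(1, 1, 3),
                                           kind = "mask")), 125 * 3 / 1000)
})

test_that("volume is invariant to translation and axis permutation", {
  m <- array(0L, c(6, 8, 10)); m[2:4, 3:6, 2:9] <- 1L
  v1 <- voxel_volume(m, spacing = c(1, 2, 3), kind = "mask")
  tr <- diag(c(1, 2, 3, 1)); tr[1:3, 4] <- c(50, -20, 7)
  v2 <- voxel_volume(m, spacing = c(1, 2, 3), transform = tr, kind = "mask")
  v3 <- voxel_volume(aperm(m, c(3, 1, 2)), spacing = c(3, 1, 2),
                     kind = "mask")
  expect_equal(mask_volume_ml(v1), mask_volume_ml(v2))
  expect_equal(mask_volume_ml(v1), mask_volume_ml(v3))
})

test_that("NIfTI write/read round-trips data, spacing and transform", {
  withr::with_tempdir({
    m <- array(0L, c(4, 5, 6)); m[2:3, 2:4, 3:5] <- 1L
    tr <- diag(c(1, 1, 3, 1)); tr[1:3, 4] <- c(-10, 4.5, 2)
    v <- voxel_volume(m, transform = tr, kind = "mask")
    for (f in c("v.nii", "v.nii.gz")) {
      write_volume(v, f)
      r <- read_volume(f, kind = "mask")
      expect_equal(r$data, m, ignore_attr = TRUE)
      expect_equal(r$spacing, c(1, 1, 3))
      expect_equal(r$transform, tr, tolerance = 1e-6)
    }
    # float maps survive losslessly (written as float64)
    mp <- array(rnorm(4 * 5 * 6) * 800, c(4, 5, 6))
    write_volume(voxel_volume(mp, spacing = c(2, 2, 2), kind = "ct1_ms"),
                 "map.nii.gz")
    r <- read_volume("map.nii.gz", kind = "ct1_ms")
    expect_equal(r$data, mp, ignore_attr = TRUE)
    expect_error(read_volume("absent.nii"), "absent.nii")
  })
})

test_that("NIfTI files interoperate with an independent reader/writer", {
  withr::with_tempdir({
    m <- array(0L, c(7, 6, 5)); m[2:6, 2:5, 2:4] <- 1L
    tr <- diag(c(1.5, 1.5, 2, 1)); tr[1:3, 4] <- c(-5, 0, 12)
    write_volume(voxel_volume(m, transform = tr, kind = "mask"), "ours.nii.gz")
    script <- '
import json, sys
import numpy as np, nibabel as nib
img = nib.load("ours.nii.gz")
d = np.asanyarray(img.dataobj)
print(json.dumps({"sum": float(d.sum()), "shape": list(d.shape),
                  "zooms": [float(z) for z in img.header.get_zooms()],
                  "aff": np.asarray(img.affine).tolist()}))
arr = np.zeros((4, 4, 4), dtype=np.int16); arr[1:3, 1:3, 1:3] = 1
nib.save(nib.Nifti1Image(arr, np.diag([2.0, 2.0, 2.0, 1.0])), "theirs.nii.gz")
'
    out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
    info <- jsonlite::fromJSON(out[length(out)])
    expect_equal(info$sum, sum(m))
    expect_equal(info$shape, dim(m))
    expect_equal(info$zooms, c(1.5, 1.5, 2))
    expect_equal(info$aff, tr, tolerance = 1e-5, ignore_attr = TRUE)
    theirs <- read_volume("theirs.nii.gz", kind = "mask")
    expect_equal(sum(theirs$data), 8)
    expect_equal(theirs$spacing, c(2, 2, 2))
  })
})

test_that("4D NIfTI input is rejected", {
  withr::with_tempdir({
    script <- '
import numpy as np, nibabel as nib
nib.save(nib.Nifti1Image(np.zeros((3, 3, 3, 2), dtype=np.float32),
                         np.eye(4)), "vol4d.nii")
'
    system2("python", c("-c", shQuote(script)))
    expect_error(read_volume("vol4d.nii"), "[0-9] dimensions|only 3D")
  })
})

test_that("fov coverage: interior masks are fully covered", {
  ph <- phantom_2mm()
  res <- check_fov_coverage(ph$liver)
  expect_identical(res$status, "included")
  expect_identical(res$fraction, 0)
})

test_that("fov coverage estimates the clipped fraction of a sphere", {
  # caps above z: fraction = pi*(r-z)^2*(2r+z)/3 / V
  cap_frac <- function(r, z) pi * (r - z)^2 * (2 * r + z) / 3 /
    (4 / 3 * pi * r^3)
  clipped <- make_phantom(radii_mm = 50, spacing_mm = 1, clip_z_mm = 35)
  res <- check_fov_coverage(clipped$liver)
  expect_identical(res$status, "excluded")     # 6.07% truncated
  expect_lt(abs(res$fraction - cap_frac(50, 35)), 0.01)
  mild <- make_phantom(radii_mm = 50, spacing_mm = 1, clip_z_mm = 38)
  res2 <- check_fov_coverage(mild$liver)
  expect_identical(res2$status, "included")    # 3.97% truncated
  expect_lt(abs(res2$fraction - cap_frac(50, 38)), 0.01)
})

test_that("fov exclusion rule is strictly 'more than 5%'", {
  expect_identical(liverplanr:::.fov_status(0.05), "included")
  expect_identical(liverplanr:::.fov_status(0.05 + 1e-9), "excluded")
  expect_identical(liverplanr:::.fov_status(0), "included")
})

test_that("landmark and cohort CSV schemas are validated", {
  withr::with_tempdir({
    ph <- phantom_2mm()
    write_landmarks(ph$landmarks, "lm.csv")
    lm2 <- read_landmarks("lm.csv")
    expect_equal(unclass(lm2), unclass(ph$landmarks), tolerance = 1e-12)
    df <- utils::read.csv("lm.csv")
    utils::write.csv(df[df$name != "mhv", ], "bad.csv", row.names = FALSE)
    expect_error(read_landmarks("bad.csv"), "mhv")
    utils::write.csv(df[, -2], "bad2.csv", row.names = FALSE)
    expect_error(read_landmarks("bad2.csv"), "x_mm")

    co <- synthetic_cohort(12, seed = 7)
    write_cohort(co$cohort, "cohort.csv")
    back <- read_cohort("cohort.csv")
    expect_s3_class(back, "liver_cohort")
    expect_equal(nrow(back), nrow(co$cohort))
    expect_match(attr(back, "units")[["bilirubin"]], "umol/L")
    broken <- as.data.frame(co$cohort)
    broken$bilirubin_umol_l <- NULL
    utils::write.csv(broken, "broken.csv", row.names = FALSE)
    expect_error(read_cohort("broken.csv"), "bilirubin_umol_l")
  })
})
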