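test_that("SUV statistics agree with a naive reference on the value list", {
  a <- array(1, c(6, 6, 6))
  a[1:3, 1, 1] <- c(2.5, 3.5, 4.5)
  v <- pet_volume(a, units = "suv")
  m <- array(FALSE, dim(a)); m[1:3, 1, 1] <- TRUE
  s <- suv_statistics(v, region_from_mask(m))
  expect_equal(s$suv_max, 4.5)
  expect_equal(s$suv_min, 2.5)
  expect_equal(s$suv_mean, 3.5)
  expect_equal(s$suv_median, 3.5)
  expect_equal(s$suv_range, 2.0)

  # random regions, full naive recomputation
  set.seed(5)
  for (rep in 1:5) {
    vals <- runif(40, 2.5, 9)
    a <- array(0, c(6, 6, 6)); a[1:40] <- vals
    v <- pet_volume(a, units = "suv")
    m <- array(FALSE, c(6, 6, 6)); m[1:40] <- TRUE
    s <- suv_statistics(v, region_from_mask(m))
    mu <- mean(vals); m2 <- mean((vals - mu)^2)
    expect_equal(s$suv_mean, mu)
    expect_equal(s$suv_variance, m2)
    expect_equal(s$suv_sd, sqrt(m2))
    expect_equal(s$suv_energy, sum(vals^2))
    expect_equal(s$suv_mad, mean(abs(vals - mu)))
    expect_equal(s$suv_rms, sqrt(mean(vals^2)))
    expect_equal(s$suv_skewness, mean((vals - mu)^3) / m2^1.5)
    expect_equal(s$suv_kurtosis, mean((vals - mu)^4) / m2^2)
    p <- as.vector(table(quantize_suv(vals))) / 40
    expect_equal(s$suv_entropy, -sum(p * log2(p)))
    expect_equal(s$suv_uniformity, sum(p^2))
  }
})

test_that("degenerate SUV statistics follow the documented conventions", {
  a <- array(4.4, c(4, 4, 4))
  v <- pet_volume(a, units = "suv")
  m <- array(FALSE, dim(a)); m[1:9] <- TRUE
  s <- suv_statistics(v, region_from_mask(m))
  expect_equal(s$suv_variance, 0)
  expect_equal(s$suv_sd, 0)
  expect_equal(s$suv_mad, 0)
  expect_equal(s$suv_entropy, 0)
  expect_equal(s$suv_uniformity, 1)
  expect_equal(s$suv_rms, 4.4)
  expect_equal(s$suv_skewness, 0)
  expect_equal(s$suv_kurtosis, 0)

  # mirroring values about the mean flips the skewness sign
  vals <- c(3, 3, 3, 8)
  a1 <- array(0, c(4, 4, 4)); a1[1:4] <- vals
  a2 <- array(0, c(4, 4, 4)); a2[1:4] <- 2 * mean(vals) - vals
  m4 <- array(FALSE, c(4, 4, 4)); m4[1:4] <- TRUE
  s1 <- suv_statistics(pet_volume(a1, units = "suv"), region_from_mask(m4))
  s2 <- suv_statistics(pet_volume(a2, units = "suv"), region_from_mask(m4))
  expect_equal(s1$suv_skewness, -s2$suv_skewness)
})

test_that("NGTDM features match brute-force enumeration exactly", {
  # constant region: guarded degenerate values
  v <- make_block_volume(value = 6)
  m <- v$voxels == 6
  f <- ngtdm_features(v, region_from_mask(m))
  expect_equal(f$ngtdm_coarseness, 1e6)
  expect_equal(f$ngtdm_contrast, 0)
  expect_equal(f$ngtdm_busyness, 0)
  expect_equal(f$ngtdm_complexity, 0)

  # hand-built two-tone region
  a <- array(2.6, c(3, 3, 3))
  a[c(1, 5, 9, 14, 22)] <- 4.1
  v2 <- pet_volume(a, units = "suv")
  m2 <- array(TRUE, c(3, 3, 3))
  got <- ngtdm_features(v2, region_from_mask(m2))
  want <- oracle_ngtdm_features(oracle_ngtdm(quantize_suv(a), m2))
  expect_equal(got$ngtdm_coarseness, want[1], tolerance = 1e-12)
  expect_equal(got$ngtdm_contrast, want[2], tolerance = 1e-12)
  expect_equal(got$ngtdm_busyness, want[3], tolerance = 1e-12)
  expect_equal(got$ngtdm_complexity, want[4], tolerance = 1e-12)

  # random regions up to 4x4x4
  set.seed(13)
  for (rep in 1:10) {
    dm <- c(4, 4, 4)
    a <- array(runif(64, 2.5, 7.5), dm)
    inside <- array(runif(64) < 0.6, dm)
    if (sum(inside) < 2) next
    v3 <- pet_volume(a, units = "suv")
    o <- oracle_ngtdm(quantize_suv(a), inside)
    if (o$n_valid == 0) next
    got <- ngtdm_features(v3, region_from_mask(inside))
    want <- oracle_ngtdm_features(o)
    expect_equal(got$ngtdm_coarseness, want[1], tolerance = 1e-10)
    expect_equal(got$ngtdm_contrast, want[2], tolerance = 1e-10)
    expect_equal(got$ngtdm_busyness, want[3], tolerance = 1e-10)
    expect_equal(got$ngtdm_complexity, want[4], tolerance = 1e-10)
  }
})

test_that("NGTDM features are invariant under 90-degree rotation about z", {
  set.seed(17)
  a <- array(runif(5 * 5 * 3, 2.5, 7), c(5, 5, 3))
  inside <- array(runif(75) < 0.6, c(5, 5, 3))
  inside[1, 1, 1] <- TRUE; inside[2, 1, 1] <- TRUE
  rot <- function(x) aperm(x, c(2, 1, 3))[, rev(seq_len(dim(x)[1])), ,
                                          drop = FALSE]
  v1 <- pet_volume(a, units = "suv")
  v2 <- pet_volume(rot(a), units = "suv")
  f1 <- ngtdm_features(v1, region_from_mask(inside))
  f2 <- ngtdm_features(v2, region_from_mask(rot(inside)))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("outside difference contrasts the region with its shell", {
  v <- make_block_volume(lo = c(4, 4, 4), hi = c(6, 6, 6), value = 6, bg = 2)
  m <- v$voxels == 6
  r <- region_from_mask(m)
  expect_equal(outside_difference(v, r), 4.0)

  # identical levels inside and out -> 0
  v0 <- make_block_volume(value = 3, bg = 3)
  expect_equal(outside_difference(v0, region_from_mask(v0$voxels > 0 &
    array(seq_len(1000) <= 27, c(10, 10, 10)))), 0)

  # swapping levels flips the sign
  vs <- make_block_volume(lo = c(4, 4, 4), hi = c(6, 6, 6), value = 2, bg = 6)
  expect_equal(outside_difference(vs, r), -4.0)

  # other regions' voxels are excluded from the shell
  lab <- array(0L, dim(v$voxels))
  lab[m] <- 1L
  lab[7, 4:6, 4:6] <- 2L               # a second region hugging the first
  v2 <- v
  v2$voxels[7, 4:6, 4:6] <- 100        # would wreck the shell mean if counted
  expect_equal(outside_difference(v2, r, labels = lab), 4.0)
})

test_that("shape features behave on canonical solids", {
  # single voxel at 4 mm: 0.064 ml, 6 faces of 16 mm^2, zero diameter
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  r <- region_from_mask(m)
  s <- shape_features(r)
  expect_equal(s$volume_ml, 0.064)
  expect_equal(s$surface_area_mm2, 96)
  expect_equal(s$max_diameter, 0)
  expect_equal(s$surface_difference, 1)
  expect_equal(s$area_surface_ratio, 64 / 96)

  # digital ball is more compact than a same-volume rod
  ball <- array(FALSE, c(13, 13, 13))
  cc <- which(array(TRUE, c(13, 13, 13)), arr.ind = TRUE)
  ball[cc[rowSums((cc - 7)^2) <= 9, ]] <- TRUE
  nb <- sum(ball)
  rod <- array(FALSE, c(3, 3, nb))
  rod[2, 2, seq_len(nb)] <- TRUE
  sb <- shape_features(region_from_mask(ball))
  sr <- shape_features(region_from_mask(rod))
  expect_gt(sb$compactness, sr$compactness)

  # rod diameter equals its end-to-end physical length
  expect_equal(sr$max_diameter, (nb - 1) * 4)
  expect_true(sb$surface_difference > 0 && sb$surface_difference <= 1)

  # deterministic given the sampling seed
  s2 <- shape_features(region_from_mask(ball))
  expect_identical(sb, s2)
})

test_that("location features are normalized and axis-aligned shapes recover their axis", {
  dm <- c(21, 21, 41)
  ext <- list(x = c(1, 21), y = c(1, 21))
  b <- crop_boundaries(1, 41, TRUE, TRUE)
  m <- array(FALSE, dm); m[9:13, 9:13, 19:23] <- TRUE
  lf <- location_features(region_from_mask(m), b, ext)
  expect_equal(lf$centroid_x, 0.5, tolerance = 0.01)
  expect_equal(lf$centroid_y, 0.5, tolerance = 0.01)
  expect_equal(lf$centroid_z, 0.5, tolerance = 0.01)
  # isotropic block: degenerate tensor reports +z
  expect_equal(c(lf$major_axis_x, lf$major_axis_y, lf$major_axis_z),
               c(0, 0, 1))

  rodx <- array(FALSE, dm); rodx[3:19, 11, 21] <- TRUE
  lx <- location_features(region_from_mask(rodx), b, ext)
  expect_equal(abs(lx$major_axis_x), 1, tolerance = 1e-6)
  expect_equal(lx$major_axis_y, 0, tolerance = 1e-6)
  expect_equal(lx$major_axis_z, 0, tolerance = 1e-6)
  # sign fix: x component reported non-negative when z is 0
  expect_gte(lx$major_axis_x, 0)

  # axis is always unit length; centroids always within [0, 1]
  set.seed(3)
  for (rep in 1:5) {
    mm <- array(runif(prod(dm)) < 0.02, dm)
    if (!any(mm)) next
    l <- location_features(region_from_mask(mm), b, ext)
    expect_equal(l$major_axis_x^2 + l$major_axis_y^2 + l$major_axis_z^2, 1,
                 tolerance = 1e-9)
    expect_true(all(c(l$centroid_x, l$centroid_y, l$centroid_z) >= 0))
    expect_true(all(c(l$centroid_x, l$centroid_y, l$centroid_z) <= 1))
  }
})

test_that("size normalization follows the stated scaling laws", {
  fv <- list(volume_ml = 10, surface_area_mm2 = 2000, max_diameter = 30)
  n1 <- normalize_features(fv, body_length_mm = 600)
  expect_equal(n1$scaled_volume, 10 / 600^3 * 1e6)
  expect_equal(n1$scaled_surface_area, 2000 / 600^2 * 1e4)
  expect_equal(n1$max_diameter, 30 / 600)
  # doubling the body length halves the diameter feature
  n2 <- normalize_features(fv, body_length_mm = 1200)
  expect_equal(n2$max_diameter, n1$max_diameter / 2)
  expect_error(normalize_features(fv, body_length_mm = 0), "positive")
})

test_that("the same physical sphere yields consistent scaled volume across resolutions", {
  render_ball <- function(sp) {
    n <- round(120 / sp)
    cc <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
    m <- array(FALSE, c(n, n, n))
    m[cc[rowSums(((cc - (n + 1) / 2) * sp)^2) <= 25^2, ]] <- TRUE
    region_from_mask(m, spacing = rep(sp, 3))
  }
  r2 <- render_ball(2); r4 <- render_ball(4)
  v2 <- normalize_features(list(volume_ml = r2$volume_ml,
                                surface_area_mm2 = 0, max_diameter = 0),
                           600)$scaled_volume
  v4 <- normalize_features(list(volume_ml = r4$volume_ml,
                                surface_area_mm2 = 0, max_diameter = 0),
                           600)$scaled_volume
  expect_lt(abs(v2 - v4) / v2, 0.1)
})

test_that("the extractor returns exactly the 31 features, translation-invariant off-location", {
  expect_length(FEATURE_NAMES, 31)

  dm <- c(24, 20, 40)
  base <- array(1, dm)
  blk <- function(off) {
    a <- base
    a[(6:9) + off[1], (6:9) + off[2], (12:15) + off[3]] <-
      4 + array(seq(0, 1.5, length.out = 64), c(4, 4, 4))
    pet_volume(a, units = "suv")
  }
  b <- crop_boundaries(2, 39, TRUE, TRUE)
  f1 <- {
    v <- blk(c(0, 0, 0))
    lab <- array(0L, dm); lab[v$voxels >= 2.5] <- 1L
    extract_features(v, lab, label_regions(lab, v$spacing, "p1"), b)
  }
  f2 <- {
    v <- blk(c(5, 4, 9))
    lab <- array(0L, dm); lab[v$voxels >= 2.5] <- 1L
    extract_features(v, lab, label_regions(lab, v$spacing, "p1"), b)
  }
  expect_equal(ncol(f1), 3 + 31)
  expect_named(f1, c("patient_id", "region_id", "volume_ml", FEATURE_NAMES),
               ignore.order = FALSE)
  loc <- c("major_axis_x", "major_axis_y", "major_axis_z",
           "centroid_x", "centroid_y", "centroid_z")
  for (fn in setdiff(FEATURE_NAMES, loc))
    expect_equal(f1[[fn]], f2[[fn]], tolerance = 1e-9, label = fn)
  expect_false(isTRUE(all.equal(f1$centroid_z, f2$centroid_z)))
  expect_true(all(is.finite(as.matrix(f1[, FEATURE_NAMES]))))
})
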