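test_that("the SUV threshold is inclusive at the cut", {
  a <- array(1, c(4, 4, 4))
  a[1, 1, 1] <- 2.4; a[2, 2, 2] <- 2.5; a[3, 3, 3] <- 3.0
  v <- pet_volume(a, units = "suv")
  m <- threshold_mask(v)
  expect_false(m[1, 1, 1])
  expect_true(m[2, 2, 2])
  expect_true(m[3, 3, 3])
  expect_equal(sum(m), 2)

  expect_equal(sum(threshold_mask(pet_volume(array(0, c(3, 3, 3)),
                                             units = "suv"))), 0)
  expect_true(all(threshold_mask(v, t = 1e-9)))
})

test_that("watershed splits two bumps at the valley and partitions the mask", {
  dm <- c(30, 9, 9)
  x <- 1:30
  # wide bumps so the mask is one connected component with a valley at x=15
  prof <- 6 * exp(-(x - 8)^2 / 40) + 6 * exp(-(x - 22)^2 / 40)
  a <- array(rep(prof, times = 81), dm)
  v <- pet_volume(a, units = "suv")
  mask <- threshold_mask(v, 2.5)
  expect_gt(min(a[14:17, , ]), 2.5)
  lab <- watershed_segment(v, mask)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  expect_length(ids, 2)
  # every masked voxel carries a label; nothing outside the mask does
  expect_true(all(lab[mask] > 0))
  expect_true(all(lab[!mask] == 0))
  # each basin holds its own peak and the split falls in the valley
  expect_true(lab[8, 5, 5] != lab[22, 5, 5])
  xs <- which(apply(lab == lab[8, 5, 5], 1, any))
  ys <- which(apply(lab == lab[22, 5, 5], 1, any))
  boundary <- max(min(ys), min(xs))
  expect_gte(boundary, 14)
  expect_lte(boundary, 17)

  plateau <- pet_volume(array(5, c(4, 4, 4)), units = "suv")
  lab1 <- watershed_segment(plateau, threshold_mask(plateau))
  expect_equal(sort(unique(as.vector(lab1))), 1L)

  empty <- watershed_segment(v, array(FALSE, dm))
  expect_true(all(empty == 0L))
})

test_that("co-occurrence texture matches brute-force enumeration", {
  # constant region: all mass on one diagonal cell
  v <- make_block_volume(value = 5)
  lab <- array(0L, dim(v$voxels)); lab[v$voxels == 5] <- 1L
  tx <- glcm_texture(v, lab, 1L)
  expect_equal(tx$contrast, 0)
  expect_equal(tx$entropy, 0)
  expect_equal(tx$inverse_difference_moment, 1)
  expect_equal(tx$aggregated, 1 / 3)

  # random small regions: exact agreement with the oracle
  set.seed(21)
  for (rep in 1:8) {
    dm <- c(5, 5, 5)
    a <- array(runif(125, 2.5, 8), dm)
    inside <- array(runif(125) < 0.55, dm)
    if (sum(inside) < 3) next
    v <- pet_volume(a, units = "suv")
    lab <- array(0L, dm); lab[inside] <- 1L
    got <- glcm_texture(v, lab, 1L)
    want <- oracle_glcm(quantize_suv(a), inside)
    expect_equal(got$contrast, want$contrast, tolerance = 1e-12)
    expect_equal(got$entropy, want$entropy, tolerance = 1e-12)
    expect_equal(got$inverse_difference_moment, want$idm, tolerance = 1e-12)
    expect_equal(got$n_pairs, want$n)
  }

  solo <- array(0L, c(3, 3, 3)); solo[2, 2, 2] <- 1L
  v1 <- pet_volume(array(5, c(3, 3, 3)), units = "suv")
  expect_error(glcm_texture(v1, solo, 1L), "texture undefined")
})

test_that("texture merging is strict, adjacency-limited and monotone", {
  # two adjacent constant blocks of identical value: aggregated diff 0 -> merge
  a <- array(1, c(8, 4, 4))
  a[2:4, 2:3, 2:3] <- 5
  a[5:7, 2:3, 2:3] <- 5
  v <- pet_volume(a, units = "suv")
  lab <- array(0L, dim(a))
  lab[2:4, 2:3, 2:3] <- 1L
  lab[5:7, 2:3, 2:3] <- 2L
  merged <- texture_merge(lab, v, threshold = 2)
  expect_length(setdiff(unique(as.vector(merged)), 0L), 1)
  # voxel count conserved
  expect_equal(sum(merged > 0), sum(lab > 0))

  # the merge inequality is strict: threshold equal to the actual difference
  # must not merge, threshold just above must
  b <- array(1, c(8, 4, 4))
  b[2:4, 2:3, 2:3] <- 5
  b[5:7, 2:3, 2:3] <- c(5, 9, 5, 9, 5, 9, 5, 9, 5, 9, 5, 9)
  vb <- pet_volume(b, units = "suv")
  t1 <- glcm_texture(vb, lab, 1L)
  t2 <- glcm_texture(vb, lab, 2L)
  d <- abs(t1$aggregated - t2$aggregated)
  expect_gt(d, 0)
  at <- texture_merge(lab, vb, threshold = d)
  expect_length(setdiff(unique(as.vector(at)), 0L), 2)
  above <- texture_merge(lab, vb, threshold = d + 1e-9)
  expect_length(setdiff(unique(as.vector(above)), 0L), 1)

  # non-adjacent regions are never merged
  c3 <- array(1, c(9, 4, 4))
  c3[2:3, 2:3, 2:3] <- 5
  c3[6:7, 2:3, 2:3] <- 5
  vc <- pet_volume(c3, units = "suv")
  labc <- array(0L, dim(c3))
  labc[2:3, 2:3, 2:3] <- 1L
  labc[6:7, 2:3, 2:3] <- 2L
  mc <- texture_merge(labc, vc, threshold = 10)
  expect_length(setdiff(unique(as.vector(mc)), 0L), 2)
})

test_that("the volume filter keeps regions of at least the minimum size", {
  dm <- c(10, 10, 10)
  mk <- function(n) {
    m <- array(FALSE, dm); m[seq_len(n)] <- TRUE
    region_from_mask(m, spacing = c(4, 4, 4))
  }
  r31 <- mk(31)   # 31 * 0.064 = 1.984 ml
  r32 <- mk(32)   # 2.048 ml
  expect_equal(r31$volume_ml, 1.984)
  kept <- filter_small(list(r31, r32), min_ml = 2)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$volume_ml, 2.048)

  # volume of exactly the threshold is kept
  m <- array(FALSE, c(10, 10, 10)); m[1:2] <- TRUE
  r2 <- region_from_mask(m, spacing = c(10, 10, 10))  # 2 * 1.0 ml
  expect_length(filter_small(list(r2), min_ml = 2), 1)

  expect_length(filter_small(list(), 2), 0)
})

test_that("watershed plus merge partitions random masks; merging never increases labels", {
  set.seed(31)
  for (rep in 1:10) {
    dm <- c(12, 12, 12)
    a <- array(runif(prod(dm), 0, 6), dm)
    v <- gaussian_smooth(pet_volume(a, units = "suv"), 1)
    mask <- threshold_mask(v, 2.5)
    if (!any(mask)) next
    lab <- watershed_segment(v, mask)
    expect_true(all(lab[mask] > 0))
    expect_true(all(lab[!mask] == 0))
    merged <- texture_merge(lab, v, threshold = 2)
    expect_true(all((merged > 0) == (lab > 0)))
    expect_lte(length(unique(merged[merged > 0])),
               length(unique(lab[lab > 0])))
  }
})

test_that("well-separated hot blobs come out as exactly K regions end to end", {
  for (K in c(1, 3, 5)) {
    spec <- phantom_spec(
      dim = c(60L, 45L, 120L), spacing = c(4, 4, 4), seed = 100L + K,
      classes = list(T = list(prob = 1, n_if_present = K, suv_mean = 8,
                              suv_sd = 0.5, vol_ml = c(5, 8),
                              z_prior = NULL, z_range = c(0.15, 0.85),
                              lateral = "any", shape = "ellipsoid",
                              texture_sd = 0.1)))
    ph <- generate_phantom(spec)
    v <- gaussian_smooth(ph$vol, 2)
    lab <- texture_merge(watershed_segment(v, threshold_mask(v)), v)
    regions <- filter_small(label_regions(lab, v$spacing), 2)
    expect_length(regions, K)
  }
})
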