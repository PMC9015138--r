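#' SUV threshold mask
#'
#' All voxels with an SUV below the threshold are excluded from segmentation;
#' the mask is `TRUE` exactly where `SUV >= t`. The default 2.5 is a
#' sensitive fixed threshold chosen to include all potential tumor lesions.
#'
#' @param vol a [pet_volume()] in SUV units.
#' @param t SUV threshold (> 0, default 2.5).
#' @return Logical 3-D array.
#' @export
threshold_mask <- function(vol, t = 2.5) {
  assert_pet_volume(vol)
  if (vol$units != "suv") stopf("threshold_mask expects an SUV volume")
  if (!is.finite(t) || t <= 0) stopf("threshold must be positive")
  vol$voxels >= t
}

#' Watershed segmentation of the masked SUV volume
#'
#' Classic flooding watershed on the inverted SUV topography inside the mask:
#' catchment basins are seeded at the regional maxima (26-connectivity) and
#' flooding proceeds in descending SUV order until every masked voxel belongs
#' to a basin. Voxels reachable from more than one basin (watershed-line
#' voxels) are assigned to the neighbouring basin with the higher SUV
#' maximum, so the final labels partition the mask.
#'
#' @param vol a [pet_volume()] in SUV units (typically already denoised).
#' @param mask logical array from [threshold_mask()].
#' @return Integer 3-D array of basin labels; background is 0.
#' @export
watershed_segment <- function(vol, mask) {
  assert_pet_volume(vol)
  if (!identical(dim(mask), dim(vol$voxels)))
    stopf("mask dimensions do not match the volume")
  if (!any(mask)) {
    return(array(0L, dim(vol$voxels)))
  }
  cpp_watershed(as.numeric(vol$voxels), as.logical(mask), dim(vol$voxels))
}

#' Quantize SUV values to grey-tone bins
#'
#' Fixed-width binning in absolute SUV units: bin 1 covers
#' `[base, base + width)`, bin 2 the next interval, and so on; values below
#' `base` fall into bin 1. Absolute binning keeps texture comparable across
#' scans and scanners, consistent with the absolute SUV segmentation
#' threshold.
#'
#' @param values numeric vector or array of SUV values.
#' @param base lower edge of bin 1 (default 2.5, the segmentation threshold).
#' @param width bin width in SUV (default 0.5).
#' @return Integer bins with the same shape as `values`.
#' @export
quantize_suv <- function(values, base = 2.5, width = 0.5) {
  b <- floor((values - base) / width) + 1L
  b[b < 1L] <- 1L
  storage.mode(b) <- "integer"
  b
}

#' Co-occurrence texture summary of one region
#'
#' Symmetric grey-level co-occurrence counts over all 26 direction offsets at
#' distance one, restricted to voxel pairs both inside the region, normalized
#' to probabilities `p(i, j)`. Returns contrast `sum (i-j)^2 p`, entropy
#' `-sum p log2 p`, inverse difference moment `sum p / (1 + (i-j)^2)`, and
#' their mean as the aggregated texture measure used for region merging.
#'
#' @param vol a [pet_volume()] in SUV units.
#' @param labels integer label array.
#' @param region_id the label to summarize.
#' @param base,width quantization, see [quantize_suv()].
#' @return List with `contrast`, `entropy`, `inverse_difference_moment`,
#'   `aggregated`, `n_pairs`.
#' @export
glcm_texture <- function(vol, labels, region_id, base = 2.5, width = 0.5) {
  assert_pet_volume(vol)
  bins <- quantize_suv(vol$voxels, base = base, width = width)
  idx <- which(as.integer(labels) == as.integer(region_id))
  s <- cpp_glcm_summary(as.integer(bins), as.integer(labels),
                        as.integer(region_id), dim(vol$voxels),
                        as.integer(idx))
  if (s[4] == 0)
    stopf("region %d has no interior voxel pairs; texture undefined",
          region_id)
  list(contrast = s[1], entropy = s[2], inverse_difference_moment = s[3],
       aggregated = mean(s[1:3]), n_pairs = s[4])
}

# aggregated texture for every label; NA where no interior pairs exist
aggregated_textures <- function(bins, labels, idx_by_id, dm) {
  vapply(names(idx_by_id), function(id) {
    s <- cpp_glcm_summary(bins, labels, as.integer(id), dm,
                          idx_by_id[[id]])
    if (s[4] == 0) NA_real_ else mean(s[1:3])
  }, numeric(1))
}

#' Merge neighbouring regions of similar texture
#'
#' Adjacent (26-connected) regions whose aggregated texture measures differ
#' by strictly less than `threshold` are merged. Merging is best-first: the
#' currently most similar adjacent pair is merged, the merged region's
#' texture is recomputed, and the process repeats until no adjacent pair
#' qualifies. Regions too small to define a texture are never merged.
#'
#' @param labels integer label array from [watershed_segment()].
#' @param vol the matching [pet_volume()] in SUV units.
#' @param threshold merge threshold on the absolute aggregated-texture
#'   difference (default 2; strict inequality).
#' @param base,width quantization, see [quantize_suv()].
#' @return Relabelled integer array; the label count never increases.
#' @export
texture_merge <- function(labels, vol, threshold = 2.0,
                          base = 2.5, width = 0.5) {
  assert_pet_volume(vol)
  dm <- dim(vol$voxels)
  lab <- as.integer(labels)
  bins <- as.integer(quantize_suv(vol$voxels, base = base, width = width))
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) < 2) {
    out <- array(lab, dm)
    return(out)
  }
  idx_by_id <- split(seq_along(lab)[lab > 0L], lab[lab > 0L])
  idx_by_id <- lapply(idx_by_id, as.integer)
  agg <- aggregated_textures(bins, lab, idx_by_id, dm)
  pairs <- cpp_adjacent_pairs(lab, dm)

  repeat {
    if (nrow(pairs) == 0) break
    d <- abs(agg[as.character(pairs[, 1])] - agg[as.character(pairs[, 2])])
    cand <- which(!is.na(d) & d < threshold)
    if (length(cand) == 0) break
    k <- cand[order(d[cand], pairs[cand, 1], pairs[cand, 2])][1]
    a <- pairs[k, 1]; b <- pairs[k, 2]
    ka <- as.character(a); kb <- as.character(b)
    lab[idx_by_id[[kb]]] <- a
    idx_by_id[[ka]] <- c(idx_by_id[[ka]], idx_by_id[[kb]])
    idx_by_id[[kb]] <- NULL
    # recompute merged texture, rewire adjacency of b to a
    s <- cpp_glcm_summary(bins, lab, a, dm, idx_by_id[[ka]])
    agg[[ka]] <- if (s[4] == 0) NA_real_ else mean(s[1:3])
    agg <- agg[names(agg) != kb]
    pairs[pairs == b] <- a
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > 0) {
      lo <- pmin(pairs[, 1], pairs[, 2])
      hi <- pmax(pairs[, 1], pairs[, 2])
      pairs <- unique(cbind(lo, hi))
    }
  }
  array(lab, dm)
}

#' A segmented region
#'
#' A connected set of voxels produced by segmentation, with its physical
#' volume and z extent.
#'
#' @param region_id integer label.
#' @param idx 1-based linear voxel indices into the parent grid.
#' @param dim parent grid dimensions.
#' @param spacing voxel spacing in mm.
#' @param patient_id scan identifier.
#' @return An object of class `segmented_region` with fields `region_id`,
#'   `idx`, `coords` (voxel coordinates), `dim`, `spacing`, `volume_ml`,
#'   `z_range`, `patient_id`.
#' @export
segmented_region <- function(region_id, idx, dim, spacing,
                             patient_id = NA_character_) {
  if (length(idx) == 0) stopf("a segmented region cannot be empty")
  coords <- idx_to_coord(as.integer(idx), dim)
  structure(
    list(region_id = as.integer(region_id), idx = as.integer(idx),
         coords = coords, dim = as.integer(dim),
         spacing = as.numeric(spacing),
         volume_ml = length(idx) * prod(spacing) / 1000,
         z_range = range(coords[, 3]),
         patient_id = patient_id),
    class = "segmented_region"
  )
}

#' @export
print.segmented_region <- function(x, ...) {
  cat(sprintf("<segmented_region> id %d: %d voxels, %.2f ml, z %d..%d\n",
              x$region_id, length(x$idx), x$volume_ml,
              x$z_range[1], x$z_range[2]))
  invisible(x)
}

#' Extract region objects from a label array
#'
#' @param labels integer label array (0 = background).
#' @param spacing voxel spacing in mm.
#' @param patient_id scan identifier attached to every region.
#' @return List of [segmented_region()] objects, ordered by label.
#' @export
label_regions <- function(labels, spacing, patient_id = NA_character_) {
  dm <- dim(labels)
  lab <- as.integer(labels)
  ids <- sort(unique(lab[lab > 0L]))
  idx_by_id <- split(seq_along(lab)[lab > 0L], lab[lab > 0L])
  lapply(ids, function(id) {
    segmented_region(id, idx_by_id[[as.character(id)]], dm, spacing,
                     patient_id)
  })
}

#' Drop regions below the minimum volume
#'
#' Volumes smaller than `min_ml` are excluded from further analysis; a region
#' of exactly `min_ml` is kept.
#'
#' @param regions list of [segmented_region()] objects.
#' @param min_ml minimum volume in ml (default 2.0).
#' @return Filtered list.
#' @export
filter_small <- function(regions, min_ml = 2.0) {
  if (!is.finite(min_ml) || min_ml <= 0) stopf("min_ml must be positive")
  regions[vapply(regions, function(r) r$volume_ml >= min_ml, logical(1))]
}
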