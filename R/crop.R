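#' Crop boundaries along the scan axis
#'
#' Result of the heuristic z-axis cropping: the slice indices of the cranial
#' anchor (brain level) and the caudal anchor (urinary-bladder level), with
#' flags recording whether each was found.
#'
#' @param z_top,z_bottom slice indices (NA when not found).
#' @param top_found,bottom_found logical status flags.
#' @return An object of class `crop_boundaries`.
#' @export
crop_boundaries <- function(z_top = NA_integer_, z_bottom = NA_integer_,
                            top_found = FALSE, bottom_found = FALSE) {
  if (top_found && bottom_found && !(z_top < z_bottom))
    stopf("z_top must be strictly above (smaller than) z_bottom")
  structure(list(z_top = as.integer(z_top), z_bottom = as.integer(z_bottom),
                 top_found = top_found, bottom_found = bottom_found),
            class = "crop_boundaries")
}

#' @export
print.crop_boundaries <- function(x, ...) {
  cat(sprintf("<crop_boundaries> top: %s (found: %s), bottom: %s (found: %s)\n",
              x$z_top, x$top_found, x$z_bottom, x$bottom_found))
  invisible(x)
}

#' Sagittal-axis maximum projection (xz-plane)
#'
#' First step of the cropping heuristic: the SUV volume is projected onto the
#' xz-plane by taking the maximum along the antero-posterior (y) axis.
#'
#' @param vol a [pet_volume()] in SUV units.
#' @return Numeric matrix with x rows and z columns.
#' @export
project_xz <- function(vol) {
  assert_pet_volume(vol)
  apply(vol$voxels, c(1, 3), max)
}

#' Remove lateral extremities from an xz projection
#'
#' Arms raised or resting beside the body produce lateral uptake columns that
#' would distort the z-profile. The heuristic keeps a symmetric band around
#' the body axis: the x column with the largest summed intensity is taken as
#' the body centre, and a band covering `band_frac` of the image width around
#' it is retained.
#'
#' @param img x-by-z projection matrix.
#' @param band_frac fraction of the image width to keep (default 0.6).
#' @return The cropped matrix, with attribute `x_range` giving the retained
#'   column range. An all-zero image is returned unchanged with a warning.
#' @export
crop_extremities <- function(img, band_frac = 0.6) {
  if (!is.matrix(img) || nrow(img) == 0 || ncol(img) == 0)
    stopf("img must be a nonempty matrix")
  if (all(img == 0)) {
    warnf("all-zero projection; extremity crop skipped")
    attr(img, "x_range") <- c(1L, nrow(img))
    return(img)
  }
  nx <- nrow(img)
  half <- floor(band_frac * nx / 2)
  if (nx <= 2 * half + 1) {           # image no wider than the band
    attr(img, "x_range") <- c(1L, nx)
    return(img)
  }
  centre <- which.max(rowSums(img))
  x0 <- max(1L, centre - half)
  x1 <- min(nx, centre + half)
  out <- img[x0:x1, , drop = FALSE]
  attr(out, "x_range") <- c(x0, x1)
  out
}

#' Per-slice SUV maxima from cranial to caudal
#'
#' Projects the extremity-cropped xz image onto the z axis, giving a 1-D
#' function of SUV maxima ordered cranial to caudal.
#'
#' @param img x-by-z projection matrix.
#' @return Numeric vector of length `ncol(img)`.
#' @export
z_profile <- function(img) {
  if (!is.matrix(img) || ncol(img) == 0) stopf("img must be a nonempty matrix")
  apply(img, 2, max)
}

# interior local maxima of a 1-D signal, plateaus collapsed to their midpoint
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) {
        peaks <- c(peaks, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

# topographic prominence of each peak index (scipy-style: per side, the
# minimum between the peak and the nearest higher ground, or the signal end)
peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    h <- v[p]
    left <- v[seq_len(p - 1)]
    higher <- which(left > h)
    lmin <- if (length(higher)) min(left[(max(higher) + 1):(p - 1)])
            else min(left)
    right <- v[(p + 1):length(v)]
    higher <- which(right > h)
    rmin <- if (length(higher)) min(right[seq_len(min(higher) - 1)])
            else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect cropping boundaries on a z profile
#'
#' Smooths the profile with a 1-D Gaussian, finds its local maxima, and keeps
#' those whose topographic prominence is at least `prominence_frac` of the
#' global profile maximum. Brain and bladder both show a distinct
#' physiological uptake, so on a complete scan they produce the first and the
#' last significant peak; those become the cropping anchors.
#'
#' @param profile numeric vector of per-slice SUV maxima (cranial first).
#' @param sigma Gaussian smoothing width in slices (default 2).
#' @param prominence_frac significance threshold as a fraction of the global
#'   maximum of the smoothed profile (default 0.25).
#' @return A [crop_boundaries()]; with fewer than two significant peaks the
#'   corresponding flags are `FALSE`.
#' @export
detect_boundaries <- function(profile, sigma = 2.0, prominence_frac = 0.25) {
  if (length(profile) < 3) stopf("profile must have length >= 3")
  v <- as.numeric(profile)
  if (sigma > 0) {
    v <- as.numeric(cpp_gauss3d(v, c(length(v), 1L, 1L), c(sigma, 0, 0)))
  }
  if (max(v) <= 0 || diff(range(v)) == 0)
    return(crop_boundaries())
  peaks <- local_maxima(v)
  if (length(peaks) == 0) return(crop_boundaries())
  prom <- peak_prominence(v, peaks)
  sig <- peaks[prom >= prominence_frac * max(v)]
  if (length(sig) == 0) return(crop_boundaries())
  if (length(sig) == 1)
    return(crop_boundaries(z_top = sig, top_found = TRUE))
  crop_boundaries(z_top = sig[1], z_bottom = sig[length(sig)],
                  top_found = TRUE, bottom_found = TRUE)
}

#' Run the full cropping heuristic on an SUV volume
#'
#' Chains [project_xz()], [crop_extremities()], [z_profile()] and
#' [detect_boundaries()].
#'
#' @param vol a [pet_volume()] in SUV units.
#' @param band_frac see [crop_extremities()].
#' @param sigma,prominence_frac see [detect_boundaries()].
#' @return A [crop_boundaries()], with the smoothed-profile inputs attached as
#'   attribute `profile` for plotting.
#' @export
detect_scan_boundaries <- function(vol, band_frac = 0.6, sigma = 2.0,
                                   prominence_frac = 0.25) {
  img <- project_xz(vol)
  img <- crop_extremities(img, band_frac = band_frac)
  prof <- z_profile(img)
  b <- detect_boundaries(prof, sigma = sigma,
                         prominence_frac = prominence_frac)
  attr(b, "profile") <- prof
  b
}

#' Drop regions overlapping or outside the crop boundaries
#'
#' A region is kept only when its whole voxel extent lies strictly between
#' `z_top` and `z_bottom`; regions touching either boundary slice are removed,
#' matching the exclusion of boundary-overlapping lesions from further
#' analysis.
#'
#' @param regions list of [segmented_region()] objects.
#' @param boundaries a [crop_boundaries()].
#' @param strict when boundaries were not found: `FALSE` (default) passes all
#'   regions through with a warning, `TRUE` raises an error.
#' @return Filtered list of regions.
#' @export
filter_regions_by_boundaries <- function(regions, boundaries,
                                         strict = FALSE) {
  if (!inherits(boundaries, "crop_boundaries"))
    stopf("boundaries must be a crop_boundaries object")
  if (!boundaries$top_found || !boundaries$bottom_found) {
    if (strict) stopf("crop boundaries not found")
    warnf("crop boundaries not found; regions passed through unfiltered")
    return(regions)
  }
  keep <- vapply(regions, function(r) {
    r$z_range[1] > boundaries$z_top && r$z_range[2] < boundaries$z_bottom
  }, logical(1))
  regions[keep]
}
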