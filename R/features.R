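#' Names of the 31 classification features
#'
#' 19 SUV-based features (order statistics, moments, histogram measures,
#' NGTDM texture, contrast to the surrounding), 6 shape-based features, and
#' 6 spatial location features.
#'
#' @format Character vector of length 31.
#' @export
FEATURE_NAMES <- c(
  # SUV-based (19)
  "suv_max", "suv_min", "suv_mean", "suv_median", "suv_range",
  "suv_variance", "suv_energy", "suv_entropy", "suv_kurtosis",
  "suv_uniformity", "suv_mad", "suv_rms", "suv_sd", "suv_skewness",
  "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness", "ngtdm_complexity",
  "outside_difference",
  # shape-based (6)
  "area_surface_ratio", "surface_difference", "scaled_surface_area",
  "scaled_volume", "compactness", "max_diameter",
  # spatial location (6)
  "major_axis_x", "major_axis_y", "major_axis_z",
  "centroid_x", "centroid_y", "centroid_z"
)

region_label_array <- function(region) {
  arr <- integer(prod(region$dim))
  arr[region$idx] <- 1L
  arr
}

#' First-order SUV statistics of a region
#'
#' Order statistics and moments of the region's SUV values. Moments are
#' population moments (divide by n), so they remain defined for tiny regions;
#' kurtosis follows the Pearson convention (normal distribution gives 3).
#' Entropy and uniformity are computed on the same fixed-width absolute-SUV
#' histogram as the segmentation texture (see [quantize_suv()]). For regions
#' where the variance is zero (including single voxels) skewness and kurtosis
#' are defined as 0.
#'
#' @param vol a [pet_volume()] in SUV units.
#' @param region a [segmented_region()].
#' @param base,width histogram binning for entropy/uniformity.
#' @return Named list of 14 scalars: `suv_max`, `suv_min`, `suv_mean`,
#'   `suv_median`, `suv_range`, `suv_variance`, `suv_energy`, `suv_entropy`,
#'   `suv_kurtosis`, `suv_uniformity`, `suv_mad`, `suv_rms`, `suv_sd`,
#'   `suv_skewness`.
#' @export
suv_statistics <- function(vol, region, base = 2.5, width = 0.5) {
  v <- vol$voxels[region$idx]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  p <- tabulate(quantize_suv(v, base = base, width = width))
  p <- p[p > 0] / n
  list(
    suv_max = max(v), suv_min = min(v), suv_mean = mu,
    suv_median = median(v), suv_range = max(v) - min(v),
    suv_variance = m2, suv_energy = sum(v^2),
    suv_entropy = -sum(p * log2(p)),
    suv_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    suv_uniformity = sum(p^2),
    suv_mad = mean(abs(v - mu)),
    suv_rms = sqrt(mean(v^2)),
    suv_sd = sqrt(m2),
    suv_skewness = if (m2 > 0) m3 / m2^1.5 else 0
  )
}

#' NGTDM texture features of a region
#'
#' Neighbouring grey-tone difference matrix features (Amadasun-King, as
#' standardized by the IBSI): for every region voxel with at least one
#' region neighbour (26-neighbourhood), the absolute difference between its
#' grey tone and the mean tone of its neighbours is accumulated per tone;
#' coarseness, contrast, busyness and complexity are derived from the
#' per-tone probabilities `p_i` and difference sums `s_i`. Grey tones are
#' the fixed-width absolute-SUV bins of [quantize_suv()].
#'
#' @param vol a [pet_volume()] in SUV units.
#' @param region a [segmented_region()] with at least 2 voxels.
#' @param base,width quantization.
#' @param eps guard for the coarseness denominator; a perfectly homogeneous
#'   region reports coarseness `1/eps`.
#' @param labels optional label array of the whole scan (with `region` under
#'   its own id); when omitted a one-region array is built.
#' @param bins optional precomputed [quantize_suv()] array.
#' @return Named list: `ngtdm_coarseness`, `ngtdm_contrast`,
#'   `ngtdm_busyness`, `ngtdm_complexity`.
#' @export
ngtdm_features <- function(vol, region, base = 2.5, width = 0.5,
                           eps = 1e-6, labels = NULL, bins = NULL) {
  if (is.null(bins))
    bins <- as.integer(quantize_suv(vol$voxels, base = base, width = width))
  if (is.null(labels)) {
    labels <- region_label_array(region)
    target <- 1L
  } else target <- region$region_id
  m <- cpp_ngtdm(bins, as.integer(labels), target, region$dim, region$idx)
  if (m$n_valid == 0)
    stopf("region %d has no voxel with a neighbour; NGTDM undefined",
          region$region_id)
  i <- as.numeric(m$tone)
  ni <- m$n; si <- m$s
  N <- m$n_valid
  p <- ni / N
  ng <- length(i)
  psi <- sum(p * si)
  coarseness <- 1 / max(psi, eps)
  contrast <- 0
  busyness <- 0
  complexity <- 0
  if (ng > 1) {
    dij <- outer(i, i, "-")
    pij <- outer(p, p)
    contrast <- sum(pij * dij^2) / (ng * (ng - 1)) * sum(si) / N
    denom <- sum(abs(outer(i * p, i * p, "-")))
    busyness <- if (denom > 0) psi / denom else 0
    ps <- p * si
    complexity <- sum(abs(dij) * (outer(ps, rep(1, ng)) +
                                  outer(rep(1, ng), ps)) /
                      (outer(p, rep(1, ng)) + outer(rep(1, ng), p))) / N
  }
  list(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
       ngtdm_busyness = busyness, ngtdm_complexity = complexity)
}

#' Mean SUV contrast between a region and its surrounding
#'
#' Mean SUV inside the region minus the mean SUV over a surrounding shell.
#' The shell is the ring obtained by 26-connected dilation of the region
#' (default thickness 1 voxel), excluding voxels that belong to any
#' segmented region.
#'
#' @param vol a [pet_volume()] in SUV units.
#' @param region a [segmented_region()].
#' @param labels integer label array of all segmented regions of the scan
#'   (used to exclude other regions from the shell); pass `NULL` to exclude
#'   only the region itself.
#' @param thickness shell thickness in voxels.
#' @return Scalar difference (inside minus surrounding).
#' @export
outside_difference <- function(vol, region, labels = NULL, thickness = 1L) {
  dm <- region$dim
  inside <- region$idx
  cur <- inside
  for (t in seq_len(thickness)) {
    xyz <- idx_to_coord(cur, dm)
    grown <- unique(do.call(rbind, lapply(seq_len(27), function(k) {
      d <- c((k - 1) %% 3, ((k - 1) %/% 3) %% 3, (k - 1) %/% 9) - 1L
      sweep(xyz, 2, d, "+")
    })))
    ok <- grown[, 1] >= 1 & grown[, 1] <= dm[1] &
          grown[, 2] >= 1 & grown[, 2] <= dm[2] &
          grown[, 3] >= 1 & grown[, 3] <= dm[3]
    cur <- unique(coord_to_idx(grown[ok, , drop = FALSE], dm))
  }
  shell <- setdiff(cur, inside)
  if (!is.null(labels)) shell <- shell[labels[shell] == 0]
  if (length(shell) == 0) stopf("empty surrounding shell for region %d",
                                region$region_id)
  mean(vol$voxels[inside]) - mean(vol$voxels[shell])
}

surface_pairs_among <- function(surf_idx, dm) {
  # 26-adjacency edges among surface voxels, as index pairs into surf_idx
  xyz <- idx_to_coord(surf_idx, dm)
  from <- integer(0); to <- integer(0)
  for (o in seq_len(27)) {
    d <- c((o - 1) %% 3, ((o - 1) %/% 3) %% 3, (o - 1) %/% 9) - 1L
    if (all(d == 0)) next
    nb <- sweep(xyz, 2, d, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nidx <- coord_to_idx(nb[ok, , drop = FALSE], dm)
    src <- which(ok)
    hit <- match(nidx, surf_idx)
    keep <- !is.na(hit) & src < hit   # undirected, each edge once
    from <- c(from, src[keep]); to <- c(to, hit[keep])
  }
  cbind(from, to)
}

#' Shape features of a region
#'
#' Surface area by exposed-face counting in mm^2; area-surface ratio =
#' volume / surface (mm); sphere-normalized compactness
#' `36 pi V^2 / S^3` (a perfect sphere gives 1, elongated or ragged shapes
#' less); maximum diameter = the largest Euclidean distance between region
#' voxel centres in mm (attained on the surface, so only surface voxels are
#' searched; very large surfaces are deterministically subsampled to 1500
#' voxels); surface difference = the mean, over up to `n_pairs` sampled
#' surface-voxel pairs, of Euclidean distance divided by geodesic distance
#' along the 26-connected surface-voxel graph — 1 for convex, locally flat
#' surfaces, smaller for folded ones.
#'
#' @param region a [segmented_region()].
#' @param n_pairs sampling budget for the surface-difference estimate.
#' @param sample_seed RNG seed for pair sampling (local; does not disturb
#'   the caller's RNG state).
#' @param labels optional label array of the whole scan.
#' @return Named list: `surface_area_mm2`, `volume_ml`,
#'   `area_surface_ratio`, `compactness`, `max_diameter`,
#'   `surface_difference`.
#' @export
shape_features <- function(region, n_pairs = 500L, sample_seed = 42L,
                           labels = NULL) {
  dm <- region$dim
  sp <- region$spacing
  if (is.null(labels)) {
    labels <- region_label_array(region)
    target <- 1L
  } else target <- region$region_id
  s <- cpp_surface(as.integer(labels), target, dm, sp, region$idx)
  area <- s$area_mm2
  vol_mm3 <- length(region$idx) * prod(sp)
  surf <- s$surface_idx
  if (length(region$idx) == 1) {
    return(list(surface_area_mm2 = area, volume_ml = region$volume_ml,
                area_surface_ratio = vol_mm3 / area,
                compactness = 36 * pi * vol_mm3^2 / area^3,
                max_diameter = 0, surface_difference = 1))
  }
  surf_d <- surf
  if (length(surf_d) > 1500)
    surf_d <- surf_d[round(seq(1, length(surf_d), length.out = 1500))]
  pts <- sweep(idx_to_coord(surf_d, dm), 2, sp, "*")
  maxdiam <- max(stats::dist(pts))

  # surface difference on the full surface graph
  edges <- surface_pairs_among(surf, dm)
  sd_val <- 1
  if (nrow(edges) > 0 && length(surf) >= 2) {
    ptsall <- sweep(idx_to_coord(surf, dm), 2, sp, "*")
    w <- sqrt(rowSums((ptsall[edges[, 1], , drop = FALSE] -
                       ptsall[edges[, 2], , drop = FALSE])^2))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(surf) - igraph::vcount(g)))
    np <- min(n_pairs, choose(length(surf), 2))
    pr <- with_local_seed(sample_seed, {
      cbind(sample.int(length(surf), np, replace = TRUE),
            sample.int(length(surf), np, replace = TRUE))
    })
    pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
    if (nrow(pr) > 0) {
      froms <- sort(unique(pr[, 1]))
      dmat <- igraph::distances(g, v = froms, weights = w)
      geo <- dmat[cbind(match(pr[, 1], froms), pr[, 2])]
      eu <- sqrt(rowSums((ptsall[pr[, 1], , drop = FALSE] -
                          ptsall[pr[, 2], , drop = FALSE])^2))
      ratio <- eu / geo
      ratio <- ratio[is.finite(ratio)]
      if (length(ratio) > 0) sd_val <- mean(pmin(ratio, 1))
    }
  }
  list(surface_area_mm2 = area, volume_ml = region$volume_ml,
       area_surface_ratio = vol_mm3 / area,
       compactness = 36 * pi * vol_mm3^2 / area^3,
       max_diameter = maxdiam, surface_difference = sd_val)
}

#' Body extent in x and y
#'
#' Index ranges of the body mask (voxels above a low SUV cut separating the
#' body from surrounding air), used to normalize centroid locations.
#'
#' @param vol a [pet_volume()] in SUV units.
#' @param air_suv body/air cut (default 0.5).
#' @return List with `x` and `y` index ranges.
#' @export
body_extent <- function(vol, air_suv = 0.5) {
  mask <- vol$voxels >= air_suv
  if (!any(mask)) {
    dm <- dim(vol$voxels)
    return(list(x = c(1L, dm[1]), y = c(1L, dm[2])))
  }
  xs <- apply(mask, 1, any)
  ys <- apply(mask, 2, any)
  list(x = range(which(xs)), y = range(which(ys)))
}

#' Spatial location features of a region
#'
#' Centroid location as fractions of the cropped body bounding box — x and y
#' over the body-mask extent, z over the crop interval — so values are
#' scanner- and patient-size-independent. Major-axis direction is the unit
#' eigenvector of the largest eigenvalue of the voxel-coordinate inertia
#' (second-moment) tensor in mm, sign-fixed so the z component is
#' non-negative (by x, then y, when z is 0); a degenerate (isotropic) tensor
#' reports +z.
#'
#' @param region a [segmented_region()].
#' @param boundaries a found [crop_boundaries()].
#' @param extent body extent from [body_extent()].
#' @return Named list: `major_axis_x/y/z`, `centroid_x/y/z`.
#' @export
location_features <- function(region, boundaries, extent) {
  if (!boundaries$top_found || !boundaries$bottom_found)
    stopf("location features require found crop boundaries")
  xyz <- region$coords
  cen <- colMeans(xyz)
  frac <- function(v, r) {
    if (r[2] == r[1]) return(0.5)
    min(max((v - r[1]) / (r[2] - r[1]), 0), 1)
  }
  cx <- frac(cen[1], extent$x)
  cy <- frac(cen[2], extent$y)
  cz <- frac(cen[3], c(boundaries$z_top, boundaries$z_bottom))

  axis <- c(0, 0, 1)
  if (nrow(xyz) > 1) {
    mm <- sweep(xyz, 2, region$spacing, "*")
    cc <- sweep(mm, 2, colMeans(mm))
    ine <- crossprod(cc) / nrow(cc)
    ev <- eigen(ine, symmetric = TRUE)
    if ((ev$values[1] - ev$values[2]) > 1e-9 * max(ev$values[1], 1e-12)) {
      a <- ev$vectors[, 1]
      if (a[3] < 0 || (a[3] == 0 && (a[1] < 0 || (a[1] == 0 && a[2] < 0))))
        a <- -a
      axis <- a
    }
  }
  list(major_axis_x = axis[1], major_axis_y = axis[2], major_axis_z = axis[3],
       centroid_x = cx, centroid_y = cy, centroid_z = cz)
}

#' Normalize size features to a standardized body scale
#'
#' Features are computed in physical units on the original grid and then
#' rescaled to a standardized patient size so that they are comparable
#' across scans: with `L` the cropped body length in mm,
#' `scaled_volume = volume_ml / L^3 * 1e6`,
#' `scaled_surface_area = surface_mm2 / L^2 * 1e4`, and the maximum diameter
#' is divided by `L`. SUV statistics and texture are quantized in absolute
#' SUV and are resolution-independent by construction; centroid and axis
#' features are already normalized.
#'
#' @param fv named list or one-row data.frame holding `volume_ml`,
#'   `surface_area_mm2` and `max_diameter` (mm).
#' @param body_length_mm cropped z extent in mm (> 0).
#' @return `fv` with `scaled_volume`, `scaled_surface_area` and rescaled
#'   `max_diameter` fields set.
#' @export
normalize_features <- function(fv, body_length_mm) {
  if (!is.finite(body_length_mm) || body_length_mm <= 0)
    stopf("body_length_mm must be positive; crop extent missing?")
  fv$scaled_volume <- fv$volume_ml / body_length_mm^3 * 1e6
  fv$scaled_surface_area <- fv$surface_area_mm2 / body_length_mm^2 * 1e4
  fv$max_diameter <- fv$max_diameter / body_length_mm
  fv
}

#' Compute the full 31-feature vector for every region
#'
#' Runs [suv_statistics()], [ngtdm_features()], [outside_difference()],
#' [shape_features()], [location_features()] and [normalize_features()] for
#' each region and assembles the feature table.
#'
#' @param vol a [pet_volume()] in SUV units.
#' @param labels label array covering all regions of the scan.
#' @param regions list of [segmented_region()] objects.
#' @param boundaries a found [crop_boundaries()].
#' @param base,width SUV quantization for histogram/texture features.
#' @param sample_seed seed for surface-pair sampling.
#' @return data.frame with columns `patient_id`, `region_id`, `volume_ml`
#'   and the 31 [FEATURE_NAMES].
#' @export
extract_features <- function(vol, labels, regions, boundaries,
                             base = 2.5, width = 0.5, sample_seed = 42L) {
  assert_pet_volume(vol)
  ext <- body_extent(vol)
  L <- (boundaries$z_bottom - boundaries$z_top) * vol$spacing[3]
  bins <- as.integer(quantize_suv(vol$voxels, base = base, width = width))
  lab_int <- as.integer(labels)
  rows <- lapply(regions, function(r) {
    su <- suv_statistics(vol, r, base = base, width = width)
    ng <- ngtdm_features(vol, r, base = base, width = width,
                         labels = lab_int, bins = bins)
    od <- outside_difference(vol, r, labels = labels)
    sh <- shape_features(r, sample_seed = sample_seed, labels = lab_int)
    lo <- location_features(r, boundaries, ext)
    fv <- c(su, ng, list(outside_difference = od), sh, lo)
    fv <- normalize_features(fv, body_length_mm = L)
    data.frame(patient_id = r$patient_id, region_id = r$region_id,
               volume_ml = r$volume_ml,
               as.data.frame(fv[FEATURE_NAMES]),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(), region_id = integer(),
                      volume_ml = numeric())
  rownames(out) <- NULL
  out
}
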