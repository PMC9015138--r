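#' Phantom specification
#'
#' Describes a synthetic whole-body FDG-PET phantom: grid geometry, body
#' background, and per-class blob templates (how many uptake foci of each
#' tissue class to place, their SUV level and spread, size range in ml,
#' location prior along the normalized cranio-caudal axis, lateral placement
#' and texture amplitude). The defaults emulate the physiological whole-body
#' FDG distribution: a high-uptake brain at the cranial end and bladder at
#' the caudal end (the two cropping anchors), an elongated midline skeleton
#' column, paired kidneys, heart, head-and-neck and brown-fat foci, scattered
#' gastrointestinal foci, and ellipsoidal tumor lesions anywhere in the nodal
#' stations; per-patient counts roughly mirror the class frequencies of a
#' clinical lymphoma cohort (skeleton-heavy, rare liver/genital/composed
#' volumes, about 4.1 tumor lesions per patient). All blob constants are
#' invented plumbing, not measured values.
#'
#' Count samplers: `lambda` draws Poisson counts (clamped to `min_count`),
#' `prob` draws Bernoulli presence of `n_if_present` blobs.
#'
#' @param dim grid dimensions (x, y, z).
#' @param spacing voxel spacing in mm.
#' @param background_suv body background SUV level.
#' @param noise_sd additive Gaussian noise sd on the background.
#' @param air_suv SUV level outside the body.
#' @param brain_absent drop the brain blob (exercises the documented
#'   cropping failure mode: the crop then lands at the salivary glands).
#' @param seed RNG seed fixing all randomness.
#' @param classes per-class blob templates; see the default for the schema.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(102L, 77L, 272L), spacing = c(2.5, 2.5, 2.5),
                         background_suv = 1.0, noise_sd = 0.1,
                         air_suv = 0.05, brain_absent = FALSE,
                         seed = 1L, classes = NULL) {
  if (is.null(classes)) classes <- default_class_templates()
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 background_suv = background_suv, noise_sd = noise_sd,
                 air_suv = air_suv, brain_absent = brain_absent,
                 seed = as.integer(seed), classes = classes),
            class = "phantom_spec")
}

default_class_templates <- function() {
  list(
    BRAIN = list(lambda = NULL, prob = 1.0, n_if_present = 1,
                 suv_mean = 7.0, suv_sd = 0.5, vol_ml = c(60, 90),
                 z_prior = c(0.075, 0.005), lateral = "mid",
                 shape = "ellipsoid", interior = "peaked",
                 texture_sd = 0.04),
    HN = list(lambda = 1.4, min_count = 0, max_count = 2, suv_mean = 4.3,
              suv_sd = 0.3, vol_ml = c(4, 8), z_prior = c(0.12, 0.015),
              lateral = "any",
              shape = "ellipsoid", texture_sd = 0.05),
    BF = list(prob = 0.2, n_if_present = 2, suv_mean = 4.2, suv_sd = 0.4,
              vol_ml = c(3, 6), z_prior = c(0.15, 0.02),
              lateral = "paired", shape = "ellipsoid", texture_sd = 0.12),
    HT = list(prob = 0.5, n_if_present = 1, suv_mean = 5.0, suv_sd = 0.5,
              vol_ml = c(15, 30), z_prior = c(0.33, 0.02), lateral = "left",
              shape = "ellipsoid", texture_sd = 0.10),
    SK = list(lambda = 4.9, min_count = 2, max_count = 7, suv_mean = 4.6,
              suv_sd = 0.3,
              vol_ml = c(8, 16), z_prior = c(0.50, 0.18), lateral = "mid",
              shape = "rod", texture_sd = 0.05),
    RK = list(prob = 1.0, n_if_present = 1, suv_mean = 6.0, suv_sd = 0.5,
              vol_ml = c(10, 20), z_prior = c(0.55, 0.02),
              lateral = "right", shape = "ellipsoid", texture_sd = 0.06),
    LK = list(prob = 1.0, n_if_present = 1, suv_mean = 6.0, suv_sd = 0.5,
              vol_ml = c(10, 20), z_prior = c(0.55, 0.02), lateral = "left",
              shape = "ellipsoid", texture_sd = 0.06),
    LI = list(prob = 0.02, n_if_present = 1, suv_mean = 4.0, suv_sd = 0.2,
              vol_ml = c(30, 50), z_prior = c(0.45, 0.02),
              lateral = "right", shape = "ellipsoid", texture_sd = 0.05),
    GI = list(lambda = 0.62, min_count = 0, max_count = 3, suv_mean = 4.2,
              suv_sd = 0.5, vol_ml = c(3.5, 6), z_prior = c(0.68, 0.06), lateral = "any",
              shape = "ellipsoid", texture_sd = 0.15),
    G = list(prob = 0.05, n_if_present = 1, suv_mean = 4.2, suv_sd = 0.4,
             vol_ml = c(4, 8), z_prior = c(0.855, 0.01), lateral = "left",
             shape = "ellipsoid", texture_sd = 0.06),
    BL = list(prob = 1.0, n_if_present = 1, suv_mean = 8.0, suv_sd = 0.5,
              vol_ml = c(15, 30), z_prior = c(0.93, 0.005), lateral = "mid",
              shape = "ellipsoid", interior = "peaked",
              texture_sd = 0.04),
    T = list(lambda = 3.75, min_count = 1, suv_mean = 8.0, suv_sd = 1.0,
             vol_ml = c(3, 15), z_prior = NULL, z_range = c(0.12, 0.80),
             lateral = "any", shape = "ellipsoid", texture_sd = 0.15),
    `T+NT` = list(prob = 0.35, n_if_present = 1, suv_mean = 7.5,
                  suv_sd = 0.8, vol_ml = c(4, 10), z_prior = NULL,
                  z_range = c(0.15, 0.75), lateral = "any",
                  shape = "composite", second_suv = 4.5,
                  texture_sd = 0.15),
    `NT+NT` = list(prob = 0.1, n_if_present = 1, suv_mean = 4.8,
                   suv_sd = 0.4, vol_ml = c(4, 8), z_prior = c(0.5, 0.15),
                   lateral = "any", shape = "composite", second_suv = 4.2,
                   texture_sd = 0.10)
  )
}

sample_count <- function(tpl) {
  if (!is.null(tpl$lambda)) {
    n <- max(rpois(1, tpl$lambda), tpl$min_count %||% 0L)
    min(n, tpl$max_count %||% n)
  } else if (runif(1) < (tpl$prob %||% 0)) {
    tpl$n_if_present %||% 1L
  } else 0L
}

# semi-axes (mm) of an ellipsoid of the given volume with mild random
# anisotropy; rods are strongly elongated along z
blob_axes <- function(vol_ml, shape) {
  r0 <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
  if (shape == "rod") {
    el <- runif(1, 2.0, 2.8)
    a <- r0 / el^(1 / 3)
    c(a, a, a * el)
  } else {
    f <- exp(runif(3, -0.25, 0.25))
    r0 * f / prod(f)^(1 / 3)
  }
}

lateral_centre <- function(lateral, nx, ny, side = 1) {
  cx <- switch(lateral,
    mid = 0.5 + runif(1, -0.04, 0.04),
    left = 0.68 + runif(1, -0.04, 0.04),
    right = 0.32 + runif(1, -0.04, 0.04),
    paired = (if (side == 1) 0.28 else 0.72) + runif(1, -0.03, 0.03),
    any = runif(1, 0.28, 0.72))
  cy <- 0.5 + runif(1, -0.12, 0.12)
  c(cx * nx, cy * ny)
}

# render one plateau ellipsoid into vox (by max), mark truth; uptake is a
# flat plateau inside the ellipsoid with a short Gaussian falloff beyond the
# edge — real uptake boundaries are sharp and the pipeline's denoising plays
# the role of the scanner point-spread function
render_blob <- function(vox, truth, id, centre, axes_mm, suv, spacing,
                        texture_sd, edge_vox = 1.2, interior = "flat") {
  dm <- dim(vox)
  ax_vox <- pmax(axes_mm / spacing, 0.6)
  pad <- 4
  lo <- pmax(floor(centre - ax_vox - pad), 1)
  hi <- pmin(ceiling(centre + ax_vox + pad), dm)
  if (any(lo > hi)) return(list(vox = vox, truth = truth, n = 0L))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- (xs - centre[1]) / ax_vox[1]
  gy <- (ys - centre[2]) / ax_vox[2]
  gz <- (zs - centre[3]) / ax_vox[3]
  rho2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  rho <- sqrt(rho2)
  # interior: flat-topped profile declining to the edge level at rho = 1;
  # outside: short Gaussian tail (in voxels). The edge level is chosen so
  # that after denoising the threshold contour sits at the truth boundary:
  # the blurred step midpoint (edge + background)/2 equals the 2.5 cut.
  edge_suv <- 4.0
  reff <- 1 / mean(1 / ax_vox)
  d <- pmax(rho - 1, 0) * reff
  c0 <- log(max(suv / edge_suv, 1.001))
  # anchor organs (brain, bladder) get a centrally peaked interior so their
  # intensity maximum is a stable landmark; other tissues are flat-topped
  rin <- if (interior == "peaked") rho2 else rho2^2
  val <- ifelse(rho <= 1, suv * exp(-c0 * rin),
                edge_suv * exp(-(d / edge_vox)^2))
  if (texture_sd > 0)
    val <- val * exp(array(rnorm(length(val), 0, texture_sd), dim(val)))
  sub <- vox[xs, ys, zs]
  upd <- val > sub
  sub[upd] <- val[upd]
  vox[xs, ys, zs] <- sub
  tsub <- truth[xs, ys, zs]
  inside <- rho2 <= 1 & tsub == 0L
  tsub[inside] <- id
  truth[xs, ys, zs] <- tsub
  list(vox = vox, truth = truth, n = sum(inside))
}

# does a candidate ellipsoid (with margin, in voxels) overlap existing truth?
blob_clear <- function(truth, centre, axes_mm, spacing, margin_vox = 7) {
  dm <- dim(truth)
  ax <- pmax(axes_mm / spacing, 0.6) + margin_vox
  lo <- pmax(floor(centre - ax), 1)
  hi <- pmin(ceiling(centre + ax), dm)
  if (any(lo > hi)) return(FALSE)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- (xs - centre[1]) / ax[1]
  gy <- (ys - centre[2]) / ax[2]
  gz <- (zs - centre[3]) / ax[3]
  rho2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  !any(truth[xs, ys, zs][rho2 <= 1] > 0L)
}

#' Generate one synthetic whole-body phantom
#'
#' Renders the body background with additive Gaussian noise, places the
#' per-class blobs of the spec with rejection sampling against overlap, and
#' returns the volume together with voxel-level ground truth.
#'
#' Composite classes (T+NT, NT+NT) are rendered as two overlapping
#' ellipsoids of different SUV levels sharing one truth region. The bladder
#' sits at the caudal crop anchor, so like the brain it is normally removed
#' by the crop filter rather than classified.
#'
#' @param spec a [phantom_spec()].
#' @param units `"suv"` returns SUV voxels directly; `"activity"` converts
#'   to activity concentration (Bq/ml) with the given dose and weight so the
#'   SUV conversion stage can be exercised.
#' @param dose,weight metadata used when `units = "activity"`.
#' @param patient_id identifier stamped on the volume and truth table.
#' @return List: `vol` (a [pet_volume()]), `truth` (integer array of blob
#'   ids), `table` (data.frame: `region_id`, `class`, `volume_ml`,
#'   `centroid_x/y/z`).
#' @export
generate_phantom <- function(spec = phantom_spec(), units = c("suv", "activity"),
                             dose = 1e8, weight = 20,
                             patient_id = "phantom01") {
  units <- match.arg(units)
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    dm <- spec$dim
    sp <- spec$spacing
    nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
    # elliptic-cylinder body on an air background
    bx <- 0.42 * nx; by <- 0.40 * ny
    xs <- ((1:nx) - (nx + 1) / 2) / bx
    ys <- ((1:ny) - (ny + 1) / 2) / by
    body2d <- outer(xs^2, ys^2, "+") <= 1
    vox <- array(spec$air_suv, dm)
    body <- array(body2d, dm)
    vox[body] <- spec$background_suv
    vox <- vox + array(rnorm(prod(dm), 0, spec$noise_sd), dm)
    vox[vox < 0] <- 0
    truth <- array(0L, dm)

    rows <- list()
    id <- 0L
    for (cls in names(spec$classes)) {
      if (cls == "BRAIN" && spec$brain_absent) next
      tpl <- spec$classes[[cls]]
      n <- sample_count(tpl)
      for (b in seq_len(n)) {
        suv <- max(rnorm(1, tpl$suv_mean, tpl$suv_sd), 4.2)
        vol_ml <- runif(1, tpl$vol_ml[1], tpl$vol_ml[2])
        axes <- blob_axes(vol_ml, tpl$shape)
        if (tpl$shape == "rod") {
          # keep each spine segment within its station slot
          hl_max <- 0.30 * 0.64 / n * nz * sp[3]
          if (axes[3] > hl_max) {
            r0 <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
            axes[3] <- hl_max
            axes[1] <- axes[2] <- sqrt(r0^3 / hl_max)
          }
        }
        placed <- FALSE
        for (attempt in 1:100) {
          zfrac <- if (tpl$shape == "rod") {
            # spine segments are sequential stations along the column
            0.22 + (b - 0.5) * 0.64 / n + rnorm(1, 0, 0.01)
          } else if (!is.null(tpl$z_prior))
            rnorm(1, tpl$z_prior[1], tpl$z_prior[2])
          else runif(1, tpl$z_range[1], tpl$z_range[2])
          zfrac <- min(max(zfrac, 0.01), 0.97)
          centre <- c(lateral_centre(tpl$lateral, nx, ny, side = b),
                      zfrac * nz)
          if (!blob_clear(truth, centre, axes, sp)) next
          id <- id + 1L
          r <- render_blob(vox, truth, id, centre, axes, suv, sp,
                           tpl$texture_sd,
                           interior = tpl$interior %||% "flat")
          vox <- r$vox; truth <- r$truth
          if (tpl$shape == "composite") {
            # attach a second, lower-uptake lobe sharing the truth id
            off <- axes / sp * runif(3, 0.8, 1.2) *
              sample(c(-1, 1), 3, replace = TRUE)
            r2 <- render_blob(vox, truth, id, centre + off,
                              axes * runif(1, 0.7, 1.0), tpl$second_suv,
                              sp, tpl$texture_sd)
            vox <- r2$vox; truth <- r2$truth
          }
          cen <- colMeans(idx_to_coord(which(truth == id), dm))
          rows[[length(rows) + 1]] <- data.frame(
            region_id = id, class = cls,
            volume_ml = sum(truth == id) * prod(sp) / 1000,
            centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3],
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stopf("could not place a %s blob after 100 attempts", cls)
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(region_id = integer(), class = character(),
                 volume_ml = numeric(), centroid_x = numeric(),
                 centroid_y = numeric(), centroid_z = numeric())
    rownames(tab) <- NULL
    if (units == "activity") {
      vol <- pet_volume(vox * dose / (weight * 1000), spacing = sp,
                        units = "activity", dose = dose, weight = weight,
                        patient_id = patient_id)
    } else {
      vol <- pet_volume(vox, spacing = sp, units = "suv",
                        dose = dose, weight = weight,
                        patient_id = patient_id)
    }
    list(vol = vol, truth = truth, table = tab)
  })
}

#' Generate a phantom cohort
#'
#' Draws `n_patients` phantoms with per-patient randomized specs: body size
#' varies mildly, blob counts are resampled per patient, and a fraction of
#' patients lack the brain on the scan (exercising the cropping failure
#' mode).
#'
#' @param n_patients cohort size (>= 1).
#' @param template a [phantom_spec()] used as the base.
#' @param seed master seed; patient `i` uses a seed derived from it.
#' @param brain_absent_frac fraction of patients without a brain blob
#'   (default 0.15).
#' @param units,dose,weight passed to [generate_phantom()].
#' @return List of phantoms (as returned by [generate_phantom()]), named by
#'   patient id.
#' @export
generate_cohort <- function(n_patients, template = phantom_spec(),
                            seed = 1L, brain_absent_frac = 0.15,
                            units = "suv", dose = 1e8, weight = 20) {
  if (n_patients < 1) stopf("n_patients must be >= 1")
  absent <- with_local_seed(seed,
                            runif(n_patients) < brain_absent_frac)
  lapply(seq_len(n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    sp <- template
    sp$seed <- as.integer((seed * 1009L + i * 131L) %% .Machine$integer.max)
    sp$brain_absent <- absent[i]
    generate_phantom(sp, units = units, dose = dose, weight = weight,
                     patient_id = pid)
  })
}

#' Match segmented regions to phantom ground truth
#'
#' Labels each segmented region with the class of the truth blob covering
#' the majority of its voxels; regions without any truth overlap get `NA`.
#'
#' @param regions list of [segmented_region()] objects.
#' @param truth integer truth array from [generate_phantom()].
#' @param truth_table the matching truth table.
#' @return Character vector of class labels, one per region.
#' @export
match_truth_labels <- function(regions, truth, truth_table) {
  cls <- setNames(truth_table$class, truth_table$region_id)
  vapply(regions, function(r) {
    tv <- truth[r$idx]
    tv <- tv[tv > 0L]
    if (length(tv) == 0) return(NA_character_)
    tb <- table(tv)
    cls[[names(tb)[which.max(tb)]]]
  }, character(1))
}
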