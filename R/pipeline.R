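#' Pipeline configuration
#'
#' All tunable constants of the pipeline in one serializable object:
#' denoising width, SUV segmentation threshold, texture-merge threshold,
#' minimum region volume, cropping parameters, SUV quantization, the
#' cross-validation configuration and the master seed.
#'
#' @param sigma Gaussian denoising width in voxels (default 2.0).
#' @param sigma_in_mm interpret `sigma` in mm instead.
#' @param suv_threshold segmentation threshold (default 2.5).
#' @param texture_threshold merge threshold on aggregated texture
#'   difference (default 2.0).
#' @param min_volume_ml minimum region volume (default 2.0 ml).
#' @param crop list: `band_frac`, `sigma`, `prominence_frac`.
#' @param quant list: `base`, `width` of the SUV histogram bins.
#' @param sample_seed seed for surface-pair sampling in the shape features.
#' @param cv a [cv_config()].
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sigma = 2.0, sigma_in_mm = FALSE,
                            suv_threshold = 2.5, texture_threshold = 2.0,
                            min_volume_ml = 2.0,
                            crop = list(band_frac = 0.6, sigma = 2.0,
                                        prominence_frac = 0.25),
                            quant = list(base = 2.5, width = 0.5),
                            sample_seed = 42L, cv = cv_config(),
                            seed = 1L) {
  stopifnot(suv_threshold > 0, texture_threshold > 0, min_volume_ml > 0,
            sigma >= 0)
  structure(list(sigma = sigma, sigma_in_mm = sigma_in_mm,
                 suv_threshold = suv_threshold,
                 texture_threshold = texture_threshold,
                 min_volume_ml = min_volume_ml, crop = crop, quant = quant,
                 sample_seed = as.integer(sample_seed), cv = cv,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration
#'
#' YAML round-trip: `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns the
#'   [pipeline_config()].
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$cv <- unclass(x$cv)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  cv <- do.call(cv_config, x$cv)
  x$cv <- NULL
  cfg <- do.call(pipeline_config, c(x, list(cv = cv)))
  cfg
}

#' Process one scan through segmentation and feature extraction
#'
#' Runs denoising, SUV conversion (when needed), boundary detection,
#' thresholded watershed segmentation, texture merging, crop/volume
#' filtering and feature extraction for a single scan.
#'
#' @param vol a [pet_volume()] (activity or SUV units).
#' @param config a [pipeline_config()].
#' @return List: `suv` (denoised SUV volume), `boundaries`, `labels`
#'   (post-merge label array), `regions` (surviving regions), `features`
#'   (feature table) and `counts` (regions per stage).
#' @export
process_scan <- function(vol, config = pipeline_config()) {
  sm <- gaussian_smooth(vol, sigma = config$sigma,
                        sigma_in_mm = config$sigma_in_mm)
  suv <- if (sm$units == "activity") compute_suv(sm) else sm
  boundaries <- detect_scan_boundaries(
    suv, band_frac = config$crop$band_frac, sigma = config$crop$sigma,
    prominence_frac = config$crop$prominence_frac)
  mask <- threshold_mask(suv, t = config$suv_threshold)
  ws <- watershed_segment(suv, mask)
  labels <- texture_merge(ws, suv, threshold = config$texture_threshold,
                          base = config$quant$base,
                          width = config$quant$width)
  regions <- label_regions(labels, suv$spacing, patient_id = suv$patient_id)
  n_segmented <- length(regions)
  regions <- filter_regions_by_boundaries(regions, boundaries)
  n_cropped <- length(regions)
  regions <- filter_small(regions, min_ml = config$min_volume_ml)
  feats <- if (boundaries$top_found && boundaries$bottom_found &&
               length(regions) > 0) {
    extract_features(suv, labels, regions, boundaries,
                     base = config$quant$base, width = config$quant$width,
                     sample_seed = config$sample_seed)
  } else NULL
  list(suv = suv, boundaries = boundaries, labels = labels,
       regions = regions, features = feats,
       counts = c(segmented = n_segmented, after_crop = n_cropped,
                  after_volume_filter = length(regions)))
}

#' Build a labelled dataset from a phantom cohort
#'
#' Processes every phantom with [process_scan()] and labels each surviving
#' region by ground-truth majority overlap.
#'
#' @param cohort list from [generate_cohort()].
#' @param config a [pipeline_config()].
#' @param verbose print per-scan region counts.
#' @return List: `dataset` (features + `label`), `scans` (per-scan
#'   [process_scan()] results), `counts` (stage bookkeeping matrix).
#' @export
cohort_dataset <- function(cohort, config = pipeline_config(),
                           verbose = FALSE) {
  scans <- vector("list", length(cohort))
  rows <- list()
  for (i in seq_along(cohort)) {
    ph <- cohort[[i]]
    res <- process_scan(ph$vol, config)
    scans[[i]] <- res
    if (!is.null(res$features) && nrow(res$features) > 0) {
      lab <- match_truth_labels(res$regions, ph$truth, ph$table)
      f <- res$features[!is.na(lab), , drop = FALSE]
      f$label <- lab[!is.na(lab)]
      rows[[length(rows) + 1]] <- f
    }
    if (verbose)
      message(sprintf("%s: %s", ph$vol$patient_id,
                      paste(names(res$counts), res$counts,
                            collapse = ", ", sep = "=")))
  }
  dataset <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(dataset)) rownames(dataset) <- NULL
  counts <- do.call(rbind, lapply(scans, `[[`, "counts"))
  list(dataset = dataset, scans = scans, counts = counts)
}

#' Run the full pipeline on a phantom cohort
#'
#' Segmentation, feature extraction, nested cross-validated classification
#' and evaluation in one call: the end-to-end workflow of the method.
#'
#' @param cohort list from [generate_cohort()].
#' @param config a [pipeline_config()]; its `cv` element steers the
#'   classification.
#' @param verbose print progress.
#' @return List: `dataset`, `cv` ([nested_cv()] result), `report`
#'   ([evaluation_report()] on the modal predictions), `counts`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         verbose = FALSE) {
  built <- cohort_dataset(cohort, config, verbose = verbose)
  if (is.null(built$dataset) || nrow(built$dataset) == 0)
    stopf("no regions survived the pipeline; nothing to classify")
  cv <- nested_cv(built$dataset, config$cv)
  report <- evaluation_report(cv$predictions$manual, cv$predictions$modal,
                              patient_id = cv$predictions$patient_id)
  list(dataset = built$dataset, cv = cv, report = report,
       counts = built$counts)
}
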