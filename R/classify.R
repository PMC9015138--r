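#' Nested cross-validation configuration
#'
#' The dataset is split into `n_parts` parts (training / validation / test);
#' the inner step picks the hyperparameter pair — maximum tree depth and
#' number of selectable features per split — that maximizes validation
#' accuracy, the winning model predicts the test part, and the parts rotate
#' until each was the test set once. The whole procedure is repeated
#' `repetitions` times with fresh random partitions and the results are
#' averaged.
#'
#' @param n_parts number of parts (>= 3; default 3).
#' @param repetitions number of repetitions (default 10).
#' @param depth_grid maximum tree depths to try; 0 means unlimited.
#' @param mtry_grid numbers of selectable features per split to try.
#' @param n_trees trees per forest (default 500).
#' @param seed master seed; all partitioning and training randomness derives
#'   from it.
#' @param patient_level partition at patient level (default, prevents
#'   within-patient leakage) or at region level.
#' @param stratified class-stratified partitioning (region-level only).
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_parts = 3L, repetitions = 10L,
                      depth_grid = c(4L, 8L, 16L, 0L),
                      mtry_grid = c(6L, 10L, 16L),
                      n_trees = 500L, seed = 1L,
                      patient_level = TRUE, stratified = FALSE) {
  if (n_parts < 3) stopf("n_parts must be >= 3")
  if (repetitions < 1) stopf("repetitions must be >= 1")
  if (length(depth_grid) == 0 || length(mtry_grid) == 0)
    stopf("hyperparameter grid must be nonempty")
  structure(list(n_parts = as.integer(n_parts),
                 repetitions = as.integer(repetitions),
                 depth_grid = as.integer(depth_grid),
                 mtry_grid = as.integer(mtry_grid),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 patient_level = patient_level, stratified = stratified),
            class = "cv_config")
}

dataset_features <- function(data) {
  miss <- setdiff(FEATURE_NAMES, names(data))
  if (length(miss) > 0)
    stopf("dataset is missing feature columns: %s",
          paste(miss, collapse = ", "))
  data[, FEATURE_NAMES, drop = FALSE]
}

#' Train a random forest on a labelled dataset
#'
#' Trees are trained independently on bootstrap samples; each split chooses
#' among `mtry` randomly selectable features and trees are capped at `depth`
#' levels. Training is deterministic given `seed`. A single-class training
#' set yields a degenerate constant classifier with a warning.
#'
#' @param train data.frame with the [FEATURE_NAMES] columns and a `label`
#'   column.
#' @param depth maximum tree depth; 0 = unlimited.
#' @param mtry features considered per split.
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed.
#' @return An object of class `pet_forest`.
#' @export
train_forest <- function(train, depth = 0L, mtry = 6L, n_trees = 500L,
                         seed = 1L) {
  x <- dataset_features(train)
  if (anyNA(x)) stopf("training features contain missing values")
  lv <- intersect(PET_CLASSES, unique(as.character(train$label)))
  if (length(lv) == 0) lv <- sort(unique(as.character(train$label)))
  y <- factor(as.character(train$label), levels = lv)
  if (anyNA(y)) stopf("labels outside the class vocabulary")
  if (length(lv) < 2) {
    warnf("single-class training set; returning constant classifier")
    return(structure(list(constant = lv, levels = lv), class = "pet_forest"))
  }
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        mtry = min(mtry, ncol(x)),
                        max.depth = if (depth > 0) depth else NULL,
                        seed = seed, num.threads = 1)
  structure(list(fit = fit, levels = lv), class = "pet_forest")
}

#' Predict classes by majority vote
#'
#' Each region is classified by every tree; the final class is the majority
#' vote, with ties broken by the canonical class order ([PET_CLASSES]).
#'
#' @param forest a [train_forest()] result.
#' @param newdata data.frame with the [FEATURE_NAMES] columns.
#' @return Character vector of predicted class labels.
#' @export
predict_forest <- function(forest, newdata) {
  x <- dataset_features(newdata)
  if (anyNA(x)) stopf("feature vector with missing entries")
  if (!is.null(forest$constant))
    return(rep(forest$constant, nrow(x)))
  votes <- stats::predict(forest$fit, data = x, predict.all = TRUE,
                          num.threads = 1)$predictions
  lv <- forest$levels
  rank <- match(lv, c(PET_CLASSES, setdiff(lv, PET_CLASSES)))
  apply(votes, 1, function(v) {
    cnt <- tabulate(v, nbins = length(lv))
    win <- which(cnt == max(cnt))
    lv[win[which.min(rank[win])]]
  })
}

partition_units <- function(units, n_parts) {
  # shuffle, then deal into n_parts nearly equal parts
  sh <- sample(units)
  split(sh, rep_len(seq_len(n_parts), length(sh)))
}

partition_dataset <- function(data, cfg) {
  if (cfg$patient_level) {
    parts <- partition_units(unique(data$patient_id), cfg$n_parts)
    lapply(parts, function(p) which(data$patient_id %in% p))
  } else if (cfg$stratified) {
    idx_parts <- vector("list", cfg$n_parts)
    for (cl in unique(as.character(data$label))) {
      rows <- sample(which(data$label == cl))
      asg <- rep_len(seq_len(cfg$n_parts), length(rows))
      for (p in seq_len(cfg$n_parts))
        idx_parts[[p]] <- c(idx_parts[[p]], rows[asg == p])
    }
    idx_parts
  } else {
    parts <- partition_units(seq_len(nrow(data)), cfg$n_parts)
    lapply(parts, as.integer)
  }
}

#' Nested cross-validated classification
#'
#' Runs the full nested cross-validation: per repetition the dataset is
#' randomly partitioned (by patient, by default) into `n_parts` parts; the
#' parts rotate so each is the test set exactly once, the inner step selects
#' the hyperparameter pair with the best validation accuracy, and the model
#' trained on the training part with those hyperparameters predicts the test
#' part. Per-region predictions are collected for every repetition; the
#' averaged confusion matrix (cell counts averaged over repetitions, then
#' rounded to integers) and the modal per-region prediction summarize the
#' repetitions.
#'
#' @param data labelled dataset: `patient_id`, `region_id`, the
#'   [FEATURE_NAMES] columns and `label`.
#' @param cfg a [cv_config()].
#' @return List of class `nested_cv_result`: `predictions` (data.frame with
#'   one column per repetition plus `modal`), `confusion` (averaged, rounded
#'   [confusion()] matrix), `per_rep_confusion`, `chosen` (hyperparameters
#'   per repetition and rotation).
#' @export
nested_cv <- function(data, cfg = cv_config()) {
  if (anyDuplicated(data[, c("patient_id", "region_id")]))
    stopf("duplicate (patient_id, region_id) rows")
  n <- nrow(data)
  grid <- expand.grid(depth = cfg$depth_grid, mtry = cfg$mtry_grid,
                      KEEP.OUT.ATTRS = FALSE)
  preds <- matrix(NA_character_, n, cfg$repetitions)
  chosen <- list()
  per_rep_cm <- vector("list", cfg$repetitions)
  manual <- as.character(data$label)

  for (r in seq_len(cfg$repetitions)) {
    parts <- with_local_seed(cfg$seed + 7919L * r,
                             partition_dataset(data, cfg))
    for (rot in seq_len(cfg$n_parts)) {
      test_idx <- parts[[rot]]
      val_idx <- parts[[rot %% cfg$n_parts + 1L]]
      train_idx <- setdiff(seq_len(n), c(test_idx, val_idx))
      if (length(train_idx) == 0 || length(test_idx) == 0) next
      fit_seed <- cfg$seed + 1000L * r + 10L * rot
      fits <- lapply(seq_len(nrow(grid)), function(g) {
        train_forest(data[train_idx, ], depth = grid$depth[g],
                     mtry = grid$mtry[g], n_trees = cfg$n_trees,
                     seed = fit_seed + g)
      })
      acc <- vapply(fits, function(f) {
        mean(predict_forest(f, data[val_idx, ]) == manual[val_idx])
      }, numeric(1))
      best <- which.max(acc)
      preds[test_idx, r] <- predict_forest(fits[[best]], data[test_idx, ])
      chosen[[length(chosen) + 1]] <-
        data.frame(repetition = r, rotation = rot,
                   depth = grid$depth[best], mtry = grid$mtry[best],
                   val_accuracy = acc[best])
    }
    per_rep_cm[[r]] <- confusion(manual, preds[, r])
  }

  avg <- Reduce(`+`, per_rep_cm) / cfg$repetitions
  avg <- round(avg)
  storage.mode(avg) <- "integer"
  modal <- apply(preds, 1, function(v) {
    v <- v[!is.na(v)]
    tb <- table(factor(v, levels = PET_CLASSES))
    names(tb)[which.max(tb)]   # which.max keeps canonical order on ties
  })
  pred_df <- data.frame(patient_id = data$patient_id,
                        region_id = data$region_id,
                        manual = manual, stringsAsFactors = FALSE)
  for (r in seq_len(cfg$repetitions))
    pred_df[[paste0("rep", r)]] <- preds[, r]
  pred_df$modal <- modal
  structure(list(predictions = pred_df, confusion = avg,
                 per_rep_confusion = per_rep_cm,
                 chosen = do.call(rbind, chosen), config = cfg),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> %d regions, %d repetitions\n",
              nrow(x$predictions), x$config$repetitions))
  bm <- binary_metrics(x$confusion)
  cat(sprintf("  tumor vs non-tumor: sensitivity %.0f%%, specificity %.0f%%\n",
              100 * bm$sensitivity, 100 * bm$specificity))
  invisible(x)
}
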