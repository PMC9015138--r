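#' Confusion matrix of manual vs automatic classification
#'
#' Rows are the automatic class, columns the manual (reference) class, both
#' over the full 14-class vocabulary in canonical order.
#'
#' @param manual,automatic aligned character vectors of class labels; `NA`
#'   automatic entries (regions never tested) are dropped pairwise.
#' @return 14 x 14 integer matrix of class `pet_confusion`.
#' @export
confusion <- function(manual, automatic) {
  if (length(manual) != length(automatic))
    stopf("label vectors must have equal length")
  keep <- !is.na(automatic)
  manual <- as.character(manual[keep])
  automatic <- as.character(automatic[keep])
  bad <- setdiff(unique(c(manual, automatic)), PET_CLASSES)
  if (length(bad) > 0)
    stopf("labels outside the class vocabulary: %s",
          paste(bad, collapse = ", "))
  m <- table(factor(automatic, levels = PET_CLASSES),
             factor(manual, levels = PET_CLASSES))
  out <- matrix(as.integer(m), nrow = length(PET_CLASSES),
                dimnames = list(automatic = PET_CLASSES,
                                manual = PET_CLASSES))
  class(out) <- c("pet_confusion", class(out))
  out
}

as_pet_confusion <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(14L, 14L)))
    stopf("expected a 14 x 14 matrix")
  dimnames(m) <- list(automatic = PET_CLASSES, manual = PET_CLASSES)
  if (!inherits(m, "pet_confusion")) class(m) <- c("pet_confusion", class(m))
  m
}

#' Read a confusion matrix from CSV
#'
#' Expects a header of manual-class columns and a first column of
#' automatic-class row labels. Classes missing from the file (e.g. brain on
#' cropped scans) are filled with zero rows/columns so the result is always
#' the full 14 x 14 frame.
#'
#' @param path CSV path.
#' @return A `pet_confusion` matrix.
#' @export
read_confusion_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, row.names = 1)
  bad <- setdiff(c(rownames(df), colnames(df)), PET_CLASSES)
  if (length(bad) > 0)
    stopf("unknown classes in %s: %s", path, paste(bad, collapse = ", "))
  m <- matrix(0L, 14, 14,
              dimnames = list(automatic = PET_CLASSES, manual = PET_CLASSES))
  m[rownames(df), colnames(df)] <- as.matrix(df)
  as_pet_confusion(m)
}

#' The published reference confusion matrix
#'
#' The 14-class confusion matrix reported for a manually classified cohort
#' of 60 clinical Hodgkin-lymphoma PET scans (853 segmented volumes),
#' shipped with the package as a reference for the evaluation functions.
#' Brain volumes never reached classification in that cohort (removed by
#' cropping), so its row and column are zero.
#'
#' @return A `pet_confusion` matrix with total 853.
#' @export
clinical_confusion_matrix <- function() {
  read_confusion_csv(system.file("extdata", "clinical_confusion_matrix.csv",
                                 package = "petlymph", mustWork = TRUE))
}

#' @export
print.pet_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = automatic, columns = manual):\n")
  print(unclass(x))
  invisible(x)
}

#' Binary tumor vs non-tumor metrics
#'
#' Collapses the 14-class matrix to 2 x 2 with tumor = \{T, T+NT\} on both
#' axes (composed tumor volumes count as tumor so that no tumor lesion is
#' missed) and derives sensitivity, specificity, PPV, NPV and
#' `F1 = 2 / (sensitivity^-1 + PPV^-1)`. Proportions are kept raw; the
#' `*_pct` fields give the whole-percent presentation.
#'
#' @param cm a [confusion()] matrix.
#' @return List with counts `tp`, `fp`, `fn`, `tn`, raw proportions
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `f1`, and rounded
#'   `sensitivity_pct` etc. Undefined proportions are `NaN`.
#' @export
binary_metrics <- function(cm) {
  cm <- as_pet_confusion(cm)
  tum <- PET_CLASSES %in% TUMOR_CLASSES
  tp <- sum(cm[tum, tum])
  fp <- sum(cm[tum, !tum])
  fn <- sum(cm[!tum, tum])
  tn <- sum(cm[!tum, !tum])
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NaN
  npv <- if (tn + fn > 0) tn / (tn + fn) else NaN
  f1 <- if (is.finite(sens) && is.finite(ppv) && sens > 0 && ppv > 0)
    2 / (1 / sens + 1 / ppv) else NaN
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              sensitivity = sens, specificity = spec,
              ppv = ppv, npv = npv, f1 = f1)
  pct <- lapply(out[c("sensitivity", "specificity", "ppv", "npv", "f1")],
                function(v) round(100 * v))
  names(pct) <- paste0(names(pct), "_pct")
  c(out, pct)
}

#' Per-tissue classification accuracy
#'
#' For each manual class, the fraction of its volumes the automatic
#' classification assigned to the same class (matrix diagonal over column
#' sum). The two kidneys are additionally reported pooled.
#'
#' @param cm a [confusion()] matrix.
#' @return List with `accuracy` (named proportions; `NaN` for empty
#'   classes), `accuracy_pct` (whole percent) and `kidneys_pooled` /
#'   `kidneys_pooled_pct`.
#' @export
per_class_accuracy <- function(cm) {
  cm <- as_pet_confusion(cm)
  colsum <- colSums(cm)
  acc <- ifelse(colsum > 0, diag(cm) / colsum, NaN)
  names(acc) <- PET_CLASSES
  kd <- sum(cm["RK", "RK"], cm["LK", "LK"])
  kn <- sum(colsum[c("RK", "LK")])
  kidneys <- if (kn > 0) kd / kn else NaN
  list(accuracy = acc, accuracy_pct = round(100 * acc),
       kidneys_pooled = kidneys, kidneys_pooled_pct = round(100 * kidneys))
}

#' Per-patient classification summary
#'
#' Tallies, per patient, the false-negative tumor lesions (manual tumor
#' classified non-tumor) and false-positive non-tumor volumes (manual
#' non-tumor classified tumor), and summarizes the cohort: patients with all
#' tumor lesions correct, with exactly one false negative, with at least one
#' false positive, and with every volume correct.
#'
#' @param results data.frame with `patient_id`, `manual` and `automatic`
#'   label columns.
#' @return List with `per_patient` (data.frame) and cohort `tallies`.
#' @export
patient_summary <- function(results) {
  if (!all(c("patient_id", "manual", "automatic") %in% names(results)))
    stopf("results needs patient_id, manual, automatic columns")
  man_t <- results$manual %in% TUMOR_CLASSES
  aut_t <- results$automatic %in% TUMOR_CLASSES
  fn <- man_t & !aut_t
  fp <- !man_t & aut_t
  wrong <- results$manual != results$automatic
  per <- do.call(rbind, lapply(split(seq_len(nrow(results)),
                                     results$patient_id), function(ix) {
    data.frame(patient_id = results$patient_id[ix[1]],
               n_regions = length(ix),
               n_tumor_manual = sum(man_t[ix]),
               n_false_negative = sum(fn[ix]),
               n_false_positive = sum(fp[ix]),
               n_misclassified = sum(wrong[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  tallies <- list(
    n_patients = nrow(per),
    all_tumor_correct = sum(per$n_false_negative == 0),
    exactly_one_false_negative = sum(per$n_false_negative == 1),
    with_false_positive = sum(per$n_false_positive > 0),
    all_volumes_correct = sum(per$n_misclassified == 0)
  )
  list(per_patient = per, tallies = tallies)
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, binary tumor metrics, per-class accuracies
#' and (when patient ids are available) the per-patient summary.
#'
#' @param manual,automatic aligned label vectors.
#' @param patient_id optional aligned patient ids.
#' @return List of class `evaluation_report`.
#' @export
evaluation_report <- function(manual, automatic, patient_id = NULL) {
  cm <- confusion(manual, automatic)
  rep <- list(confusion = cm,
              binary = binary_metrics(cm),
              per_class = per_class_accuracy(cm),
              n_regions = sum(cm))
  if (!is.null(patient_id)) {
    keep <- !is.na(automatic)
    rep$patients <- patient_summary(data.frame(
      patient_id = patient_id[keep], manual = manual[keep],
      automatic = automatic[keep], stringsAsFactors = FALSE))
  }
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  b <- x$binary
  cat(sprintf("Evaluation of %d volumes\n", x$n_regions))
  cat(sprintf("  tumor correct:     %d/%d\n", b$tp, b$tp + b$fn))
  cat(sprintf("  non-tumor correct: %d/%d\n", b$tn, b$tn + b$fp))
  cat(sprintf("  sensitivity %d%%  specificity %d%%  PPV %d%%  NPV %d%%  F1 %d%%\n",
              b$sensitivity_pct, b$specificity_pct, b$ppv_pct, b$npv_pct,
              b$f1_pct))
  acc <- x$per_class$accuracy_pct
  shown <- acc[!is.na(acc)]
  cat("  per-class accuracy (%):\n")
  print(shown)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an [evaluation_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  out <- list(
    confusion = unclass(report$confusion),
    binary = report$binary,
    per_class = report$per_class,
    n_regions = report$n_regions
  )
  if (!is.null(report$patients)) out$patients <- report$patients$tallies
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
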