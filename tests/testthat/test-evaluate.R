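test_that("confusion matrices tabulate automatic rows against manual columns", {
  man <- c("T", "SK", "SK", "HT")
  aut <- c("T", "SK", "T", "HT")
  cm <- confusion(man, aut)
  expect_equal(dim(cm), c(14L, 14L))
  expect_equal(sum(cm), 4)
  expect_equal(cm["T", "SK"], 1L)
  expect_equal(cm["SK", "SK"], 1L)

  # perfect agreement is diagonal
  cmp <- confusion(man, man)
  expect_equal(sum(diag(cmp)), 4)
  expect_equal(sum(cmp) - sum(diag(cmp)), 0)

  # empty input gives the zero matrix; unknown labels fail
  expect_equal(sum(confusion(character(0), character(0))), 0)
  expect_error(confusion("SPLEEN", "T"), "vocabulary")

  # regions never tested (NA automatic) are dropped pairwise
  expect_equal(sum(confusion(c("T", "SK"), c("T", NA))), 1)
})

test_that("the published reference matrix reproduces every derived number", {
  cm <- clinical_confusion_matrix()
  expect_equal(sum(cm), 853)

  b <- binary_metrics(cm)
  expect_equal(b$tp, 203)
  expect_equal(b$fn, 43)
  expect_equal(b$fp, 53)
  expect_equal(b$tn, 554)
  expect_equal(b$tp + b$fn, 246)
  expect_equal(b$tn + b$fp, 607)
  expect_equal(b$sensitivity_pct, 83)
  expect_equal(b$specificity_pct, 91)
  expect_equal(b$ppv_pct, 79)
  expect_equal(b$npv_pct, 93)
  expect_equal(b$f1_pct, 81)

  pc <- per_class_accuracy(cm)
  expect_equal(pc$accuracy_pct[["SK"]], 94)
  expect_equal(pc$accuracy_pct[["HN"]], 94)
  expect_equal(pc$accuracy_pct[["HT"]], 77)
  expect_equal(pc$accuracy_pct[["GI"]], 46)
  expect_equal(pc$accuracy_pct[["BF"]], 17)
  expect_equal(pc$accuracy_pct[["NT+NT"]], 0)
  expect_equal(pc$kidneys_pooled_pct, 90)
  expect_equal(pc$accuracy[["GI"]], 17 / 37)
})

test_that("binary metrics satisfy their marginal identities", {
  cm <- clinical_confusion_matrix()
  b <- binary_metrics(cm)
  tum <- PET_CLASSES %in% TUMOR_CLASSES
  expect_equal(b$tp + b$fn, sum(cm[, tum]))
  expect_equal(b$tp + b$fp, sum(cm[tum, ]))
  expect_equal(b$tp + b$fp + b$fn + b$tn, sum(cm))
  expect_equal(b$f1, 2 / (1 / b$sensitivity + 1 / b$ppv))

  # all-correct toy case
  toy <- confusion(c("T", "SK"), c("T", "SK"))
  bt <- binary_metrics(toy)
  expect_equal(bt$sensitivity, 1)
  expect_equal(bt$specificity, 1)
  expect_equal(bt$f1, 1)

  # no tumor column -> undefined sensitivity
  none <- confusion(c("SK", "HT"), c("SK", "HT"))
  expect_true(is.nan(binary_metrics(none)$sensitivity))
})

test_that("per-class accuracy is bounded and NaN on empty classes", {
  cm <- clinical_confusion_matrix()
  acc <- per_class_accuracy(cm)$accuracy
  defined <- acc[!is.nan(acc)]
  expect_true(all(defined >= 0 & defined <= 1))
  expect_true(is.nan(acc[["BRAIN"]]))

  ident <- confusion(PET_CLASSES, PET_CLASSES)
  expect_true(all(per_class_accuracy(ident)$accuracy == 1))
})

test_that("patient summaries tally false negatives and positives per patient", {
  res <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "C", "C", "C"),
    manual = c("T", "T", "SK", "T", "SK", "T", "GI", "SK"),
    automatic = c("T", "SK", "SK", "T", "T", "T", "T", "SK"),
    stringsAsFactors = FALSE)
  ps <- patient_summary(res)
  per <- ps$per_patient
  expect_equal(per$n_false_negative[per$patient_id == "A"], 1)
  expect_equal(per$n_false_positive[per$patient_id == "A"], 0)
  expect_equal(per$n_false_positive[per$patient_id == "B"], 1)
  expect_equal(per$n_false_positive[per$patient_id == "C"], 1)
  expect_equal(ps$tallies$n_patients, 3)
  expect_equal(ps$tallies$all_tumor_correct, 2)      # B and C
  expect_equal(ps$tallies$exactly_one_false_negative, 1)
  expect_equal(ps$tallies$with_false_positive, 2)
  expect_equal(ps$tallies$all_volumes_correct, 0)

  all_right <- data.frame(patient_id = c("A", "B"), manual = c("T", "SK"),
                          automatic = c("T", "SK"))
  expect_equal(patient_summary(all_right)$tallies$all_volumes_correct, 2)
})

test_that("evaluation reports serialize to JSON and back", {
  man <- c("T", "SK", "SK", "HT", "T")
  aut <- c("T", "SK", "T", "HT", "T")
  rep <- evaluation_report(man, aut, patient_id = c("A", "A", "B", "B", "B"))
  path <- tempfile(fileext = ".json")
  write_evaluation_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_regions, 5)
  expect_equal(back$binary$tp, 2)
  expect_equal(length(back$confusion), 14)
})
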