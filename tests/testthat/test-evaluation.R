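test_that("confusion tallies labels correctly", {
  # identical sequences -> diagonal
  labs <- rep(beat_classes(), times = c(3, 1, 2, 1, 1))
  cm <- confusion(labs, labs)
  expect_equal(diag(unclass(cm)), setNames(c(3L, 1L, 2L, 1L, 1L), beat_classes()))
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0L)
  # hand-placed off-diagonals
  cm2 <- confusion(c("NSR", "PVC", "APC"), c("NSR", "APC", "APC"))
  expect_equal(cm2["NSR", "NSR"], 1L)
  expect_equal(cm2["PVC", "APC"], 1L)
  expect_equal(cm2["APC", "APC"], 1L)
  expect_equal(sum(cm2), 3L)
  expect_error(confusion(c("NSR"), c("XYZ")), "outside")
  expect_error(confusion(c("NSR", "PVC"), c("NSR")), "equal length")
})

test_that("confusion matches a brute-force tally on random label pairs", {
  set.seed(8)
  truth <- sample(beat_classes(), 1000, replace = TRUE)
  pred <- sample(beat_classes(), 1000, replace = TRUE)
  expect_equal(unclass(confusion(truth, pred)),
               naive_confusion(truth, pred, beat_classes()),
               ignore_attr = "dimnames")
  expect_equal(dimnames(confusion(truth, pred))$truth, beat_classes())
})

test_that("published five-class matrices reproduce every printed error cell", {
  basic <- benchmark_matrix("basic_5class")
  expect_equal(round_half_up(misclassification_error(basic), 2),
               c(NSR = 1.87, LBBB = 3.05, RBBB = 3.45, APC = 13.99, PVC = 5.5))
  expanded <- benchmark_matrix("expanded_5class")
  err <- misclassification_error(expanded)
  expect_equal(round_half_up(err[1:4], 2),
               c(NSR = 2.68, LBBB = 4.93, RBBB = 3.61, APC = 7.21))
  expect_equal(round_half_up(err[["PVC"]], 1), 7.2)  # printed at 1 decimal
  # overall accuracy / error of the expanded model
  expect_equal(round_half_up(overall_accuracy(expanded), 2), 95.94)
  expect_equal(round_half_up(100 - overall_accuracy(expanded), 2), 4.06)
  expect_equal(sum(diag(unclass(expanded))), 9786L)
  expect_equal(sum(expanded), 10200L)
})

test_that("published three-class comparison matrices reproduce printed errors", {
  expect_equal(round_half_up(misclassification_error(
    benchmark_matrix("kiranyaz_3class")), 2),
    c(NSR = 1.43, APC = 36.36, PVC = 9.38))
  expect_equal(round_half_up(misclassification_error(
    benchmark_matrix("luo_3class")), 2),
    c(NSR = 6.18, APC = 52.61, PVC = 32.98))
  expect_equal(round_half_up(misclassification_error(
    benchmark_matrix("proposed_3class")), 2),
    c(NSR = 1.66, APC = 6.32, PVC = 6.61))
})

test_that("misclassification error is 100 - PPV per predicted class", {
  for (nm in c("basic_5class", "expanded_5class", "proposed_3class")) {
    m <- benchmark_matrix(nm)
    for (cls in colnames(m)) {
      bm <- binary_metrics(m, positive_classes = cls)
      expect_equal(misclassification_error(m, cls)[[cls]], 100 - bm$ppv,
                   tolerance = 1e-12)
    }
  }
  # diagonal matrix -> all zeros; empty column -> NA, not 0
  d <- as_confusion_matrix(diag(c(5L, 3L, 2L, 1L, 4L)), beat_classes())
  expect_equal(unname(misclassification_error(d)), rep(0, 5))
  m0 <- as_confusion_matrix(matrix(c(2L, 1L, 0L, 0L, 3L, 0L, 0L, 0L, 0L), 3),
                            c("NSR", "APC", "PVC"))
  expect_true(is.na(misclassification_error(m0)[["PVC"]]))
})

test_that("overall accuracy: closed forms and permutation invariance", {
  d <- as_confusion_matrix(diag(c(5L, 3L, 2L, 1L, 4L)), beat_classes())
  expect_equal(overall_accuracy(d), 100)
  basic <- benchmark_matrix("basic_5class")
  # independent hand summation of the printed diagonal and total
  diag_sum <- 4788 + 1973 + 1371 + 541 + 1169
  expect_equal(overall_accuracy(basic), 100 * diag_sum / sum(basic))
  # permuting classes consistently cannot change overall accuracy
  set.seed(13)
  for (r in 1:20) {
    p <- sample(5)
    perm <- as_confusion_matrix(unclass(basic)[p, p], beat_classes()[p])
    expect_equal(overall_accuracy(perm), overall_accuracy(basic))
  }
  expect_error(overall_accuracy(as_confusion_matrix(matrix(0L, 2, 2),
                                                    c("a", "b"))), "empty")
})

test_that("binary metrics evaluate the four ratios with NA degenerates", {
  m <- as_confusion_matrix(matrix(c(9L, 1L, 2L, 88L), 2, byrow = TRUE),
                           c("ABN", "NORM"))
  # TP=9 FN=1 FP=2 TN=88
  bm <- binary_metrics(m, positive_classes = "ABN")
  expect_equal(bm$tp, 9); expect_equal(bm$fn, 1)
  expect_equal(bm$fp, 2); expect_equal(bm$tn, 88)
  expect_equal(bm$sensitivity, 90)
  expect_equal(round_half_up(bm$specificity, 2), 97.78)
  expect_equal(round_half_up(bm$ppv, 2), 81.82)
  expect_equal(bm$accuracy, 97)
  # sensitivity + false-negative rate = 100
  expect_equal(bm$sensitivity + 100 * bm$fn / (bm$tp + bm$fn), 100)
  # perfect classifier
  perfect <- as_confusion_matrix(diag(c(4L, 6L)), c("ABN", "NORM"))
  bp <- binary_metrics(perfect, "ABN")
  expect_equal(c(bp$accuracy, bp$sensitivity, bp$specificity, bp$ppv),
               rep(100, 4))
  # all-negative predictions: Se = 0, PPV undefined
  allneg <- as_confusion_matrix(matrix(c(0L, 5L, 0L, 7L), 2, byrow = TRUE),
                                c("ABN", "NORM"))
  bn <- binary_metrics(allneg, "ABN")
  expect_equal(bn$sensitivity, 0)
  expect_true(is.na(bn$ppv))
  expect_error(binary_metrics(m, character(0)), "subset")
  expect_error(binary_metrics(m, c("ABN", "NORM")), "subset")
})

test_that("binary metrics agree after a label-sequence round trip", {
  set.seed(99)
  truth <- sample(beat_classes(), 400, replace = TRUE,
                  prob = c(0.5, 0.15, 0.1, 0.1, 0.15))
  pred <- ifelse(runif(400) < 0.8, truth,
                 sample(beat_classes(), 400, replace = TRUE))
  cm <- confusion(truth, pred)
  direct <- binary_metrics(cm, c("APC", "PVC"))
  # rebuild the 2x2 straight from the label sequences
  t2 <- ifelse(truth %in% c("APC", "PVC"), "pos", "neg")
  p2 <- ifelse(pred %in% c("APC", "PVC"), "pos", "neg")
  cm2 <- confusion(t2, p2, class_order = c("pos", "neg"))
  from_seq <- binary_metrics(cm2, "pos")
  expect_equal(direct, from_seq)
})

test_that("patient-specific relabeling follows the bundle-branch rules", {
  # records whose baseline rhythm is LBBB/RBBB keep those beats as normal
  expect_equal(as.character(patient_specific_relabel("109", "LBBB")), "normal")
  expect_equal(as.character(patient_specific_relabel("232", "RBBB")), "normal")
  # elsewhere a bundle branch block beat is abnormal
  expect_equal(as.character(patient_specific_relabel("100", "LBBB")), "abnormal")
  # NSR always normal, APC/PVC always abnormal
  expect_equal(as.character(patient_specific_relabel("109", "NSR")), "normal")
  expect_equal(as.character(patient_specific_relabel("109", "PVC")), "abnormal")
  expect_equal(as.character(patient_specific_relabel("207", "APC")), "abnormal")
  # vectorized and map-configurable
  out <- patient_specific_relabel(c("109", "100"), c("RBBB", "RBBB"),
                                  bbb_normal_records = "100")
  expect_equal(as.character(out), c("abnormal", "normal"))
  expect_setequal(bbb_record_ids(),
                  c("109", "111", "118", "124", "207", "214", "232"))
})

test_that("confusion CSVs round-trip through read/write", {
  dir <- withr::local_tempdir()
  m <- benchmark_matrix("basic_5class")
  write_confusion_csv(m, file.path(dir, "m.csv"))
  expect_equal(read_confusion_csv(file.path(dir, "m.csv")), m)
})

test_that("display rounding is half-up, not banker's", {
  # 0.125 is exactly representable: banker's rounding would give 0.12
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(100 * 88 / 629, 2), 13.99)
})
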