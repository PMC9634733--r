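test_that("voxel confusion matches a brute-force loop and exclusion semantics", {
  set.seed(7)
  dims <- c(6, 5, 4)
  gt <- array(sample(0:3, prod(dims), replace = TRUE), dims)
  pred <- array(sample(0:3, prod(dims), replace = TRUE), dims)
  conf <- voxel_confusion(gt, pred, exclude = c(0L, 1L), n_classes = 4L)
  # brute-force voxel loop; voxels with excluded ground truth are outside
  # the calculation entirely
  for (k in 0:3) {
    tp <- fp <- fn <- 0
    for (i in seq_len(prod(dims))) {
      if (gt[i] %in% c(0L, 1L)) next
      if (gt[i] == k && pred[i] == k) tp <- tp + 1
      if (gt[i] != k && pred[i] == k) fp <- fp + 1
      if (gt[i] == k && pred[i] != k) fn <- fn + 1
    }
    expect_equal(conf$tp[k + 1], tp)
    expect_equal(conf$fp[k + 1], fp)
    expect_equal(conf$fn[k + 1], fn)
  }
  # a prediction on a non-annotated (excluded) voxel is unverifiable, not
  # a false positive
  gtx <- array(1L, c(2, 2, 2)); prx <- array(3L, c(2, 2, 2))
  gtx[1, 1, 1] <- 3L; prx[1, 1, 1] <- 3L
  confx <- voxel_confusion(gtx, prx, n_classes = 4L)
  expect_equal(confx$fp[4], 0)
  expect_equal(confx$tp[4], 1)
  # perfect prediction: zero FP/FN
  confp <- voxel_confusion(gt, gt, n_classes = 4L)
  expect_true(all(confp$fp == 0) && all(confp$fn == 0))
  # predicting an excluded class still yields FN for the true class
  gt2 <- array(2L, c(2, 2, 2))
  pred2 <- array(0L, c(2, 2, 2))
  conf2 <- voxel_confusion(gt2, pred2, n_classes = 3L)
  expect_equal(conf2$fn[3], 8)
  expect_equal(conf2$tp[3], 0)
  expect_error(voxel_confusion(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 3))),
               "shape")
})

test_that("scores reproduce hand-computed F1, mF1 and bAcc exactly", {
  # class 1: TP=8 FN=2 FP=1; class 2: TP=4 FN=1 FP=2 (on included indices)
  conf <- structure(list(
    classes = 0:3, tp = c(0, 0, 8, 4), fp = c(0, 0, 1, 2),
    fn = c(0, 0, 2, 1), excluded = c(0L, 1L), included = c(2L, 3L),
    level = "voxel"), class = "confusion_counts")
  rep <- confusion_scores(conf)
  f1a <- 16 / 19
  f1b <- 8 / 11
  expect_equal(rep$per_class$f1, c(f1a, f1b), tolerance = 1e-12)
  expect_equal(rep$mF1, (f1a + f1b) / 2, tolerance = 1e-12)
  expect_equal(rep$bAcc, (0.8 + 0.8) / 2, tolerance = 1e-12)
  # perfect prediction scores 1
  confp <- structure(list(
    classes = 0:2, tp = c(5, 0, 9), fp = c(0, 0, 0), fn = c(0, 0, 0),
    excluded = c(0L, 1L), included = 2L, level = "voxel"),
    class = "confusion_counts")
  repp <- confusion_scores(confp)
  expect_equal(repp$mF1, 1.0)
  expect_equal(repp$bAcc, 1.0)
  # unsupported class: rejected when nothing remains
  conf0 <- structure(list(
    classes = 0:2, tp = c(1, 0, 0), fp = c(0, 0, 0), fn = c(0, 0, 0),
    excluded = c(0L, 1L), included = 2L, level = "voxel"),
    class = "confusion_counts")
  expect_error(confusion_scores(conf0), "support")
})

test_that("performance categories honor the published boundaries", {
  expect_equal(performance_category(c(0.91, 0.76, 0.61, 0.60)),
               c("excellent", "good", "moderate", "poor"))
  # half-open boundaries: exactly 0.9 / 0.75 are not in the higher band
  expect_equal(performance_category(c(0.9, 0.75)), c("good", "moderate"))
})

test_that("segment-wise scoring counts one prediction per segment", {
  # four single-voxel-run segments of distinct classes, one mislabeled
  dims <- c(8, 2, 2)
  table <- structure(list(
    segments = lapply(1:4, function(i) list(
      id = i, coords = matrix(c(2 * i - 2, 0, 0), 1, 3),
      endpoint_types = c("end", "end"), gt_label = i + 1L)),
    bifurcations = list(), dim = dims, spacing = c(1, 1, 1)),
    class = "segment_table")
  washed <- array(0L, dims)
  washed[1, 1, 1] <- 2L; washed[3, 1, 1] <- 3L
  washed[5, 1, 1] <- 4L; washed[7, 1, 1] <- 4L   # segment 4 mislabeled
  rep <- segment_scores(table, washed, n_classes = 6L)
  expect_equal(rep$level, "segment")
  expect_equal(sort(rep$per_class$recall), c(0, 1, 1, 1))
  expect_equal(rep$bAcc, 0.75, tolerance = 1e-12)
  # all correct: mF1 1
  washed[7, 1, 1] <- 5L
  expect_equal(segment_scores(table, washed, n_classes = 6L)$mF1, 1.0)
  # non-homogeneous segment rejected
  t2 <- table
  t2$segments[[1]]$coords <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  w2 <- washed; w2[1, 1, 1] <- 2L; w2[2, 1, 1] <- 3L
  expect_error(segment_scores(t2, w2, n_classes = 6L), "homogeneous")
})

test_that("cross-fold summary reports mean and sample sd", {
  mk <- function(mf1, bacc) structure(list(
    level = "voxel", per_class = data.frame(class = 2L, f1 = mf1,
                                            recall = bacc, precision = 1,
                                            support = 10, category = "good"),
    mF1 = mf1, bAcc = bacc, n_skipped = 0L, fold = NA_integer_),
    class = "metrics_report")
  s <- crossfold_summary(list(mk(0.8, 0.8), mk(0.9, 0.9)))
  expect_equal(unname(s$mF1["mean"]), 0.85)
  expect_equal(unname(s$mF1["sd"]), 0.07071068, tolerance = 1e-6)
  # identical reports: sd 0
  s2 <- crossfold_summary(list(mk(0.8, 0.8), mk(0.8, 0.8)))
  expect_equal(unname(s2$mF1["sd"]), 0)
  expect_error(crossfold_summary(list(mk(0.8, 0.8))), "two")
  bad <- mk(0.5, 0.5); bad$level <- "segment"
  expect_error(crossfold_summary(list(mk(0.8, 0.8), bad)), "mixed")
})

test_that("bAcc equals mF1 on a symmetric confusion (FP = FN per class)", {
  conf <- structure(list(
    classes = 0:3, tp = c(0, 0, 6, 6), fp = c(0, 0, 2, 2),
    fn = c(0, 0, 2, 2), excluded = c(0L, 1L), included = c(2L, 3L),
    level = "voxel"), class = "confusion_counts")
  rep <- confusion_scores(conf)
  expect_equal(rep$mF1, rep$bAcc, tolerance = 1e-12)
})
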