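subjects_df <- function(nA, nB) data.frame(
  id = sprintf("s%03d", seq_len(nA + nB)),
  tag = rep(c("A", "B"), c(nA, nB)), stringsAsFactors = FALSE)

test_that("stratified 4-fold split reproduces the 182/60 cohort arithmetic", {
  subj <- subjects_df(72, 170)
  fs <- make_folds(subj, k = 4, seed = 1)
  for (f in fs$folds) {
    expect_length(f$test, 60L)
    expect_length(f$train, 182L)
    expect_equal(sum(fs$strata[f$test] == "A"), 18L)
    expect_equal(sum(fs$strata[f$test] == "B"), 42L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  # test sets pairwise disjoint
  tests <- lapply(fs$folds, `[[`, "test")
  expect_length(unique(unlist(tests)), 240L)
  # leftovers (242 - 240) are in every training set
  left <- setdiff(subj$id, unlist(tests))
  expect_length(left, 2L)
  for (f in fs$folds) expect_true(all(left %in% f$train))
})

test_that("fold splitting covers edge cases and is reproducible", {
  # leave-one-out style: 4 subjects, one stratum, k = 4
  subj <- data.frame(id = letters[1:4], tag = "A")
  fs <- make_folds(subj, k = 4, seed = 2)
  for (f in fs$folds) {
    expect_length(f$test, 1L)
    expect_length(f$train, 3L)
  }
  # 8 A + 12 B with k = 4: 2 A + 3 B per test fold
  subj2 <- subjects_df(8, 12)
  fs2 <- make_folds(subj2, k = 4, seed = 3)
  for (f in fs2$folds) {
    expect_equal(sum(fs2$strata[f$test] == "A"), 2L)
    expect_equal(sum(fs2$strata[f$test] == "B"), 3L)
  }
  # reproducibility
  expect_identical(make_folds(subj2, k = 4, seed = 3), fs2)
  expect_false(identical(make_folds(subj2, k = 4, seed = 4)$folds,
                         fs2$folds))
  # stratum smaller than k is rejected
  expect_error(make_folds(subjects_df(2, 12), k = 4), "at least k")
})

test_that("patch centers are sampled per segment without replacement", {
  arr <- array(0L, c(60, 8, 8))
  arr[2:55, 4, 4] <- 1L
  st <- extract_segments(skeletonize(volume_grid(arr)))
  ctr <- sample_patch_centers(st, per_segment = 8, seed = 1)
  expect_equal(nrow(ctr), 8L)
  expect_equal(nrow(unique(ctr)), 8L)
  # centers lie on the segment
  seg_flat <- st$segments[[1]]$coords
  expect_true(all(apply(ctr, 1, function(r)
    any(seg_flat[, 1] == r[1] & seg_flat[, 2] == r[2] &
        seg_flat[, 3] == r[3]))))
  # short segment: all its voxels are used
  arr2 <- array(0L, c(10, 6, 6))
  arr2[3:7, 3, 3] <- 1L
  st2 <- extract_segments(skeletonize(volume_grid(arr2)))
  n2 <- nrow(st2$segments[[1]]$coords)
  expect_lt(n2, 8)
  expect_equal(nrow(sample_patch_centers(st2, 8, seed = 1)), n2)
  # empty table: no centers
  empty <- extract_segments(skeletonize(volume_grid(array(0L, c(8, 8, 8)))))
  expect_equal(nrow(sample_patch_centers(empty, 8, seed = 1)), 0L)
  # seeded determinism
  expect_identical(sample_patch_centers(st, 8, seed = 9),
                   sample_patch_centers(st, 8, seed = 9))
})

test_that("dual patches are concentric, aligned and zero-padded at borders", {
  dims <- c(24, 24, 16)
  img <- volume_grid(array(seq_len(prod(dims)), dims))
  ves <- volume_grid(array(0, dims))
  ves[12, 12, 8] <- 2.5
  gt <- volume_grid(array(3L, dims))
  # interior center: main patch equals the direct crop
  pp <- extract_dual_patch(img, ves, gt, center = c(11, 11, 7),
                           main_size = c(8, 8, 4))
  direct <- img[8:15, 8:15, 6:9]
  expect_equal(pp$main[, , , 1], unclass(direct), ignore_attr = TRUE)
  # the vessel channel has the radius at the patch center
  expect_equal(pp$main[5, 5, 3, 2], 2.5)
  expect_equal(pp$context[9, 9, 5, 2], 2.5)
  # corner center: exactly the out-of-volume region is zero
  pc <- extract_dual_patch(img, ves, gt, center = c(0, 0, 0),
                           main_size = c(8, 8, 4))
  brute <- array(0, c(8, 8, 4))
  brute[5:8, 5:8, 3:4] <- img[1:4, 1:4, 1:2]
  expect_equal(pc$main[, , , 1], brute, ignore_attr = TRUE)
  expect_true(all(pc$gt[1:4, , ] == 0))
  expect_true(all(pc$gt[5:8, 5:8, 3:4] == 3L))
  # contract checks
  expect_error(extract_dual_patch(img, ves, gt, c(30, 0, 0), c(8, 8, 4)),
               "outside")
  expect_error(extract_dual_patch(img, ves, gt, c(4, 4, 4), c(8, 8, 4),
                                  context_size = c(12, 16, 8)), "2 x")
})

test_that("min-max scaling uses training statistics and clips test values", {
  subs <- list(list(image = array(c(0, 100), c(2, 1, 1)),
                    vessel = array(c(0, 4), c(2, 1, 1))))
  stats <- fit_scaling(subs)
  expect_equal(unname(stats["image", ]), c(0, 100), ignore_attr = TRUE)
  p <- structure(list(
    main = array(50, c(2, 2, 2, 2)), context = array(120, c(4, 4, 4, 2)),
    gt = NULL, center = c(1, 1, 1), spacing = c(1, 1, 1),
    subject_id = "t"), class = "patch_pair")
  p$main[, , , 2] <- 0
  sc <- apply_scaling(p, stats)
  expect_equal(unique(as.vector(sc$main[, , , 1])), 0.5)
  expect_equal(unique(as.vector(sc$main[, , , 2])), 0)   # fixed point at 0
  expect_equal(unique(as.vector(sc$context[, , , 1])), 1)  # clipped
  # degenerate channel rejected
  bad <- list(list(image = array(5, c(2, 1, 1)), vessel = array(0:1, c(2, 1, 1))))
  expect_error(fit_scaling(bad), "degenerate")
})

test_that("rotation augmentation keeps originals and cannot invent labels", {
  s <- local_phantom(42)
  stats <- fit_scaling(list(s))
  centers <- sample_patch_centers(s$segments, 1, seed = 2)
  pts <- lapply(1:4, function(i)
    extract_dual_patch(s$image, s$vessel, s$gt_labels, centers[i, ],
                       c(16, 16, 8)))
  aug <- augment_rotations(pts, inflation = 3, seed = 5)
  expect_length(aug, 12L)
  for (i in 1:4) expect_identical(aug[[i]], pts[[i]])
  for (i in 5:12) {
    orig <- pts[[(i - 1) %% 4 + 1]]
    expect_true(all(unique(as.integer(aug[[i]]$gt)) %in%
                    c(0L, unique(as.integer(orig$gt)))))
  }
  # inflation 1 is the identity
  expect_identical(augment_rotations(pts, inflation = 1, seed = 5), pts)
  # determinism
  aug2 <- augment_rotations(pts, inflation = 3, seed = 5)
  expect_identical(aug, aug2)
})
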