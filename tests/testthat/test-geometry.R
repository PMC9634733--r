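test_that("skeletonizing a solid cylinder recovers its axis and radius", {
  for (sp in list(c(1, 1, 1), c(0.6, 0.6, 0.7))) {
    r_mm <- 3 * sp[1]     # nominal radius: 3 voxels in x/y units
    mask <- cylinder_mask(dims = c(24, 24, 24), radius = r_mm, axis = 3,
                          spacing = sp)
    cl <- skeletonize(mask)
    expect_gt(nrow(cl$coords), 0)
    # oracle: the analytic axis (x = y = center)
    ctr <- (dim(mask)[1:2] + 1) / 2 - 1   # 0-based
    off <- sqrt((cl$coords[, 1] - ctr[1])^2 * sp[1]^2 +
                (cl$coords[, 2] - ctr[2])^2 * sp[2]^2)
    expect_lt(max(off), 1.5 * max(sp[1:2]))   # on-axis up to grid parity
    # radius encoded within one voxel of the nominal value
    mid <- cl$coords[, 3] > 4 & cl$coords[, 3] < 19  # away from the caps
    expect_true(all(abs(cl$radius_mm[mid] - r_mm) <= max(sp)))
    # one voxel thin: interior centerline voxels have exactly 2 neighbors
    # (interior relative to the skeleton's own extent — caps erode a bit)
    dense01 <- array(cl$dense > 0, dim(mask))
    cnt <- cpp_neighbor_count26(dense01, dim(mask))
    zr <- range(cl$coords[, 3])
    inner <- cl$coords[, 3] > zr[1] + 2 & cl$coords[, 3] < zr[2] - 2
    flat <- cl$coords[, 1] + 1 + dim(mask)[1] * cl$coords[, 2] +
      dim(mask)[1] * dim(mask)[2] * cl$coords[, 3]
    expect_true(all(cnt[flat[inner]] == 2))
  }
})

test_that("skeletonize validates input and handles the empty mask", {
  expect_error(skeletonize(volume_grid(array(2, c(4, 4, 4)))), "binary")
  cl <- skeletonize(volume_grid(array(0L, c(8, 8, 8))))
  expect_equal(nrow(cl$coords), 0L)
  expect_equal(length(extract_segments(cl)$segments), 0L)
})

test_that("a Y-shaped mask yields one bifurcation and three segments", {
  mask <- y_mask()
  cl <- skeletonize(mask)
  # brute-force degree count: at least one centerline voxel of degree >= 3
  dense01 <- array(cl$dense > 0, dim(mask))
  cnt <- cpp_neighbor_count26(dense01, dim(mask))
  flat <- cl$coords[, 1] + 1 + dim(mask)[1] * cl$coords[, 2] +
    dim(mask)[1] * dim(mask)[2] * cl$coords[, 3]
  expect_gte(max(cnt[flat]), 3)
  st <- extract_segments(cl)
  expect_equal(length(st$segments), 3L)
  expect_equal(length(st$bifurcations), 1L)
  # branch tips are free ends, junction sides are bifurcation-typed
  types <- t(sapply(st$segments, `[[`, "endpoint_types"))
  expect_equal(sum(types == "bifurcation"), 3L)
  expect_equal(sum(types == "end"), 3L)
})

test_that("segment runs partition the centerline; curves and components behave", {
  # single open curve: 1 segment, both endpoints free
  arr <- array(0L, c(20, 8, 8))
  arr[3:18, 4, 4] <- 1L
  cl <- skeletonize(volume_grid(arr))
  st <- extract_segments(cl)
  expect_equal(length(st$segments), 1L)
  expect_equal(st$segments[[1]]$endpoint_types, c("end", "end"))
  # ordered run: consecutive voxels are 26-adjacent
  co <- st$segments[[1]]$coords
  steps <- abs(diff(co))
  expect_true(all(steps <= 1))
  # two disjoint curves: 2 segments, 0 bifurcations
  arr2 <- arr
  arr2[3:18, 4, 6] <- 1L
  st2 <- extract_segments(skeletonize(volume_grid(arr2)))
  expect_equal(length(st2$segments), 2L)
  expect_equal(length(st2$bifurcations), 0L)
  # partition on a full phantom: every centerline voxel in exactly one run
  prep <- local_phantom(42)
  tot <- sum(vapply(prep$segments$segments,
                    function(s) nrow(s$coords), 0L))
  expect_equal(tot, nrow(prep$centerline$coords))
  allco <- do.call(rbind, lapply(prep$segments$segments, `[[`, "coords"))
  expect_equal(nrow(unique(allco)), nrow(allco))
})

test_that("thinning preserves connected-component count on phantoms", {
  for (seed in c(5, 17)) {
    s <- sample_subject(seed = seed)
    dims <- dim(s$vessel_mask)
    n_before <- max(cpp_components26(array(s$vessel_mask == 1, dims), dims))
    cl <- skeletonize(s$vessel_mask, prune_spurs = 0)
    dense01 <- array(cl$dense > 0, dims)
    n_after <- max(cpp_components26(dense01, dims))
    expect_equal(n_after, n_before)
  }
})

test_that("segment-id volume assigns each lumen voxel its nearest run", {
  # mask == centerline: ids are the table's own per-voxel ids
  arr <- array(0L, c(16, 8, 8))
  arr[2:14, 4, 4] <- 1L
  vol <- volume_grid(arr)
  cl <- skeletonize(vol)
  st <- extract_segments(cl)
  ids <- segment_id_volume(st, vol)
  flat <- st$segments[[1]]$coords
  expect_true(all(ids[flat[, 1] + 1 + 16 * flat[, 2] + 128 * flat[, 3]] ==
                  st$segments[[1]]$id))
  # single straight tube: all lumen voxels share one id
  tube <- cylinder_mask(dims = c(16, 16, 20), radius = 2.5, axis = 3)
  stt <- extract_segments(skeletonize(tube))
  idt <- segment_id_volume(stt, tube)
  expect_equal(sort(unique(as.integer(idt))), c(0L, stt$segments[[1]]$id))
  expect_true(all(idt[tube == 1] > 0))
  # two parallel tubes 6 voxels apart: no bleed, oracle by brute force
  arr2 <- array(0L, c(20, 16, 8))
  arr2[3:17, 5, 4] <- 1L
  arr2[3:17, 11, 4] <- 1L
  vol2 <- volume_grid(arr2)
  st2 <- extract_segments(skeletonize(vol2))
  ids2 <- segment_id_volume(st2, vol2)
  expect_length(unique(ids2[arr2[, 5, ] == 1]), 0L + 0L + 1L)
  expect_length(unique(as.integer(ids2[, 5, ][arr2[, 5, ] == 1])), 1L)
  expect_length(unique(as.integer(ids2[, 11, ][arr2[, 11, ] == 1])), 1L)
  expect_false(ids2[10, 5, 4] == ids2[10, 11, 4])
  # empty table with non-empty mask is rejected
  empty <- extract_segments(skeletonize(volume_grid(array(0L, dim(arr2)))))
  expect_error(segment_id_volume(empty, vol2), "empty segment table")
})

test_that("per-segment ground-truth labels use majority with fallbacks", {
  arr <- array(0L, c(12, 6, 6))
  arr[2:10, 3, 3] <- 1L
  vol <- volume_grid(arr)
  st <- extract_segments(skeletonize(vol))
  # homogeneous segment
  gt <- volume_grid(array(0L, dim(arr)))
  gt[arr == 1] <- 7L
  st1 <- segment_gt_labels(st, gt)
  expect_equal(st1$segments[[1]]$gt_label, 7L)
  # 60/40 mix: majority wins (and a message reports the mixed segment)
  n <- nrow(st$segments[[1]]$coords)
  co <- st$segments[[1]]$coords
  flat <- co[, 1] + 1 + 12 * co[, 2] + 72 * co[, 3]
  gt2 <- array(0L, dim(arr))
  gt2[flat] <- c(rep(4L, ceiling(0.6 * n)), rep(9L, floor(0.4 * n)))
  expect_message(st2 <- segment_gt_labels(st, volume_grid(gt2)), "majority")
  expect_equal(st2$segments[[1]]$gt_label, 4L)
  # no ground-truth overlap: non-annotated fallback
  st3 <- segment_gt_labels(st, volume_grid(array(0L, dim(arr))))
  expect_equal(st3$segments[[1]]$gt_label, 1L)
})

test_that("re-skeletonizing a rasterized tree recovers its segment count", {
  # well-separated tree: no dropped segments, no twigs
  s <- sample_subject(seed = 3, missing_prob = 0, nonannotated_prob = 0)
  prep <- prepare_subject(s)
  n_template <- 24L
  n_found <- length(prep$segments$segments)
  # thinning can add/merge a couple of short runs near complex junctions
  expect_gte(n_found, n_template - 2L)
  expect_lte(n_found, n_template + 4L)
})
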