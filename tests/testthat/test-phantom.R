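test_that("the template tree is complete, symmetric and anatomically wired", {
  tree <- build_template_tree()
  codes <- vapply(tree$segments, `[[`, "", "code")
  expect_length(codes, 24L)
  expect_true(all(tree$present))
  expect_setequal(codes, detailed_taxonomy()$classes$code[-(1:2)])
  # AcomA endpoints coincide with the A1/A2 junctions on both sides
  acom <- tree$segments[[which(codes == "ACOM")]]
  a1d <- tree$segments[[which(codes == "D-A1")]]
  a1s <- tree$segments[[which(codes == "S-A1")]]
  expect_equal(acom$points[1, ], a1d$points[nrow(a1d$points), ])
  expect_equal(acom$points[2, ], a1s$points[nrow(a1s$points), ])
  conn <- tree$connectivity
  pair <- function(a, b) any((conn$seg_a == a & conn$seg_b == b) |
                             (conn$seg_a == b & conn$seg_b == a))
  expect_true(pair("ACOM", "D-A1"))
  expect_true(pair("ACOM", "S-A2"))
  expect_true(pair("D-ICA", "D-ICA-CoW"))
  expect_true(pair("BA", "D-P1"))
  expect_true(pair("D-PCOM", "D-ICA-CoW"))
  expect_true(pair("D-PCOM", "D-P1"))
  # M2 radii never exceed the parent M1 radius
  for (side in c("D", "S")) {
    m1 <- tree$segments[[which(codes == paste0(side, "-M1"))]]
    for (sub in c("-M2-sup", "-M2-inf")) {
      m2 <- tree$segments[[which(codes == paste0(side, sub))]]
      expect_lte(max(m2$radius), min(m1$radius))
    }
  }
  # mirror symmetry of paired segments across x = 0.5
  m1d <- tree$segments[[which(codes == "D-M1")]]$points
  m1s <- tree$segments[[which(codes == "S-M1")]]$points
  expect_equal(1 - m1d[, 1], m1s[, 1])
  expect_equal(m1d[, 2:3], m1s[, 2:3])
  # all radii positive
  expect_true(all(unlist(lapply(tree$segments, `[[`, "radius")) > 0))
})

test_that("sampled subjects honor the label/mask contract and determinism", {
  s <- sample_subject(seed = 1234)
  expect_identical(dim(s$image), dim(s$vessel_mask))
  expect_identical(dim(s$image), dim(s$gt_labels))
  expect_true(all((s$gt_labels > 0) == (s$vessel_mask == 1)))
  expect_true(all(s$gt_labels %in% 0:25))
  # same seed: bit-identical subject
  s2 <- sample_subject(seed = 1234)
  expect_identical(unclass(s$image), unclass(s2$image))
  expect_identical(unclass(s$gt_labels), unclass(s2$gt_labels))
  expect_identical(s$tree$present, s2$tree$present)
  # different seed: different image
  s3 <- sample_subject(seed = 1235)
  expect_false(identical(unclass(s$image), unclass(s3$image)))
  # grid validation
  expect_error(sample_subject(seed = 1, dims = c(8, 96, 48)), "16")
})

test_that("missing-segment simulation follows the droppable set", {
  # nothing missing at probability 0
  s0 <- sample_subject(seed = 2, missing_prob = 0)
  expect_setequal(setdiff(unique(as.integer(s0$gt_labels)), c(0L, 1L)), 2:25)
  # forced dropping restricted to the requested segments
  tax <- detailed_taxonomy()
  pcom <- tax$classes$index[tax$classes$code %in% c("D-PCOM", "S-PCOM")]
  hits <- 0L
  for (seed in 1:6) {
    s1 <- sample_subject(seed = seed, missing_prob = 1,
                         droppable = c("D-PCOM", "S-PCOM"))
    codes <- vapply(s1$tree$segments, `[[`, "", "code")
    dropped <- codes[!s1$tree$present]
    expect_gt(length(dropped), 0L)
    expect_true(all(dropped %in% c("D-PCOM", "S-PCOM")))
    present_labels <- unique(as.integer(s1$gt_labels))
    expect_false(any(pcom[!codes[match(c("D-PCOM", "S-PCOM"), codes)] %in%
                            dropped] %in% setdiff(2:25, present_labels)))
    if (length(dropped) == 2L) {
      expect_false(any(pcom %in% present_labels))
      hits <- hits + 1L
    }
  }
})

test_that("vessel voxels are separable from background at default noise", {
  s <- sample_subject(seed = 77)
  m <- s$vessel_mask == 1
  bg <- s$image[!m]
  expect_gte(mean(s$image[m]) - mean(bg), 2 * stats::sd(bg))
})

test_that("rasterized tube radius is recovered by the distance transform", {
  # straight, well-separated tubes of known radius via the same rasterizer
  sp <- c(0.6, 0.6, 0.7)
  dims <- c(48L, 24L, 24L)
  for (r in c(1.5, 2.5)) {
    pts <- cbind(seq(5, 24, by = 0.25), 7.2, 8.4)
    ras <- cpp_rasterize_tubes(pts, rep(r, nrow(pts)),
                               rep(1L, nrow(pts)), dims, sp)
    mask <- array(ras$mask, dims)
    edt <- cpp_edt(mask, dims, sp)
    cl <- skeletonize(volume_grid(array(as.integer(mask), dims), sp))
    mid <- cl$coords[, 1] > 12 & cl$coords[, 1] < 36
    expect_true(all(abs(cl$radius_mm[mid] - r) <= max(sp)))
  }
})

test_that("ground truth is homogeneous within each tree segment", {
  s <- sample_subject(seed = 31, missing_prob = 0, nonannotated_prob = 0)
  prep <- prepare_subject(s)
  labs <- vapply(prep$segments$segments, `[[`, 0L, "gt_label")
  # each extracted run is dominated by a single ground-truth class: tube
  # overlap near junctions may hand a few voxels to neighboring classes
  dims <- dim(s$gt_labels)
  for (seg in prep$segments$segments) {
    flat <- seg$coords[, 1] + 1 + dims[1] * seg$coords[, 2] +
      dims[1] * dims[2] * seg$coords[, 3]
    vals <- as.integer(s$gt_labels[flat])
    vals <- vals[vals > 0]
    expect_gte(max(table(vals)) / length(vals), 0.5)
  }
  expect_gte(length(intersect(labs, 2:25)), 22L)
})

test_that("cohorts have derived seeds, requested tags and manifest output", {
  n <- 6
  cohort <- generate_cohort(n, c(A = 2, B = 4), base_seed = 9,
                            dims = c(48, 48, 24))
  expect_length(cohort, n)
  tags <- vapply(cohort, `[[`, "", "cohort_tag")
  expect_equal(unname(table(tags)[c("A", "B")]), c(2L, 4L),
               ignore_attr = TRUE)
  seeds <- vapply(cohort, `[[`, 0L, "seed")
  expect_length(unique(seeds), n)
  # distinct trees
  expect_false(identical(cohort[[1]]$tree$segments[[1]]$points,
                         cohort[[2]]$tree$segments[[1]]$points))
  # cohort IO: manifest + per-subject files round-trip
  td <- tempfile()
  man <- write_cohort(cohort[1:2], td)
  expect_true(file.exists(file.path(td, "manifest.tsv")))
  expect_equal(nrow(man), 2L)
  img <- read_volume(file.path(td, cohort[[1]]$subject_id, "image.nii.gz"))
  expect_equal(unclass(img), unclass(cohort[[1]]$image), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(vg_spacing(img), vg_spacing(cohort[[1]]$image),
               tolerance = 1e-6)
  # deterministic regeneration yields an identical manifest
  cohort2 <- generate_cohort(n, c(A = 2, B = 4), base_seed = 9,
                             dims = c(48, 48, 24))
  expect_identical(vapply(cohort2, `[[`, 0L, "seed"), seeds)
})
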