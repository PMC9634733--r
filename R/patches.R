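# Cohort fold-splitting, patch-center sampling, dual-scale concentric patch
# extraction with zero padding, training-set min-max intensity scaling, and
# rotation augmentation.

#' Stratified k-fold split at subject level
#'
#' Shuffles each stratum (cohort tag) under `seed`, then assigns
#' `floor(stratum size / k)` subjects of every stratum to each test fold.
#' Leftover subjects (stratum size mod k) never appear in any test set and
#' are part of every training set; each train set is the complement of its
#' test set. With a 242-subject cohort split 72 + 170 and k = 4 this gives
#' the 182 train / 60 test arithmetic of a two-study stroke cohort.
#'
#' @param subjects data.frame with columns `id` and `tag` (stratum).
#' @param k number of folds (>= 2).
#' @param seed RNG seed for the within-stratum shuffles.
#' @return a `fold_split`: `k`, `folds` (list of `train`/`test` id vectors),
#'   `strata`.
#' @export
make_folds <- function(subjects, k = 4, seed = 1) {
  stopifnot(k >= 2, all(c("id", "tag") %in% names(subjects)))
  tabs <- table(subjects$tag)
  if (any(tabs < k))
    stop("every stratum needs at least k subjects; smallest has ", min(tabs))
  test_sets <- rep(list(character(0)), k)
  with_seed(seed, {
    for (tg in names(tabs)) {
      ids <- sample(subjects$id[subjects$tag == tg])
      f <- length(ids) %/% k
      for (i in seq_len(k))
        test_sets[[i]] <- c(test_sets[[i]], ids[((i - 1) * f + 1):(i * f)])
    }
  })
  folds <- lapply(test_sets, function(te)
    list(train = setdiff(subjects$id, te), test = te))
  structure(list(k = k, folds = folds,
                 strata = stats::setNames(as.character(subjects$tag),
                                          subjects$id)),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("fold_split: k=%d\n", x$k))
  for (i in seq_len(x$k))
    cat(sprintf("  fold %d: train %d / test %d\n", i,
                length(x$folds[[i]]$train), length(x$folds[[i]]$test)))
  invisible(x)
}

#' Sample patch centers along centerline segments
#'
#' For each segment, up to `per_segment` distinct centerline voxel
#' coordinates are drawn uniformly without replacement (all voxels when the
#' segment is shorter than `per_segment`).
#'
#' @param table a `segment_table`.
#' @param per_segment centers per segment (default 8).
#' @param seed RNG seed.
#' @return integer matrix (n x 3) of 0-based voxel coordinates with a
#'   `segment_id` attribute.
#' @export
sample_patch_centers <- function(table, per_segment = 8, seed = 1) {
  stopifnot(per_segment >= 1)
  if (!length(table$segments)) {
    out <- matrix(integer(0), 0, 3)
    attr(out, "segment_id") <- integer(0)
    return(out)
  }
  with_seed(seed, {
    picks <- lapply(table$segments, function(s) {
      nvox <- nrow(s$coords)
      take <- min(per_segment, nvox)
      rows <- if (nvox == 1) 1L else sample.int(nvox, take)
      cbind(s$coords[rows, , drop = FALSE], s$id)
    })
    all <- do.call(rbind, picks)
    out <- all[, 1:3, drop = FALSE]
    attr(out, "segment_id") <- all[, 4]
    out
  })
}

# crop arr around 0-based center with zero padding; patch voxel at offset
# floor(size/2) is the center voxel
crop_pad <- function(arr, center, size) {
  dims <- dim(arr)
  out <- array(0, size)
  start <- center - size %/% 2L               # 0-based start in volume
  src_lo <- pmax(start, 0L)
  src_hi <- pmin(start + size - 1L, dims - 1L)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - start
  out[(dst_lo[1] + 1):(dst_lo[1] + src_hi[1] - src_lo[1] + 1),
      (dst_lo[2] + 1):(dst_lo[2] + src_hi[2] - src_lo[2] + 1),
      (dst_lo[3] + 1):(dst_lo[3] + src_hi[3] - src_lo[3] + 1)] <-
    arr[(src_lo[1] + 1):(src_hi[1] + 1),
        (src_lo[2] + 1):(src_hi[2] + 1),
        (src_lo[3] + 1):(src_hi[3] + 1)]
  out
}

#' Extract a concentric dual-scale patch pair
#'
#' Crops image and vessel (centerline-radius) channels at two concentric
#' sizes around `center` — the main patch for the standard encoder and a
#' context patch twice its size per axis for the context path — plus the
#' ground-truth label patch at main size. Regions beyond the volume border
#' are zero-padded. Both channels come from the same grid, so they are
#' aligned by construction.
#'
#' @param image intensity `volume_grid`.
#' @param vessel centerline radius `volume_grid` (dense channel from
#'   [skeletonize()]).
#' @param gt integer class-index `volume_grid`, or `NULL` at predict time.
#' @param center 0-based voxel index (length 3).
#' @param main_size,context_size per-axis patch dims;
#'   `context_size = 2 * main_size`.
#' @param subject_id carried through for bookkeeping.
#' @return a `patch_pair`: `main` and `context` arrays (x,y,z,channel),
#'   `gt`, `center`, `spacing`, `subject_id`.
#' @export
extract_dual_patch <- function(image, vessel, gt, center,
                               main_size = c(32, 32, 16),
                               context_size = 2 * main_size,
                               subject_id = NA_character_) {
  main_size <- as.integer(main_size)
  context_size <- as.integer(context_size)
  center <- as.integer(center)
  if (!all(context_size == 2L * main_size))
    stop("context_size must be exactly 2 x main_size per axis")
  if (any(main_size %% 2L != 0L))
    stop("patch dims must be even")
  dims <- dim(image)
  if (any(center < 0L) || any(center >= dims))
    stop("center outside grid: ", paste(center, collapse = ","))
  check_same_grid(image, vessel, "image and vessel channels")
  main <- array(0, c(main_size, 2L))
  main[, , , 1] <- crop_pad(image, center, main_size)
  main[, , , 2] <- crop_pad(vessel, center, main_size)
  ctx <- array(0, c(context_size, 2L))
  ctx[, , , 1] <- crop_pad(image, center, context_size)
  ctx[, , , 2] <- crop_pad(vessel, center, context_size)
  gtp <- if (is.null(gt)) NULL else {
    storage.mode(gt) <- "double"
    array(as.integer(crop_pad(gt, center, main_size)), main_size)
  }
  structure(list(main = main, context = ctx, gt = gtp, center = center,
                 spacing = vg_spacing(image), subject_id = subject_id),
            class = "patch_pair")
}

#' Fit / apply training-set min-max scaling
#'
#' `fit_scaling` computes global per-channel minima and maxima over the
#' training subjects (image channel over the whole volume, vessel channel
#' over the dense radius map). `apply_scaling` maps each channel of a patch
#' pair through `(x - min) / (max - min)`, clipping test values outside the
#' training range to `[0, 1]`.
#'
#' @param subjects list of `phantom_subject`s, or a list of
#'   `list(image=, vessel=)` volumes.
#' @return `fit_scaling`: a `scaling_stats` matrix (2 channels x min, max).
#' @export
fit_scaling <- function(subjects) {
  rng <- sapply(subjects, function(s) {
    img <- s$image
    ves <- if (!is.null(s$vessel)) s$vessel else s$centerline$dense
    if (is.null(ves)) stop("subject lacks a vessel/centerline channel")
    c(min(img), max(img), min(ves), max(ves))
  })
  stats <- matrix(c(min(rng[1, ]), max(rng[2, ]),
                    min(rng[3, ]), max(rng[4, ])),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("image", "vessel"), c("min", "max")))
  if (any(stats[, "max"] <= stats[, "min"]))
    stop("degenerate channel: max equals min in training set")
  structure(stats, class = c("scaling_stats", "matrix"))
}

#' @rdname fit_scaling
#' @param patch a `patch_pair` (or plain 4-D array x,y,z,channel).
#' @param stats a `scaling_stats`.
#' @export
apply_scaling <- function(patch, stats) {
  scale_arr <- function(a) {
    for (c in seq_len(dim(a)[4])) {
      lo <- stats[c, "min"]; hi <- stats[c, "max"]
      a[, , , c] <- pmin(pmax((a[, , , c] - lo) / (hi - lo), 0), 1)
    }
    a
  }
  if (inherits(patch, "patch_pair")) {
    patch$main <- scale_arr(patch$main)
    patch$context <- scale_arr(patch$context)
    patch
  } else scale_arr(patch)
}

# rotation matrix about unit axis u by angle theta (Rodrigues)
.rot_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation augmentation of training patches
#'
#' Inflates the training set: originals are kept and each patch gains
#' `inflation - 1` independently rotated copies. The rotation axis is
#' uniform on the sphere and the angle uniform in `angle_range_deg`
#' (default -60 to +60 degrees); the same rotation is applied to main,
#' context and ground-truth patches about their centers in physical (mm)
#' space. The image channel is interpolated trilinearly, the vessel and
#' label channels nearest-neighbor; regions rotated in from outside are 0.
#'
#' @param patches list of `patch_pair`s.
#' @param inflation total multiplication factor (default 3: originals plus
#'   two rotated copies each).
#' @param angle_range_deg length-2 angle interval in degrees.
#' @param seed RNG seed.
#' @return list of `patch_pair`s of length `inflation * length(patches)`,
#'   originals first.
#' @export
augment_rotations <- function(patches, inflation = 3,
                              angle_range_deg = c(-60, 60), seed = 1) {
  stopifnot(inflation >= 1)
  if (inflation == 1) return(patches)
  out <- patches
  with_seed(seed, {
    for (r in seq_len(inflation - 1)) {
      for (p in patches) {
        ax <- stats::rnorm(3)
        th <- stats::runif(1, angle_range_deg[1], angle_range_deg[2]) *
          pi / 180
        R <- .rot_matrix(ax, th)
        q <- p
        md <- dim(p$main)[1:3]
        cd <- dim(p$context)[1:3]
        q$main[, , , 1] <- cpp_rotate_patch(p$main[, , , 1], md, p$spacing,
                                            R, 1L)
        q$main[, , , 2] <- cpp_rotate_patch(p$main[, , , 2], md, p$spacing,
                                            R, 0L)
        q$context[, , , 1] <- cpp_rotate_patch(p$context[, , , 1], cd,
                                               p$spacing, R, 1L)
        q$context[, , , 2] <- cpp_rotate_patch(p$context[, , , 2], cd,
                                               p$spacing, R, 0L)
        if (!is.null(p$gt))
          q$gt <- array(as.integer(cpp_rotate_patch(p$gt + 0, md, p$spacing,
                                                    R, 0L)), md)
        out[[length(out) + 1L]] <- q
      }
    }
  })
  out
}
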