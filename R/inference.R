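# Whole-volume inference by patch tiling, per-voxel argmax, and the
# softmax segment-washing post-processor.

#' Predict a whole volume by patch tiling
#'
#' Covers the volume with a regular grid of main-size tiles (stride
#' defaults to the tile size, i.e., non-overlapping; the last tile per axis
#' is shifted inward so the whole volume is covered). For each tile the
#' concentric context patch is extracted with zero padding at the borders,
#' both channels are min-max scaled with the training statistics, and the
#' model's softmax output is accumulated; overlapping contributions are
#' averaged and renormalized.
#'
#' @param model a `brave_net`.
#' @param image,vessel `volume_grid`s on the same grid (vessel = dense
#'   centerline-radius channel).
#' @param stats `scaling_stats` fitted on the training fold.
#' @param stride per-axis tile stride; default = main patch size.
#' @return a `softmax_volume`: `probs` array (x, y, z, classes) summing to
#'   1 per voxel, plus `spacing`.
#' @export
predict_volume <- function(model, image, vessel, stats, stride = NULL) {
  check_same_grid(image, vessel, "image and vessel volumes")
  dims <- dim(image)
  msz <- model$config$main_size
  if (any(dims < msz))
    stop("volume smaller than the main patch size")
  if (is.null(stride)) stride <- msz
  stride <- as.integer(pmin(stride, msz))
  K <- model$config$classes

  starts <- lapply(1:3, function(a) {
    s <- seq(0L, dims[a] - msz[a], by = stride[a])
    if (s[length(s)] != dims[a] - msz[a]) s <- c(s, dims[a] - msz[a])
    s
  })
  probs <- array(0, c(dims, K))
  count <- array(0, dims)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    center <- c(sx, sy, sz) + msz %/% 2L
    pp <- extract_dual_patch(image, vessel, NULL, center, msz, 2L * msz)
    pp <- apply_scaling(pp, stats)
    pr <- predict(model, pp)
    xr <- (sx + 1):(sx + msz[1]); yr <- (sy + 1):(sy + msz[2])
    zr <- (sz + 1):(sz + msz[3])
    probs[xr, yr, zr, ] <- probs[xr, yr, zr, ] + pr
    count[xr, yr, zr] <- count[xr, yr, zr] + 1
  }
  probs <- probs / array(count, c(dims, K))
  structure(list(probs = probs, spacing = vg_spacing(image)),
            class = "softmax_volume")
}

#' @export
print.softmax_volume <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("softmax_volume: grid %s, %d classes\n",
              paste(d[1:3], collapse = "x"), d[4]))
  invisible(x)
}

#' Per-voxel argmax labels
#'
#' Highest-probability class per voxel; exact ties break to the lowest
#' class index.
#'
#' @param probs a `softmax_volume`.
#' @return integer class-index `volume_grid`.
#' @export
argmax_labels <- function(probs) {
  d <- dim(probs$probs)
  lab <- max.col(matrix(probs$probs, ncol = d[4]), ties.method = "first") - 1L
  volume_grid(array(as.integer(lab), d[1:3]), probs$spacing)
}

#' Segment washing
#'
#' For every segment id > 0, the softmax scores of its voxels are summed
#' per class and the class with the highest total is assigned to all
#' voxels of the segment (equivalently, the label of the highest average
#' likelihood; ties break to the lowest class index). Voxels outside every
#' segment keep their plain per-voxel argmax. The result is
#' label-homogeneous within each segment.
#'
#' @param probs a `softmax_volume`.
#' @param seg_ids integer segment-id `volume_grid` (0 = no segment), from
#'   [segment_id_volume()].
#' @return integer class-index `volume_grid`.
#' @export
segment_wash <- function(probs, seg_ids) {
  d <- dim(probs$probs)
  if (!identical(as.integer(d[1:3]), as.integer(dim(seg_ids))))
    stop("segment-id map and probabilities are on different grids")
  lab <- argmax_labels(probs)
  ids <- as.integer(seg_ids)
  sel <- ids > 0L
  if (any(sel)) {
    pm <- matrix(probs$probs, ncol = d[4])
    sums <- rowsum(pm[sel, , drop = FALSE], group = ids[sel])
    seg_lab <- max.col(sums, ties.method = "first") - 1L
    names(seg_lab) <- rownames(sums)
    lab[sel] <- as.integer(seg_lab[as.character(ids[sel])])
  }
  lab
}
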