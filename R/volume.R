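# Lightweight 3-D volume container: a plain array carrying voxel spacing
# (mm) and an affine as attributes. Kept deliberately thin so arrays from
# RNifti or base R interoperate; all package code goes through the
# accessors below.

#' Construct a volume grid
#'
#' A `volume_grid` is a 3-D array with voxel spacing in mm and a 4x4
#' voxel-to-world affine attached. It carries image intensities, binary
#' masks, class indices, segment ids or centerline radii depending on
#' context.
#'
#' @param data 3-D array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @return a `volume_grid` (array subclass).
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  structure(data, spacing = as.numeric(spacing), affine = affine,
            class = c("volume_grid", class(data)))
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid %s, spacing %s mm, %s values in [%g, %g]\n",
              paste(dim(x), collapse = "x"),
              paste(signif(vg_spacing(x), 3), collapse = "x"),
              storage.mode(x), min(x), max(x)))
  invisible(x)
}

#' Voxel spacing of a volume (mm)
#' @param x a `volume_grid` or array; arrays without spacing default to 1 mm.
#' @return numeric length-3.
#' @export
vg_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) c(1, 1, 1) else sp
}

#' @rdname vg_spacing
#' @export
vg_affine <- function(x) {
  af <- attr(x, "affine")
  if (is.null(af)) diag(c(vg_spacing(x), 1)) else af
}

# propagate grid metadata from `like` onto array `data`
same_grid <- function(data, like) {
  volume_grid(data, spacing = vg_spacing(like), affine = vg_affine(like))
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(what, " differ in shape: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  if (max(abs(vg_spacing(a) - vg_spacing(b))) > 1e-9)
    stop(what, " differ in voxel spacing")
  invisible(TRUE)
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers around RNifti keeping spacing/affine attributes in sync.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: a `volume_grid`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  sp <- RNifti::pixdim(img)[1:3]
  volume_grid(arr, spacing = sp, affine = RNifti::xform(img))
}

#' @rdname read_volume
#' @param vol a `volume_grid` to write.
#' @export
write_volume <- function(vol, path) {
  arr <- unclass(vol)
  attr(arr, "spacing") <- NULL
  attr(arr, "affine") <- NULL
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vg_spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}
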