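# Synthetic cerebrovascular phantom: a Circle-of-Willis-like template tree
# of the 24 named artery segments, rasterized into tube masks with
# per-voxel ground-truth labels on a noisy, bias-field-modulated tissue
# background. Template coordinates live in the unit cube and are scaled to
# the physical extent of the requested grid; paired segments are exact
# mirror images across the mid-sagittal plane (x = 0.5).

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# dexter-side + unpaired control polylines, normalized coordinates.
# Shared junctions are repeated verbatim so connected segments share an
# endpoint exactly; the sinister side is generated by mirroring x -> 1 - x.
.template_dexter <- function() {
  seg <- function(code, pts, r) list(code = code, points = pts, radius = r)
  P <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  ica2 <- c(0.360, 0.600, 0.360)
  c1   <- c(0.375, 0.585, 0.440)   # PcomA takeoff on ICA-CoW
  Tt   <- c(0.385, 0.600, 0.500)   # ICA terminus (M1/A1 junction)
  M    <- c(0.200, 0.550, 0.520)   # M1/M2 junction
  # A1/A2/AcomA junctions sit far enough apart that the communicating
  # artery keeps voxels of its own after rasterization overlap resolution
  aD   <- c(0.458, 0.720, 0.540)
  aS   <- c(1 - 0.458, 0.720, 0.540)
  V    <- c(0.500, 0.310, 0.180)   # vertebrobasilar junction
  B    <- c(0.500, 0.370, 0.420)   # basilar tip
  Pp   <- c(0.355, 0.400, 0.470)   # P1/P2/PcomA junction
  list(
    seg("D-ICA", P(0.340, 0.540, 0.040, 0.370, 0.560, 0.220, ica2),
        c(2.0, 1.9, 1.8)),
    seg("D-ICA-CoW", P(ica2, c1, Tt), c(1.8, 1.7, 1.7)),
    seg("D-M1", P(Tt, 0.300, 0.570, 0.510, M), c(1.5, 1.4, 1.3)),
    seg("D-M2-sup", P(M, 0.130, 0.530, 0.640, 0.080, 0.500, 0.720),
        c(1.0, 0.9, 0.8)),
    seg("D-M2-inf", P(M, 0.120, 0.480, 0.460, 0.070, 0.440, 0.380),
        c(1.0, 0.9, 0.8)),
    seg("D-A1", P(Tt, 0.440, 0.660, 0.520, aD), c(1.2, 1.1, 1.1)),
    seg("ACOM", P(aD, aS), c(0.9, 0.9)),
    seg("D-A2", P(aD, 0.465, 0.780, 0.660, 0.450, 0.820, 0.780),
        c(1.1, 1.0, 0.9)),
    seg("D-VA", P(0.420, 0.260, 0.020, 0.460, 0.280, 0.100, V),
        c(1.6, 1.5, 1.5)),
    seg("BA", P(V, 0.500, 0.340, 0.300, B), c(1.7, 1.6, 1.5)),
    seg("D-PCOM", P(c1, 0.370, 0.500, 0.460, Pp), c(0.8, 0.8, 0.8)),
    seg("D-P1", P(B, 0.420, 0.385, 0.450, Pp), c(1.2, 1.1, 1.1)),
    seg("D-P2", P(Pp, 0.280, 0.350, 0.500, 0.220, 0.280, 0.550),
        c(1.0, 0.9, 0.8))
  )
}

#' Template Circle-of-Willis vessel tree
#'
#' Fixed template of all 24 detailed artery segments with plausible
#' topology (ICA to ICA-CoW to M1 to M2 sup/inf; A1 to AcomA and A2;
#' VA to BA to P1 to P2; PcomA bridging ICA-CoW and the P1/P2 junction) in
#' unit-cube coordinates, radii in mm. Paired segments are mirror images
#' across the mid-sagittal plane.
#'
#' @return a `vessel_tree` object: `segments` (code, class index, control
#'   points, radius profile), `present` flags and `connectivity` (segment
#'   pairs sharing a control point).
#' @export
build_template_tree <- function() {
  dex <- .template_dexter()
  tax <- detailed_taxonomy()
  segs <- list()
  for (s in dex) {
    segs[[length(segs) + 1L]] <- s
    if (startsWith(s$code, "D-")) {
      m <- s
      m$code <- sub("^D-", "S-", s$code)
      m$points[, 1] <- 1 - m$points[, 1]
      segs[[length(segs) + 1L]] <- m
    }
  }
  for (i in seq_along(segs)) {
    ci <- tax$classes$index[tax$classes$code == segs[[i]]$code]
    stopifnot(length(ci) == 1L)
    segs[[i]]$class_index <- ci
  }
  tree <- structure(list(
    segments = segs,
    present = rep(TRUE, length(segs)),
    connectivity = NULL
  ), class = "vessel_tree")
  tree$connectivity <- tree_connectivity(tree)
  tree
}

#' Segment connectivity of a vessel tree
#'
#' Two segments are connected when one segment's endpoint coincides (within
#' `tol`) with any control point of the other.
#'
#' @param tree a `vessel_tree`.
#' @param tol coordinate tolerance.
#' @return data.frame with columns `seg_a`, `seg_b` (segment codes).
#' @export
tree_connectivity <- function(tree, tol = 1e-9) {
  n <- length(tree$segments)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    a <- tree$segments[[i]]$points
    b <- tree$segments[[j]]$points
    ends_a <- a[c(1, nrow(a)), , drop = FALSE]
    ends_b <- b[c(1, nrow(b)), , drop = FALSE]
    hit <- FALSE
    for (e in seq_len(2)) {
      if (any(sqrt(rowSums((b - matrix(ends_a[e, ], nrow(b), 3,
                                       byrow = TRUE))^2)) < tol) ||
          any(sqrt(rowSums((a - matrix(ends_b[e, ], nrow(a), 3,
                                       byrow = TRUE))^2)) < tol))
        hit <- TRUE
    }
    if (hit)
      out <- rbind(out, data.frame(seg_a = tree$segments[[i]]$code,
                                   seg_b = tree$segments[[j]]$code,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("vessel_tree: %d segments (%d present)\n",
              length(x$segments), sum(x$present)))
  invisible(x)
}

# low-frequency multiplicative bias field: coarse iid normal grid,
# trilinearly interpolated to the full grid, unit sd
.smooth_field <- function(dims, ncoarse = c(5, 5, 4)) {
  g <- array(stats::rnorm(prod(ncoarse)), ncoarse)
  interp1 <- function(a, axis, nout) {
    nin <- dim(a)[axis]
    pos <- seq(0, nin - 1, length.out = nout)
    i0 <- pmin(floor(pos), nin - 2)
    t <- pos - i0
    idx0 <- i0 + 1
    take <- function(i) {
      switch(axis,
             a[i, , , drop = FALSE],
             a[, i, , drop = FALSE],
             a[, , i, drop = FALSE])
    }
    lo <- take(idx0)
    hi <- take(idx0 + 1)
    tt <- array(t[slice.index(lo, axis)], dim(lo))
    lo * (1 - tt) + hi * tt
  }
  f <- g
  for (ax in 1:3) f <- interp1(f, ax, dims[ax])
  (f - mean(f)) / max(stats::sd(f), 1e-12)
}

.default_droppable <- c("D-PCOM", "S-PCOM", "D-A1", "S-A1", "D-P1", "S-P1",
                        "ACOM")
.terminal_segments <- c("D-M2-sup", "S-M2-sup", "D-M2-inf", "S-M2-inf",
                        "D-A2", "S-A2", "D-P2", "S-P2")

# densify a polyline to step <= `step` (mm), carrying radius along
.densify <- function(pts, radius, step) {
  out_p <- NULL
  out_r <- NULL
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = k)
    seg_p <- outer(1 - t, a) + outer(t, b)
    seg_r <- radius[i] * (1 - t) + radius[i + 1] * t
    if (!is.null(out_p)) { seg_p <- seg_p[-1, , drop = FALSE]; seg_r <- seg_r[-1] }
    out_p <- rbind(out_p, seg_p)
    out_r <- c(out_r, seg_r)
  }
  list(points = out_p, radius = out_r)
}

#' Sample one phantom subject
#'
#' Jitters the template tree (shared junctions stay shared), drops a random
#' nonempty subset of `droppable` segments with probability `missing_prob`
#' (emulating the high prevalence of missing arterial segments in
#' cerebrovascular disease cohorts), optionally grows short non-annotated
#' distal twigs, rasterizes the tubes into a vessel mask and ground-truth
#' label volume, and synthesizes a raw angiography-like image: tissue
#' background times a smooth multiplicative bias field plus Gaussian noise,
#' with bright flow-like vessel voxels. Deterministic given `seed`.
#'
#' @param seed integer RNG seed for this subject.
#' @param missing_prob probability that the subject has missing segments
#'   (default 0.8).
#' @param droppable codes of segments eligible for dropping (common
#'   hypoplastic Circle-of-Willis elements by default).
#' @param dims grid dimensions (default desk scale 96 x 96 x 48).
#' @param spacing voxel spacing mm (default 0.6 x 0.6 x 0.7, anisotropic).
#' @param jitter_mm control-point jitter sd in mm.
#' @param radius_jitter multiplicative sd of per-segment radius scaling.
#' @param nonannotated_prob probability of a non-annotated distal twig at
#'   each terminal segment.
#' @param bg_level,vessel_level,noise_sd,bias_amp intensity model settings.
#' @param subject_id,cohort_tag identifiers carried through.
#' @return a `phantom_subject`: image, vessel_mask, gt_labels
#'   (`volume_grid`s), the jittered `vessel_tree`, and bookkeeping fields.
#' @export
sample_subject <- function(seed, missing_prob = 0.8,
                           droppable = .default_droppable,
                           dims = c(96, 96, 48),
                           spacing = c(0.6, 0.6, 0.7),
                           jitter_mm = 0.8, radius_jitter = 0.08,
                           nonannotated_prob = 0.25,
                           bg_level = 100, vessel_level = 300,
                           noise_sd = 20, bias_amp = 0.2,
                           subject_id = sprintf("sub-%06d", seed),
                           cohort_tag = "A") {
  stopifnot(length(dims) == 3L, all(dims >= 16), length(spacing) == 3L,
            missing_prob >= 0, missing_prob <= 1)
  dims <- as.integer(dims)
  with_seed(seed, {
    tree <- build_template_tree()
    extent <- dims * spacing
    margin <- 0.06
    scale <- extent * (1 - 2 * margin)
    shift <- extent * margin

    # jitter unique control points so shared junctions move together
    allpts <- do.call(rbind, lapply(tree$segments, `[[`, "points"))
    key <- apply(round(allpts, 9), 1, paste, collapse = "/")
    uniq <- !duplicated(key)
    jit <- matrix(stats::rnorm(sum(uniq) * 3, sd = jitter_mm), ncol = 3)
    rownames(jit) <- key[uniq]
    for (i in seq_along(tree$segments)) {
      p <- tree$segments[[i]]$points
      k <- apply(round(p, 9), 1, paste, collapse = "/")
      pm <- sweep(sweep(p, 2, scale, "*"), 2, shift, "+")  # mm
      tree$segments[[i]]$points <- pm + jit[k, , drop = FALSE]
      tree$segments[[i]]$radius <- tree$segments[[i]]$radius *
        exp(stats::rnorm(1, sd = radius_jitter))
    }

    # drop missing segments
    codes <- vapply(tree$segments, `[[`, "", "code")
    present <- rep(TRUE, length(codes))
    if (missing_prob > 0 && length(droppable) > 0 &&
        stats::runif(1) < missing_prob) {
      cand <- which(codes %in% droppable)
      ndrop <- sample.int(length(cand), 1)
      present[sample(cand, ndrop)] <- FALSE
    }
    tree$present <- present

    # non-annotated distal twigs on terminal segments (own tube, class 1)
    twigs <- list()
    for (i in which(present & codes %in% .terminal_segments)) {
      if (stats::runif(1) < nonannotated_prob) {
        p <- tree$segments[[i]]$points
        dirv <- p[nrow(p), ] - p[nrow(p) - 1, ]
        dirv <- dirv / sqrt(sum(dirv^2))
        twigs[[length(twigs) + 1L]] <- list(
          points = rbind(p[nrow(p), ], p[nrow(p), ] + 5 * dirv),
          radius = c(0.6, 0.6))
      }
    }

    # rasterize present segments + twigs
    step <- min(spacing) / 2
    pts <- NULL; rad <- NULL; sidx <- NULL; seg_class <- integer(0)
    si <- 0L
    for (i in seq_along(tree$segments)) {
      if (!present[i]) next
      si <- si + 1L
      d <- .densify(tree$segments[[i]]$points, tree$segments[[i]]$radius, step)
      pts <- rbind(pts, d$points); rad <- c(rad, d$radius)
      sidx <- c(sidx, rep(si, nrow(d$points)))
      seg_class[si] <- tree$segments[[i]]$class_index
    }
    for (tw in twigs) {
      si <- si + 1L
      d <- .densify(tw$points, tw$radius, step)
      pts <- rbind(pts, d$points); rad <- c(rad, d$radius)
      sidx <- c(sidx, rep(si, nrow(d$points)))
      seg_class[si] <- 1L   # non-annotated
    }
    ras <- cpp_rasterize_tubes(pts, rad, as.integer(sidx), dims, spacing)
    mask <- array(as.integer(ras$mask), dims)
    gt <- array(0L, dims)
    nz <- ras$seg > 0
    gt[nz] <- seg_class[ras$seg[nz]]

    # image synthesis
    bias <- 1 + bias_amp * .smooth_field(dims)
    base <- array(bg_level, dims)
    base[mask == 1L] <- vessel_level
    img <- base * bias + array(stats::rnorm(prod(dims), sd = noise_sd), dims)

    structure(list(
      subject_id = subject_id,
      cohort_tag = cohort_tag,
      seed = seed,
      image = volume_grid(img, spacing),
      vessel_mask = volume_grid(mask, spacing),
      gt_labels = volume_grid(gt, spacing),
      tree = tree
    ), class = "phantom_subject")
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("phantom_subject %s (cohort %s, seed %d): %s grid, %d vessel voxels, %d/%d segments present\n",
              x$subject_id, x$cohort_tag, x$seed,
              paste(dim(x$image), collapse = "x"),
              sum(x$vessel_mask == 1), sum(x$tree$present),
              length(x$tree$present)))
  invisible(x)
}

#' Cohort inclusion plan emulated by the phantom defaults
#'
#' The two-study design the phantom cohort tags emulate: study A enrolls
#' `enrolled_a` patients of whom `no_imaging_a` lack angiography and
#' `low_quality_a` are excluded for motion-degraded imaging; study B
#' contributes `processed_b` fully processed patients. The included totals
#' drive the default tag ratio of [generate_cohort()].
#'
#' @param enrolled_a,no_imaging_a,low_quality_a,processed_b inclusion
#'   numbers (defaults 82, 4, 6, 170).
#' @return list with per-study included counts `A`, `B` and `total`.
#' @export
default_cohort_plan <- function(enrolled_a = 82, no_imaging_a = 4,
                                low_quality_a = 6, processed_b = 170) {
  a <- enrolled_a - no_imaging_a - low_quality_a
  list(A = a, B = processed_b, total = a + processed_b)
}

#' Generate a phantom cohort
#'
#' Draws `n` subjects with per-subject seeds derived from `base_seed` and
#' cohort tags assigned per `tag_counts` (two tags emulate a two-study
#' cohort; the study-scale default is 72 + 170 = 242 subjects, desk scale
#' is whatever you pass).
#'
#' @param n number of subjects.
#' @param tag_counts named integer vector of per-tag counts summing to `n`.
#' @param base_seed integer; per-subject seeds are drawn without
#'   replacement under this seed, so subjects are distinct and the cohort
#'   is reproducible.
#' @param ... forwarded to [sample_subject()].
#' @return list of `phantom_subject`s.
#' @export
generate_cohort <- function(n, tag_counts = c(A = ceiling(n * 72 / 242),
                                              B = n - ceiling(n * 72 / 242)),
                            base_seed = 1, ...) {
  stopifnot(all(tag_counts > 0), sum(tag_counts) == n)
  seeds <- with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n))
  tags <- rep(names(tag_counts), tag_counts)
  lapply(seq_len(n), function(i) {
    sample_subject(seed = seeds[i], subject_id = sprintf("sub-%03d", i),
                   cohort_tag = tags[i], ...)
  })
}

#' Write a phantom subject / cohort manifest to disk
#'
#' Per subject: `image.nii.gz`, `mask.nii.gz`, `labels.nii.gz` and
#' `tree.json` under `dir/<subject_id>/`. `write_cohort` also writes a TSV
#' manifest (subject_id, tag, seed, missing segments).
#'
#' @param subject a `phantom_subject`.
#' @param dir output directory.
#' @return the subject directory (invisibly).
#' @export
write_subject <- function(subject, dir) {
  sd <- file.path(dir, subject$subject_id)
  dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  write_volume(subject$image, file.path(sd, "image.nii.gz"))
  write_volume(subject$vessel_mask, file.path(sd, "mask.nii.gz"))
  write_volume(subject$gt_labels, file.path(sd, "labels.nii.gz"))
  tr <- lapply(subject$tree$segments, function(s)
    list(code = s$code, class_index = s$class_index,
         points = s$points, radius = s$radius))
  jsonlite::write_json(list(segments = tr, present = subject$tree$present),
                       file.path(sd, "tree.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(sd)
}

#' @rdname write_subject
#' @param cohort list of `phantom_subject`s.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    write_subject(s, dir)
    codes <- vapply(s$tree$segments, `[[`, "", "code")
    data.frame(subject_id = s$subject_id, tag = s$cohort_tag, seed = s$seed,
               missing = paste(codes[!s$tree$present], collapse = ","),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
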