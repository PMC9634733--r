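# High-level orchestration: per-subject preparation (centerline, segments,
# segment-id map), patch-set construction, whole-subject evaluation and an
# end-to-end experiment runner. These are the building blocks behind the
# command-line interface and are exercised directly by the test suite.

#' Prepare a subject for training / evaluation
#'
#' Runs the geometry stage: skeletonizes the vessel mask, decomposes the
#' centerline into bifurcation-bounded segments, fills per-segment
#' ground-truth labels (when ground truth is available) and rasterizes the
#' segment-id map over the full lumen.
#'
#' @param subject a `phantom_subject`, or any list with `image`,
#'   `vessel_mask` and optionally `gt_labels` volumes.
#' @return the subject with `centerline`, `segments` (a `segment_table`)
#'   and `seg_ids` attached, plus `vessel` (the dense radius channel).
#' @export
prepare_subject <- function(subject) {
  cl <- skeletonize(subject$vessel_mask)
  st <- extract_segments(cl)
  if (!is.null(subject$gt_labels))
    st <- suppressMessages(segment_gt_labels(st, subject$gt_labels))
  subject$centerline <- cl
  subject$vessel <- cl$dense
  subject$segments <- st
  subject$seg_ids <- segment_id_volume(st, subject$vessel_mask)
  subject
}

#' Build the training patch set of a prepared subject
#'
#' Samples up to `per_segment` centers per centerline segment and extracts
#' concentric dual-scale patch pairs around them.
#'
#' @param prep a prepared subject (see [prepare_subject()]).
#' @param per_segment centers per segment (default 8).
#' @param main_size main patch dims; context is twice per axis.
#' @param seed RNG seed for center sampling.
#' @param constellation `"detailed"` or `"aggregated"`; aggregated maps the
#'   ground-truth patches through the label aggregation.
#' @return list of `patch_pair`s.
#' @export
subject_patches <- function(prep, per_segment = 8, main_size = c(32, 32, 16),
                            seed = 1, constellation = "aggregated") {
  gt <- prep$gt_labels
  if (constellation == "aggregated") gt <- aggregate_labels(gt)
  centers <- sample_patch_centers(prep$segments, per_segment, seed)
  lapply(seq_len(nrow(centers)), function(i)
    extract_dual_patch(prep$image, prep$vessel, gt, centers[i, ],
                       main_size, 2L * as.integer(main_size),
                       subject_id = prep$subject_id))
}

#' Evaluate a model on a prepared subject
#'
#' Predicts the whole volume by tiling, optionally applies segment
#' washing, and computes voxel-wise (and, when washed, segment-wise)
#' metrics against the subject's ground truth.
#'
#' @param model a `brave_net` or `rf_voxel_model`.
#' @param prep prepared subject.
#' @param stats `scaling_stats` of the training fold (ignored by the RF).
#' @param constellation `"detailed"` or `"aggregated"`.
#' @param wash apply segment washing (default TRUE).
#' @param stride tiling stride forwarded to [predict_volume()] (`NULL` =
#'   non-overlapping tiles; a half-size stride averages overlaps).
#' @param n_classes class-universe size (26 detailed / 13 aggregated).
#' @return list: `probs`, `labels` (washed when `wash`), `voxel` report,
#'   `segment` report (NULL unless washed).
#' @export
evaluate_subject <- function(model, prep, stats = NULL,
                             constellation = "aggregated", wash = TRUE,
                             stride = NULL,
                             n_classes = if (constellation == "aggregated")
                               13L else 26L) {
  gt <- prep$gt_labels
  st <- prep$segments
  if (constellation == "aggregated") {
    gt <- aggregate_labels(gt)
    st <- .aggregate_table(st)
  }
  probs <- if (inherits(model, "rf_voxel_model")) {
    predict(model, list(image = prep$image, vessel = prep$vessel,
                        mask = prep$vessel_mask))
  } else {
    predict_volume(model, prep$image, prep$vessel, stats, stride = stride)
  }
  labels <- if (wash) segment_wash(probs, prep$seg_ids) else
    argmax_labels(probs)
  voxel <- confusion_scores(voxel_confusion(gt, labels,
                                            n_classes = n_classes))
  segment <- NULL
  if (wash)
    segment <- segment_scores(st, labels, n_classes = n_classes)
  list(probs = probs, labels = labels, voxel = voxel, segment = segment)
}

# map a segment table's gt labels onto the aggregated constellation
.aggregate_table <- function(st) {
  map <- detailed_taxonomy()$aggregation_map
  for (i in seq_along(st$segments)) {
    g <- st$segments[[i]]$gt_label
    if (!is.na(g)) st$segments[[i]]$gt_label <- unname(map[g + 1L])
  }
  st
}

#' Run a cohort experiment end to end
#'
#' Generates (or takes) a phantom cohort, prepares every subject, splits
#' train/test, fits the scaling statistics and the network on training
#' patches (with optional rotation augmentation), and evaluates every test
#' subject voxel- and segment-wise.
#'
#' @param cohort list of `phantom_subject`s.
#' @param train_ids,test_ids subject ids for the split.
#' @param constellation `"detailed"` or `"aggregated"`.
#' @param main_size main patch dims.
#' @param base_filters,depth,context_path,deep_supervision,l2 model
#'   settings (see [brave_net()]).
#' @param channels `"both"`, `"image"` or `"vessel"` — which input
#'   channels carry signal (the other is zeroed; input stays 2-channel).
#' @param per_segment patch centers per segment.
#' @param augment rotation-augmentation inflation factor (1 = off).
#' @param epochs,batch_size,lr,seed training settings.
#' @param class_weights forwarded to [train_network()] (`NULL`,
#'   `"balanced"`, `"sqrt"` or a numeric vector).
#' @param head_prior_init initialize softmax-head biases to log class
#'   priors (see [init_head_bias()]).
#' @param wash apply segment washing at evaluation.
#' @param eval_stride tiling stride at evaluation (see [predict_volume()]).
#' @param prepared optional pre-computed [prepare_subject()] results
#'   (named by subject id), to reuse geometry across experiments.
#' @param verbose print progress.
#' @return list: `model`, `stats`, per-test-subject `evals`, pooled
#'   voxel/segment reports (`voxel`, `segment`), `prepared` subjects.
#' @export
run_experiment <- function(cohort, train_ids, test_ids,
                           constellation = "aggregated",
                           main_size = c(32, 32, 16), base_filters = 4,
                           depth = 2, context_path = TRUE,
                           deep_supervision = TRUE, l2 = 1e-3,
                           channels = "both", per_segment = 8,
                           augment = 1, epochs = 4, batch_size = 4,
                           lr = 1e-3, class_weights = NULL,
                           head_prior_init = FALSE, seed = 1, wash = TRUE,
                           eval_stride = NULL, prepared = NULL,
                           verbose = FALSE) {
  ids <- vapply(cohort, `[[`, "", "subject_id")
  prep <- if (is.null(prepared)) {
    p <- lapply(cohort, prepare_subject)
    names(p) <- ids
    p
  } else prepared
  n_classes <- if (constellation == "aggregated") 13L else 26L

  stats <- fit_scaling(prep[train_ids])
  # stream patches per subject into the compact float dataset so cohort
  # training fits in ordinary RAM; augmentation is seeded per subject
  ds <- patch_dataset(main_size = main_size)
  for (id in train_ids) {
    ps <- subject_patches(prep[[id]], per_segment, main_size,
                          seed = seed + match(id, ids),
                          constellation = constellation)
    ps <- lapply(ps, apply_scaling, stats = stats)
    ps <- lapply(ps, .mask_channels, channels = channels)
    if (augment > 1)
      ps <- augment_rotations(ps, inflation = augment,
                              seed = seed + 7777L + match(id, ids))
    for (p in ps) ds_append(ds, p)
  }

  model <- brave_net(main_size = main_size, classes = n_classes,
                     base_filters = base_filters, depth = depth,
                     context_path = context_path,
                     deep_supervision = deep_supervision, l2 = l2,
                     seed = seed)
  if (head_prior_init) model <- init_head_bias(model, ds)
  model <- train_network(model, ds, epochs = epochs,
                         batch_size = batch_size, lr = lr,
                         class_weights = class_weights, seed = seed,
                         verbose = verbose)

  evals <- list()
  for (id in test_ids) {
    pr <- prep[[id]]
    if (channels != "both") {
      pr <- .mask_subject_channels(pr, channels)
    }
    evals[[id]] <- evaluate_subject(model, pr, stats,
                                    constellation = constellation,
                                    wash = wash, stride = eval_stride,
                                    n_classes = n_classes)
    evals[[id]]$probs <- NULL   # whole-volume softmax is large; keep labels
    if (verbose)
      cat(sprintf("  %s: voxel mF1 %.3f\n", id, evals[[id]]$voxel$mF1))
  }
  pooled <- .pool_evals(evals, prep[test_ids], constellation, n_classes,
                        wash)
  c(list(model = model, stats = stats, evals = evals, prepared = prep),
    pooled)
}

# zero out the unused input channel (channel 1 = image, 2 = vessel)
.mask_channels <- function(p, channels) {
  if (channels == "both") return(p)
  drop <- if (channels == "image") 2L else 1L
  p$main[, , , drop] <- 0
  p$context[, , , drop] <- 0
  p
}

.mask_subject_channels <- function(prep, channels) {
  if (channels == "image") {
    prep$vessel <- same_grid(array(0, dim(prep$vessel)), prep$vessel)
  } else if (channels == "vessel") {
    prep$image <- same_grid(array(0, dim(prep$image)), prep$image)
  }
  prep
}

# pool test-set confusions into single voxel-/segment-level reports
.pool_evals <- function(evals, preps, constellation, n_classes, wash) {
  gt_all <- integer(0); pred_all <- integer(0)
  seg_gt <- integer(0); seg_pred <- integer(0)
  for (id in names(evals)) {
    prep <- preps[[id]]
    gt <- prep$gt_labels
    st <- prep$segments
    if (constellation == "aggregated") {
      gt <- aggregate_labels(gt)
      st <- .aggregate_table(st)
    }
    lab <- evals[[id]]$labels
    keep <- !(gt %in% c(0L, 1L))   # masked evaluation (see voxel_confusion)
    gt_all <- c(gt_all, as.integer(gt[keep]))
    pred_all <- c(pred_all, as.integer(lab[keep]))
    if (wash) {
      dims <- dim(lab)
      for (s in st$segments) {
        if (s$gt_label %in% c(0L, 1L)) next
        flat <- s$coords[, 1] + 1L + dims[1] * s$coords[, 2] +
          dims[1] * dims[2] * s$coords[, 3]
        seg_gt <- c(seg_gt, s$gt_label)
        seg_pred <- c(seg_pred, as.integer(lab[flat[1]]))
      }
    }
  }
  tabv <- table(factor(gt_all, levels = 0:(n_classes - 1)),
                factor(pred_all, levels = 0:(n_classes - 1)))
  voxel <- confusion_scores(.confusion_from_table(tabv, c(0L, 1L), "voxel"))
  segment <- NULL
  if (wash) {
    tabs <- table(factor(seg_gt, levels = 0:(n_classes - 1)),
                  factor(seg_pred, levels = 0:(n_classes - 1)))
    segment <- confusion_scores(.confusion_from_table(tabs, c(0L, 1L),
                                                      "segment"))
  }
  list(voxel = voxel, segment = segment)
}
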