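# Evaluation: per-class F1, macro F1 (mF1), balanced class accuracy
# (bAcc), qualitative performance categories, voxel-wise and segment-wise
# confusion, and cross-fold aggregation. Background and non-annotated
# classes are excluded from all macro means by default.

#' Voxel-wise confusion counts
#'
#' Per-class true positives, false positives and false negatives over an
#' explicit class universe. Excluded classes (background and non-annotated
#' by default) are excluded from the calculation in both directions:
#' voxels whose ground truth is an excluded class do not contribute at all
#' — a prediction on an unannotated vessel is unverifiable, not wrong, and
#' the labeling task is defined over the annotated vasculature — while a
#' prediction of an excluded class on an included-class voxel still counts
#' as that class's false negative.
#'
#' @param gt,pred integer class-index volumes on the same grid.
#' @param exclude class indices excluded from evaluation (default
#'   background 0 and non-annotated 1).
#' @param n_classes size of the class universe (max index + 1); defaults
#'   to covering everything seen in `gt` and `pred`.
#' @return a `confusion_counts` object.
#' @export
voxel_confusion <- function(gt, pred, exclude = c(0L, 1L),
                            n_classes = NULL) {
  if (!identical(dim(gt), dim(pred)))
    stop("gt and pred differ in shape")
  g <- as.integer(gt)
  p <- as.integer(pred)
  if (is.null(n_classes)) n_classes <- max(g, p) + 1L
  keep <- !(g %in% exclude)
  tab <- table(factor(g[keep], levels = 0:(n_classes - 1)),
               factor(p[keep], levels = 0:(n_classes - 1)))
  .confusion_from_table(tab, exclude, level = "voxel")
}

.confusion_from_table <- function(tab, exclude, level) {
  n_classes <- nrow(tab)
  cls <- 0:(n_classes - 1)
  tp <- diag(tab)
  fn <- rowSums(tab) - tp
  fp <- colSums(tab) - tp
  included <- setdiff(cls, exclude)
  structure(list(
    classes = cls, tp = as.numeric(tp), fp = as.numeric(fp),
    fn = as.numeric(fn), excluded = as.integer(exclude),
    included = as.integer(included), level = level, table = tab),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts (%s level): %d classes, %d excluded\n",
              x$level, length(x$classes), length(x$excluded)))
  invisible(x)
}

#' Performance category of an F1 score
#'
#' Qualitative bands: excellent (> 0.9), good (> 0.75), moderate (> 0.6),
#' poor (<= 0.6). Boundaries are half-open and exhaustive.
#'
#' @param f1 numeric vector of F1 scores.
#' @return character vector of categories.
#' @export
performance_category <- function(f1) {
  out <- rep("poor", length(f1))
  out[f1 > 0.6] <- "moderate"
  out[f1 > 0.75] <- "good"
  out[f1 > 0.9] <- "excellent"
  out
}

#' Scores from confusion counts
#'
#' Per-class F1 = 2TP / (2TP + FP + FN) (0 when the denominator is 0) and
#' recall = TP / (TP + FN); macro F1 and balanced class accuracy are
#' unweighted means over included classes that have ground-truth support
#' (TP + FN > 0). Classes without support are excluded from the means and
#' counted in `n_skipped` — unavoidable in cohorts with missing arterial
#' segments.
#'
#' @param conf a `confusion_counts`.
#' @param fold optional fold id carried into the report.
#' @return a `metrics_report`: per-class data.frame (f1, recall, precision,
#'   support, category), `mF1`, `bAcc`, `level`, `n_skipped`.
#' @export
confusion_scores <- function(conf, fold = NA_integer_) {
  inc <- conf$included + 1L   # 1-based rows
  support <- conf$tp + conf$fn
  use <- intersect(inc, which(support > 0))
  if (!length(use))
    stop("no included class with ground-truth support")
  denom <- 2 * conf$tp + conf$fp + conf$fn
  f1 <- ifelse(denom > 0, 2 * conf$tp / denom, 0)
  recall <- ifelse(support > 0, conf$tp / support, NA_real_)
  prec <- ifelse(conf$tp + conf$fp > 0, conf$tp / (conf$tp + conf$fp), 0)
  per_class <- data.frame(
    class = conf$classes[use], f1 = f1[use], recall = recall[use],
    precision = prec[use], support = support[use],
    category = performance_category(f1[use]))
  structure(list(
    level = conf$level, per_class = per_class,
    mF1 = mean(f1[use]), bAcc = mean(recall[use]),
    n_skipped = length(setdiff(inc, use)), fold = fold),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (%s level%s): mF1 %.4f, bAcc %.4f (%d classes, %d skipped)\n",
              x$level, ifelse(is.na(x$fold), "", sprintf(", fold %d", x$fold)),
              x$mF1, x$bAcc, nrow(x$per_class), x$n_skipped))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Segment-wise scores
#'
#' Each segment contributes a single (ground-truth label, predicted label)
#' pair — all voxel-wise predictions within the segment are pulled
#' together, so scores are independent of segment size. Requires washed
#' (segment-homogeneous) predictions; a non-homogeneous segment means
#' washing was skipped and is rejected.
#'
#' @param table a `segment_table` with `gt_label` filled
#'   (see [segment_gt_labels()]).
#' @param washed integer class-index volume, segment-homogeneous.
#' @param exclude class indices excluded from the metrics.
#' @param n_classes class-universe size; defaults to covering all labels.
#' @param fold optional fold id.
#' @return a `metrics_report` at segment level.
#' @export
segment_scores <- function(table, washed, exclude = c(0L, 1L),
                           n_classes = NULL, fold = NA_integer_) {
  if (!length(table$segments)) stop("empty segment table")
  dims <- dim(washed)
  gt_lab <- integer(0)
  pred_lab <- integer(0)
  for (s in table$segments) {
    if (is.na(s$gt_label))
      stop("segment table lacks gt labels; run segment_gt_labels() first")
    flat <- s$coords[, 1] + 1L + dims[1] * s$coords[, 2] +
      dims[1] * dims[2] * s$coords[, 3]
    vals <- unique(as.integer(washed[flat]))
    if (length(vals) != 1)
      stop("segment ", s$id, " is not label-homogeneous; wash predictions ",
           "with segment_wash() before segment-wise scoring")
    gt_lab <- c(gt_lab, s$gt_label)
    pred_lab <- c(pred_lab, vals)
  }
  if (is.null(n_classes)) n_classes <- max(gt_lab, pred_lab) + 1L
  keep <- !(gt_lab %in% exclude)   # same exclusion semantics as voxel level
  gt_lab <- gt_lab[keep]
  pred_lab <- pred_lab[keep]
  if (!length(gt_lab)) stop("no segment with included ground truth")
  tab <- table(factor(gt_lab, levels = 0:(n_classes - 1)),
               factor(pred_lab, levels = 0:(n_classes - 1)))
  confusion_scores(.confusion_from_table(tab, exclude, level = "segment"),
                   fold = fold)
}

#' Cross-fold summary
#'
#' Mean and sample standard deviation of mF1 and bAcc across fold reports
#' of the same level, plus per-class mean F1 (the bar-chart-style output).
#'
#' @param reports list of >= 2 `metrics_report`s of one level.
#' @return a `crossfold_summary`: `level`, `n_folds`, `mF1` and `bAcc`
#'   (mean, sd), per-class mean F1 data.frame.
#' @export
crossfold_summary <- function(reports) {
  if (length(reports) < 2) stop("need at least two fold reports")
  lv <- unique(vapply(reports, `[[`, "", "level"))
  if (length(lv) != 1) stop("mixed report levels: ", paste(lv, collapse = ", "))
  mf1 <- vapply(reports, `[[`, 0, "mF1")
  bacc <- vapply(reports, `[[`, 0, "bAcc")
  pc <- do.call(rbind, lapply(reports, `[[`, "per_class"))
  agg <- stats::aggregate(f1 ~ class, data = pc, FUN = mean)
  agg$category <- performance_category(agg$f1)
  structure(list(
    level = lv, n_folds = length(reports),
    mF1 = c(mean = mean(mf1), sd = stats::sd(mf1)),
    bAcc = c(mean = mean(bacc), sd = stats::sd(bacc)),
    per_class = agg), class = "crossfold_summary")
}

#' @export
print.crossfold_summary <- function(x, ...) {
  cat(sprintf("crossfold_summary (%s level, %d folds): mF1 %.3f +/- %.3f, bAcc %.3f +/- %.3f\n",
              x$level, x$n_folds, x$mF1["mean"], x$mF1["sd"],
              x$bAcc["mean"], x$bAcc["sd"]))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Per-patient error map
#'
#' Flags misclassified voxels (1) over the evaluated region — by default
#' wherever ground truth or prediction is an artery class — for visual
#' inspection; write it out with [write_volume()].
#'
#' @param gt,pred integer class-index volumes on the same grid.
#' @param exclude auxiliary classes ignored when defining the region.
#' @return binary `volume_grid` (1 = misclassified).
#' @export
error_map <- function(gt, pred, exclude = c(0L, 1L)) {
  if (!identical(dim(gt), dim(pred))) stop("gt and pred differ in shape")
  region <- !(gt %in% exclude) | !(pred %in% exclude)
  out <- array(0L, dim(gt))
  out[region & (gt != pred)] <- 1L
  same_grid(out, gt)
}

#' Write a metrics report as TSV (one row per class)
#' @param report a `metrics_report`.
#' @param path output path.
#' @export
report_to_tsv <- function(report, path) {
  utils::write.table(report$per_class, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
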