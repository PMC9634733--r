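# The multi-scale encoder-decoder voxel classifier: model object,
# training loop (Adam, categorical cross-entropy, optional deep
# supervision and L2 penalty), and the random-forest voxel baseline.

#' Construct the multi-scale voxel-labeling network
#'
#' Builds the dual-path encoder-decoder: a standard encoder over the main
#' patch and, when `context_path` is on, a parallel context encoder whose
#' input is the twice-as-large context patch down-sampled by 2 at entry.
#' The two paths are fused at the bottleneck by channel concatenation and a
#' convolution; a standard decoder with skip connections from the main
#' encoder restores main-patch resolution, and a per-voxel softmax yields
#' class probabilities. Convolutions are 3x3x3 (two per level), filter
#' counts double with depth starting at `base_filters`, down-sampling is
#' 2x max-pooling and up-sampling a transposed convolution. Optional
#' auxiliary softmax heads at intermediate decoder levels implement deep
#' supervision. Weights are Glorot-uniform initialized (seeded) and carry
#' an L2 penalty.
#'
#' With `context_path = FALSE` the model accepts only the main patch — the
#' plain single-scale baseline.
#'
#' @param main_size main patch dims, each divisible by `2^depth`
#'   (desk-scale default 32 x 32 x 16; the study-scale analog is
#'   128 x 128 x 64 with a 256 x 256 x 128 context patch).
#' @param classes number of output classes (26 detailed / 13 aggregated).
#' @param channels input channels (2: image + vessel).
#' @param base_filters filters in the first level (desk default 4;
#'   study-scale setting 16).
#' @param depth number of resolution levels.
#' @param context_path,deep_supervision architecture switches.
#' @param l2 L2 weight-penalty coefficient (default 1e-3).
#' @param seed RNG seed for weight initialization.
#' @return a `brave_net` model object.
#' @export
brave_net <- function(main_size = c(32, 32, 16), classes = 13, channels = 2,
                      base_filters = 4, depth = 2, context_path = TRUE,
                      deep_supervision = TRUE, l2 = 1e-3, seed = 1) {
  main_size <- as.integer(main_size)
  if (any(main_size %% 2L^depth != 0L))
    stop("main_size must be divisible by 2^depth per axis")
  ptr <- net_create(main_size, as.integer(channels), as.integer(classes),
                    as.integer(base_filters), as.integer(depth),
                    context_path, deep_supervision, l2)
  with_seed(seed, net_init_glorot(ptr))
  structure(list(
    ptr = ptr,
    config = list(main_size = main_size, classes = as.integer(classes),
                  channels = as.integer(channels),
                  base_filters = as.integer(base_filters),
                  depth = as.integer(depth), context_path = context_path,
                  deep_supervision = deep_supervision, l2 = l2, seed = seed),
    history = NULL
  ), class = "brave_net")
}

#' @export
print.brave_net <- function(x, ...) {
  info <- net_info(x$ptr)
  cat(sprintf(
    "brave_net: main %s, %d classes, %d base filters, depth %d\n",
    paste(info$main_dims, collapse = "x"), info$classes, info$base_filters,
    info$depth))
  cat(sprintf("  context path: %s, deep supervision: %s, L2 %g, %s parameters\n",
              info$context_path, info$deep_supervision, info$l2,
              format(info$n_params, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained: %d epochs, final loss %.4f\n",
                nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.brave_net <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) print(object$history)
  invisible(object)
}

#' Number of trainable parameters
#' @param model a `brave_net`.
#' @export
n_params <- function(model) net_nparams(model$ptr)

#' Extract / restore network weights
#' @param model a `brave_net`.
#' @return numeric vector of all weights and biases.
#' @export
get_weights <- function(model) net_get_weights(model$ptr)

#' @rdname get_weights
#' @param weights numeric vector from [get_weights()].
#' @export
set_weights <- function(model, weights) {
  net_set_weights(model$ptr, weights)
  invisible(model)
}

#' Save / load a trained model
#'
#' The checkpoint is a directory with the weights (binary, RDS) and a JSON
#' sidecar of the model configuration and training history.
#'
#' @param model a `brave_net`.
#' @param dir checkpoint directory.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(get_weights(model), file.path(dir, "weights.rds"))
  jsonlite::write_json(model$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history))
    utils::write.csv(model$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  model <- brave_net(main_size = cfg$main_size, classes = cfg$classes,
                     channels = cfg$channels, base_filters = cfg$base_filters,
                     depth = cfg$depth, context_path = cfg$context_path,
                     deep_supervision = cfg$deep_supervision, l2 = cfg$l2,
                     seed = cfg$seed)
  set_weights(model, readRDS(file.path(dir, "weights.rds")))
  hp <- file.path(dir, "history.csv")
  if (file.exists(hp)) model$history <- utils::read.csv(hp)
  model
}

#' Compact training dataset resident in C++
#'
#' Holds training patches in single precision with the context patch
#' stored pre-pooled (the network down-samples it by 2 at entry anyway),
#' using about 16x less memory than a list of R double arrays — what makes
#' cohort-scale training fit in ordinary RAM. Append scaled `patch_pair`s
#' with [ds_append()]; pass the dataset to [train_network()] in place of a
#' patch list.
#'
#' @param main_size main patch dims.
#' @param channels input channels.
#' @return a `patch_dataset` (environment with `ptr`, `n`, `main_size`,
#'   `channels`).
#' @export
patch_dataset <- function(main_size = c(32, 32, 16), channels = 2) {
  e <- new.env(parent = emptyenv())
  e$ptr <- ds_create()
  e$n <- 0L
  e$main_size <- as.integer(main_size)
  e$channels <- as.integer(channels)
  class(e) <- "patch_dataset"
  e
}

#' @rdname patch_dataset
#' @param ds a `patch_dataset`.
#' @param patch a scaled `patch_pair` with `gt`.
#' @export
ds_append <- function(ds, patch) {
  ds$n <- ds_add(ds$ptr, patch$main, patch$context, as.integer(patch$gt),
                 ds$main_size, ds$channels)
  invisible(ds)
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("patch_dataset: %d patches (%s main, %d channels)\n", x$n,
              paste(x$main_size, collapse = "x"), x$channels))
  invisible(x)
}

#' Initialize the classification-head biases to log class priors
#'
#' The weight initialization of the convolutions is Glorot uniform; bias
#' initialization is free, and setting the softmax-head biases (main and
#' deep-supervision heads) to the log of the class prior frequencies makes
#' the untrained network predict the priors instead of spending the first
#' epochs collapsing to the majority class — useful under the extreme
#' foreground/background imbalance of vessel volumes.
#'
#' @param model a `brave_net`.
#' @param patches training `patch_pair`s (or a `patch_dataset`) from which
#'   priors are counted.
#' @param floor minimum prior to avoid log(0) for absent classes.
#' @return the model, with biases set in place.
#' @export
init_head_bias <- function(model, patches, floor = 1e-4) {
  K <- model$config$classes
  cnt <- .gt_class_counts(patches, K)
  pri <- pmax(cnt / sum(cnt), floor)
  net_set_head_bias(model$ptr, log(pri))
  invisible(model)
}

.gt_class_counts <- function(patches, K) {
  if (inherits(patches, "patch_dataset"))
    return(as.numeric(ds_class_counts(patches$ptr, K)))
  cnt <- rep(0, K)
  for (p in patches)
    cnt <- cnt + tabulate(as.integer(p$gt) + 1L, nbins = K)
  cnt
}

# flatten a patch_pair into the sample list the C++ engine expects
.as_sample <- function(p, classes) {
  gt <- as.integer(p$gt)
  if (any(gt < 0L | gt >= classes))
    stop("ground-truth patch contains labels outside 0..", classes - 1)
  list(main = p$main, context = p$context, gt = gt)
}

#' Train the network
#'
#' Minimizes the total loss — main categorical cross-entropy, weighted
#' auxiliary cross-entropies of the deep-supervision heads (0.5 per level
#' halving), and the L2 weight penalty — with Adam. Patches are shuffled
#' each epoch under the training seed; gradients are accumulated over
#' `batch_size` patches per step.
#'
#' @param model a `brave_net`.
#' @param patches list of scaled `patch_pair`s with `gt` filled.
#' @param val_patches optional held-out patches; per-epoch validation
#'   macro F1 over classes with support (background and non-annotated
#'   excluded) is recorded in the history.
#' @param epochs,batch_size,lr training-loop settings (initial learning
#'   rate default 1e-3).
#' @param class_weights optional per-class loss weights (length =
#'   classes); `"balanced"` uses inverse-frequency and `"sqrt"`
#'   inverse-square-root-frequency weights computed from the training
#'   patches, normalized to mean 1 over observed classes. `NULL` (default)
#'   is plain unweighted cross-entropy.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch losses.
#' @return the model with `history` (data.frame of per-epoch losses and
#'   validation mF1) attached.
#' @export
train_network <- function(model, patches, val_patches = NULL, epochs = 4,
                          batch_size = 4, lr = 1e-3, class_weights = NULL,
                          seed = 1, verbose = FALSE) {
  is_ds <- inherits(patches, "patch_dataset")
  n_items <- if (is_ds) patches$n else length(patches)
  if (!n_items) stop("empty training set")
  classes <- model$config$classes
  samples <- if (!is_ds) lapply(patches, .as_sample, classes = classes)
  if (is.character(class_weights)) {
    cnt <- .gt_class_counts(patches, classes)
    w <- switch(match.arg(class_weights, c("balanced", "sqrt")),
                balanced = ifelse(cnt > 0, 1 / pmax(cnt, 1), 0),
                sqrt = ifelse(cnt > 0, 1 / sqrt(pmax(cnt, 1)), 0))
    w <- w / mean(w[cnt > 0])
    class_weights <- w
  }
  if (!is.null(class_weights))
    stopifnot(length(class_weights) == classes, all(class_weights >= 0))
  hist <- NULL
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_items)
      tot_main <- 0; tot_aux <- 0; l2v <- 0
      net_zero_grads(model$ptr)
      nb <- 0L
      for (j in seq_along(ord)) {
        lc <- if (is_ds) {
          net_accumulate_ds(model$ptr, patches$ptr, ord[j] - 1L,
                            class_weights)
        } else {
          s <- samples[[ord[j]]]
          net_accumulate(model$ptr,
                         s$main,
                         if (model$config$context_path) s$context else NULL,
                         s$gt, class_weights)
        }
        tot_main <- tot_main + lc[["main"]]
        tot_aux <- tot_aux + lc[["aux"]]
        l2v <- lc[["l2"]]
        nb <- nb + 1L
        if (nb == batch_size || j == length(ord)) {
          net_step(model$ptr, lr)
          nb <- 0L
        }
      }
      val_mf1 <- NA_real_
      if (!is.null(val_patches)) val_mf1 <- .patch_mf1(model, val_patches)
      row <- data.frame(epoch = ep,
                        loss = (tot_main + tot_aux) / n_items + l2v,
                        main = tot_main / n_items,
                        aux = tot_aux / n_items,
                        l2 = l2v, val_mf1 = val_mf1)
      hist <- rbind(hist, row)
      if (verbose)
        cat(sprintf("epoch %d: loss %.4f (main %.4f aux %.4f l2 %.4f) val mF1 %s\n",
                    ep, row$loss, row$main, row$aux, row$l2,
                    ifelse(is.na(val_mf1), "-", sprintf("%.3f", val_mf1))))
    }
  })
  model$history <- if (is.null(model$history)) hist else rbind(model$history,
                                                               hist)
  model
}

# quick voxel-wise macro F1 over a list of patches (aux-free forward)
.patch_mf1 <- function(model, patches) {
  K <- model$config$classes
  tp <- fp <- fn <- numeric(K)
  for (p in patches) {
    probs <- predict(model, p)
    pred <- max.col(matrix(probs, ncol = K), ties.method = "first") - 1L
    gt <- as.integer(p$gt)
    for (k in 2:(K - 1)) {
      tp[k + 1] <- tp[k + 1] + sum(pred == k & gt == k)
      fp[k + 1] <- fp[k + 1] + sum(pred == k & gt != k)
      fn[k + 1] <- fn[k + 1] + sum(pred != k & gt == k)
    }
  }
  support <- (tp + fn) > 0
  support[1:2] <- FALSE
  if (!any(support)) return(NA_real_)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  mean(f1[support])
}

#' Predict per-voxel class probabilities for a patch
#'
#' @param object a `brave_net`.
#' @param newdata a `patch_pair` (scaled like the training data).
#' @param ... unused.
#' @return array (x, y, z, classes) of softmax probabilities.
#' @export
predict.brave_net <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "patch_pair"))
  net_forward(object$ptr, newdata$main,
              if (object$config$context_path) newdata$context else NULL)
}

# ---------------------------------------------------------------------------

#' Random-forest voxel baseline
#'
#' Classical per-voxel baseline: a random forest (50 trees by default) on
#' hand-crafted features — image intensity, vessel-channel radius value,
#' and voxel coordinates normalized to [0, 1] per axis — trained on a
#' class-balanced sample of up to `per_class_voxels` voxels per class per
#' subject. Classes absent from all training subjects are skipped (and
#' reported); prediction covers mask voxels, everything else is background.
#'
#' @param subjects list of training subjects, each with `image`,
#'   `gt_labels` and a `vessel` (dense radius) channel or `centerline`.
#' @param per_class_voxels voxels sampled per class per subject.
#' @param trees number of trees (default 50).
#' @param seed RNG seed.
#' @param n_classes optional class-universe size; classes absent from all
#'   training subjects are skipped and reported via a message.
#' @return an `rf_voxel_model`.
#' @export
rf_baseline <- function(subjects, per_class_voxels = 200, trees = 50,
                        seed = 1, n_classes = NULL) {
  stopifnot(per_class_voxels >= 1)
  feats <- NULL
  labs <- NULL
  with_seed(seed, {
    for (s in subjects) {
      ves <- if (!is.null(s$vessel)) s$vessel else s$centerline$dense
      gt <- s$gt_labels
      dims <- dim(gt)
      for (k in sort(unique(as.integer(gt[gt > 0])))) {
        idx <- which(gt == k)
        take <- min(per_class_voxels, length(idx))
        idx <- if (length(idx) == 1) idx else sample(idx, take)
        co <- arrayInd(idx, dims)
        feats <- rbind(feats, cbind(
          intensity = s$image[idx], radius = ves[idx],
          x = (co[, 1] - 1) / (dims[1] - 1),
          y = (co[, 2] - 1) / (dims[2] - 1),
          z = (co[, 3] - 1) / (dims[3] - 1)))
        labs <- c(labs, rep(k, take))
      }
    }
  })
  present <- sort(unique(labs))
  if (!is.null(n_classes)) {
    absent <- setdiff(seq_len(n_classes) - 1L, c(0L, present))
    if (length(absent))
      message("classes absent from all training subjects, skipped: ",
              paste(absent, collapse = ", "))
  }
  df <- data.frame(feats, label = factor(labs, levels = present))
  fit <- ranger::ranger(label ~ ., data = df, num.trees = trees,
                        probability = TRUE, seed = seed,
                        num.threads = 1)
  structure(list(fit = fit, classes = present, trees = trees),
            class = "rf_voxel_model")
}

#' @export
print.rf_voxel_model <- function(x, ...) {
  cat(sprintf("rf_voxel_model: %d trees, %d classes\n", x$trees,
              length(x$classes)))
  invisible(x)
}

#' Predict a whole volume with the random-forest baseline
#'
#' @param object an `rf_voxel_model`.
#' @param newdata list with `image`, `vessel` (dense radius volume) and
#'   `mask` (voxels to classify; elsewhere background).
#' @param ... unused.
#' @return a `softmax_volume` over the full class universe (background
#'   probability 1 outside the mask).
#' @export
predict.rf_voxel_model <- function(object, newdata, ...) {
  image <- newdata$image
  vessel <- newdata$vessel
  mask <- newdata$mask
  dims <- dim(image)
  K <- max(object$classes) + 1L
  probs <- array(0, c(dims, K))
  probs[, , , 1] <- 1         # background everywhere by default
  idx <- which(mask == 1)
  if (length(idx)) {
    co <- arrayInd(idx, dims)
    df <- data.frame(intensity = image[idx], radius = vessel[idx],
                     x = (co[, 1] - 1) / (dims[1] - 1),
                     y = (co[, 2] - 1) / (dims[2] - 1),
                     z = (co[, 3] - 1) / (dims[3] - 1))
    pr <- predict(object$fit, data = df, num.threads = 1)$predictions
    n <- prod(dims)
    flat <- array(probs, c(n, K))
    flat[idx, ] <- 0
    for (j in seq_along(object$classes))
      flat[idx, object$classes[j] + 1L] <- pr[, j]
    probs <- array(flat, c(dims, K))
  }
  structure(list(probs = probs, spacing = vg_spacing(image)),
            class = "softmax_volume")
}
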