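make_toy_patch <- function(md = c(8, 8, 4), K = 3, seed = 1) {
  set.seed(seed)
  structure(list(
    main = array(stats::runif(prod(md) * 2), c(md, 2)),
    context = array(stats::runif(prod(md) * 16), c(2 * md, 2)),
    gt = array(sample(0:(K - 1), prod(md), replace = TRUE), md),
    center = c(0, 0, 0), spacing = c(1, 1, 1), subject_id = "toy"),
    class = "patch_pair")
}

test_that("the network emits normalized per-voxel probabilities of the right shape", {
  md <- c(8, 8, 4)
  m <- brave_net(main_size = md, classes = 5, base_filters = 2, depth = 2,
                 seed = 1)
  p <- make_toy_patch(md, 5)
  pr <- predict(m, p)
  expect_equal(dim(pr), c(md, 5))
  sums <- apply(pr, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(pr >= 0))
})

test_that("the context path adds parameters and the plain baseline ignores context", {
  md <- c(8, 8, 4)
  full <- brave_net(main_size = md, classes = 4, base_filters = 2,
                    context_path = TRUE, seed = 1)
  plain <- brave_net(main_size = md, classes = 4, base_filters = 2,
                     context_path = FALSE, seed = 1)
  expect_gt(n_params(full), n_params(plain))
  # the plain model predicts from the main patch alone
  p <- make_toy_patch(md, 4)
  pr1 <- predict(plain, p)
  p2 <- p
  p2$context <- p2$context * 0
  expect_equal(predict(plain, p2), pr1)
  # the full model needs its context input
  expect_error(net_forward(full$ptr, p$main, NULL), "context")
})

test_that("initialization is seeded and weights round-trip", {
  md <- c(8, 8, 4)
  a <- brave_net(main_size = md, classes = 3, base_filters = 2, seed = 7)
  b <- brave_net(main_size = md, classes = 3, base_filters = 2, seed = 7)
  expect_identical(get_weights(a), get_weights(b))
  cdiff <- brave_net(main_size = md, classes = 3, base_filters = 2, seed = 8)
  expect_false(identical(get_weights(a), get_weights(cdiff)))
  w <- get_weights(a)
  set_weights(cdiff, w)
  expect_identical(get_weights(cdiff), w)
  # dims must be divisible by 2^depth
  expect_error(brave_net(main_size = c(10, 8, 4), depth = 2), "divisible")
})

test_that("training reduces the loss, is seeded, and overfits a single patch", {
  md <- c(8, 8, 4)
  p <- make_toy_patch(md, 3, seed = 3)
  # structured target: class depends on x-half, so it is learnable
  p$gt <- array(rep(c(0L, 2L), each = 4, times = 8 * 4), md)
  m <- brave_net(main_size = md, classes = 3, base_filters = 2, l2 = 0,
                 seed = 1)
  m <- train_network(m, list(p), epochs = 100, batch_size = 1, lr = 2e-3,
                     seed = 1)
  expect_lt(m$history$main[100], m$history$main[1])
  pr <- predict(m, p)
  pred <- max.col(matrix(pr, ncol = 3), ties.method = "first") - 1L
  expect_gt(mean(pred == as.integer(p$gt)), 0.95)
  # seeded reproducibility of the loss trace
  m2 <- brave_net(main_size = md, classes = 3, base_filters = 2, l2 = 0,
                  seed = 1)
  m2 <- train_network(m2, list(p), epochs = 3, batch_size = 1, lr = 2e-3,
                      seed = 1)
  expect_equal(m2$history$main, m$history$main[1:3], tolerance = 1e-6)
  expect_error(train_network(m, list(), epochs = 1), "empty")
})

test_that("the L2 penalty equals the direct weight-norm sum", {
  md <- c(8, 8, 4)
  lambda <- 1e-3
  F <- 2
  # plain single-scale net, depth 1: the penalized weights are the conv /
  # up-sampling / head kernels; instance-norm scales (one per filter of
  # the 6 normalized convs = 8F entries, initialized to 1) and all biases
  # (initialized to 0) are exempt. So at initialization the penalty is
  # lambda * (sum(weights^2) - 8F), derived from the documented layout.
  m <- brave_net(main_size = md, classes = 3, base_filters = F, depth = 1,
                 context_path = FALSE, deep_supervision = FALSE,
                 l2 = lambda, seed = 2)
  p <- make_toy_patch(md, 3, seed = 4)
  lc <- net_accumulate(m$ptr, p$main, NULL, as.integer(p$gt))
  w <- get_weights(m)
  expect_equal(lc[["l2"]], lambda * (sum(w^2) - 8 * F), tolerance = 1e-5)
  # disabling L2 zeroes the reported penalty and leaves the data loss alone
  m0 <- brave_net(main_size = md, classes = 3, base_filters = F, depth = 1,
                  context_path = FALSE, deep_supervision = FALSE, l2 = 0,
                  seed = 2)
  lc0 <- net_accumulate(m0$ptr, p$main, NULL, as.integer(p$gt))
  expect_equal(lc[["main"]], lc0[["main"]], tolerance = 1e-6)
  expect_equal(lc0[["l2"]], 0)
})

test_that("a gradient step decreases the loss on a fixed small batch", {
  md <- c(8, 8, 4)
  p <- make_toy_patch(md, 3, seed = 5)
  m <- brave_net(main_size = md, classes = 3, base_filters = 2, l2 = 0,
                 seed = 3)
  l0 <- net_accumulate(m$ptr, p$main, p$context, as.integer(p$gt))[["main"]]
  net_step(m$ptr, 1e-3)
  net_zero_grads(m$ptr)
  l1 <- net_accumulate(m$ptr, p$main, p$context, as.integer(p$gt))[["main"]]
  expect_lt(l1, l0)
})

test_that("checkpoints round-trip through save_model / load_model", {
  md <- c(8, 8, 4)
  m <- brave_net(main_size = md, classes = 4, base_filters = 2, seed = 11)
  p <- make_toy_patch(md, 4, seed = 6)
  m <- train_network(m, list(p), epochs = 2, batch_size = 1, seed = 1)
  td <- tempfile()
  save_model(m, td)
  m2 <- load_model(td)
  expect_equal(get_weights(m2), get_weights(m))
  expect_equal(predict(m2, p), predict(m, p))
  expect_equal(m2$history$loss, m$history$loss, tolerance = 1e-6)
})

test_that("the random-forest baseline defaults to 50 trees and fits separable toys", {
  dims <- c(16, 16, 8)
  mk <- function(seed) {
    set.seed(seed)
    gt <- array(0L, dims)
    gt[1:8, , ] <- 2L
    gt[9:16, , ] <- 3L
    img <- array(stats::rnorm(prod(dims)), dims)
    img[gt == 3L] <- img[gt == 3L] + 6      # separable intensity
    list(image = volume_grid(img, c(1, 1, 1)),
         vessel = volume_grid(array(0.5, dims), c(1, 1, 1)),
         gt_labels = volume_grid(gt, c(1, 1, 1)))
  }
  rf <- rf_baseline(list(mk(1), mk(2)), per_class_voxels = 100, seed = 1)
  expect_equal(rf$trees, 50L)
  expect_equal(rf$fit$num.trees, 50L)
  # balanced separable toy: near-perfect training accuracy
  sub <- mk(3)
  sv <- predict(rf, list(image = sub$image, vessel = sub$vessel,
                         mask = volume_grid(array(1L, dims))))
  pred <- argmax_labels(sv)
  conf <- voxel_confusion(sub$gt_labels, pred, n_classes = 4L)
  rep <- confusion_scores(conf)
  expect_gt(rep$bAcc, 0.95)
  # single-class degenerate fit predicts that class everywhere
  one <- mk(4)
  one$gt_labels[] <- 7L
  rf1 <- rf_baseline(list(one), per_class_voxels = 50, seed = 1)
  sv1 <- predict(rf1, list(image = one$image, vessel = one$vessel,
                           mask = volume_grid(array(1L, dims))))
  expect_equal(unique(as.integer(argmax_labels(sv1))), 7L)
})
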