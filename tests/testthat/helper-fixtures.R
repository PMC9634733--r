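# shared in-code fixtures for the test suite

# axis-aligned solid cylinder mask along the given axis
cylinder_mask <- function(dims = c(24, 24, 24), radius = 3, axis = 3,
                          spacing = c(1, 1, 1)) {
  arr <- array(0L, dims)
  ctr <- (dims + 1) / 2
  idx <- arrayInd(seq_len(prod(dims)), dims)
  perp <- setdiff(1:3, axis)
  d2 <- (idx[, perp[1]] - ctr[perp[1]])^2 * spacing[perp[1]]^2 +
    (idx[, perp[2]] - ctr[perp[2]])^2 * spacing[perp[2]]^2
  arr[d2 <= (radius)^2] <- 1L
  volume_grid(arr, spacing)
}

# Y-shaped union of three tubes meeting at a central junction
y_mask <- function(dims = c(40, 40, 12), radius = 2) {
  arr <- array(0L, dims)
  ctr <- c(20, 20, 6)
  dirs <- list(c(0, -1, 0), c(-0.8, 0.7, 0), c(0.8, 0.7, 0))
  pts <- NULL
  for (d in dirs) {
    d <- d / sqrt(sum(d^2))
    for (t in seq(0, 15, by = 0.25))
      pts <- rbind(pts, ctr + t * d)
  }
  idx <- arrayInd(seq_len(prod(dims)), dims)
  for (i in seq_len(nrow(pts))) {
    d2 <- (idx[, 1] - pts[i, 1])^2 + (idx[, 2] - pts[i, 2])^2 +
      (idx[, 3] - pts[i, 3])^2
    arr[d2 <= radius^2] <- 1L
  }
  volume_grid(arr, c(1, 1, 1))
}

# random softmax field (dims x K), rows normalized
random_probs <- function(dims, K) {
  p <- array(stats::runif(prod(dims) * K), c(dims, K))
  s <- apply(p, 1:3, sum)
  structure(list(probs = p / array(s, c(dims, K)), spacing = c(1, 1, 1)),
            class = "softmax_volume")
}

# tiny prepared subject cache (desk phantom is ~0.5 s to prepare)
local_phantom <- local({
  cache <- new.env()
  function(seed = 42, ...) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- prepare_subject(sample_subject(seed = seed, ...))
    cache[[key]]
  }
})
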