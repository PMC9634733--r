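# Centerline geometry: topology-preserving 3-D thinning of a binary vessel
# mask into a one-voxel-thin centerline with radii encoded from the
# Euclidean distance transform, and decomposition of the centerline into
# bifurcation-bounded segments. Voxel indices are 0-based throughout;
# physical quantities (radii) are in mm using the grid spacing.

#' Skeletonize a binary vessel mask
#'
#' Thins the mask into a one-voxel-thin centerline by sequential removal of
#' simple points (26-connectivity for foreground, 6 for background) in
#' increasing distance-transform order, protecting curve endpoints. Each
#' centerline voxel's radius is the Euclidean distance (mm, spacing-aware)
#' from that voxel to the nearest background voxel. Short spurs (free-ended
#' runs below `prune_spurs` voxels) are removed afterwards.
#'
#' @param mask binary `volume_grid` (or array; values 0/1).
#' @param prune_spurs minimum run length (voxels) for free-ended spurs;
#'   shorter ones are thinning artifacts and are pruned. 0 disables.
#' @return a `centerline_map`: `coords` (m x 3, 0-based), `radius_mm`,
#'   `dense` (radius-valued volume, the vessel-specific input channel),
#'   `dim`, `spacing`.
#' @export
skeletonize <- function(mask, prune_spurs = 3) {
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1)))
    stop("mask must be binary (0/1); found values: ",
         paste(utils::head(setdiff(vals, 0:1), 3), collapse = ", "))
  dims <- dim(mask)
  sp <- vg_spacing(mask)
  m <- array(mask == 1, dims)
  if (!any(m)) {
    return(structure(list(
      coords = matrix(integer(0), 0, 3), radius_mm = numeric(0),
      dense = volume_grid(array(0, dims), sp), dim = dims, spacing = sp),
      class = "centerline_map"))
  }
  edt <- cpp_edt(m, dims, sp)
  thin <- array(cpp_thin(m, edt, dims), dims)

  if (prune_spurs > 0) thin <- .prune_spurs(thin, prune_spurs)

  idx <- which(thin)
  coords <- arrayInd(idx, dims) - 1L
  # radius at the centerline voxel, from the EDT of the original mask
  radius <- edt[idx]
  dense <- array(0, dims)
  dense[idx] <- radius
  structure(list(coords = coords, radius_mm = radius,
                 dense = volume_grid(dense, sp), dim = dims, spacing = sp),
            class = "centerline_map")
}

# remove free-ended runs shorter than min_len (iterating walk from each
# endpoint until a junction); junction-free tiny components are kept
.prune_spurs <- function(thin, min_len) {
  dims <- dim(thin)
  repeat {
    cnt <- array(cpp_neighbor_count26(thin, dims), dims)
    ends <- which(thin & cnt == 1)
    removed <- FALSE
    for (e in ends) {
      if (!thin[e]) next
      run <- integer(0)
      cur <- e
      repeat {
        run <- c(run, cur)
        nb <- .neighbors26(cur, dims)
        nb <- nb[thin[nb] & !(nb %in% run)]
        if (length(nb) != 1) break
        deg <- cnt[nb]
        if (deg >= 3) { run <- c(run, NA) ; break }  # reached a junction
        cur <- nb
        if (length(run) >= min_len) break
      }
      hit_junction <- length(run) > 0 && is.na(run[length(run)])
      run <- run[!is.na(run)]
      if (hit_junction && length(run) < min_len) {
        thin[run] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  thin
}

# flat (1-based) indices of in-bounds 26-neighbors of flat index i
.neighbors26 <- function(i, dims) {
  xyz <- arrayInd(i, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nb <- sweep(offs, 2, as.integer(xyz), "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
    nb[, 3] >= 1 & nb[, 3] <= dims[3]
  nb <- nb[ok, , drop = FALSE]
  nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] * (nb[, 3] - 1L)
}

#' @export
print.centerline_map <- function(x, ...) {
  cat(sprintf("centerline_map: %d voxels, radius %.2f-%.2f mm, grid %s\n",
              nrow(x$coords),
              if (length(x$radius_mm)) min(x$radius_mm) else NA,
              if (length(x$radius_mm)) max(x$radius_mm) else NA,
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Decompose a centerline into bifurcation-bounded segments
#'
#' Bifurcation nodes are maximal 26-connected clusters of centerline voxels
#' with three or more centerline neighbors; segments are the connected runs
#' between node/endpoint boundaries. Every centerline voxel belongs to
#' exactly one segment: node voxels are attached to their adjacent run of
#' lowest id so the runs partition the centerline. Disconnected components
#' simply yield separate segments, which keeps the decomposition robust to
#' missing arteries (disconnected vessel trees).
#'
#' @param cl a `centerline_map` from [skeletonize()].
#' @return a `segment_table`: `segments` (list of id, ordered `coords`,
#'   `endpoint_types`, `gt_label`), `bifurcations` (cluster coords),
#'   `dim`, `spacing`.
#' @export
extract_segments <- function(cl) {
  dims <- cl$dim
  m <- nrow(cl$coords)
  empty <- structure(list(segments = list(), bifurcations = list(),
                          dim = dims, spacing = cl$spacing),
                     class = "segment_table")
  if (m == 0) return(empty)
  flat <- cl$coords[, 1] + 1L + dims[1] * cl$coords[, 2] +
    dims[1] * dims[2] * cl$coords[, 3]
  pos <- integer(prod(dims))         # flat -> row lookup
  pos[flat] <- seq_len(m)

  # adjacency among centerline voxels (26-connectivity)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(cl$coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] & nb[, 2] >= 0 & nb[, 2] < dims[2] &
      nb[, 3] >= 0 & nb[, 3] < dims[3]
    nflat <- nb[ok, 1] + 1L + dims[1] * nb[ok, 2] +
      dims[1] * dims[2] * nb[ok, 3]
    hit <- pos[nflat] > 0
    a <- which(ok)[hit]
    b <- pos[nflat[hit]]
    keep <- a < b
    if (any(keep)) edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  deg <- igraph::degree(g)

  junction <- deg >= 3
  # bifurcation clusters: 26-components of junction voxels
  bif_clusters <- list()
  cluster_of <- integer(m)
  if (any(junction)) {
    sg <- igraph::induced_subgraph(g, which(junction))
    comp <- igraph::components(sg)
    for (ci in seq_len(comp$no)) {
      members <- which(junction)[comp$membership == ci]
      bif_clusters[[ci]] <- members
      cluster_of[members] <- ci
    }
  }

  # runs: components after removing junction voxels
  run_of <- integer(m)
  segments <- list()
  rest <- which(!junction)
  if (length(rest)) {
    sg <- igraph::induced_subgraph(g, rest)
    comp <- igraph::components(sg)
    for (ci in seq_len(comp$no)) {
      members <- rest[comp$membership == ci]
      segments[[length(segments) + 1L]] <- list(id = length(segments) + 1L,
                                                rows = .order_run(g, members))
      run_of[members] <- length(segments)
    }
  }

  # attach junction voxels to the adjacent run with the lowest id; a
  # cluster with no adjacent run becomes its own segment
  if (any(junction)) {
    for (ci in seq_along(bif_clusters)) {
      members <- bif_clusters[[ci]]
      nbr_runs <- sort(unique(run_of[unlist(
        igraph::adjacent_vertices(g, members))]))
      nbr_runs <- nbr_runs[nbr_runs > 0]
      if (!length(nbr_runs)) {
        segments[[length(segments) + 1L]] <- list(id = length(segments) + 1L,
                                                  rows = members)
        run_of[members] <- length(segments)
      } else {
        target <- nbr_runs[1]
        rows <- segments[[target]]$rows
        # append at the touching extremity
        nb_first <- any(members %in% as.integer(
          igraph::neighbors(g, rows[1])))
        if (nb_first) segments[[target]]$rows <- c(rev(members), rows)
        else segments[[target]]$rows <- c(rows, members)
        run_of[members] <- target
      }
    }
  }

  # endpoint types: 'bifurcation' when the extremity touches a junction
  # cluster (or is one), else 'end'
  segs_out <- list()
  for (s in segments) {
    rows <- s$rows
    etype <- c("end", "end")
    for (side in 1:2) {
      v <- if (side == 1) rows[1] else rows[length(rows)]
      nbs <- as.integer(igraph::neighbors(g, v))
      if (cluster_of[v] > 0 ||
          any(cluster_of[nbs] > 0 & run_of[nbs] != s$id) ||
          any(run_of[nbs] != s$id & run_of[nbs] > 0))
        etype[side] <- "bifurcation"
    }
    segs_out[[length(segs_out) + 1L]] <- list(
      id = s$id,
      coords = cl$coords[rows, , drop = FALSE],
      radius_mm = cl$radius_mm[rows],
      endpoint_types = etype,
      gt_label = NA_integer_)
  }
  structure(list(
    segments = segs_out,
    bifurcations = lapply(bif_clusters, function(r)
      cl$coords[r, , drop = FALSE]),
    dim = dims, spacing = cl$spacing), class = "segment_table")
}

# order a run's voxel rows by walking the induced path; cycles start
# anywhere, branched leftovers fall back to DFS order
.order_run <- function(g, members) {
  if (length(members) <= 2) return(members)
  sg <- igraph::induced_subgraph(g, members)
  degs <- igraph::degree(sg)
  start <- if (any(degs <= 1)) which(degs <= 1)[1] else 1L
  ord <- as.integer(igraph::dfs(sg, root = start)$order)
  members[ord]
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("segment_table: %d segments, %d bifurcation nodes, grid %s\n",
              length(x$segments), length(x$bifurcations),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Segment-id volume: nearest-centerline assignment over the lumen
#'
#' Every mask voxel receives the segment id of its nearest centerline
#' voxel (Euclidean, spacing-aware); non-mask voxels get 0. This
#' translates the bifurcation-based segment decomposition into a 3-D map
#' of the same dimensions as the image, the input of segment washing.
#'
#' @param table a `segment_table`.
#' @param mask binary `volume_grid` on the same grid.
#' @return integer `volume_grid` of segment ids.
#' @export
segment_id_volume <- function(table, mask) {
  dims <- dim(mask)
  if (!identical(as.integer(dims), as.integer(table$dim)))
    stop("segment table and mask are on different grids")
  if (!length(table$segments)) {
    if (any(mask == 1)) stop("empty segment table with non-empty mask")
    return(same_grid(array(0L, dims), mask))
  }
  coords <- do.call(rbind, lapply(table$segments, `[[`, "coords"))
  ids <- unlist(lapply(table$segments, function(s)
    rep(s$id, nrow(s$coords))))
  out <- cpp_nearest_centerline(array(mask == 1, dims), as.integer(dims),
                                vg_spacing(mask), coords, as.integer(ids))
  same_grid(array(as.integer(out), dims), mask)
}

#' Fill per-segment ground-truth labels by majority vote
#'
#' Each segment's `gt_label` is the majority ground-truth class over its
#' centerline voxels (ties to the lowest class index). Segments with no
#' ground-truth overlap fall back to the non-annotated class; segments that
#' are not label-homogeneous are labeled by majority and reported via a
#' message.
#'
#' @param table a `segment_table`.
#' @param gt integer class-index `volume_grid`.
#' @return the table with `gt_label` filled per segment.
#' @export
segment_gt_labels <- function(table, gt) {
  dims <- dim(gt)
  n_mixed <- 0L
  for (i in seq_along(table$segments)) {
    co <- table$segments[[i]]$coords
    flat <- co[, 1] + 1L + dims[1] * co[, 2] + dims[1] * dims[2] * co[, 3]
    vals <- as.integer(gt[flat])
    vals <- vals[vals > 0]          # background overlap carries no vote
    if (!length(vals)) {
      table$segments[[i]]$gt_label <- 1L   # non-annotated fallback
      next
    }
    tab <- table(vals)
    if (length(tab) > 1) n_mixed <- n_mixed + 1L
    best <- as.integer(names(tab)[which.max(tab)])
    table$segments[[i]]$gt_label <- best
  }
  if (n_mixed > 0)
    message(n_mixed, " segment(s) had mixed ground truth; labeled by majority")
  table
}

#' Serialize a centerline map to JSON
#'
#' Writes the sparse representation (0-based voxel coordinates with radii
#' in mm); the dense radius volume is written separately as NIfTI via
#' [write_volume()] on `cl$dense`.
#'
#' @param cl a `centerline_map`.
#' @param path output path.
#' @export
centerline_to_json <- function(cl, path) {
  jsonlite::write_json(
    list(coords = cl$coords, radius_mm = cl$radius_mm,
         dim = cl$dim, spacing = cl$spacing),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a segment table to JSON
#' @param table a `segment_table`.
#' @param path output path.
#' @export
segment_table_to_json <- function(table, path) {
  obj <- list(
    segments = lapply(table$segments, function(s)
      list(id = s$id, coords = s$coords, endpoint_types = s$endpoint_types,
           gt_label = s$gt_label)),
    bifurcations = table$bifurcations,
    dim = table$dim, spacing = table$spacing)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
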