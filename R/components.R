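# 3D connected-component labeling of a logical array.
#
# Builds the adjacency graph of foreground voxels (26- or 6-connectivity)
# and labels components with igraph. Components are numbered 1..n in
# ascending order of their minimum linear index, which corresponds to
# lexicographic order over (axis3, axis2, axis1) voxel indices — i.e. the
# slowest-varying (superior-inferior) axis ranks first. This makes ids
# reproducible across runs and platforms, so manual-label files stay valid.
#
# Returns list(membership = integer array-length vector of labels (0 =
# background), voxels = list of integer vectors of linear indices, one per
# component, sorted ascending).
label_components_3d <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  idx <- which(mask != 0)
  nfg <- length(idx)
  membership <- integer(prod(d))
  if (nfg == 0L)
    return(list(membership = membership, voxels = list()))

  offsets <- neighbor_offsets(connectivity)
  # forward half of the neighborhood is enough for an undirected graph
  fwd <- offsets[offsets[, 3] > 0 |
                 (offsets[, 3] == 0 & offsets[, 2] > 0) |
                 (offsets[, 3] == 0 & offsets[, 2] == 0 & offsets[, 1] > 0),
                 , drop = FALSE]
  co <- arrayInd(idx, d)
  rank_of <- integer(prod(d))
  rank_of[idx] <- seq_len(nfg)
  edges <- vector("list", nrow(fwd))
  for (k in seq_len(nrow(fwd))) {
    nb <- co + matrix(fwd[k, ], nfg, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
          nb[, 2] >= 1L & nb[, 2] <= d[2] &
          nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    nidx <- (nb[ok, 3] - 1L) * (d[1] * d[2]) + (nb[ok, 2] - 1L) * d[1] +
      nb[ok, 1]
    hit <- rank_of[nidx] > 0L
    if (!any(hit)) next
    from <- which(ok)[hit]
    edges[[k]] <- rbind(from, rank_of[nidx[hit]])
  }
  em <- do.call(cbind, edges)
  if (is.null(em)) {
    comp <- seq_len(nfg)  # all isolated voxels
  } else {
    g <- igraph::make_graph(as.vector(em), n = nfg, directed = FALSE)
    comp <- igraph::components(g)$membership
  }
  # renumber by minimum linear index per component
  comp_min <- vapply(split(idx, comp), min, numeric(1))
  newid <- integer(length(comp_min))
  newid[order(comp_min)] <- seq_along(comp_min)
  lab <- newid[comp]
  membership[idx] <- lab
  voxels <- split(idx, lab)
  voxels <- lapply(voxels, function(v) sort(as.integer(v)))
  names(voxels) <- NULL
  list(membership = membership, voxels = voxels)
}

neighbor_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) {
    g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  } else if (connectivity != 26L) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  unname(g)
}
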