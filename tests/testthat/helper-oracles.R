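# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no igraph, no separable convolution): flood
# fill by frontier expansion, direct truncated-kernel Gaussian evaluation,
# and double-loop pair enumeration.

# Flood-fill component labeling of a logical 3D array. Returns a list of
# sorted voxel-index vectors, ordered by minimum linear index.
oracle_flood_fill <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  offs <- as.matrix(offs)
  unvisited <- mask
  comps <- list()
  repeat {
    seed <- which(unvisited)
    if (length(seed) == 0L) break
    seed <- seed[1]
    comp <- integer(0)
    frontier <- seed
    unvisited[seed] <- FALSE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      co <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        co + matrix(offs[k, ], nrow(co), 3, byrow = TRUE)))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      nidx <- unique((nb[, 3] - 1) * d[1] * d[2] + (nb[, 2] - 1) * d[1] +
                       nb[, 1])
      frontier <- nidx[unvisited[nidx]]
      unvisited[frontier] <- FALSE
    }
    comps[[length(comps) + 1L]] <- sort(as.integer(comp))
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# Normalized truncated 3D Gaussian kernel evaluated directly from the
# density, in physical units; offsets in voxels, per-axis spacing in mm.
oracle_gauss_kernel <- function(spacing_mm, sigma_mm, truncate = 4) {
  r <- pmax(1L, as.integer(ceiling(truncate * sigma_mm / spacing_mm)))
  ax <- lapply(1:3, function(a) seq.int(-r[a], r[a]) * spacing_mm[a])
  k <- array(0, 2L * r + 1L)
  for (i in seq_along(ax[[1]])) for (j in seq_along(ax[[2]]))
    for (l in seq_along(ax[[3]]))
      k[i, j, l] <- exp(-0.5 * (ax[[1]][i]^2 + ax[[2]][j]^2 +
                                  ax[[3]][l]^2) / sigma_mm^2)
  k / sum(k)
}

# Scatter a sparse volume through the truncated kernel (valid when no
# nonzero voxel is within a kernel radius of the boundary, so boundary
# reflection never engages).
oracle_smooth_sparse <- function(vals, spacing_mm, sigma_mm, truncate = 4) {
  k <- oracle_gauss_kernel(spacing_mm, sigma_mm, truncate)
  r <- (dim(k) - 1L) %/% 2L
  d <- dim(vals)
  out <- array(0, d)
  for (v in which(vals != 0)) {
    co <- arrayInd(v, d)[1, ]
    stopifnot(all(co - r >= 1L), all(co + r <= d))
    out[(co[1] - r[1]):(co[1] + r[1]), (co[2] - r[2]):(co[2] + r[2]),
        (co[3] - r[3]):(co[3] + r[3])] <-
      out[(co[1] - r[1]):(co[1] + r[1]), (co[2] - r[2]):(co[2] + r[2]),
          (co[3] - r[3]):(co[3] + r[3])] + vals[v] * k
  }
  out
}

# Double-loop Harrell C-index (higher biomarker = worse prognosis).
oracle_cindex <- function(time, event, x) {
  conc <- 0
  npairs <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    npairs <- npairs + 1
    if (x[i] > x[j]) conc <- conc + 1
    else if (x[i] == x[j]) conc <- conc + 0.5
  }
  if (npairs == 0) return(NA_real_)
  conc / npairs
}

# Hand product-limit log-rank chi-square (observed minus expected over
# event times, hypergeometric variance), independent of survdiff.
oracle_logrank_chi2 <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(1:2, c(length(time_a), length(time_b)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & grp == 1)
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Voxel centers of a phantom-style grid with origin at half spacing.
sphere_voxel_count <- function(dims, spacing, center, radius) {
  x <- (seq_len(dims[1]) - 0.5) * spacing[1]
  y <- (seq_len(dims[2]) - 0.5) * spacing[2]
  z <- (seq_len(dims[3]) - 0.5) * spacing[3]
  sum(outer(outer((x - center[1])^2, (y - center[2])^2, "+"),
            (z - center[3])^2, "+") <= radius^2)
}

# A small digitized-sphere SUV scene on its own grid (origin half-voxel).
make_sphere_scene <- function(dims, spacing, spheres, background = 1) {
  x <- (seq_len(dims[1]) - 0.5) * spacing[1]
  y <- (seq_len(dims[2]) - 0.5) * spacing[2]
  z <- (seq_len(dims[3]) - 0.5) * spacing[3]
  vals <- array(background, dims)
  for (s in spheres) {
    inside <- outer(outer((x - s$center[1])^2, (y - s$center[2])^2, "+"),
                    (z - s$center[3])^2, "+") <= s$radius^2
    vals[inside] <- pmax(vals[inside], s$value)
  }
  suv_map(vals, spacing, origin_mm = spacing / 2)
}
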