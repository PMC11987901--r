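# Independent brute-force oracles used by the unit and acceptance tests.
# Everything here is written with plain loops, deliberately avoiding the
# package's vectorized implementations.

# random discretized ROI on a grid of up to 8^3 voxels
random_roi <- function(seed, max_dim = 8, n_levels = 4) {
  set.seed(seed)
  dims <- sample(2:max_dim, 3, replace = TRUE)
  vals <- array(runif(prod(dims)), dims)
  mask <- array(runif(prod(dims)) < 0.6, dims)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  list(values = vals, mask = mask, dims = dims, n_levels = n_levels)
}

# all 26 neighbor offsets, plain enumeration
oracle_offsets <- function() {
  out <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (!(dx == 0 && dy == 0 && dz == 0))
      out <- rbind(out, c(dx, dy, dz))
  out
}

in_grid <- function(p, dims) {
  all(p >= 1) && all(p <= dims)
}

# brute-force merged symmetric GLCM counts over all voxel pairs at
# Chebyshev distance 1 (all 26 directed offsets = symmetrized 13)
oracle_glcm_counts <- function(levels, mask, ng) {
  dims <- dim(levels)
  offs <- oracle_offsets()
  counts <- matrix(0, ng, ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    a <- levels[x, y, z]
    for (r in 1:nrow(offs)) {
      q <- c(x, y, z) + offs[r, ]
      if (!in_grid(q, dims)) next
      if (!mask[q[1], q[2], q[3]]) next
      b <- levels[q[1], q[2], q[3]]
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts
}

# brute-force Chebyshev distance of every masked voxel to the border
# (outside-of-mask voxels and the region beyond the grid both count as
# border at distance 0; a masked voxel touching them has distance 1)
oracle_distance_map <- function(mask) {
  dims <- dim(mask)
  dmap <- array(NA_integer_, dims)
  outside <- which(!mask, arr.ind = TRUE)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    d <- min(x, y, z, dims[1] - x + 1, dims[2] - y + 1, dims[3] - z + 1)
    if (nrow(outside) > 0) {
      cheb <- pmax(abs(outside[, 1] - x),
                   pmax(abs(outside[, 2] - y), abs(outside[, 3] - z)))
      d <- min(d, min(cheb))
    }
    dmap[x, y, z] <- d
  }
  dmap
}

# queue-based flood fill of 26-connected equal-level zones
oracle_zones <- function(levels, mask) {
  dims <- dim(levels)
  seen <- array(FALSE, dims)
  offs <- oracle_offsets()
  zones <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z] || seen[x, y, z]) next
    g <- levels[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    members <- NULL
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- rbind(members, p)
      for (r in 1:nrow(offs)) {
        q <- p + offs[r, ]
        if (!in_grid(q, dims)) next
        if (seen[q[1], q[2], q[3]]) next
        if (!mask[q[1], q[2], q[3]]) next
        if (levels[q[1], q[2], q[3]] != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- list(level = g, members = members)
  }
  zones
}

# brute-force GLDZM: zone count matrix m(level, min zone distance)
oracle_gldzm <- function(levels, mask, ng) {
  dmap <- oracle_distance_map(mask)
  zones <- oracle_zones(levels, mask)
  maxd <- 0
  rows <- NULL
  for (zn in zones) {
    dmin <- Inf
    for (r in 1:nrow(zn$members)) {
      p <- zn$members[r, ]
      dmin <- min(dmin, dmap[p[1], p[2], p[3]])
    }
    rows <- rbind(rows, c(zn$level, dmin))
    maxd <- max(maxd, dmin)
  }
  m <- matrix(0, ng, maxd)
  for (r in 1:nrow(rows)) m[rows[r, 1], rows[r, 2]] <-
      m[rows[r, 1], rows[r, 2]] + 1
  m
}

# brute-force NGLDM: voxel count matrix s(level, dependence k)
oracle_ngldm <- function(levels, mask, ng) {
  dims <- dim(levels)
  offs <- oracle_offsets()
  recs <- NULL
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    g <- levels[x, y, z]
    k <- 1
    for (r in 1:nrow(offs)) {
      q <- c(x, y, z) + offs[r, ]
      if (!in_grid(q, dims)) next
      if (!mask[q[1], q[2], q[3]]) next
      if (levels[q[1], q[2], q[3]] == g) k <- k + 1
    }
    recs <- rbind(recs, c(g, k))
  }
  m <- matrix(0, ng, max(recs[, 2]))
  for (r in 1:nrow(recs)) m[recs[r, 1], recs[r, 2]] <-
      m[recs[r, 1], recs[r, 2]] + 1
  m
}

# exhaustive Mann-Whitney pair counting on raw score vectors
oracle_mann_whitney <- function(pos, neg) {
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# build a discretized_roi-compatible object through the public API
make_droi <- function(values, mask, n_levels) {
  v <- pcrpet::pet_volume(values)
  pcrpet::discretize(v, mask, scheme = "fbn", parameter = n_levels)
}

# small cohort used by several tests (cached per session)
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- pcrpet::generate_cohort(pcrpet::cohort_spec(seed = 1))
    cache
  }
})
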