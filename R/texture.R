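# the 13 unique direction offsets at Chebyshev distance 1 in 3D
direction_offsets_13 <- function() {
  offs <- neighbor_offsets_26()
  # keep one of each +/- pair: lexicographically positive
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs[keep, , drop = FALSE]
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Co-occurrence counts of gray-level pairs at the 13 unique 3D direction
#' offsets at distance 1, symmetrized and merged into a single matrix
#' before normalization (the IBSI "merged" aggregation).
#'
#' @param d A [discretize()]d region.
#' @return Named list of features.
#' @export
#' @examples
#' v <- pet_volume(array(c(1, 3, rep(1, 6)), c(2, 2, 2)))
#' m <- array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2))
#' glcm_features(discretize(v, m, "fbn", 3))$glcm_contrast  # 4
glcm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  ng <- max(d$levels, na.rm = TRUE)
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(direction_offsets_13()))) {
    off <- direction_offsets_13()[r, ]
    nb <- shift3(d$levels, off, fill = NA_integer_)
    ok <- !is.na(d$levels) & !is.na(nb)
    if (!any(ok)) next
    a <- d$levels[ok]; b <- nb[ok]
    tab <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts <- counts + t(counts)  # symmetrize
  if (sum(counts) == 0) {
    warn("single-voxel region: co-occurrence matrix is empty")
    return(glcm_from_p(matrix(0, 1, 1), degenerate = TRUE))
  }
  glcm_from_p(counts / sum(counts))
}

glcm_from_p <- function(p, degenerate = FALSE) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_m <- rowSums(p)
  mu_i <- sum(i * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p))
  corr <- if (!degenerate && sd_i > 0)
    sum((i - mu_i) * (j - mu_i) * p) / sd_i^2 else 1
  ent <- { occ <- p > 0; if (any(occ)) -sum(p[occ] * log2(p[occ])) else 0 }
  list(
    glcm_contrast = sum(p * (i - j)^2),
    glcm_dissimilarity = sum(p * abs(i - j)),
    glcm_inverse_difference = sum(p / (1 + abs(i - j))),
    glcm_inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    glcm_joint_energy = sum(p^2),
    glcm_joint_entropy = ent,
    glcm_joint_maximum = if (degenerate) 1 else max(p),
    glcm_correlation = corr,
    glcm_sum_average = sum((i + j) * p),
    glcm_cluster_tendency = sum((i + j - 2 * mu_i)^2 * p)
  )
}

# Chebyshev distance map to the region border: border voxels (any
# 26-neighbor outside the mask, with voxels beyond the grid counting as
# outside) have distance 1; computed by iterated 26-erosion
distance_map_cheb <- function(mask) {
  dmap <- array(0L, dim(mask))
  current <- mask
  d <- 0L
  offs <- neighbor_offsets_26()
  while (any(current)) {
    d <- d + 1L
    ero <- current
    for (r in seq_len(nrow(offs)))
      ero <- ero & shift3(current, offs[r, ], fill = FALSE)
    dmap[current & !ero] <- d
    current <- ero
  }
  dmap
}

# gray-level distance-zone matrix: rows = gray level, cols = zone distance
gldzm_matrix <- function(d) {
  dmap <- distance_map_cheb(d$mask)
  ng <- max(d$levels, na.rm = TRUE)
  zones <- list()
  for (g in sort(unique(d$levels[d$mask]))) {
    labs <- label_components_26(!is.na(d$levels) & d$levels == g)
    for (z in seq_len(max(labs))) {
      zd <- min(dmap[labs == z])
      zones[[length(zones) + 1L]] <- c(g, zd)
    }
  }
  zz <- do.call(rbind, zones)
  maxd <- max(zz[, 2])
  m <- matrix(0, ng, maxd)
  for (r in seq_len(nrow(zz))) m[zz[r, 1], zz[r, 2]] <-
      m[zz[r, 1], zz[r, 2]] + 1
  m
}

#' Gray-level distance-zone (GLDZM) features
#'
#' Zones are 26-connected components of equal gray level; the zone
#' distance is the minimum over the zone's voxels of the Chebyshev step
#' count to the region border (border voxels have distance 1). Features
#' are the standard emphasis sums over the zone-count matrix `m(i, d)`
#' divided by the number of zones.
#'
#' @param d A [discretize()]d region.
#' @return Named list of features.
#' @export
gldzm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  m <- gldzm_matrix(d)
  nz <- sum(m)
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  dd <- t(matrix(seq_len(ncol(m)), ncol(m), nrow(m)))
  list(
    gldzm_small_distance_emphasis = sum(m / dd^2) / nz,
    gldzm_large_distance_emphasis = sum(m * dd^2) / nz,
    gldzm_low_gray_level_zone_emphasis = sum(m / i^2) / nz,
    gldzm_high_gray_level_zone_emphasis = sum(m * i^2) / nz,
    gldzm_small_distance_low_gray_level_emphasis =
      sum(m / (i^2 * dd^2)) / nz,
    gldzm_small_distance_high_gray_level_emphasis =
      sum(m * i^2 / dd^2) / nz,
    gldzm_large_distance_low_gray_level_emphasis =
      sum(m * dd^2 / i^2) / nz,
    gldzm_large_distance_high_gray_level_emphasis =
      sum(m * i^2 * dd^2) / nz,
    gldzm_zone_percentage = nz / sum(d$mask),
    gldzm_gray_level_nonuniformity = sum(rowSums(m)^2) / nz
  )
}

# neighboring gray-level dependence matrix: rows = gray level,
# cols = dependence count k (1 + same-level 26-neighbors in the mask)
ngldm_matrix <- function(d) {
  offs <- neighbor_offsets_26()
  cnt <- array(0L, dim(d$mask))
  for (r in seq_len(nrow(offs))) {
    nb <- shift3(d$levels, offs[r, ], fill = NA_integer_)
    same <- !is.na(d$levels) & !is.na(nb) & d$levels == nb
    cnt <- cnt + same
  }
  k <- cnt[d$mask] + 1L
  g <- d$levels[d$mask]
  ng <- max(g)
  maxk <- max(k)
  m <- matrix(0, ng, maxk)
  for (r in seq_along(k)) m[g[r], k[r]] <- m[g[r], k[r]] + 1
  m
}

#' Neighboring gray-level dependence (NGLDM) features
#'
#' For every masked voxel the dependence count is 1 plus the number of
#' its 26-neighbors inside the mask with an identical gray level
#' (coarseness 0). Features are emphasis sums over the voxel-count
#' matrix `s(i, k)` divided by the number of voxels.
#'
#' @param d A [discretize()]d region.
#' @return Named list of features.
#' @export
ngldm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  m <- ngldm_matrix(d)
  nv <- sum(m)
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  k <- t(matrix(seq_len(ncol(m)), ncol(m), nrow(m)))
  p <- m / nv
  occ <- p > 0
  list(
    ngldm_low_dependence_emphasis = sum(m / k^2) / nv,
    ngldm_high_dependence_emphasis = sum(m * k^2) / nv,
    ngldm_low_gray_level_count_emphasis = sum(m / i^2) / nv,
    ngldm_high_gray_level_count_emphasis = sum(m * i^2) / nv,
    ngldm_low_dependence_low_gray_level_emphasis =
      sum(m / (i^2 * k^2)) / nv,
    ngldm_low_dependence_high_gray_level_emphasis =
      sum(m * i^2 / k^2) / nv,
    ngldm_high_dependence_low_gray_level_emphasis =
      sum(m * k^2 / i^2) / nv,
    ngldm_high_dependence_high_gray_level_emphasis =
      sum(m * i^2 * k^2) / nv,
    ngldm_dependence_count_entropy = -sum(p[occ] * log2(p[occ]))
  )
}
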