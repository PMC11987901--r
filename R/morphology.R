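# --- surface mesh via marching tetrahedra --------------------------------
#
# The mask is treated as a scalar field on voxel centers (1 inside, 0
# outside, zero-padded), optionally smoothed by a narrow Gaussian before
# extracting the 0.5 iso-surface. Each cell between 8 voxel centers is
# split into 6 tetrahedra; iso-surface vertices are linearly interpolated
# along tetrahedron edges. Triangles are oriented outward by comparing
# each normal with the above/below centroid direction, so the enclosed
# volume follows from the divergence theorem.

# unit-cube corner offsets, column order x, y, z
.cube_corners <- matrix(c(
  0, 0, 0,  1, 0, 0,  0, 1, 0,  1, 1, 0,
  0, 0, 1,  1, 0, 1,  0, 1, 1,  1, 1, 1
), ncol = 3, byrow = TRUE)

# 6-tetrahedra decomposition of the cube (indices into .cube_corners)
.cube_tets <- matrix(c(
  1, 2, 4, 8,
  1, 2, 6, 8,
  1, 5, 6, 8,
  1, 5, 7, 8,
  1, 3, 7, 8,
  1, 3, 4, 8
), ncol = 4, byrow = TRUE)

# triangles for one batch of tetrahedra; F: n x 4 field values,
# P: list of 4 (n x 3) corner coordinate matrices. Returns list of
# triangle vertex matrices (each n_tri x 9: p1, p2, p3) oriented outward
# (away from the above-iso side).
tet_triangles <- function(F, P, iso = 0.5) {
  above <- F > iso
  nab <- rowSums(above)
  tris <- list()
  interp <- function(i, j, rows) {
    t <- (iso - F[rows, i]) / (F[rows, j] - F[rows, i])
    P[[i]][rows, , drop = FALSE] +
      t * (P[[j]][rows, , drop = FALSE] - P[[i]][rows, , drop = FALSE])
  }
  orient <- function(p1, p2, p3, inward_pt) {
    # flip triangles whose normal points toward the above-iso (inside) side
    n <- cross3(p2 - p1, p3 - p1)
    s <- rowSums(n * (inward_pt - p1))  # > 0: normal points inward
    flip <- s > 0
    tmp <- p2[flip, , drop = FALSE]
    p2[flip, ] <- p3[flip, , drop = FALSE]
    p3[flip, ] <- tmp
    cbind(p1, p2, p3)
  }
  for (cnt in c(1L, 3L)) {
    rows <- which(nab == cnt)
    if (!length(rows)) next
    for (v in 1:4) {
      # rows where vertex v is the lone vertex on the minority side
      lone <- if (cnt == 1L) above[rows, v] & nab[rows] == 1L else
        !above[rows, v] & nab[rows] == 3L
      rr <- rows[lone]
      if (!length(rr)) next
      others <- setdiff(1:4, v)
      p1 <- interp(v, others[1], rr)
      p2 <- interp(v, others[2], rr)
      p3 <- interp(v, others[3], rr)
      # centroid of the above-iso vertices as the inward reference
      inward <- above_centroid(F, P, rr, iso)
      tris[[length(tris) + 1L]] <- orient(p1, p2, p3, inward)
    }
  }
  rows2 <- which(nab == 2L)
  if (length(rows2)) {
    pairs <- utils::combn(4, 2)
    for (pi in seq_len(ncol(pairs))) {
      a <- pairs[1, pi]; b <- pairs[2, pi]
      rr <- rows2[above[rows2, a] & above[rows2, b]]
      if (!length(rr)) next
      cd <- setdiff(1:4, c(a, b))
      q1 <- interp(a, cd[1], rr)
      q2 <- interp(a, cd[2], rr)
      q3 <- interp(b, cd[2], rr)
      q4 <- interp(b, cd[1], rr)
      inward <- above_centroid(F, P, rr, iso)
      tris[[length(tris) + 1L]] <- orient(q1, q2, q3, inward)
      tris[[length(tris) + 1L]] <- orient(q1, q3, q4, inward)
    }
  }
  tris
}

above_centroid <- function(F, P, rows, iso) {
  w <- (F[rows, , drop = FALSE] > iso) * 1
  num <- matrix(0, length(rows), 3)
  for (v in 1:4) num <- num + w[, v] * P[[v]][rows, , drop = FALSE]
  num / rowSums(w)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Triangulated iso-surface of a binary mask
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm.
#' @param smooth_sigma Gaussian pre-smoothing of the binary field, in
#'   voxels; 0 extracts the raw binary surface. A narrow smoothing (the
#'   default, 0.9 voxels) removes voxelization staircase bias from area
#'   estimates of smooth objects.
#' @return A list with `area` (mm^2), `volume` (mm^3, via the divergence
#'   theorem) and `n_triangles`.
#' @export
mask_mesh <- function(mask, spacing = c(1, 1, 1), smooth_sigma = 0.9) {
  d <- dim(mask)
  pad <- 3L
  f <- array(0, d + 2L * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  if (smooth_sigma > 0) f <- blur3d(f, smooth_sigma)
  dp <- dim(f)
  # surface cells: any corner difference across the iso level
  inside <- f > 0.5
  cell_mixed <- array(FALSE, dp - 1L)
  agg <- array(0L, dp - 1L)
  for (v in 1:8) {
    o <- .cube_corners[v, ]
    agg <- agg + inside[o[1] + seq_len(dp[1] - 1), o[2] + seq_len(dp[2] - 1),
                        o[3] + seq_len(dp[3] - 1)]
  }
  cells <- which(agg > 0L & agg < 8L)
  if (!length(cells))
    return(list(area = 0, volume = 0, n_triangles = 0L))
  base <- arrayInd(cells, dp - 1L)  # lower corner voxel index
  corner_f <- sapply(1:8, function(v) {
    o <- .cube_corners[v, ]
    f[cbind(base[, 1] + o[1], base[, 2] + o[2], base[, 3] + o[3])]
  })
  # physical coordinates of corners (voxel centers), mm
  sp <- spacing
  corner_p <- lapply(1:8, function(v) {
    o <- .cube_corners[v, ]
    cbind((base[, 1] + o[1] - pad - 1) * sp[1],
          (base[, 2] + o[2] - pad - 1) * sp[2],
          (base[, 3] + o[3] - pad - 1) * sp[3])
  })
  area <- 0; vol <- 0; ntri <- 0L
  for (t in seq_len(nrow(.cube_tets))) {
    vids <- .cube_tets[t, ]
    Ft <- corner_f[, vids, drop = FALSE]
    Pt <- corner_p[vids]
    tris <- tet_triangles(Ft, Pt)
    for (tr in tris) {
      p1 <- tr[, 1:3, drop = FALSE]
      p2 <- tr[, 4:6, drop = FALSE]
      p3 <- tr[, 7:9, drop = FALSE]
      cr <- cross3(p2 - p1, p3 - p1)
      a <- 0.5 * sqrt(rowSums(cr^2))
      area <- area + sum(a)
      # signed volume of (origin, p1, p2, p3); outward normals sum to +V
      vol <- vol + sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
                         p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
                         p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
      ntri <- ntri + nrow(tr)
    }
  }
  list(area = area, volume = abs(vol), n_triangles = ntri)
}

# exposed voxel-face surface area and voxel volume
voxel_surface <- function(mask, spacing) {
  d <- dim(mask)
  area <- 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  for (ax in 1:3) {
    pad_dim <- d; pad_dim[ax] <- d[ax] + 2L
    p <- array(FALSE, pad_dim)
    idx <- lapply(seq_len(3), function(a)
      if (a == ax) 1L + seq_len(d[a]) else seq_len(d[a]))
    p[idx[[1]], idx[[2]], idx[[3]]] <- mask
    n_lo <- slice_shift(p, ax, 1L)
    n_hi <- slice_shift(p, ax, -1L)
    inner <- p[idx[[1]], idx[[2]], idx[[3]]]
    area <- area + sum(inner & !n_lo[idx[[1]], idx[[2]], idx[[3]]]) * face[ax]
    area <- area + sum(inner & !n_hi[idx[[1]], idx[[2]], idx[[3]]]) * face[ax]
  }
  list(area = area, volume = sum(mask) * prod(spacing))
}

# shift an array by `by` along axis `ax` (fill FALSE/NA)
slice_shift <- function(arr, ax, by, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) {
    dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by)
  } else if (by < 0) {
    dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# general 3D shift by integer offset vector
shift3 <- function(arr, off, fill = NA) {
  for (ax in 1:3) if (off[ax] != 0)
    arr <- slice_shift(arr, ax, off[ax], fill = fill)
  arr
}

#' Morphological (size and shape) features of a tumor mask
#'
#' Sphericity is `(36 pi V^2)^(1/3) / A` with `V` the enclosed volume and
#' `A` the surface area; with `surface = "mesh"` both come from a
#' marching-tetrahedra iso-surface, with `"voxel"` from exposed voxel
#' faces and the voxel count.
#'
#' @param mask A `tumor_mask` or logical array.
#' @param spacing Voxel spacing, mm.
#' @param surface `"mesh"` (default) or `"voxel"`.
#' @param smooth_sigma Mesh pre-smoothing, voxels (see [mask_mesh()]).
#' @return Named list of features (volumes mm^3, areas mm^2, lengths mm).
#' @export
morphology_features <- function(mask, spacing = c(1, 1, 1),
                                surface = c("mesh", "voxel"),
                                smooth_sigma = 0.9) {
  surface <- match.arg(surface)
  flags <- if (inherits(mask, "tumor_mask")) mask$flags else mask
  n <- sum(flags)
  assert_that(n > 0, "empty mask")
  if (surface == "mesh" && n > 1) {
    ms <- mask_mesh(flags, spacing, smooth_sigma)
    A <- ms$area; V <- ms$volume
  } else {
    vs <- voxel_surface(flags, spacing)
    A <- vs$area; V <- vs$volume
  }
  v_vox <- n * prod(spacing)
  sph <- (36 * pi * V^2)^(1 / 3) / A
  # principal-axis lengths from the voxel-center covariance
  idx <- arrayInd(which(flags), dim(flags))
  xyz <- sweep(idx, 2, c(1, 1, 1)) %*% diag(spacing)
  if (n > 3) {
    ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- rep(0, 3)
  axis_len <- 4 * sqrt(ev)
  # max 3D diameter over boundary voxel centers (deterministic subsample
  # when the boundary is very large)
  bnd <- boundary_voxels(flags)
  bxyz <- sweep(arrayInd(which(bnd), dim(flags)), 2, c(1, 1, 1)) %*%
    diag(spacing)
  if (nrow(bxyz) > 2000)
    bxyz <- bxyz[unique(round(seq(1, nrow(bxyz), length.out = 2000))), ,
                 drop = FALSE]
  maxdiam <- if (nrow(bxyz) >= 2) {
    g <- tcrossprod(bxyz)
    sq <- diag(g)
    sqrt(max(outer(sq, sq, `+`) - 2 * g)) + 0  # distances between centers
  } else 0
  list(
    morphological_volume = V,
    morphological_volume_voxel = v_vox,
    morphological_surface_area = A,
    morphological_sphericity = sph,
    morphological_surface_to_volume_ratio = A / V,
    morphological_compactness1 = V / (sqrt(pi) * A^1.5),
    morphological_compactness2 = 36 * pi * V^2 / A^3,
    morphological_spherical_disproportion = 1 / sph,
    morphological_asphericity = (A^3 / (36 * pi * V^2))^(1 / 3) - 1,
    morphological_max_3d_diameter = maxdiam,
    morphological_major_axis_length = axis_len[1],
    morphological_minor_axis_length = axis_len[2],
    morphological_least_axis_length = axis_len[3],
    morphological_elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    morphological_flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}

# voxels of the mask with at least one 26-neighbor outside the mask
# (voxels beyond the grid count as outside)
boundary_voxels <- function(mask) {
  all_in <- array(TRUE, dim(mask))
  for (o in seq_len(26)) {
    off <- neighbor_offsets_26()[o, ]
    all_in <- all_in & shift3(mask, -off, fill = FALSE)
  }
  mask & !all_in
}
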