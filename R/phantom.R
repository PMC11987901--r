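#' Specification of a synthetic PET tumor phantom
#'
#' Describes an ellipsoidal high-uptake lesion on a low-uptake background:
#' the digital substrate on which segmentation and radiomic extraction are
#' exercised. Inside the ellipsoid the uptake equals `peak_uptake`,
#' multiplicatively modulated by a smooth random texture field of relative
#' amplitude `heterogeneity_scale`; Gaussian noise of `noise_sd` SUV units
#' is added everywhere and the result clipped at zero.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_spacing Numeric length-3, mm per axis.
#' @param tumor_center Numeric length-3, 1-based voxel coordinates.
#' @param tumor_radii Numeric length-3, ellipsoid semi-axes in mm.
#' @param peak_uptake Tumor uptake in SUV units (> background).
#' @param background_uptake Background uptake in SUV units (>= 0).
#' @param heterogeneity_scale Relative amplitude of the smooth texture
#'   field (0 = homogeneous tumor).
#' @param heterogeneity_width Gaussian filter width of the texture field,
#'   in voxels.
#' @param noise_sd Additive Gaussian noise, SUV units.
#' @param seed Integer seed; identical seeds give bit-identical volumes.
#' @return A `phantom_spec` object.
#' @export
#' @examples
#' spec <- phantom_spec(tumor_radii = c(10, 10, 10), seed = 1)
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_spacing = c(2, 2, 2),
                         tumor_center = (grid_shape + 1) / 2,
                         tumor_radii = c(12, 10, 8),
                         peak_uptake = 10,
                         background_uptake = 0.5,
                         heterogeneity_scale = 0,
                         heterogeneity_width = 2,
                         noise_sd = 0,
                         seed = 1L) {
  assert_that(peak_uptake > background_uptake && background_uptake >= 0,
              "need peak_uptake > background_uptake >= 0")
  assert_that(all(tumor_radii > 0), "all tumor radii must be > 0")
  lo <- tumor_center - tumor_radii / voxel_spacing
  hi <- tumor_center + tumor_radii / voxel_spacing
  if (any(lo < 1) || any(hi > grid_shape))
    abort(paste0("tumor does not fit in the grid: extent [",
                 paste(signif(lo, 3), collapse = ","), "] to [",
                 paste(signif(hi, 3), collapse = ","), "] vs grid ",
                 paste(grid_shape, collapse = "x")))
  structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_spacing = as.numeric(voxel_spacing),
         tumor_center = as.numeric(tumor_center),
         tumor_radii = as.numeric(tumor_radii),
         peak_uptake = peak_uptake,
         background_uptake = background_uptake,
         heterogeneity_scale = heterogeneity_scale,
         heterogeneity_width = heterogeneity_width,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# separable Gaussian blur of a 3D array, sigma in voxels
blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_dim1 <- function(a) {
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    # band matrix with edge-renormalized truncated kernels
    band <- matrix(0, d[1], d[1])
    for (i in seq_len(d[1])) {
      idx <- (i - r):(i + r)
      ok <- idx >= 1 & idx <= d[1]
      band[i, idx[ok]] <- k[ok] / sum(k[ok])
    }
    array(band %*% m, d)
  }
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    arr <- aperm(conv_dim1(aperm(arr, perm)), order(perm))
  }
  arr
}

#' Generate a synthetic PET phantom volume
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [pet_volume()]), `tumor_mask` (logical
#'   array: true ellipsoid extent by voxel-center membership), and `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0, seed = 7))
#' max(ph$volume$values)  # peak uptake
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  ax <- lapply(1:3, function(a)
    (seq_len(d[a]) - spec$tumor_center[a]) * spec$voxel_spacing[a] /
      spec$tumor_radii[a])
  # squared normalized ellipsoid radius at voxel centers
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  inside <- r2 <= 1
  vol <- array(spec$background_uptake, d)
  vol[inside] <- spec$peak_uptake
  with_seed(spec$seed, {
    if (spec$heterogeneity_scale > 0) {
      field <- blur3d(array(rnorm(prod(d)), d), spec$heterogeneity_width)
      field <- field / sd(field)
      vol[inside] <- vol[inside] * (1 + spec$heterogeneity_scale *
                                      field[inside])
    }
    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(prod(d), sd = spec$noise_sd), d)
  })
  vol[vol < 0] <- 0
  list(volume = pet_volume(vol, spacing = spec$voxel_spacing),
       tumor_mask = inside, spec = spec)
}
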