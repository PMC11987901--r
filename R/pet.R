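#' PET volume container
#'
#' A minimal 3D standardized-uptake-value (SUV) grid with physical voxel
#' spacing. SUV is the tissue tracer concentration normalized by injected
#' dose per body weight (g/mL by convention, treated as unitless).
#' Physical coordinates follow voxel centers: `physical = origin +
#' (index - 1) * spacing` for 1-based voxel indices.
#'
#' @param values 3D numeric array of SUV, all values >= 0.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, physical offset in mm of voxel (1,1,1).
#' @return A `pet_volume` object.
#' @export
#' @examples
#' vol <- pet_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
pet_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  assert_that(is.array(values) && length(dim(values)) == 3L,
              "`values` must be a 3D array")
  assert_that(all(values >= 0, na.rm = TRUE), "SUV values must be >= 0")
  assert_that(length(spacing) == 3L && all(spacing > 0),
              "`spacing` must be 3 positive numbers (mm)")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 3), collapse = "x"),
      " mm; SUV range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$values)

#' Convert an activity-concentration grid to standardized uptake values
#'
#' SUV = tracer concentration (kBq/mL) / (injected activity (kBq) /
#' body weight (g)).
#'
#' @param activity 3D array of tracer concentration in kBq/mL.
#' @param injected_activity Injected activity in kBq (> 0).
#' @param body_weight Patient body weight in g (> 0).
#' @inheritParams pet_volume
#' @return A [pet_volume()].
#' @export
#' @examples
#' v <- to_suv(array(5, c(2, 2, 2)), injected_activity = 350000,
#'             body_weight = 70000)
#' max(v$values)  # 1
to_suv <- function(activity, injected_activity, body_weight,
                   spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  assert_that(is_scalar_number(injected_activity) && injected_activity > 0,
              "`injected_activity` must be a positive number (kBq)")
  assert_that(is_scalar_number(body_weight) && body_weight > 0,
              "`body_weight` must be a positive number (g)")
  pet_volume(activity / (injected_activity / body_weight),
             spacing = spacing, origin = origin)
}

# 26-connectivity neighbor offsets (3D Moore neighborhood)
neighbor_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

# flood fill the 26-connected component of `mask` containing voxel `seed`
# (matrix row c(i,j,k), 1-based); returns a logical array
flood_component <- function(mask, seed) {
  dims <- dim(mask)
  lin <- function(m) (m[, 1] - 1L) + dims[1] * (m[, 2] - 1L) +
    dims[1] * dims[2] * (m[, 3] - 1L) + 1L
  offs <- neighbor_offsets_26()
  comp <- array(FALSE, dims)
  frontier <- matrix(as.integer(seed), ncol = 3)
  comp[lin(frontier)] <- TRUE
  while (nrow(frontier) > 0) {
    # expand frontier by all 26 offsets at once
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                     drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    li <- lin(cand)
    new <- mask[li] & !comp[li]
    li_new <- unique(li[new])
    if (length(li_new) == 0) break
    comp[li_new] <- TRUE
    frontier <- arrayInd(li_new, dims)
  }
  comp
}

# label all 26-connected components of a logical array; returns integer array
# with 0 = background
label_components_26 <- function(mask) {
  labels <- array(0L, dim(mask))
  remaining <- which(mask)
  lab <- 0L
  while (length(remaining) > 0) {
    lab <- lab + 1L
    seed <- arrayInd(remaining[1], dim(mask))
    comp <- flood_component(mask, seed)
    labels[comp] <- lab
    remaining <- which(mask & labels == 0L)
  }
  labels
}

#' Segment a tumor by a fixed fraction of SUVmax
#'
#' Implements fixed-threshold 3D segmentation: within a region of interest,
#' the threshold is `fraction` times the maximum SUV, and the mask is the
#' 26-connected component of voxels at or above the threshold that contains
#' the maximum voxel. The default 42% fraction is the conventional
#' fixed-fraction setting for FDG-avid breast tumors.
#'
#' @param volume A [pet_volume()].
#' @param roi Optional bounding box, a list with `lower` and `upper`
#'   1-based voxel index triplets (inclusive). Default: the whole grid.
#' @param fraction Threshold as a fraction of the ROI SUVmax, in (0, 1).
#' @return A `tumor_mask`: list with logical array `flags` (same shape as
#'   the volume), `seed_point` (voxel index of the ROI maximum),
#'   `threshold`, and `fraction`.
#' @export
#' @examples
#' v <- pet_volume(array(c(10, rep(0, 26)), c(3, 3, 3)))
#' m <- segment_fixed_fraction(v)
#' sum(m$flags)  # 1
segment_fixed_fraction <- function(volume, roi = NULL, fraction = 0.42) {
  stopifnot(inherits(volume, "pet_volume"))
  assert_that(is_scalar_number(fraction) && fraction > 0 && fraction < 1,
              "`fraction` must be in (0, 1)")
  dims <- dim(volume$values)
  if (is.null(roi)) roi <- list(lower = c(1L, 1L, 1L), upper = dims)
  lo <- pmax(as.integer(roi$lower), 1L)
  hi <- pmin(as.integer(roi$upper), dims)
  assert_that(all(lo <= hi), "ROI bounding box is empty")
  in_roi <- array(FALSE, dims)
  in_roi[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  vmax <- max(volume$values[in_roi])
  if (vmax <= 0) abort("ROI contains no signal (all SUV zero)")
  threshold <- fraction * vmax
  above <- in_roi & volume$values >= threshold
  seed <- arrayInd(which(in_roi & volume$values == vmax)[1], dims)
  flags <- flood_component(above, seed)
  structure(
    list(flags = flags, seed_point = as.integer(seed),
         threshold = threshold, fraction = fraction),
    class = "tumor_mask"
  )
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat("<tumor_mask> ", sum(x$flags), " voxels; threshold ",
      signif(x$threshold, 4), " (", x$fraction * 100, "% of SUVmax)\n",
      sep = "")
  invisible(x)
}

#' Basic PET metrics over a segmented tumor
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask` (or logical array) aligned to `volume`.
#' @return A one-row tibble with `suv_max`, `suv_mean`, `mtv_cm3`
#'   (metabolic tumor volume) and `voxel_count`.
#' @export
basic_metrics <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"))
  flags <- if (inherits(mask, "tumor_mask")) mask$flags else mask
  assert_that(identical(dim(flags), dim(volume$values)),
              "mask and volume shapes differ")
  n <- sum(flags)
  if (n == 0) abort("empty mask")
  vox_mm3 <- prod(volume$spacing)
  vals <- volume$values[flags]
  tibble(
    suv_max = max(vals),
    suv_mean = mean(vals),
    mtv_cm3 = n * vox_mm3 / 1000,
    voxel_count = n
  )
}

#' Read / write PET volumes and masks as NIfTI
#'
#' Thin wrappers around RNifti preserving voxel spacing.
#'
#' @param volume A [pet_volume()]; `path` a file path ending in `.nii` or
#'   `.nii.gz`.
#' @return `write_pet_nifti()` returns `path` invisibly;
#'   `read_pet_nifti()` returns a [pet_volume()].
#' @export
write_pet_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_pet_nifti
#' @param path File path of a NIfTI volume.
#' @export
read_pet_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pet_volume(array(as.numeric(img), dim(img)),
             spacing = RNifti::pixdim(img)[seq_len(3)])
}
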