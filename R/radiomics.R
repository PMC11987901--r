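#' Extract an IBSI-style radiomic feature set from a segmented volume
#'
#' Computes a representative panel of radiomic features spanning the four
#' families (size, shape, intensity, texture), always including the six
#' features used in the final multimodal model: morphological sphericity,
#' intensity skewness, discretized intensity uniformity, GLCM contrast,
#' GLDZM large distance low gray-level emphasis and NGLDM low dependence
#' low gray-level emphasis.
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask` or logical array.
#' @param scheme,parameter Discretization settings (see [discretize()]).
#' @param surface,smooth_sigma Surface settings (see
#'   [morphology_features()]).
#' @return A `radiomic_features` tibble with columns `feature`, `value`,
#'   `family`; discretization metadata is attached as attributes.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 3, noise_sd = 0.1,
#'                                     heterogeneity_scale = 0.2))
#' m <- segment_fixed_fraction(ph$volume)
#' fs <- extract_features(ph$volume, m, parameter = 16)
#' dplyr::count(fs, family)
extract_features <- function(volume, mask, scheme = "fbn", parameter = 64,
                             surface = "mesh", smooth_sigma = 0.9) {
  flags <- if (inherits(mask, "tumor_mask")) mask$flags else mask
  d <- discretize(volume, flags, scheme, parameter)
  vals <- c(
    morphology_features(flags, volume$spacing, surface, smooth_sigma),
    intensity_features(volume, flags),
    histogram_features(d),
    glcm_features(d),
    gldzm_features(d),
    ngldm_features(d)
  )
  out <- tibble(
    feature = names(vals),
    value = unname(unlist(vals)),
    family = feature_family(names(vals))
  )
  attr(out, "discretization") <- list(scheme = d$scheme,
                                      parameter = d$parameter,
                                      n_levels = d$n_levels)
  class(out) <- c("radiomic_features", class(out))
  out
}

feature_family <- function(nm) {
  size_feats <- c("morphological_volume", "morphological_volume_voxel",
                  "morphological_surface_area",
                  "morphological_max_3d_diameter",
                  "morphological_major_axis_length",
                  "morphological_minor_axis_length",
                  "morphological_least_axis_length")
  dplyr::case_when(
    nm %in% size_feats ~ "size",
    startsWith(nm, "morphological_") ~ "shape",
    startsWith(nm, "intensity_") ~ "intensity",
    startsWith(nm, "discretized_") ~ "intensity",
    TRUE ~ "texture"
  )
}

#' The six radiomic features retained in the final multimodal model
#' @return Character vector of feature names.
#' @export
selected_radiomic_features <- function() {
  c("morphological_sphericity", "intensity_skewness",
    "discretized_intensity_uniformity", "glcm_contrast",
    "gldzm_large_distance_low_gray_level_emphasis",
    "ngldm_low_dependence_low_gray_level_emphasis")
}
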