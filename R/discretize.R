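#' Discretize SUV intensities inside a tumor mask
#'
#' Texture and histogram features operate on gray levels, not raw SUV.
#' Two IBSI schemes are supported:
#' * fixed bin number (`"fbn"`): `level = 1 + floor(N_g (x - min) /
#'   (max - min))`, capped at `N_g`; a constant region maps to level 1.
#' * fixed bin size (`"fbs"`): `level = 1 + floor((x - min) / width)`.
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask` or logical array.
#' @param scheme `"fbn"` (fixed bin number, the default) or `"fbs"`
#'   (fixed bin size).
#' @param parameter Bin count (fbn) or bin width in SUV (fbs); > 0.
#' @return A `discretized_roi`: integer `levels` array (NA outside the
#'   mask), logical `mask`, `n_levels`, `scheme`, `parameter`, `spacing`.
#' @export
#' @examples
#' v <- pet_volume(array(runif(27), c(3, 3, 3)))
#' d <- discretize(v, array(TRUE, c(3, 3, 3)), "fbn", 8)
#' range(d$levels[d$mask])
discretize <- function(volume, mask, scheme = c("fbn", "fbs"),
                       parameter = 64) {
  scheme <- match.arg(scheme)
  flags <- if (inherits(mask, "tumor_mask")) mask$flags else mask
  stopifnot(inherits(volume, "pet_volume"))
  assert_that(identical(dim(flags), dim(volume$values)),
              "mask and volume shapes differ")
  assert_that(sum(flags) > 0, "empty mask")
  assert_that(is_scalar_number(parameter) && parameter > 0,
              "`parameter` must be > 0")
  x <- volume$values[flags]
  if (scheme == "fbn") {
    ng <- as.integer(parameter)
    rng <- max(x) - min(x)
    lev <- if (rng == 0) rep(1L, length(x)) else
      pmin(ng, 1L + as.integer(floor(ng * (x - min(x)) / rng)))
    n_levels <- ng
  } else {
    lev <- 1L + as.integer(floor((x - min(x)) / parameter))
    n_levels <- max(lev)
  }
  levels <- array(NA_integer_, dim(flags))
  levels[flags] <- lev
  structure(
    list(levels = levels, mask = flags, n_levels = n_levels,
         scheme = scheme, parameter = parameter,
         spacing = volume$spacing),
    class = "discretized_roi"
  )
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat("<discretized_roi> ", sum(x$mask), " voxels, ", x$n_levels,
      " gray levels (", x$scheme, ", parameter ", x$parameter, ")\n",
      sep = "")
  invisible(x)
}
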