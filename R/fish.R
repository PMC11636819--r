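#' A segmented RNAscope dot field
#'
#' Measurement-level container for fluorescence in situ hybridization
#' quantification: the mean background intensity per pixel, a table of
#' segmented signal dots (integrated intensity and pixel area each), and
#' the enclosing region's total intensity and area. Segmentation itself
#' is upstream; this stage starts from the measurements.
#'
#' @param background_mean average background intensity per pixel (>= 0).
#' @param dots data.frame with columns `integrated_intensity`, `area`.
#' @param region list or data.frame with `total_intensity`, `total_area`.
#' @return object of class `dot_field`.
#' @export
dot_field <- function(background_mean, dots, region) {
  check_scalar_num(background_mean, "background_mean", 0)
  dots <- as.data.frame(dots)
  if (nrow(dots) && !all(c("integrated_intensity", "area") %in% names(dots)))
    abort_validation("dots needs columns integrated_intensity, area")
  if (nrow(dots) && any(dots$integrated_intensity < 0 | dots$area < 0))
    abort_validation("dot intensities and areas must be >= 0")
  check_scalar_num(region$total_intensity, "region$total_intensity", 0)
  check_scalar_num(region$total_area, "region$total_area", 0)
  if (nrow(dots) && sum(dots$area) > region$total_area)
    abort_validation("summed dot area exceeds the region area")
  structure(list(background_mean = background_mean, dots = dots,
                 region = list(total_intensity = region$total_intensity,
                               total_area = region$total_area)),
            class = "dot_field")
}

#' Average background-corrected intensity per dot
#'
#' `(sum of integrated dot intensities - background_mean * sum of dot
#' areas) / number of dots`. Calibrated on a representative region of
#' around 20 dots in the source protocol; the calibration-region choice
#' is the caller's.
#'
#' @param field a [dot_field()].
#' @return average intensity per single dot.
#' @export
average_dot_intensity <- function(field) {
  stopifnot(inherits(field, "dot_field"))
  n <- nrow(field$dots)
  if (n == 0L) abort("cannot calibrate on a field with 0 dots")
  num <- sum(field$dots$integrated_intensity) -
    field$background_mean * sum(field$dots$area)
  if (num < 0)
    abort("negative corrected intensity (%g): background estimate exceeds the dot signal",
          num)
  num / n
}

#' Estimate the dot count of a region from its total intensity
#'
#' `(total_intensity - background_mean * total_area) / avg_per_dot`,
#' real-valued (round at the caller if an integer count is wanted).
#'
#' @param field a [dot_field()].
#' @param avg_per_dot calibrated per-dot intensity, > 0 (typically from
#'   [average_dot_intensity()] on a calibration field).
#' @return estimated number of dots.
#' @export
estimate_dot_count <- function(field, avg_per_dot) {
  stopifnot(inherits(field, "dot_field"))
  check_scalar_num(avg_per_dot, "avg_per_dot")
  if (avg_per_dot <= 0) abort("avg_per_dot must be > 0, got %g", avg_per_dot)
  (field$region$total_intensity -
     field$background_mean * field$region$total_area) / avg_per_dot
}

#' Simulate a synthetic dot field
#'
#' Places `n_dots` dots of the given per-dot signal intensity and area on
#' a uniform background; the region totals are the exact pixel sums
#' (background everywhere plus dot signal), so with `noise_sd = 0` the
#' two estimators recover `n_dots` exactly. Per-dot intensities can be
#' jittered multiplicatively (lognormal, sd `noise_sd`).
#'
#' @param n_dots number of dots (>= 0).
#' @param dot_intensity signal (above background) integrated intensity
#'   per dot.
#' @param dot_area pixels per dot.
#' @param background mean background intensity per pixel.
#' @param region_area region pixels; must fit all dots.
#' @param noise_sd lognormal sd of per-dot intensity jitter.
#' @param seed RNG seed.
#' @return a [dot_field()].
#' @export
simulate_dot_field <- function(n_dots, dot_intensity = 100, dot_area = 5,
                               background = 2, region_area = 1000,
                               noise_sd = 0, seed = 1L) {
  check_scalar_num(n_dots, "n_dots", 0)
  if (n_dots * dot_area > region_area)
    abort_validation("dots exceed the region: %g dot pixels > %g region pixels",
                     n_dots * dot_area, region_area)
  set.seed(seed)
  signal <- if (n_dots > 0)
    dot_intensity * stats::rlnorm(n_dots, 0, noise_sd) else numeric(0)
  dots <- data.frame(integrated_intensity = signal + background * dot_area,
                     area = rep(dot_area, n_dots))
  region <- list(total_intensity = background * region_area + sum(signal),
                 total_area = region_area)
  dot_field(background, dots, region)
}

#' Read a dot field from a measurement bundle
#'
#' @param dots_path TSV with columns `dot_id`, `integrated_intensity`,
#'   `area`.
#' @param region_path JSON with `total_intensity`, `total_area`,
#'   `background_mean`.
#' @return a [dot_field()].
#' @export
read_dot_field <- function(dots_path, region_path) {
  dots <- as.data.frame(data.table::fread(dots_path, sep = "\t", header = TRUE))
  region <- jsonlite::read_json(region_path, simplifyVector = TRUE)
  dot_field(region$background_mean,
            dots[, c("integrated_intensity", "area")],
            region[c("total_intensity", "total_area")])
}
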