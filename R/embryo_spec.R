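#' Specification of a synthetic embryo image
#'
#' Bundles every parameter of the synthetic-embryo generator: geometry of the
#' periodic Engrailed-like boundary stripes, the number and intra-segment
#' placement distribution of punctate apoptotic events, the ventral-midline
#' band, the periodic signaling profile, the noise level and the random seed.
#' With a fixed spec (including its seed) the generator is bit-reproducible.
#'
#' The image uses matrix convention: rows are the dorsal-ventral (y) axis,
#' columns the anterior-posterior (x) axis, anterior at low x. Pixel
#' coordinates are 1-based, matching R indexing.
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param n_segments number of boundary (En) stripes rendered; the interiors
#'   between consecutive stripes are the `n_segments - 1` segments that can
#'   host events. The epidermis of the real embryo shows 14 such stripes.
#' @param boundary_x_px strictly increasing stripe centerline x positions.
#'   Default: evenly spaced at `boundary_spacing_px`, centred in the image.
#' @param boundary_spacing_px spacing used to build the default
#'   `boundary_x_px`.
#' @param stripe_width_px full width of each rendered stripe; must be smaller
#'   than the smallest inter-stripe spacing.
#' @param stripe_intensity intensity of stripe pixels (arbitrary units in
#'   \[0, 1\] so channels can be written to TIFF unscaled).
#' @param stripe_wiggle_amp_px,stripe_wiggle_period_px amplitude and period of
#'   an optional sinusoidal lateral displacement of the stripe centerlines
#'   along y. Zero amplitude gives straight vertical stripes; a non-zero value
#'   makes nearest-boundary distances genuinely two-dimensional.
#' @param event_count number of punctate events to sow.
#' @param event_position distribution of the intra-segment relative A/P
#'   position u in \[0, 1\]: `list(family = "uniform")` or
#'   `list(family = "beta", shape1 =, shape2 =)`.
#' @param event_radius_px radius of the rendered event disks.
#' @param event_intensity intensity of event-disk pixels.
#' @param midline_fraction fraction of the D-V extent, centred on the image
#'   mid-y, treated as the ventral-midline band. Events whose y falls inside
#'   the band are sown uniformly in x (they belong to the nervous system, not
#'   the segmental epidermis) and flagged `is_midline` in the ground truth.
#' @param noise_sd standard deviation of additive Gaussian noise (clipped at
#'   zero) applied to every channel.
#' @param profile_period_px period of the synthetic signaling profile along x.
#' @param profile_peak_amplitude,profile_baseline amplitude and baseline of
#'   the signaling profile; peaks sit at the boundaries.
#' @param boundary_jitter_px half-width of the uniform per-sample jitter
#'   applied to boundary positions in [generate_profile_samples()], to
#'   exercise landmark registration.
#' @param seed integer seed; all randomness of the generator flows from it.
#'
#' @return An object of class `embryo_spec` (a validated list).
#' @seealso [generate_embryo_image()], [generate_profile_samples()]
#' @export
#' @examples
#' spec <- embryo_spec(event_count = 100, seed = 7)
#' emb <- generate_embryo_image(spec)
#' dim(emb$image)
embryo_spec <- function(image_height_px = 220,
                        image_width_px = 900,
                        n_segments = 14,
                        boundary_x_px = NULL,
                        boundary_spacing_px = 60,
                        stripe_width_px = 8,
                        stripe_intensity = 0.8,
                        stripe_wiggle_amp_px = 0,
                        stripe_wiggle_period_px = 200,
                        event_count = 300,
                        event_position = list(family = "beta", shape1 = 2, shape2 = 2),
                        event_radius_px = 3,
                        event_intensity = 0.9,
                        midline_fraction = 0,
                        noise_sd = 0.1 * stripe_intensity,
                        profile_period_px = boundary_spacing_px,
                        profile_peak_amplitude = 0.5,
                        profile_baseline = 0.3,
                        boundary_jitter_px = 0,
                        seed = 1L) {
  if (is.null(boundary_x_px)) {
    span <- (n_segments - 1) * boundary_spacing_px
    start <- (image_width_px - span) / 2
    boundary_x_px <- start + (seq_len(n_segments) - 1) * boundary_spacing_px
  }
  spec <- structure(
    list(
      image_height_px = as.integer(image_height_px),
      image_width_px = as.integer(image_width_px),
      n_segments = as.integer(length(boundary_x_px)),
      boundary_x_px = as.numeric(boundary_x_px),
      stripe_width_px = stripe_width_px,
      stripe_intensity = stripe_intensity,
      stripe_wiggle_amp_px = stripe_wiggle_amp_px,
      stripe_wiggle_period_px = stripe_wiggle_period_px,
      event_count = as.integer(event_count),
      event_position = event_position,
      event_radius_px = event_radius_px,
      event_intensity = event_intensity,
      midline_fraction = midline_fraction,
      noise_sd = noise_sd,
      profile_period_px = profile_period_px,
      profile_peak_amplitude = profile_peak_amplitude,
      profile_baseline = profile_baseline,
      boundary_jitter_px = boundary_jitter_px,
      seed = as.integer(seed)
    ),
    class = "embryo_spec"
  )
  validate_embryo_spec(spec)
}

validate_embryo_spec <- function(spec) {
  b <- spec$boundary_x_px
  if (length(b) >= 2 && any(diff(b) <= 0)) {
    stop("boundary_x_px must be strictly increasing", call. = FALSE)
  }
  if (length(b) >= 2 && any(diff(b) <= spec$stripe_width_px)) {
    stop("inter-stripe spacing must exceed stripe_width_px", call. = FALSE)
  }
  if (any(b < 1) || any(b > spec$image_width_px)) {
    stop("boundary_x_px must lie within the image", call. = FALSE)
  }
  if (spec$event_count < 0) stop("event_count must be non-negative", call. = FALSE)
  if (spec$event_count > 0 && spec$n_segments < 2) {
    stop("event_count > 0 requires at least 2 boundary stripes: no segment interior exists",
         call. = FALSE)
  }
  if (spec$midline_fraction < 0 || spec$midline_fraction > 1) {
    stop("midline_fraction must be in [0, 1]", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (spec$stripe_width_px <= 0 || spec$event_radius_px <= 0 ||
      spec$profile_period_px <= 0) {
    stop("stripe_width_px, event_radius_px and profile_period_px must be positive",
         call. = FALSE)
  }
  fam <- spec$event_position$family
  if (!fam %in% c("uniform", "beta")) {
    stop("event_position$family must be 'uniform' or 'beta'", call. = FALSE)
  }
  if (fam == "beta" &&
      (is.null(spec$event_position$shape1) || is.null(spec$event_position$shape2))) {
    stop("beta event_position requires shape1 and shape2", call. = FALSE)
  }
  spec
}

#' Read an embryo spec from a YAML file
#'
#' Reads generator parameters from YAML and validates them via
#' [embryo_spec()]; keys mirror the argument names of that constructor.
#'
#' @param path path to a YAML file.
#' @return An `embryo_spec`.
#' @export
read_embryo_spec <- function(path) {
  do.call(embryo_spec, yaml::read_yaml(path))
}

#' @export
print.embryo_spec <- function(x, ...) {
  cat("<embryo_spec> ", x$image_height_px, "x", x$image_width_px,
      " px, ", x$n_segments, " stripes, ", x$event_count, " events (",
      x$event_position$family, "), midline_fraction=", x$midline_fraction,
      ", noise_sd=", signif(x$noise_sd, 3), ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}
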