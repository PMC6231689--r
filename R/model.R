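#' Wild-type segmental EGFR-ligand source configuration
#'
#' Builds the default source layout of the threshold-survival model: each
#' segment carries two prosurvival ligand sources flanking its boundaries —
#' a Vein-like (`vn`) domain just posterior to the anterior boundary and a
#' rhomboid/Spitz-like (`rho`) domain just anterior to the posterior
#' boundary. Positions are in segment-width units; segment `s` occupies
#' `[s - 1, s]`, so an `n_segments` embryo spans `[0, n_segments]` with
#' boundaries at the integers. Sources in even-numbered segments are tagged
#' as dependent on the pair-rule gene *ftz*: in a *ftz* null, ligand
#' expression fails to appear in alternate segments and those sources are
#' lost.
#'
#' @param n_segments number of segments (default 14, the segmented
#'   epidermis).
#' @param amplitude source strength at its position.
#' @param decay_length exponential decay length of ligand spread, in
#'   segment widths.
#' @param offset distance of each source from its boundary, in segment
#'   widths.
#' @return Data frame of class `ligand_sources`: `position`, `amplitude`,
#'   `decay_length`, `ligand` (`"vn"`/`"rho"`), `segment`, `dependency`
#'   (`"ftz"` for even segments, `"none"` otherwise).
#' @export
wildtype_sources <- function(n_segments = 14L, amplitude = 1,
                             decay_length = 0.25, offset = 0.1) {
  stopifnot(n_segments >= 1L, amplitude > 0, decay_length > 0,
            offset > 0, offset < 0.5)
  seg <- rep(seq_len(n_segments), each = 2L)
  lig <- rep(c("vn", "rho"), n_segments)
  pos <- ifelse(lig == "vn", seg - 1 + offset, seg - offset)
  structure(
    data.frame(position = pos, amplitude = amplitude,
               decay_length = decay_length, ligand = lig,
               segment = seg,
               dependency = ifelse(seg %% 2L == 0L, "ftz", "none")),
    class = c("ligand_sources", "data.frame")
  )
}

#' Evaluate the signaling landscape produced by ligand sources
#'
#' Sums symmetric exponential-decay kernels over all sources:
#' `S(x) = sum_s amplitude_s * exp(-|x - position_s| / decay_length_s)`,
#' the minimal model of secreted ligands spreading from segmental stripes
#' and decaying with distance.
#'
#' @param sources a `ligand_sources` data frame (possibly empty).
#' @param grid strictly increasing A/P coordinates (segment-width units).
#' @return A list of class `signaling_landscape`: `grid_x`, `S`, `sources`;
#'   threshold fields are added by [apply_threshold()].
#' @export
build_landscape <- function(sources, grid) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  S <- numeric(length(grid))
  if (nrow(sources) > 0L) {
    for (i in seq_len(nrow(sources))) {
      S <- S + sources$amplitude[i] *
        exp(-abs(grid - sources$position[i]) / sources$decay_length[i])
    }
  }
  structure(list(grid_x = grid, S = S, sources = sources),
            class = "signaling_landscape")
}

#' Apply the survival threshold and extract sub-threshold bands
#'
#' Cells survive where signaling stays at or above the threshold; where
#' `S < threshold` the proapoptotic gene *hid* is derepressed. The mask of
#' sub-threshold grid points is decomposed into its maximal contiguous runs
#' (`bands`) — the predicted stripes of *hid* up-regulation and apoptosis.
#'
#' @param landscape a `signaling_landscape` from [build_landscape()].
#' @param threshold positive survival threshold (default
#'   [default_survival_threshold()]).
#' @return The landscape with `threshold`, `hid_mask` (logical per grid
#'   point), `bands` (data frame `start_x`, `end_x`) and
#'   `subthreshold_fraction` added.
#' @export
apply_threshold <- function(landscape, threshold = default_survival_threshold()) {
  stopifnot(inherits(landscape, "signaling_landscape"))
  mask <- landscape$S < threshold
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sub <- which(runs$values)
  landscape$threshold <- threshold
  landscape$hid_mask <- mask
  landscape$bands <- data.frame(
    start_x = landscape$grid_x[starts[sub]],
    end_x = landscape$grid_x[ends[sub]]
  )
  landscape$subthreshold_fraction <- mean(mask)
  landscape
}

#' Count sub-threshold bands
#'
#' @param landscape a thresholded `signaling_landscape`.
#' @return Integer number of maximal contiguous sub-threshold runs — the
#'   predicted number of apoptotic bands.
#' @export
count_bands <- function(landscape) {
  if (is.null(landscape$bands)) stop("apply_threshold() first", call. = FALSE)
  nrow(landscape$bands)
}

#' Sub-threshold area of a thresholded landscape
#'
#' @param landscape a thresholded `signaling_landscape`.
#' @return Fraction of sub-threshold grid points times the domain length —
#'   the total A/P extent (in segment widths) predicted to up-regulate
#'   *hid*.
#' @export
subthreshold_area <- function(landscape) {
  if (is.null(landscape$hid_mask)) stop("apply_threshold() first", call. = FALSE)
  mean(landscape$hid_mask) * diff(range(landscape$grid_x))
}

#' Default survival threshold of the shipped calibration
#'
#' With the default source layout (amplitude 1, decay length 0.25 segment
#' widths, sources at boundary +/- 0.1), a threshold of 0.22 puts the
#' wild-type landscape entirely above threshold (minimum ~0.40 mid-segment)
#' and single-ligand configurations above it too (minimum ~0.28), while the
#' wider source-free gaps of a *ftz* mutant fall below (~0.19), producing
#' one apoptotic band per de-sourced segment.
#'
#' @return The numeric threshold.
#' @export
default_survival_threshold <- function() 0.22

#' Genotype scenario presets for the source configuration
#'
#' Edits a wild-type source list according to a genotype:
#' \describe{
#'   \item{wildtype}{unchanged.}
#'   \item{ftz}{removes every source in *ftz*-dependent (alternate)
#'     segments — ligand stripes fail to appear there.}
#'   \item{ptc}{adds one ectopic mid-segment rho-like source per segment
#'     (ectopic rhomboid expression); extra sources can only raise
#'     signaling, so no new apoptotic bands arise.}
#'   \item{egfr_null}{no functional receptor: the effective source list is
#'     empty and the whole field is sub-threshold.}
#'   \item{vn_only}{loss of the rho/Spitz ligand class; only vn-like
#'     sources remain.}
#'   \item{rho_only}{loss of Vein; only rho-like sources remain.}
#'   \item{vn_rho_double}{loss of both ligand classes — equivalent to
#'     `egfr_null` at the ligand level.}
#' }
#'
#' @param name scenario name (see above).
#' @param base wild-type `ligand_sources` (default [wildtype_sources()]).
#' @return An edited `ligand_sources` data frame.
#' @export
scenario <- function(name = c("wildtype", "ftz", "ptc", "egfr_null",
                              "vn_only", "rho_only", "vn_rho_double"),
                     base = wildtype_sources()) {
  name <- match.arg(name)
  out <- switch(name,
    wildtype = base,
    ftz = base[base$dependency != "ftz", , drop = FALSE],
    ptc = {
      segs <- unique(base$segment)
      ect <- data.frame(
        position = segs - 0.5,
        amplitude = stats::median(base$amplitude[base$ligand == "rho"]),
        decay_length = stats::median(base$decay_length[base$ligand == "rho"]),
        ligand = "rho", segment = segs, dependency = "ptc_ectopic"
      )
      rbind(base, ect)
    },
    egfr_null = base[0L, , drop = FALSE],
    vn_only = base[base$ligand == "vn", , drop = FALSE],
    rho_only = base[base$ligand == "rho", , drop = FALSE],
    vn_rho_double = base[0L, , drop = FALSE]
  )
  structure(out, class = c("ligand_sources", "data.frame"))
}

#' Run a genotype scenario end to end
#'
#' Convenience wrapper: edits the wild-type sources per `name`, evaluates
#' the landscape on a regular grid over the whole field and applies the
#' survival threshold.
#'
#' @param name scenario name, see [scenario()].
#' @param n_segments number of segments of the wild-type base.
#' @param grid_step grid resolution in segment widths.
#' @param threshold survival threshold.
#' @param base wild-type sources; default [wildtype_sources()] with
#'   `n_segments`.
#' @return A thresholded `signaling_landscape`.
#' @export
#' @examples
#' ftz <- simulate_scenario("ftz")
#' count_bands(ftz)
simulate_scenario <- function(name, n_segments = 14L, grid_step = 0.01,
                              threshold = default_survival_threshold(),
                              base = wildtype_sources(n_segments)) {
  src <- scenario(name, base)
  grid <- seq(0, n_segments, by = grid_step)
  apply_threshold(build_landscape(src, grid), threshold)
}
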