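#' Order boundary skeletons along the A/P axis
#'
#' Sorts skeleton curves by their median x; consecutive pairs define the
#' segments. Fails when fewer than two curves exist (no segment can be
#' defined) or when two curves cannot be ranked (median x closer than 1 px).
#'
#' @param skeleton a `boundary_skeleton` from [skeletonize_stripes()].
#' @return The skeleton with stripes sorted anterior to posterior.
#' @export
order_boundaries <- function(skeleton) {
  stopifnot(inherits(skeleton, "boundary_skeleton"))
  if (length(skeleton$stripes) < 2L) {
    stop("cannot define a segment: fewer than 2 boundary stripes", call. = FALSE)
  }
  ord <- order(skeleton$median_x)
  med <- skeleton$median_x[ord]
  if (any(diff(med) < 1)) {
    stop("ambiguous boundary order: stripe median x positions closer than 1 px",
         call. = FALSE)
  }
  skeleton$stripes <- skeleton$stripes[ord]
  skeleton$median_x <- med
  skeleton
}

#' Map events into the normalized segmental coordinate system
#'
#' For each event, the flanking boundary pair is the consecutive skeleton
#' pair whose median x brackets the event's x. The distances `d_anterior_px`
#' and `d_posterior_px` are the minimal Euclidean distances from the event
#' to any pixel of the anterior and posterior flanking skeletons, and the
#' normalized A/P position is
#' `rel_pos_pct = 100 * d_anterior / (d_anterior + d_posterior)`,
#' the event's position as a percentage of local segment width. For straight
#' parallel boundaries this reduces to the exact linear coordinate; for
#' curved boundaries it remains well defined because the distances are
#' genuinely two-dimensional.
#'
#' Events anterior of the first or at/posterior of the last boundary cannot
#' be assigned a segment and are flagged `unmappable` (they are excluded
#' from histograms). An event lying exactly on a skeleton pixel gets
#' `rel_pos_pct = 0`, counted as the anterior boundary of the segment
#' posterior to it.
#'
#' @param events an `event_set` (data frame with `x_px`, `y_px`) from
#'   [detect_events()], or any data frame with those columns.
#' @param boundaries an ordered `boundary_skeleton` (see
#'   [order_boundaries()]; unordered skeletons are ordered on the fly).
#' @return A data frame of event records: `event_id`, `x_px`, `y_px`,
#'   `d_anterior_px`, `d_posterior_px`, `rel_pos_pct`, `segment_index`
#'   (index of the anterior flanking boundary), `unmappable`,
#'   `excluded_midline` (initialised `FALSE`; see [exclude_midline()]).
#' @export
map_events <- function(events, boundaries) {
  boundaries <- order_boundaries(boundaries)
  med <- boundaries$median_x
  nb <- length(med)
  n <- nrow(events)
  rec <- data.frame(
    event_id = if ("event_id" %in% names(events)) events$event_id else seq_len(n),
    x_px = as.numeric(events$x_px), y_px = as.numeric(events$y_px),
    d_anterior_px = rep(NA_real_, n), d_posterior_px = rep(NA_real_, n),
    rel_pos_pct = rep(NA_real_, n), segment_index = rep(NA_integer_, n),
    unmappable = rep(FALSE, n), excluded_midline = rep(FALSE, n)
  )
  if (n == 0L) return(rec)

  # events exactly on a skeleton pixel sit at the anterior edge (0%) of the
  # segment posterior to that skeleton
  on_stripe <- rep(NA_integer_, n)
  for (k in seq_len(nb)) {
    s <- boundaries$stripes[[k]]
    hit <- match(paste(rec$x_px, rec$y_px), paste(s$x, s$y))
    on_stripe[!is.na(hit)] <- k
  }

  seg <- findInterval(rec$x_px, med) # 0 = anterior of first, nb = at/past last
  seg[!is.na(on_stripe)] <- on_stripe[!is.na(on_stripe)]
  rec$unmappable <- seg == 0L | seg >= nb
  rec$segment_index <- ifelse(rec$unmappable, NA_integer_, seg)

  for (k in unique(seg[!rec$unmappable])) {
    sel <- which(seg == k & !rec$unmappable)
    rec$d_anterior_px[sel] <- min_dist_to_skeleton(
      rec$x_px[sel], rec$y_px[sel], boundaries$stripes[[k]])
    rec$d_posterior_px[sel] <- min_dist_to_skeleton(
      rec$x_px[sel], rec$y_px[sel], boundaries$stripes[[k + 1L]])
  }
  denom <- rec$d_anterior_px + rec$d_posterior_px
  ok <- !rec$unmappable & denom > 0
  rec$rel_pos_pct[ok] <- 100 * rec$d_anterior_px[ok] / denom[ok]
  rec$rel_pos_pct[!rec$unmappable & denom == 0] <- 0
  rec
}

# minimal Euclidean distance from each point to any pixel of a skeleton
# curve; exact, vectorized over the full point x pixel distance matrix
min_dist_to_skeleton <- function(x, y, stripe) {
  d2 <- outer(x, stripe$x, "-")^2 + outer(y, stripe$y, "-")^2
  sqrt(apply(d2, 1L, min))
}

#' Exclude events near the ventral midline
#'
#' Flags events whose y coordinate lies within the central D-V band covering
#' `fraction` of the linear dorsal-to-ventral distance, centred on the
#' midpoint of `[dv_min_px, dv_max_px]`. These events sit in the developing
#' nervous system rather than the segmental epidermis and are removed from
#' downstream tabulation. The default fraction of 0.20 excludes 20% of the
#' linear D-V distance.
#'
#' @param records event records from [map_events()].
#' @param dv_min_px,dv_max_px D-V extent of the epidermal field (typically 1
#'   and the image height).
#' @param fraction band width as a fraction of the D-V extent, in \[0, 1\].
#' @return `records` with `excluded_midline` set.
#' @export
exclude_midline <- function(records, dv_min_px, dv_max_px, fraction = 0.20) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  if (dv_min_px >= dv_max_px) stop("dv_min_px must be < dv_max_px", call. = FALSE)
  band <- midline_band(dv_min_px, dv_max_px, fraction)
  records$excluded_midline <- fraction > 0 &
    records$y_px >= band[1] & records$y_px <= band[2]
  records
}

#' Tabulate the segmental apoptosis histogram across embryos
#'
#' Bins the normalized positions (`rel_pos_pct`) of retained events — mapped,
#' not midline-excluded — into `n_bins` half-open bins on \[0, 100\] (last
#' bin closed), per embryo, then averages across embryos. With
#' `normalize = "fraction"` (default) each embryo's counts are first divided
#' by its retained event total, so embryos with different amounts of
#' apoptosis contribute equally; `"count"` averages raw counts.
#'
#' @param records_per_embryo list of event-record data frames, one per
#'   embryo (see [map_events()], [exclude_midline()]).
#' @param n_bins number of bins (>= 2).
#' @param normalize `"fraction"` or `"count"`.
#' @return A list of class `apoptosis_histogram`: `bin_edges_pct`,
#'   `per_embryo_counts` (embryos x bins matrix of raw counts),
#'   `mean_frequency`, `sd` (across embryos, on the chosen scale),
#'   `normalize`, `n_embryos`.
#' @export
tabulate_histogram <- function(records_per_embryo, n_bins = 10L,
                               normalize = c("fraction", "count")) {
  normalize <- match.arg(normalize)
  if (length(records_per_embryo) == 0L) stop("zero embryos", call. = FALSE)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  edges <- seq(0, 100, length.out = n_bins + 1L)
  counts <- t(vapply(records_per_embryo, function(rec) {
    keep <- !rec$unmappable & !rec$excluded_midline & !is.na(rec$rel_pos_pct)
    bin <- findInterval(rec$rel_pos_pct[keep], edges, rightmost.closed = TRUE)
    tabulate(bin, nbins = n_bins)
  }, integer(n_bins)))
  vals <- if (normalize == "fraction") {
    tot <- rowSums(counts)
    sweep(counts, 1L, pmax(tot, 1L), "/")
  } else {
    counts
  }
  structure(
    list(bin_edges_pct = edges,
         per_embryo_counts = counts,
         mean_frequency = colMeans(vals),
         sd = apply(vals, 2L, stats::sd),
         normalize = normalize,
         n_embryos = nrow(counts)),
    class = "apoptosis_histogram"
  )
}

#' Compare mean intensities between two groups of embryos
#'
#' Classical unpaired two-sample Student t test with pooled (equal) variance
#' on per-embryo mean intensities, as used to compare e.g. cleaved-Dcp1 or
#' GFP-reporter levels between genotypes. Returns the plotted quantities
#' (group means and standard deviations) together with the test.
#'
#' @param group_a,group_b numeric vectors of per-embryo mean intensities,
#'   each of length >= 2.
#' @return A list: `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t`, `df`,
#'   `p_value` (two-sided).
#' @export
#' @examples
#' compare_mean_intensity(c(1, 2, 3), c(4, 5, 6))
compare_mean_intensity <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(mean_a = mean(group_a), mean_b = mean(group_b),
       sd_a = stats::sd(group_a), sd_b = stats::sd(group_b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
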