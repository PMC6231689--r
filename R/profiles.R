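#' Extract per-channel A/P intensity traces from a rectangular ROI
#'
#' Averages each channel over the ROI rows (the D-V direction), producing
#' one mean-intensity trace per channel ordered anterior to posterior. The
#' analysis convention is a ROI of fixed physical height (75 um in the
#' original protocol) spanning several contiguous segments.
#'
#' @param image numeric array `height x width x n_channels` (a matrix is
#'   treated as one channel).
#' @param roi list or named vector with `x0`, `y0` (1-based top-left pixel),
#'   `width_px`, `height_px`.
#' @param pixel_size_um physical pixel size, recorded for provenance.
#' @return A list of class `raw_profile`: `traces` (matrix
#'   `n_channels x width_px`), `roi`, `pixel_size_um`, `roi_height_um`.
#' @export
extract_profile <- function(image, roi, pixel_size_um = 1) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  roi <- as.list(roi)
  x0 <- roi$x0; y0 <- roi$y0; w <- roi$width_px; h <- roi$height_px
  if (is.null(x0) || is.null(y0) || is.null(w) || is.null(h)) {
    stop("roi needs x0, y0, width_px, height_px", call. = FALSE)
  }
  if (x0 < 1 || y0 < 1 || x0 + w - 1 > dim(image)[2] || y0 + h - 1 > dim(image)[1]) {
    stop("roi outside image bounds", call. = FALSE)
  }
  traces <- t(vapply(seq_len(dim(image)[3]), function(ch) {
    colMeans(image[y0:(y0 + h - 1), x0:(x0 + w - 1), ch, drop = TRUE])
  }, numeric(w)))
  structure(list(traces = traces, roi = roi, pixel_size_um = pixel_size_um,
                 roi_height_um = h * pixel_size_um),
            class = "raw_profile")
}

#' Detect landmark peaks in a 1D trace
#'
#' Finds local maxima of the (lightly smoothed) landmark trace, keeps those
#' whose topographic prominence reaches `min_prominence`, and enforces a
#' minimum separation by greedily keeping the most prominent peaks first.
#' Peak positions are returned in increasing order. Trace endpoints never
#' count as peaks, so a monotone trace has none.
#'
#' @param trace numeric vector (length >= 3).
#' @param min_separation_px minimum distance between retained peaks.
#' @param min_prominence minimum prominence (peak height above its highest
#'   enclosing saddle).
#' @param smooth_window_px width of the centred moving-average smoother
#'   applied before peak finding (odd; 1 disables smoothing).
#' @return Integer vector of peak positions (pixel indices, increasing).
#' @export
detect_landmark_peaks <- function(trace, min_separation_px = 10,
                                  min_prominence = 0.1, smooth_window_px = 5L) {
  if (length(trace) < 3L) stop("trace too short", call. = FALSE)
  s <- smooth_ma(trace, smooth_window_px)
  n <- length(s)
  i <- 2:(n - 1L)
  cand <- i[s[i] > s[i - 1L] & s[i] >= s[i + 1L]]
  if (length(cand) > 0L) {
    prom <- vapply(cand, function(p) peak_prominence(s, p), numeric(1))
    cand <- cand[prom >= min_prominence]
    prom <- prom[prom >= min_prominence]
  }
  if (length(cand) >= 2L && min_separation_px > 0) {
    keep <- logical(length(cand))
    for (j in order(prom, decreasing = TRUE)) {
      if (!any(keep & abs(cand - cand[j]) < min_separation_px)) keep[j] <- TRUE
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < 2L) stop("cannot register: fewer than 2 landmark peaks", call. = FALSE)
  as.integer(sort(cand))
}

# centred moving average; edges use the shrunken window that fits
smooth_ma <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# topographic prominence of the peak at index p: height above the higher of
# the two minima separating it from the nearest higher terrain (or the trace
# end on a side with no higher point)
peak_prominence <- function(s, p) {
  h <- s[p]
  left <- if (p > 1L) s[1:(p - 1L)] else numeric(0)
  right <- if (p < length(s)) s[(p + 1L):length(s)] else numeric(0)
  saddle <- function(side, rev) {
    if (length(side) == 0L) return(-Inf)
    v <- if (rev) rev(side) else side
    higher <- which(v > h)
    if (length(higher) == 0L) min(v) else min(v[1:higher[1L]])
  }
  mL <- saddle(left, rev = TRUE)
  mR <- saddle(right, rev = FALSE)
  h - max(mL, mR)
}

#' Register a profile to landmark peaks on a fixed per-segment grid
#'
#' Rescales each inter-peak interval onto `bins_per_segment` evenly spaced
#' sample positions (linear interpolation of the trace), concatenating the
#' intervals so that every segment occupies the same number of bins
#' regardless of its pixel width. Sampling is half-open: segment `s` covers
#' positions `p_s + k/B * (p_{s+1} - p_s)` for `k = 0 .. B-1`, so each peak
#' lands exactly on the first bin of its segment and the trace beyond the
#' last peak is discarded. This normalizes data to segment width, which
#' varies between samples.
#'
#' @param raw a `raw_profile` from [extract_profile()], or a numeric matrix
#'   `n_channels x length` (or a bare numeric vector).
#' @param peaks increasing landmark peak positions (pixel indices; >= 2).
#' @param bins_per_segment bins per segment (>= 2; the standard analysis
#'   uses 50 evenly spaced intervals per segment).
#' @return Numeric matrix `n_channels x (n_segments * bins_per_segment)`
#'   with attributes `bins_per_segment` and `n_segments`.
#' @export
register_profiles <- function(raw, peaks, bins_per_segment = 50L) {
  traces <- if (inherits(raw, "raw_profile")) raw$traces else raw
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1L)
  if (length(peaks) < 2L) stop("cannot register: fewer than 2 peaks", call. = FALSE)
  if (any(diff(peaks) <= 0)) stop("coincident or unordered peaks", call. = FALSE)
  if (bins_per_segment < 2L) stop("bins_per_segment must be >= 2", call. = FALSE)
  B <- as.integer(bins_per_segment)
  frac <- (seq_len(B) - 1L) / B
  xout <- unlist(lapply(seq_len(length(peaks) - 1L), function(i) {
    peaks[i] + frac * (peaks[i + 1L] - peaks[i])
  }))
  xin <- seq_len(ncol(traces))
  out <- t(vapply(seq_len(nrow(traces)), function(ch) {
    stats::approx(xin, traces[ch, ], xout = xout)$y
  }, numeric(length(xout))))
  rownames(out) <- rownames(traces)
  attr(out, "bins_per_segment") <- B
  attr(out, "n_segments") <- length(peaks) - 1L
  out
}

#' Average registered profiles across samples with SEM
#'
#' Computes the per-bin, per-channel mean and standard error of the mean
#' across registered samples. At least two samples are required — with one
#' sample the SEM is undefined and the shaded uncertainty band of the
#' standard plot cannot be drawn.
#'
#' @param samples list of registered matrices from [register_profiles()],
#'   all of equal dimensions.
#' @return A list of class `registered_profile`: `mean` and `sem` (matrices
#'   `n_channels x n_bins_total`), `n_samples`, `bins_per_segment`,
#'   `n_segments`.
#' @export
average_registered <- function(samples) {
  if (length(samples) < 2L) {
    stop("at least 2 samples are required: SEM is undefined for one sample",
         call. = FALSE)
  }
  dims <- lapply(samples, dim)
  if (length(unique(dims)) != 1L) stop("samples differ in dimensions", call. = FALSE)
  arr <- simplify2array(samples) # ch x bins x samples
  mu <- apply(arr, c(1L, 2L), mean)
  sem <- apply(arr, c(1L, 2L), stats::sd) / sqrt(length(samples))
  rownames(mu) <- rownames(sem) <- rownames(samples[[1L]])
  structure(
    list(mean = mu, sem = sem, n_samples = length(samples),
         bins_per_segment = attr(samples[[1L]], "bins_per_segment"),
         n_segments = attr(samples[[1L]], "n_segments")),
    class = "registered_profile"
  )
}
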