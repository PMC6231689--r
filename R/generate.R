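#' Generate a synthetic two-channel embryo image with ground truth
#'
#' Renders channel 1 (landmark) with periodic vertical Engrailed-like stripes
#' centred at `spec$boundary_x_px`, optionally bent by a sinusoidal wiggle
#' along y, and channel 2 (events) with disks of radius
#' `spec$event_radius_px` whose intra-segment relative A/P position u follows
#' `spec$event_position`. Events falling in the ventral-midline band (a
#' central horizontal strip of height `midline_fraction` times the D-V
#' extent) are instead sown uniformly in x and flagged `is_midline`,
#' emulating apoptotic figures of the developing nervous system that the
#' epidermal analysis must exclude. Additive Gaussian noise (sd
#' `spec$noise_sd`, clipped at zero) is applied to both channels.
#'
#' The ground-truth relative position of an event satisfies
#' `u = (x - x_ant) / (x_post - x_ant)`, where `x_ant` and `x_post` are the
#' flanking stripe centerline positions evaluated at the event's y (equal to
#' `boundary_x_px` when the wiggle amplitude is zero).
#'
#' @param spec an [embryo_spec()].
#' @return A list of class `synthetic_embryo` with elements
#'   \describe{
#'     \item{image}{numeric array `height x width x 2`; `[,,1]` landmark
#'       stripes, `[,,2]` events.}
#'     \item{ground_truth}{list with `boundary_x_px`, `events` (data frame
#'       `x_px`, `y_px`, `true_rel_pos`, `segment_index`, `is_midline`) and
#'       `profile_params`.}
#'     \item{spec}{the spec used.}
#'   }
#' @export
generate_embryo_image <- function(spec) {
  stopifnot(inherits(spec, "embryo_spec"))
  validate_embryo_spec(spec)
  set.seed(spec$seed)

  H <- spec$image_height_px
  W <- spec$image_width_px
  nb <- spec$n_segments
  b <- spec$boundary_x_px
  r <- spec$event_radius_px

  # stripe centerline x position of stripe k at each row y
  wiggle <- if (spec$stripe_wiggle_amp_px > 0) {
    spec$stripe_wiggle_amp_px * sin(2 * pi * seq_len(H) / spec$stripe_wiggle_period_px)
  } else {
    numeric(H)
  }
  centerline <- function(k, y) b[k] + wiggle[y]

  stripe_ch <- matrix(0, H, W)
  half_w <- spec$stripe_width_px / 2
  xs <- seq_len(W)
  for (k in seq_len(nb)) {
    cx <- b[k] + wiggle # length H
    lo <- pmax(1L, ceiling(cx - half_w))
    hi <- pmin(W, floor(cx + half_w))
    for (y in seq_len(H)) {
      if (lo[y] <= hi[y]) stripe_ch[y, lo[y]:hi[y]] <- spec$stripe_intensity
    }
  }

  event_ch <- matrix(0, H, W)
  n_ev <- spec$event_count
  events <- data.frame(
    x_px = numeric(0), y_px = numeric(0), true_rel_pos = numeric(0),
    segment_index = integer(0), is_midline = logical(0)
  )
  if (n_ev > 0) {
    y_lo <- 1 + r
    y_hi <- H - r
    y_ev <- runif(n_ev, y_lo, y_hi)
    band <- midline_band(1, H, spec$midline_fraction)
    is_mid <- spec$midline_fraction > 0 &
      y_ev >= band[1] & y_ev <= band[2]

    u <- switch(spec$event_position$family,
      uniform = runif(n_ev),
      beta = rbeta(n_ev, spec$event_position$shape1, spec$event_position$shape2)
    )
    seg <- sample.int(nb - 1L, n_ev, replace = TRUE)
    x_mid <- runif(n_ev, min(b), max(b))

    off <- wiggle[pmin(H, pmax(1L, round(y_ev)))] # centerline offset at event row
    x_ev <- numeric(n_ev)
    for (i in seq_len(n_ev)) {
      if (is_mid[i]) {
        x_ev[i] <- x_mid[i]
        # segment and relative position implied by the uniform x draw
        cx_all <- b + off[i]
        s <- findInterval(x_ev[i] - off[i], b)
        s <- min(max(s, 1L), nb - 1L)
        seg[i] <- s
        u[i] <- (x_ev[i] - cx_all[s]) / (cx_all[s + 1] - cx_all[s])
        u[i] <- min(max(u[i], 0), 1)
      } else {
        x_ant <- b[seg[i]] + off[i]
        x_post <- b[seg[i] + 1] + off[i]
        x_ev[i] <- (1 - u[i]) * x_ant + u[i] * x_post
      }
    }

    # render disks (maximum-projection of overlapping disks)
    for (i in seq_len(n_ev)) {
      cx <- x_ev[i]; cy <- y_ev[i]
      rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
      cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
      d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
      hit <- d2 <= r^2
      event_ch[rows, cols][hit] <- spec$event_intensity
    }

    events <- data.frame(
      x_px = x_ev, y_px = y_ev, true_rel_pos = u,
      segment_index = as.integer(seg), is_midline = is_mid
    )
  }

  if (spec$noise_sd > 0) {
    stripe_ch <- pmax(0, stripe_ch + rnorm(H * W, 0, spec$noise_sd))
    event_ch <- pmax(0, event_ch + rnorm(H * W, 0, spec$noise_sd))
  }

  img <- array(0, dim = c(H, W, 2))
  img[, , 1] <- stripe_ch
  img[, , 2] <- event_ch

  structure(
    list(
      image = img,
      ground_truth = list(
        boundary_x_px = b,
        events = events,
        profile_params = spec[c("profile_period_px", "profile_peak_amplitude",
                                "profile_baseline")]
      ),
      spec = spec
    ),
    class = "synthetic_embryo"
  )
}

# the central D-V band [lo, hi] covering `fraction` of the extent
# [dv_min, dv_max], centred on its midpoint
midline_band <- function(dv_min, dv_max, fraction) {
  mid <- (dv_min + dv_max) / 2
  half <- fraction * (dv_max - dv_min) / 2
  c(mid - half, mid + half)
}

#' Generate 1D multi-channel profile samples with jittered landmarks
#'
#' Emulates intensity traces taken along the A/P axis of a rectangular ROI
#' spanning several segments. Each sample carries three channels:
#' \describe{
#'   \item{landmark}{Gaussian bumps of width `stripe_width_px` at the
#'     (per-sample jittered) boundary positions — the En stripe signal.}
#'   \item{signal}{periodic profile with smooth peaks at the boundaries,
#'     `baseline + amplitude * (1 + cos(2*pi*t)) / 2`, where t is the
#'     position's phase within its inter-boundary interval — the dpERK-like
#'     signaling landscape.}
#'   \item{antisignal}{the complementary profile
#'     `(2*baseline + amplitude) - signal`, peaking mid-segment — the
#'     hid-reporter-like readout anticorrelated with signaling.}
#' }
#' Boundary positions are jittered independently per sample by a uniform
#' offset in `+/- spec$boundary_jitter_px` (so segment pixel widths vary
#' between samples, as they do between embryos), and independent Gaussian
#' noise of sd `spec$noise_sd` is added to every channel.
#'
#' @param spec an [embryo_spec()].
#' @param n_samples number of samples (>= 1).
#' @return A list of class `profile_samples`: `samples` (list of
#'   `3 x width` matrices with row names `landmark`, `signal`, `antisignal`)
#'   and `boundaries_px` (matrix `n_samples x n_boundaries` of the jittered
#'   true boundary positions).
#' @export
generate_profile_samples <- function(spec, n_samples) {
  stopifnot(inherits(spec, "embryo_spec"))
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  set.seed(spec$seed + 1L) # stream distinct from the image generator
  L <- spec$image_width_px
  x <- seq_len(L)
  b <- spec$boundary_x_px
  nb <- length(b)
  sigma <- spec$stripe_width_px / 2
  amp <- spec$profile_peak_amplitude
  base <- spec$profile_baseline

  samples <- vector("list", n_samples)
  jb_all <- matrix(0, n_samples, nb)
  for (s in seq_len(n_samples)) {
    jb <- b + if (spec$boundary_jitter_px > 0) {
      runif(nb, -spec$boundary_jitter_px, spec$boundary_jitter_px)
    } else {
      numeric(nb)
    }
    jb_all[s, ] <- jb

    landmark <- rowSums(vapply(
      jb, function(bk) spec$stripe_intensity * exp(-(x - bk)^2 / (2 * sigma^2)),
      numeric(L)
    ))

    # phase within the local inter-boundary interval; outside the landmark
    # span the pattern continues at the nominal period
    idx <- findInterval(x, jb)
    t_ph <- numeric(L)
    inner <- idx >= 1 & idx < nb
    t_ph[inner] <- (x[inner] - jb[idx[inner]]) /
      (jb[pmin(idx[inner] + 1L, nb)] - jb[idx[inner]])
    t_ph[idx == 0] <- (x[idx == 0] - jb[1]) / spec$profile_period_px
    t_ph[idx == nb] <- (x[idx == nb] - jb[nb]) / spec$profile_period_px
    signal <- base + amp * (1 + cos(2 * pi * t_ph)) / 2
    antisignal <- (2 * base + amp) - signal

    tr <- rbind(landmark = landmark, signal = signal, antisignal = antisignal)
    if (spec$noise_sd > 0) {
      tr <- tr + matrix(rnorm(length(tr), 0, spec$noise_sd), nrow(tr), ncol(tr))
    }
    samples[[s]] <- tr
  }
  structure(list(samples = samples, boundaries_px = jb_all),
            class = "profile_samples")
}

#' Write a synthetic embryo to multi-page TIFF plus a ground-truth sidecar
#'
#' Channels are written as one 32-bit float TIFF page each (values clipped to
#' \[0, 1\]); the ground truth is written as JSON next to it.
#'
#' @param embryo a `synthetic_embryo` from [generate_embryo_image()].
#' @param image_path output TIFF path.
#' @param truth_path output JSON path; default replaces the TIFF extension
#'   with `.json`.
#' @return `image_path`, invisibly.
#' @export
write_embryo_tiff <- function(embryo, image_path,
                              truth_path = sub("\\.tiff?$", ".json", image_path)) {
  stopifnot(inherits(embryo, "synthetic_embryo"))
  pages <- lapply(seq_len(dim(embryo$image)[3]), function(ch) {
    p <- embryo$image[, , ch]
    p[p < 0] <- 0
    p[p > 1] <- 1
    p
  })
  tiff::writeTIFF(pages, image_path, bits.per.sample = 32L)
  gt <- embryo$ground_truth
  jsonlite::write_json(
    list(boundary_x_px = gt$boundary_x_px, events = gt$events,
         profile_params = gt$profile_params, seed = embryo$spec$seed),
    truth_path, digits = NA, auto_unbox = TRUE
  )
  invisible(image_path)
}

#' Read a multi-channel (multi-page) TIFF as a numeric array
#'
#' @param path TIFF path; each page becomes one channel.
#' @return numeric array `height x width x n_channels`.
#' @export
read_channels_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
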