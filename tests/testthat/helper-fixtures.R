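# Shared fixtures: small, fast synthetic embryos for unit tests.

# noiseless straight-stripe embryo with a modest number of events
quiet_spec <- function(seed = 1, event_count = 60, ...) {
  embryo_spec(noise_sd = 0, event_count = event_count, seed = seed, ...)
}

# curved-stripe embryo so nearest-boundary distances are genuinely 2D; the
# wiggle period divides the image height so each curve's median x stays at
# its nominal boundary position
curved_spec <- function(seed = 1, event_count = 60, ...) {
  embryo_spec(noise_sd = 0, event_count = event_count,
              stripe_wiggle_amp_px = 6, stripe_wiggle_period_px = 110,
              seed = seed, ...)
}

# brute-force nearest-distance oracle: explicit loop over every skeleton
# pixel, independent of the vectorized implementation path
brute_force_min_dist <- function(x, y, stripe) {
  best <- Inf
  for (j in seq_len(nrow(stripe))) {
    d <- sqrt((x - stripe$x[j])^2 + (y - stripe$y[j])^2)
    if (d < best) best <- d
  }
  best
}

# closed-form pooled-variance two-sample t statistic and p-value
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# build event-record data frames directly from relative positions (for
# histogram tests that do not need the imaging stages)
records_from_rel <- function(rel, y = 50) {
  data.frame(event_id = seq_along(rel), x_px = rel, y_px = y,
             d_anterior_px = rel, d_posterior_px = 100 - rel,
             rel_pos_pct = rel, segment_index = 1L,
             unmappable = FALSE, excluded_midline = FALSE)
}
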