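test_that("generation is bit-reproducible for a fixed spec and seed", {
  spec <- embryo_spec(event_count = 40, midline_fraction = 0.2,
                      noise_sd = 0.05, seed = 11)
  a <- generate_embryo_image(spec)
  b <- generate_embryo_image(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("spec validation rejects inconsistent geometry", {
  expect_error(embryo_spec(boundary_x_px = c(100, 90, 200)), "increasing")
  expect_error(embryo_spec(boundary_x_px = c(100, 105), stripe_width_px = 8),
               "spacing")
  expect_error(embryo_spec(boundary_x_px = c(100), event_count = 10),
               "no segment interior")
  expect_error(embryo_spec(midline_fraction = 1.2), "midline_fraction")
})

test_that("an event-free spec yields a pure-noise event channel", {
  spec <- embryo_spec(event_count = 0, noise_sd = 0.08, seed = 2)
  emb <- generate_embryo_image(spec)
  expect_lt(max(emb$image[, , 2]), spec$stripe_intensity / 2)
  expect_identical(nrow(emb$ground_truth$events), 0L)
})

test_that("stripe channel has one bright component per boundary", {
  emb <- generate_embryo_image(quiet_spec(event_count = 0))
  lab <- segment_stripes(emb$image[, , 1], 0.4)
  expect_identical(nrow(lab$stats), 14L)
})

test_that("sampled intra-segment positions follow the requested distribution", {
  for (dist in list(list(family = "uniform"),
                    list(family = "beta", shape1 = 2, shape2 = 2))) {
    spec <- embryo_spec(event_count = 2000, event_position = dist,
                        noise_sd = 0, seed = 4)
    u <- generate_embryo_image(spec)$ground_truth$events$true_rel_pos
    ks <- if (dist$family == "uniform") {
      suppressWarnings(ks.test(u, punif))$statistic
    } else {
      suppressWarnings(ks.test(u, pbeta, 2, 2))$statistic
    }
    expect_lt(unname(ks), 0.05)
  }
})

test_that("ground truth is internally consistent", {
  spec <- quiet_spec(event_count = 300, seed = 9)
  gt <- generate_embryo_image(spec)$ground_truth
  ev <- gt$events
  expect_identical(nrow(ev), 300L)
  # relative position matches the flanking-boundary formula (straight stripes)
  ant <- gt$boundary_x_px[ev$segment_index]
  post <- gt$boundary_x_px[ev$segment_index + 1L]
  expect_equal(ev$true_rel_pos[!ev$is_midline],
               ((ev$x_px - ant) / (post - ant))[!ev$is_midline], tolerance = 1e-12)
  # all centers strictly inside the image and inside the landmark span
  expect_true(all(ev$x_px > 1 & ev$x_px < spec$image_width_px))
  expect_true(all(ev$y_px > 1 & ev$y_px < spec$image_height_px))
  expect_true(all(ev$x_px >= min(gt$boundary_x_px) &
                  ev$x_px <= max(gt$boundary_x_px)))
  expect_false(any(ev$is_midline)) # midline_fraction = 0
})

test_that("midline events are flagged and sown across the full A/P span", {
  spec <- quiet_spec(event_count = 500, midline_fraction = 0.3, seed = 6)
  ev <- generate_embryo_image(spec)$ground_truth$events
  H <- spec$image_height_px
  band_half <- 0.3 * (H - 1) / 2
  in_band <- abs(ev$y_px - (1 + H) / 2) <= band_half
  expect_identical(ev$is_midline, in_band)
  expect_gt(sum(ev$is_midline), 0)
})

test_that("profile samples are deterministic and degrade gracefully", {
  spec <- embryo_spec(noise_sd = 0, boundary_jitter_px = 0, seed = 3)
  s <- generate_profile_samples(spec, 3)
  expect_identical(s$samples[[1]], s$samples[[2]])
  expect_identical(s$samples[[1]], s$samples[[3]])

  flat <- embryo_spec(noise_sd = 0, profile_peak_amplitude = 0, seed = 3)
  tr <- generate_profile_samples(flat, 1)$samples[[1]]
  expect_equal(unname(tr["signal", ]),
               rep(flat$profile_baseline, flat$image_width_px))

  expect_error(generate_profile_samples(spec, 0), "n_samples")
})

test_that("landmark peaks track the per-sample jittered boundaries", {
  spec <- embryo_spec(noise_sd = 0.01, boundary_jitter_px = 4, seed = 8)
  s <- generate_profile_samples(spec, 10)
  for (i in seq_len(10)) {
    lm <- s$samples[[i]]["landmark", ]
    for (b in s$boundaries_px[i, ]) {
      win <- max(1, round(b) - 10):min(length(lm), round(b) + 10)
      expect_lte(abs(win[which.max(lm[win])] - b), 1)
    }
  }
})

test_that("tiff round trip preserves channels and ground truth sidecar", {
  spec <- quiet_spec(event_count = 20, seed = 12, image_height_px = 80,
                     image_width_px = 400, n_segments = 6,
                     boundary_spacing_px = 60)
  emb <- generate_embryo_image(spec)
  path <- withr::local_tempfile(fileext = ".tif")
  write_embryo_tiff(emb, path)
  img <- read_channels_tiff(path)
  expect_identical(dim(img), dim(emb$image))
  expect_equal(img, emb$image, tolerance = 1e-6)
  gt <- jsonlite::read_json(sub("\\.tif$", ".json", path), simplifyVector = TRUE)
  expect_equal(gt$boundary_x_px, emb$ground_truth$boundary_x_px)
  expect_equal(nrow(gt$events), 20)
})
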