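test_that("ROI extraction averages rows and respects bounds", {
  img <- array(0.7, dim = c(40, 60, 2))
  pr <- extract_profile(img, list(x0 = 5, y0 = 3, width_px = 20, height_px = 30))
  expect_equal(dim(pr$traces), c(2, 20))
  expect_true(all(pr$traces == 0.7))

  img[, 33, 1] <- 5
  pr2 <- extract_profile(img, list(x0 = 1, y0 = 1, width_px = 60, height_px = 40))
  expect_identical(which.max(pr2$traces[1, ]), 33L)

  expect_error(extract_profile(img, list(x0 = 50, y0 = 1, width_px = 20,
                                         height_px = 10)), "bounds")
})

test_that("ROI landmark trace peaks at boundaries of the synthetic embryo", {
  spec <- quiet_spec(event_count = 0, seed = 5)
  emb <- generate_embryo_image(spec)
  pr <- extract_profile(emb$image, list(x0 = 1, y0 = 1,
                                        width_px = spec$image_width_px,
                                        height_px = spec$image_height_px))
  pk <- detect_landmark_peaks(pr$traces[1, ], min_separation_px = 30,
                              min_prominence = 0.2)
  expect_length(pk, 14)
  expect_true(all(abs(pk - spec$boundary_x_px) <= 2))
})

test_that("peak detection finds cosine maxima and rejects monotone traces", {
  T <- 50
  x <- seq_len(4 * T)
  tr <- cos(2 * pi * (x - T / 2) / T) # interior peaks at T/2 + k*T
  pk <- detect_landmark_peaks(tr, min_separation_px = T / 2,
                              min_prominence = 0.5, smooth_window_px = 1)
  expect_length(pk, 4)
  expect_true(all(abs(pk - (T / 2 + (0:3) * T)) <= 1))

  expect_error(detect_landmark_peaks(seq(0, 1, length.out = 100), 10, 0.1),
               "cannot register")
})

test_that("registration reproduces analytic vectors on simple traces", {
  const <- register_profiles(rep(2.5, 200), peaks = c(20, 90, 180),
                             bins_per_segment = 50)
  expect_equal(unname(const[1, ]), rep(2.5, 100))

  lin <- register_profiles(as.numeric(0:200), peaks = c(1, 101),
                           bins_per_segment = 50)
  expect_equal(unname(lin[1, ]), seq(0, 98, by = 2))

  expect_error(register_profiles(rep(1, 100), peaks = c(50, 50)), "peaks")
  expect_error(register_profiles(rep(1, 100), peaks = 50), "cannot register")
})

test_that("registration is invariant to uniform x-axis stretching", {
  x <- seq_len(300)
  tr <- sin(x / 17) + 0.3 * cos(x / 5)
  pk <- c(40, 120, 260)
  ref <- register_profiles(tr, pk)

  s <- 3L
  xs <- seq_len(300 * s)
  trs <- approx(x * s, tr, xout = xs, rule = 2)$y
  stretched <- register_profiles(trs, pk * s)
  expect_equal(unname(stretched), unname(ref), tolerance = 0.01)
})

test_that("jittered-peak samples register with <= 1 bin phase offset", {
  spec <- embryo_spec(noise_sd = 0, boundary_jitter_px = 5, seed = 31)
  s <- generate_profile_samples(spec, 8)
  for (i in seq_len(8)) {
    pk <- detect_landmark_peaks(s$samples[[i]]["landmark", ],
                                min_separation_px = 30, min_prominence = 0.2)
    reg <- register_profiles(s$samples[[i]], pk, bins_per_segment = 50)
    nseg <- attr(reg, "n_segments")
    sig <- reg["signal", ]
    for (g in seq_len(nseg)) {
      block <- sig[(g - 1) * 50 + seq_len(50)]
      # signal peaks at the segment's anterior boundary = bin 1; the peak may
      # wrap to the last bin when the registered grid sits 1 bin early
      expect_true(which.max(block) %in% c(1L, 2L, 50L))
    }
  }
})

test_that("averaging returns per-bin mean and SEM with the two-point formula", {
  a <- matrix(0, 1, 100); b <- matrix(2, 1, 100)
  attr(a, "bins_per_segment") <- attr(b, "bins_per_segment") <- 50L
  attr(a, "n_segments") <- attr(b, "n_segments") <- 2L
  avg <- average_registered(list(a, b))
  expect_equal(unname(avg$mean[1, ]), rep(1, 100))
  expect_equal(unname(avg$sem[1, ]), rep(1, 100))

  same <- average_registered(list(b, b))
  expect_equal(unname(same$sem[1, ]), rep(0, 100))

  expect_error(average_registered(list(a)), "at least 2")
})

test_that("per-bin SEM scales with noise over many samples", {
  sigma <- 0.05
  spec <- embryo_spec(noise_sd = sigma, boundary_jitter_px = 0, seed = 13)
  s <- generate_profile_samples(spec, 10)
  regs <- lapply(s$samples, function(tr) {
    pk <- detect_landmark_peaks(tr["landmark", ], 30, 0.2)
    register_profiles(tr, pk)
  })
  nseg <- min(vapply(regs, function(r) attr(r, "n_segments"), integer(1)))
  regs <- lapply(regs, function(r) r[, seq_len(nseg * 50), drop = FALSE])
  avg <- average_registered(regs)
  med_sem <- median(avg$sem["signal", ])
  expect_gt(med_sem, 0.5 * sigma / sqrt(10))
  expect_lt(med_sem, 1.5 * sigma / sqrt(10))
})

test_that("mean of registered samples equals registration of the mean (linearity)", {
  x <- seq_len(200)
  pk <- c(30, 110, 190)
  trs <- lapply(1:4, function(k) k * sin(x / 20))
  regs <- lapply(trs, register_profiles, peaks = pk)
  mean_of_regs <- Reduce(`+`, regs) / 4
  reg_of_mean <- register_profiles(Reduce(`+`, trs) / 4, peaks = pk)
  expect_equal(unname(mean_of_regs), unname(reg_of_mean), tolerance = 1e-12)
})

test_that("anticorrelated channels stay anticorrelated after registration", {
  spec <- embryo_spec(noise_sd = 0.02, boundary_jitter_px = 3, seed = 17)
  res <- run_profile_pipeline(run_config(spec = spec, n_profile_samples = 8,
                                         seed = 17))
  r <- cor(res$profile$mean["signal", ], res$profile$mean["antisignal", ])
  expect_lte(r, -0.9)
})
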