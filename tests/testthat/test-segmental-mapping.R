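make_skeleton <- function(xs, H = 100) {
  structure(list(
    stripes = lapply(xs, function(x) data.frame(x = x, y = seq_len(H))),
    median_x = as.numeric(xs), source_image_id = "fixture"
  ), class = "boundary_skeleton")
}

test_that("boundary ordering sorts by median x and rejects degenerate input", {
  sk <- make_skeleton(c(150, 30, 90))
  ord <- order_boundaries(sk)
  expect_equal(ord$median_x, c(30, 90, 150))

  expect_error(order_boundaries(make_skeleton(100)), "cannot define a segment")
  expect_error(order_boundaries(make_skeleton(c(100, 100.5))),
               "ambiguous boundary order")
})

test_that("events map to the linear segmental coordinate for straight boundaries", {
  sk <- make_skeleton(c(100, 200, 300))
  ev <- data.frame(x_px = c(150, 100, 250, 50, 320),
                   y_px = c(40, 50, 60, 50, 50))
  rec <- map_events(ev, sk)
  expect_equal(rec$rel_pos_pct[1], 50)           # mid-segment symmetry
  expect_equal(rec$rel_pos_pct[2], 0)            # exactly on a boundary pixel
  expect_identical(rec$segment_index[2], 1L)     # anterior edge of segment behind it
  expect_equal(rec$rel_pos_pct[3], 50)
  expect_identical(rec$segment_index[3], 2L)
  expect_true(rec$unmappable[4])                 # anterior of first boundary
  expect_true(rec$unmappable[5])                 # posterior of last boundary
  expect_true(all(rec$rel_pos_pct[!rec$unmappable] >= 0 &
                  rec$rel_pos_pct[!rec$unmappable] <= 100))
})

test_that("distances on curved skeletons equal the exhaustive pixel-scan oracle", {
  spec <- curved_spec(event_count = 80, seed = 7)
  emb <- generate_embryo_image(spec)
  sk <- skeletonize_stripes(segment_stripes(emb$image[, , 1], 0.4))
  det <- detect_events(emb$image[, , 2], 0.45)
  rec <- map_events(det, sk)
  ord <- order_boundaries(sk)
  for (i in which(!rec$unmappable)) {
    s <- rec$segment_index[i]
    expect_equal(rec$d_anterior_px[i],
                 brute_force_min_dist(rec$x_px[i], rec$y_px[i], ord$stripes[[s]]),
                 tolerance = 1e-9)
    expect_equal(rec$d_posterior_px[i],
                 brute_force_min_dist(rec$x_px[i], rec$y_px[i], ord$stripes[[s + 1]]),
                 tolerance = 1e-9)
  }
})

test_that("relative position recovers ground truth within the pixel bound", {
  # overlap-free fixture: merged disks would break the event <-> truth match
  spec <- quiet_spec(event_count = 25, seed = 41, image_width_px = 1200,
                     boundary_spacing_px = 80, image_height_px = 300)
  emb <- generate_embryo_image(spec)
  sk <- skeletonize_stripes(segment_stripes(emb$image[, , 1], 0.4))
  det <- detect_events(emb$image[, , 2], 0.45)
  rec <- map_events(det, sk)
  gt <- emb$ground_truth$events
  d <- as.matrix(dist(cbind(gt$x_px, gt$y_px)))
  diag(d) <- Inf
  expect_gt(min(d), 2 * spec$event_radius_px)
  seg_w <- diff(spec$boundary_x_px)[1]
  # match detected centroids to ground-truth events by position
  for (i in which(!rec$unmappable)) {
    j <- which.min((gt$x_px - rec$x_px[i])^2 + (gt$y_px - rec$y_px[i])^2)
    expect_lte(abs(rec$rel_pos_pct[i] / 100 - gt$true_rel_pos[j]), 2 / seg_w)
  }
})

test_that("midline exclusion matches the generator band exactly", {
  spec <- quiet_spec(event_count = 400, midline_fraction = 0.2, seed = 18)
  emb <- generate_embryo_image(spec)
  gt <- emb$ground_truth$events
  sk <- skeletonize_stripes(segment_stripes(emb$image[, , 1], 0.4))
  rec <- map_events(gt, sk)
  rec <- exclude_midline(rec, 1, spec$image_height_px, 0.2)
  expect_identical(rec$excluded_midline, gt$is_midline)
})

test_that("midline exclusion limits and errors behave as specified", {
  rec <- records_from_rel(c(10, 50, 90), y = c(10, 50, 90))
  expect_false(any(exclude_midline(rec, 1, 100, 0)$excluded_midline))
  expect_true(all(exclude_midline(rec, 1, 100, 1)$excluded_midline))
  expect_error(exclude_midline(rec, 1, 100, 1.5), "fraction")
  expect_error(exclude_midline(rec, 100, 1, 0.2), "dv_min")
})

test_that("every event is retained, midline-excluded or unmappable", {
  spec <- quiet_spec(event_count = 120, midline_fraction = 0.25, seed = 23)
  res <- run_mapping_pipeline(run_config(spec = spec, n_embryos = 2,
                                         midline_fraction = 0.25, seed = 23))
  with(res$counts, {
    expect_identical(retained + midline_excluded + unmappable, detected)
    expect_identical(mapped, detected - unmappable)
  })
})

test_that("histogram tabulation matches hand counts and pools embryos", {
  h <- tabulate_histogram(list(records_from_rel(c(10, 10, 90))),
                          n_bins = 10, normalize = "count")
  expect_equal(h$per_embryo_counts[1, ], c(0, 2, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(h$sd, rep(NA_real_, 10)) # single embryo: sd undefined

  two <- list(records_from_rel(c(5, 55, 95)), records_from_rel(c(5, 55, 95)))
  h2 <- tabulate_histogram(two, n_bins = 10)
  expect_equal(h2$sd, rep(0, 10))
  expect_equal(rowSums(h2$per_embryo_counts), c(3, 3))

  expect_error(tabulate_histogram(list()), "zero embryos")
  expect_error(tabulate_histogram(two, n_bins = 1), "n_bins")
})

test_that("beta(2,2) positions produce a mid-segment-peaked histogram", {
  set.seed(99)
  recs <- lapply(1:20, function(i) records_from_rel(100 * rbeta(500, 2, 2)))
  h <- tabulate_histogram(recs, n_bins = 10)
  mf <- h$mean_frequency
  expect_gt(min(mf[5:6]), max(mf[c(1, 10)]))  # center exceeds edges
  # non-increasing from the center toward both edges, within sampling noise
  expect_true(all(diff(mf[1:5]) > -0.01))
  expect_true(all(diff(mf[6:10]) < 0.01))
})

test_that("group comparison reproduces the pooled-variance t test", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- compare_mean_intensity(a, b)
  oracle <- pooled_t_oracle(a, b)
  expect_equal(res$t, oracle$t, tolerance = 1e-9)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(round(res$t, 3), -3.674)
  expect_equal(round(res$p_value, 3), 0.021)

  same <- compare_mean_intensity(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  scaled <- compare_mean_intensity(3.7 * a, 3.7 * b)
  expect_equal(scaled$t, res$t, tolerance = 1e-12)
  expect_equal(scaled$p_value, res$p_value, tolerance = 1e-12)

  expect_error(compare_mean_intensity(1, c(1, 2)), "at least 2")
})
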