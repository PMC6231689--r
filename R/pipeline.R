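#' Build a run configuration for the pipelines
#'
#' Collects every parameter of the end-to-end runs. Either a synthetic batch
#' (`n_embryos` embryos generated from `spec` with per-embryo seeds derived
#' from `seed`) or a list of input TIFF paths (`images`, with channel roles
#' in `channels`) can be analysed.
#'
#' @param spec an [embryo_spec()] used for synthetic input (ignored when
#'   `images` is given).
#' @param n_embryos number of synthetic embryos in the batch.
#' @param images optional character vector of multi-page TIFF paths.
#' @param channels named list mapping roles to page indices, e.g.
#'   `list(landmark = 1, event = 2)`.
#' @param stripe_threshold,event_threshold intensity thresholds; defaults
#'   are half the generator's stripe/event intensity.
#' @param stripe_min_area_px,event_min_area_px,event_max_area_px component
#'   area filters.
#' @param prune_length_px skeleton spur-pruning length.
#' @param midline_fraction D-V fraction excluded around the midline.
#' @param n_bins histogram bin count on \[0, 100\]%.
#' @param normalize `"fraction"` or `"count"` histogram averaging.
#' @param n_profile_samples number of profile samples for the profile
#'   pipeline.
#' @param bins_per_segment registration bins per segment.
#' @param min_separation_px,min_prominence,smooth_window_px landmark peak
#'   detection parameters; `min_separation_px` defaults to half the profile
#'   period.
#' @param out_dir optional output directory; when set, the pipelines write
#'   CSV/JSON artifacts there.
#' @param seed master seed; all per-embryo and per-sample streams derive
#'   from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(spec = embryo_spec(), n_embryos = 1L,
                       images = NULL, channels = list(landmark = 1L, event = 2L),
                       stripe_threshold = spec$stripe_intensity / 2,
                       event_threshold = spec$event_intensity / 2,
                       stripe_min_area_px = 20L, event_min_area_px = 4L,
                       event_max_area_px = Inf, prune_length_px = 10L,
                       midline_fraction = 0.20, n_bins = 10L,
                       normalize = "fraction",
                       n_profile_samples = 10L, bins_per_segment = 50L,
                       min_separation_px = spec$profile_period_px / 2,
                       min_prominence = spec$stripe_intensity / 4,
                       smooth_window_px = 5L,
                       out_dir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; an optional `spec` block
#' is passed to [embryo_spec()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$spec)) y$spec <- do.call(embryo_spec, y$spec)
  do.call(run_config, y)
}

#' Run the event-mapping pipeline end to end
#'
#' Generates (or reads) each embryo image, segments and skeletonizes the
#' landmark stripes, detects events, maps them into normalized segmental
#' coordinates, excludes the ventral-midline band and tabulates the
#' cross-embryo histogram of apoptosis frequency along the segmental A/P
#' axis. Runs are deterministic given the configuration: embryo `i` of a
#' synthetic batch uses seed `config$seed + i - 1`.
#'
#' @param config a [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return A list of class `mapping_result`: `records` (per-embryo list of
#'   event-record data frames), `histogram` (an `apoptosis_histogram`),
#'   `counts` (detected / mapped / midline_excluded / unmappable /
#'   retained totals, satisfying detected = retained + midline_excluded +
#'   unmappable), `config`. When `config$out_dir` is set, writes
#'   `events.csv`, `histogram.csv` and `summary.json` there.
#' @export
run_mapping_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  images <- if (!is.null(config$images)) {
    lapply(config$images, read_channels_tiff)
  } else {
    lapply(seq_len(config$n_embryos), function(i) {
      sp <- config$spec
      sp$seed <- config$seed + i - 1L
      generate_embryo_image(sp)$image
    })
  }

  records <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    lm_ch <- img[, , config$channels$landmark]
    ev_ch <- img[, , config$channels$event]
    skel <- skeletonize_stripes(
      segment_stripes(lm_ch, config$stripe_threshold, config$stripe_min_area_px),
      config$prune_length_px, source_image_id = as.character(i)
    )
    ev <- detect_events(ev_ch, config$event_threshold, config$event_min_area_px,
                        config$event_max_area_px, source_image_id = as.character(i))
    rec <- map_events(ev, skel)
    rec <- exclude_midline(rec, 1, nrow(lm_ch), config$midline_fraction)
    rec$embryo <- rep(i, nrow(rec))
    records[[i]] <- rec
  }

  histogram <- tabulate_histogram(records, config$n_bins, config$normalize)
  all_rec <- do.call(rbind, records)
  counts <- list(
    detected = nrow(all_rec),
    unmappable = sum(all_rec$unmappable),
    midline_excluded = sum(all_rec$excluded_midline & !all_rec$unmappable),
    retained = sum(!all_rec$unmappable & !all_rec$excluded_midline)
  )
  counts$mapped <- counts$detected - counts$unmappable

  result <- structure(
    list(records = records, histogram = histogram, counts = counts,
         config = config),
    class = "mapping_result"
  )
  if (!is.null(config$out_dir)) write_mapping_result(result, config$out_dir)
  result
}

write_mapping_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_rec <- do.call(rbind, result$records)
  write.csv(all_rec, file.path(out_dir, "events.csv"), row.names = FALSE)
  h <- result$histogram
  write.csv(
    data.frame(bin_start_pct = h$bin_edges_pct[-length(h$bin_edges_pct)],
               bin_end_pct = h$bin_edges_pct[-1],
               mean_frequency = h$mean_frequency, sd = h$sd),
    file.path(out_dir, "histogram.csv"), row.names = FALSE
  )
  cfg <- result$config
  cfg$spec <- unclass(cfg$spec)
  jsonlite::write_json(
    list(counts = result$counts, n_embryos = length(result$records),
         normalize = h$normalize, seed = result$config$seed,
         config = cfg[setdiff(names(cfg), "images")]),
    file.path(out_dir, "summary.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(out_dir)
}

#' Run the profile-registration pipeline end to end
#'
#' Generates `config$n_profile_samples` synthetic profile samples (or
#' extracts traces from `config$images` with a full-height ROI), detects
#' landmark peaks per sample, registers every channel to the peaks on a
#' fixed per-segment grid and averages across samples with SEM. A sample
#' whose landmark trace cannot be registered (e.g. fewer than two peaks) is
#' reported as failed and skipped; the batch fails only if fewer than two
#' samples register.
#'
#' @param config a [run_config()].
#' @param extra_samples optional list of additional trace matrices
#'   (`n_channels x length`, landmark channel first) appended to the batch;
#'   used to exercise per-sample failure handling.
#' @return A list of class `profile_result`: `profile` (a
#'   `registered_profile`), `n_registered`, `failed` (integer indices of
#'   failed samples), `config`. When `config$out_dir` is set, writes
#'   `profile_long.csv` (sample, channel, segment, bin, value) and
#'   `profile_summary.csv` (channel, bin_global, mean, sem).
#' @export
run_profile_pipeline <- function(config, extra_samples = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  sp <- config$spec
  sp$seed <- config$seed
  traces <- if (!is.null(config$images)) {
    lapply(config$images, function(p) {
      img <- read_channels_tiff(p)
      pr <- extract_profile(img, list(x0 = 1, y0 = 1, width_px = dim(img)[2],
                                      height_px = dim(img)[1]))
      pr$traces
    })
  } else {
    generate_profile_samples(sp, config$n_profile_samples)$samples
  }
  if (!is.null(extra_samples)) traces <- c(traces, extra_samples)

  registered <- list()
  failed <- integer(0)
  for (i in seq_along(traces)) {
    res <- tryCatch({
      pk <- detect_landmark_peaks(traces[[i]][1L, ], config$min_separation_px,
                                  config$min_prominence, config$smooth_window_px)
      register_profiles(traces[[i]], pk, config$bins_per_segment)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
      message(sprintf("sample %d failed to register: %s", i, conditionMessage(res)))
    } else {
      registered[[length(registered) + 1L]] <- res
    }
  }
  if (length(registered) < 2L) {
    stop("fewer than 2 samples registered; cannot average", call. = FALSE)
  }
  # registration can yield different segment counts per sample (extra or
  # missed peaks); average over the common leading segments
  nseg <- min(vapply(registered, function(r) attr(r, "n_segments"), integer(1)))
  B <- attr(registered[[1L]], "bins_per_segment")
  registered <- lapply(registered, function(r) {
    out <- r[, seq_len(nseg * B), drop = FALSE]
    attr(out, "bins_per_segment") <- B
    attr(out, "n_segments") <- nseg
    out
  })
  profile <- average_registered(registered)

  result <- structure(
    list(profile = profile, n_registered = length(registered), failed = failed,
         config = config),
    class = "profile_result"
  )
  if (!is.null(config$out_dir)) write_profile_result(result, registered, config$out_dir)
  result
}

write_profile_result <- function(result, registered, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- result$profile
  B <- p$bins_per_segment
  long <- do.call(rbind, lapply(seq_along(registered), function(s) {
    r <- registered[[s]]
    chn <- rownames(r)
    if (is.null(chn)) chn <- paste0("ch", seq_len(nrow(r)))
    do.call(rbind, lapply(seq_len(nrow(r)), function(ch) {
      bin_global <- seq_len(ncol(r))
      data.frame(sample_id = s, channel = chn[ch],
                 segment = (bin_global - 1L) %/% B + 1L,
                 bin = (bin_global - 1L) %% B + 1L,
                 value = r[ch, ])
    }))
  }))
  write.csv(long, file.path(out_dir, "profile_long.csv"), row.names = FALSE)
  chn <- rownames(p$mean)
  if (is.null(chn)) chn <- paste0("ch", seq_len(nrow(p$mean)))
  summ <- do.call(rbind, lapply(seq_len(nrow(p$mean)), function(ch) {
    data.frame(channel = chn[ch], bin_global = seq_len(ncol(p$mean)),
               mean = p$mean[ch, ], sem = p$sem[ch, ])
  }))
  write.csv(summ, file.path(out_dir, "profile_summary.csv"), row.names = FALSE)
  invisible(out_dir)
}
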