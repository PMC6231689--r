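#' Segment boundary stripes by thresholding and connected components
#'
#' Thresholds the landmark channel and labels 8-connected components,
#' discarding those smaller than `min_area_px`. Components are relabelled
#' 1..K in order of increasing median x, i.e. anterior to posterior. This is
#' a deterministic stand-in for interactive pixel classification: a single
#' global threshold plus connected components is sufficient for stripe
#' landmarks whose intensity is well separated from background.
#'
#' @param stripe_channel 2D numeric matrix (rows = y, cols = x).
#' @param intensity_threshold pixels strictly above this value are
#'   foreground.
#' @param min_area_px minimum component area in pixels.
#' @return A list of class `stripe_labels`: `labels` (integer matrix, 0 =
#'   background) and `stats` (data frame `label`, `area_px`, `median_x`).
#' @export
segment_stripes <- function(stripe_channel, intensity_threshold, min_area_px = 20L) {
  stopifnot(is.matrix(stripe_channel), all(is.finite(stripe_channel)))
  mask <- stripe_channel > intensity_threshold
  lab <- .label_cc8(mask)
  if (max(lab) == 0L) stop("no landmarks found", call. = FALSE)

  tab <- tabulate(lab[lab > 0L])
  keep <- which(tab >= min_area_px)
  if (length(keep) == 0L) stop("no landmarks found", call. = FALSE)

  # median x per kept component, then relabel anterior -> posterior
  idx <- which(lab > 0L)
  labs <- lab[idx]
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  med_x <- vapply(keep, function(l) stats::median(cols[labs == l]), numeric(1))
  ord <- order(med_x)
  keep <- keep[ord]
  med_x <- med_x[ord]

  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  structure(
    list(labels = out,
         stats = data.frame(label = seq_along(keep), area_px = tab[keep],
                            median_x = med_x)),
    class = "stripe_labels"
  )
}

#' Skeletonize labelled stripes to single-pixel boundary curves
#'
#' Reduces each labelled stripe to a one-pixel-wide medial curve by
#' Zhang-Suen thinning, then prunes side branches (spurs) shorter than
#' `prune_length_px` so that the result is a simple 8-connected curve with
#' no branch points. Components that thin to an empty set are dropped with a
#' warning. Applying the operation to an already single-pixel curve returns
#' it unchanged.
#'
#' @param stripe_labels a `stripe_labels` object from [segment_stripes()],
#'   or an integer label matrix.
#' @param prune_length_px spurs with fewer pixels than this are removed.
#' @param source_image_id optional identifier carried through to outputs.
#' @return An object of class `boundary_skeleton`: `stripes` (list of data
#'   frames `x`, `y`, one per curve, ordered anterior to posterior),
#'   `median_x` (numeric vector) and `source_image_id`.
#' @export
skeletonize_stripes <- function(stripe_labels, prune_length_px = 10L,
                                source_image_id = NA_character_) {
  lab <- if (inherits(stripe_labels, "stripe_labels")) stripe_labels$labels else stripe_labels
  stopifnot(is.matrix(lab))
  n <- max(lab)
  if (n < 1L) stop("no labelled components to skeletonize", call. = FALSE)

  stripes <- list()
  for (k in seq_len(n)) {
    sk <- .thin_zhang_suen(lab == k)
    sk <- unit_width_cleanup(sk)
    sk <- prune_spurs(sk, prune_length_px)
    sk <- unit_width_cleanup(sk)
    if (!any(sk)) {
      warning(sprintf("component %d skeletonized to an empty set; dropped", k))
      next
    }
    idx <- which(sk)
    stripes[[length(stripes) + 1L]] <- data.frame(
      x = ((idx - 1L) %/% nrow(sk)) + 1L,
      y = ((idx - 1L) %% nrow(sk)) + 1L
    )
  }
  if (length(stripes) == 0L) stop("all components skeletonized to empty sets", call. = FALSE)
  med_x <- vapply(stripes, function(s) stats::median(s$x), numeric(1))
  ord <- order(med_x)
  structure(
    list(stripes = stripes[ord], median_x = med_x[ord],
         source_image_id = source_image_id),
    class = "boundary_skeleton"
  )
}

# Remove skeletal spurs: walk inward from each endpoint (pixel with one
# 8-neighbour); if a branch point (>= 3 neighbours) is reached in fewer than
# prune_length_px steps the walked pixels are deleted. A simple open curve
# has no branch points and is returned untouched. Repeats until stable.
prune_spurs <- function(sk, prune_length_px) {
  if (prune_length_px <= 0) return(sk)
  repeat {
    nb <- neighbor_count(sk)
    ends <- which(sk & nb == 1L)
    branch <- sk & nb >= 3L
    if (length(ends) == 0L || !any(branch)) return(sk)
    nr <- nrow(sk)
    removed_any <- FALSE
    for (e in ends) {
      # walk from the endpoint toward the interior; stop at a branch pixel
      path <- e
      repeat {
        nxt <- setdiff(neighbors_of(path[length(path)], sk, nr), path)
        if (any(branch[nxt])) {
          # spur terminates at a branch point: delete it if short
          if (length(path) < prune_length_px) {
            sk[path] <- FALSE
            removed_any <- TRUE
          }
          break
        }
        if (length(nxt) == 0L || length(path) >= prune_length_px) break
        path <- c(path, nxt[1L])
      }
    }
    if (!removed_any) return(sk)
  }
}

# Reduce a thinned curve to strict unit width: thinning can leave staircase
# pixels with 3+ skeletal neighbours even though no real branch exists. A
# pixel is redundant when its foreground neighbours form a single
# 8-connected component among themselves, so removing it cannot disconnect
# the curve. Redundant pixels with 3+ neighbours are removed until stable.
unit_width_cleanup <- function(sk) {
  nr <- nrow(sk)
  repeat {
    nb <- neighbor_count(sk)
    over <- sk & nb >= 3L
    if (!any(over)) return(sk)
    # removal candidates: the violating pixels and their skeletal neighbours
    cand <- unique(c(which(over),
                     unlist(lapply(which(over), neighbors_of, m = sk, nr = nr))))
    cand <- cand[order(nb[cand], decreasing = TRUE)]
    removed <- FALSE
    for (p in cand) {
      if (!sk[p]) next
      ns <- neighbors_of(p, sk, nr)
      if (length(ns) < 2L) next # never remove endpoints
      if (!any(nb[ns] >= 3L) && nb[p] < 3L) next # only act near violations
      if (ring_components(ns, nr) == 1L) {
        sk[p] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) return(sk)
  }
}

# number of 8-connected components among a set of pixels (linear indices)
ring_components <- function(idx, nr) {
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  n <- length(idx)
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(r[i] - r[j]) <= 1L && abs(c[i] - c[j]) <= 1L) {
      old <- comp[j]; new <- comp[i]
      comp[comp == old] <- new
    }
  }
  length(unique(comp))
}

# count of TRUE 8-neighbours for every pixel (matrix of same shape)
neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  acc
}

# linear indices of TRUE 8-neighbours of linear index i
neighbors_of <- function(i, m, nr) {
  r <- ((i - 1L) %% nr) + 1L
  c <- ((i - 1L) %/% nr) + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1L && rr <= nr && cc >= 1L && cc <= ncol(m) && m[rr, cc]) {
      out <- c(out, (cc - 1L) * nr + rr)
    }
  }
  out
}

#' Detect punctate events and reduce them to centroid points
#'
#' Thresholds the event channel, labels 8-connected components, retains
#' those with area in `[min_area_px, max_area_px]` and reduces each to its
#' centroid rounded to the nearest pixel. Zero events is a valid, empty
#' result. The centroid (rather than e.g. the brightest pixel) is used as
#' the stable single-pixel representation of each apoptotic figure.
#'
#' @param event_channel 2D numeric matrix.
#' @param intensity_threshold pixels strictly above this value are
#'   foreground.
#' @param min_area_px,max_area_px retained component area range; the default
#'   `min_area_px = 4` rejects single-pixel noise.
#' @param source_image_id optional identifier.
#' @return A data frame of class `event_set` with columns `event_id`,
#'   `x_px`, `y_px`, `area_px`.
#' @export
detect_events <- function(event_channel, intensity_threshold, min_area_px = 4L,
                          max_area_px = Inf, source_image_id = NA_character_) {
  stopifnot(is.matrix(event_channel))
  lab <- .label_cc8(event_channel > intensity_threshold)
  empty <- data.frame(event_id = integer(0), x_px = integer(0),
                      y_px = integer(0), area_px = integer(0))
  if (max(lab) == 0L) return(structure(empty, class = c("event_set", "data.frame"),
                                       source_image_id = source_image_id))
  tab <- tabulate(lab[lab > 0L])
  keep <- which(tab >= min_area_px & tab <= max_area_px)
  if (length(keep) == 0L) return(structure(empty, class = c("event_set", "data.frame"),
                                           source_image_id = source_image_id))
  idx <- which(lab > 0L)
  labs <- lab[idx]
  nr <- nrow(lab)
  cols <- ((idx - 1L) %/% nr) + 1L
  rows <- ((idx - 1L) %% nr) + 1L
  cx <- vapply(keep, function(l) round(mean(cols[labs == l])), numeric(1))
  cy <- vapply(keep, function(l) round(mean(rows[labs == l])), numeric(1))
  ord <- order(cx, cy)
  out <- data.frame(event_id = seq_along(keep), x_px = as.integer(cx[ord]),
                    y_px = as.integer(cy[ord]), area_px = tab[keep][ord])
  structure(out, class = c("event_set", "data.frame"),
            source_image_id = source_image_id)
}
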