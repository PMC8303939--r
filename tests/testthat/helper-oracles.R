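# Independent brute-force oracles and small fixture builders.
# Oracles deliberately re-derive each quantity from first principles
# (naive loops, pair enumeration) so they share no code with the
# implementation they check.

# Small, fast acquisition grid with the same voxel pitch as the
# cohort-scale grid (0.52 cm), so ROI rasterization behaves identically.
fast_geometry <- function() scan_geometry(n_slices = 9, matrix = 48,
                                          fov_cm = 25)

fast_session <- function(seed = 1, motion = 0.1, ...) {
  simulate_session(seed = seed, geometry = fast_geometry(),
                   air_motion_fraction = motion, air_volume_ml = 60, ...)
}

# Exhaustive evaluation of the exclusion objective G(p): for every grid
# candidate, loop over scans and locations, filter ROI voxels by the
# plain rule, and average absolute disagreements with the probe means.
oracle_g_curve <- function(series, rois, probes, grid,
                           scan_duration_s = series$scan_duration_s,
                           max_offset_s = 150) {
  pm <- aggregate(temp_C ~ location + time_s, data = probes, FUN = mean)
  cyc <- sort(unique(pm$time_s))
  G <- numeric(length(grid))
  for (k in seq_along(grid)) {
    p <- grid[k]
    diffs <- c()
    for (n in seq_along(series$maps)) {
      mid <- series$scan_times_s[n] + scan_duration_s / 2
      ci <- cyc[which.min(abs(cyc - mid))]
      if (abs(ci - mid) > max_offset_s) next
      for (loc in unique(rois$location)) {
        rv <- rois[rois$location == loc, ]
        vals <- c()
        for (r in seq_len(nrow(rv))) {
          if (series$valid[[n]][rv$ix[r], rv$iy[r], rv$slice[r]]) {
            vals <- c(vals, series$maps[[n]][rv$ix[r], rv$iy[r],
                                             rv$slice[r]])
          }
        }
        vals <- vals[abs(vals) <= p]
        if (length(vals) == 0) next
        probe <- pm$temp_C[pm$location == loc & pm$time_s == ci]
        diffs <- c(diffs, abs(mean(vals) - probe))
      }
    }
    G[k] <- if (length(diffs) > 0) mean(diffs) else Inf
  }
  G
}

# Mann-Whitney AUC by exhaustive pair enumeration (ties count 1/2).
oracle_auc_pairs <- function(scores, labels,
                             orientation = "higher_is_positive") {
  s <- if (orientation == "higher_is_positive") scores else -scores
  pos <- s[as.logical(labels)]
  neg <- s[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# ROC operating points by exhaustive threshold enumeration.
oracle_roc_points <- function(scores, labels,
                              orientation = "higher_is_positive") {
  s <- if (orientation == "higher_is_positive") scores else -scores
  l <- as.logical(labels)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  data.frame(
    threshold = thr,
    fpr = sapply(thr, function(t) mean(s[!l] >= t)),
    tpr = sapply(thr, function(t) mean(s[l] >= t))
  )
}

# Optimal cut-off by brute-force distance evaluation over finite
# thresholds.
oracle_cutoff <- function(points) {
  pts <- points[is.finite(points$threshold), ]
  d <- sqrt(pts$fpr^2 + (1 - pts$tpr)^2)
  pts$threshold[which.min(d)]
}

# Classical one-way ANOVA from raw sums of squares.
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(sapply(groups, function(g) length(g) * (mean(g) - gm)^2))
  ssw <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# Toy thermometry series with hand-set ROI voxel values: one location
# ("vagina", 2 slices) on the fast grid. `roi_values` is a list (one
# element per scan) of per-voxel temperatures to paint into the ROI;
# the rest of the map is `background`.
toy_series <- function(roi_values, probe_C, background = 0,
                       scan_times = 600 * seq_along(roi_values) - 41.5,
                       stage = "drift_corrected") {
  g <- fast_geometry()
  tracks <- tibble::tibble(
    location = "vagina", slice = c(4L, 5L),
    ix = 24L, iy = 22L, x_cm = 0, y_cm = -1,
    slice_offset_cm = c(-5, -6)
  )
  rois <- roi_set(tracks, g)
  maps <- lapply(roi_values, function(vals) {
    m <- empty_volume(g, background)
    lin <- cbind(rois$ix, rois$iy, rois$slice)
    stopifnot(length(vals) <= nrow(lin))
    m[lin[seq_along(vals), , drop = FALSE]] <- vals
    m
  })
  series <- thermo_series(maps, scan_times, g, stage = stage)
  probes <- tidyr::expand_grid(
    location = "vagina",
    time_s = seq(0, max(scan_times) + 83, by = 300),
    position_index = 1:2
  )
  probes$slice_offset_cm <- rep(c(-5, -6), length.out = nrow(probes))
  probes$temp_C <- probe_C
  list(series = series, rois = rois, probes = probes)
}
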