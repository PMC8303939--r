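#' Temperature map series container
#'
#' Holds the reconstructed temperature-change volumes of one session with
#' their per-voxel validity masks and processing stage. Stages only move
#' forward: `uncorrected` -> `snr_masked` -> `drift_corrected` ->
#' `filtered`; each processing verb checks the stage it requires.
#'
#' @param maps List of temperature-change volumes (degC, 3D arrays).
#' @param scan_times_s Scan start times, seconds from the first baseline.
#' @param geometry The matching [scan_geometry()].
#' @param valid Optional list of logical volumes (default: all valid).
#' @param stage Processing stage.
#' @param scan_duration_s Scan duration (used for probe alignment).
#'
#' @return An object of class `thermo_series`.
#' @export
thermo_series <- function(maps, scan_times_s, geometry,
                          valid = NULL, stage = "uncorrected",
                          scan_duration_s = 83) {
  stopifnot(length(maps) == length(scan_times_s),
            all(diff(scan_times_s) > 0))
  if (is.null(valid)) {
    valid <- lapply(maps, function(m) array(TRUE, dim = dim(m)))
  }
  purrr::walk2(maps, valid, stopifnot_same_shape,
               what = "maps and validity masks")
  structure(
    list(maps = maps, valid = valid, scan_times_s = scan_times_s,
         geometry = geometry, stage = stage,
         scan_duration_s = scan_duration_s),
    class = "thermo_series"
  )
}

#' @export
print.thermo_series <- function(x, ...) {
  cat(sprintf("<thermo_series> %d maps, stage '%s', %.1f%% voxels valid\n",
              length(x$maps), x$stage,
              100 * mean(unlist(lapply(x$valid, mean)))))
  invisible(x)
}

require_stage <- function(series, stage) {
  if (!identical(series$stage, stage)) {
    stop(sprintf("operation requires stage '%s' but series is at '%s'",
                 stage, series$stage), call. = FALSE)
  }
  invisible(TRUE)
}

#' Phase-difference temperature map
#'
#' Converts the wrapped phase difference between a scan and the reference
#' baseline into a temperature-change map:
#' \eqn{\Delta T = \angle e^{i(\phi_n - \phi_{00})} / (\gamma \alpha B_0 TE)}.
#' The wrapped difference keeps the conversion safe when drift or
#' artifact terms push the raw difference across the phase wrap.
#'
#' @param scan,reference Scans as produced by the simulator: lists with a
#'   `phase` volume (rad) and a `time_s` stamp.
#' @param constants A [prfs_constants()].
#' @return The temperature-change volume (degC) with the scan time as
#'   attribute `time_s`.
#' @export
compute_delta_t <- function(scan, reference, constants = prfs_constants()) {
  stopifnot_same_shape(scan$phase, reference$phase, "scan and reference")
  dphi <- wrap_phase(scan$phase - reference$phase)
  dt <- dphi / constants$rad_per_C
  attr(dt, "time_s") <- scan$time_s
  dt
}

#' Uncorrected temperature maps of a whole session
#'
#' Applies [compute_delta_t()] to every treatment scan of a session
#' against the first baseline (the reference phase). The second baseline
#' is used only for air-motion quantification, not as a reference.
#'
#' @param session A `hyperthermia_session`.
#' @param constants Overrides the session's constants if given.
#' @return A [thermo_series()] at stage `uncorrected`.
#' @export
session_delta_t <- function(session, constants = NULL) {
  stopifnot(inherits(session, "hyperthermia_session"))
  k <- constants %||% session$constants
  ref <- session$scans[[1]]
  treat <- session$scans[-(1:2)]
  maps <- lapply(treat, compute_delta_t, reference = ref, constants = k)
  thermo_series(maps, vapply(treat, `[[`, numeric(1), "time_s"),
                session$geometry,
                scan_duration_s = session$scan_duration_s)
}

#' Mask low-SNR voxels
#'
#' A voxel is invalidated when its temperature deviates by more than
#' `deviation_C` from the mean of its in-plane 3x3 neighbourhood
#' (excluding the voxel itself; border voxels use the neighbours that
#' exist). This removes isolated noisy voxels before they can pollute
#' the fat regions used for drift correction.
#'
#' @param series A `thermo_series` at stage `uncorrected`.
#' @param deviation_C Deviation threshold, degC (default 3).
#' @return The series at stage `snr_masked`.
#' @export
mask_low_snr <- function(series, deviation_C = 3) {
  require_stage(series, "uncorrected")
  for (n in seq_along(series$maps)) {
    dev <- abs(series$maps[[n]] - neighbor_mean(series$maps[[n]]))
    series$valid[[n]] <- series$valid[[n]] & (dev <= deviation_C)
  }
  series$stage <- "snr_masked"
  series
}

# Mean over the 8 in-plane neighbours (available ones at borders).
neighbor_mean <- function(vol) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]
  out <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    m <- vol[, , z]
    s <- matrix(0, nx, ny)
    cnt <- matrix(0, nx, ny)
    for (di in -1:1) {
      for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        si <- max(1, 1 + di):min(nx, nx + di)
        sj <- max(1, 1 + dj):min(ny, ny + dj)
        ti <- max(1, 1 - di):min(nx, nx - di)
        tj <- max(1, 1 - dj):min(ny, ny - dj)
        s[si, sj] <- s[si, sj] + m[ti, tj]
        cnt[si, sj] <- cnt[si, sj] + 1
      }
    }
    out[, , z] <- s / cnt
  }
  out
}

#' Fat-referenced B0 drift correction
#'
#' Scanner field drift appears as a smooth spatial phase ramp growing in
#' time and masquerades as temperature change. Fat undergoes no PRFS
#' shift, so any apparent temperature change in fat is drift. For every
#' scan and every slice a 2D polynomial (total degree `poly_order`) is
#' least-squares fitted to the valid fat voxels and subtracted from the
#' whole slice, driving the fat mean back to zero.
#'
#' If a slice has fewer fat voxels than polynomial coefficients the order
#' is lowered (with a warning); a slice with no valid fat voxels is left
#' uncorrected and flagged.
#'
#' @param series A `thermo_series` at stage `snr_masked`.
#' @param fat_mask Logical volume of fat voxels.
#' @param poly_order Total polynomial degree (default 2).
#' @return The series at stage `drift_corrected`, with a tibble of
#'   per-slice fat residual means in `$fat_residual`.
#' @export
correct_drift <- function(series, fat_mask, poly_order = 2) {
  require_stage(series, "snr_masked")
  g <- series$geometry
  stopifnot_same_shape(series$maps[[1]], fat_mask, "map and fat mask")
  xs <- axis_coords_cm(g)
  nx <- g$matrix
  x <- matrix(xs, nx, nx)
  y <- matrix(xs, nx, nx, byrow = TRUE)
  basis <- poly_basis(x, y, poly_order)

  res <- list()
  for (n in seq_along(series$maps)) {
    for (z in seq_len(dim(series$maps[[n]])[3])) {
      sl <- series$maps[[n]][, , z]
      fv <- fat_mask[, , z] & series$valid[[n]][, , z]
      nf <- sum(fv)
      corrected_flag <- TRUE
      if (nf == 0) {
        corrected_flag <- FALSE
      } else {
        use <- basis
        if (nf < ncol(basis)) {
          ord <- poly_order
          while (ord > 0 && nf < ncol(poly_basis(x, y, ord))) ord <- ord - 1
          use <- poly_basis(x, y, ord)
          warning(sprintf(
            "slice %d scan %d: only %d fat voxels; drift order lowered to %d",
            z, n, nf, ord), call. = FALSE)
        }
        X <- use[fv, , drop = FALSE]
        beta <- qr.coef(qr(X), sl[fv])
        beta[is.na(beta)] <- 0
        sl <- sl - matrix(use %*% beta, nx, nx)
        series$maps[[n]][, , z] <- sl
      }
      res[[length(res) + 1]] <- tibble::tibble(
        scan = n, slice = z, n_fat = nf, corrected = corrected_flag,
        fat_mean_C = if (nf > 0) mean(sl[fv]) else NA_real_
      )
    }
  }
  series$fat_residual <- dplyr::bind_rows(res)
  series$stage <- "drift_corrected"
  series
}

# Columns of the 2D polynomial design of total degree <= order,
# evaluated on matrices x and y (cm), flattened to vectors.
poly_basis <- function(x, y, order) {
  cols <- list(rep(1, length(x)))
  if (order >= 1) cols <- c(cols, list(as.vector(x), as.vector(y)))
  if (order >= 2) {
    cols <- c(cols, list(as.vector(x)^2, as.vector(x * y), as.vector(y)^2))
  }
  do.call(cbind, cols)
}

#' Optimize the outlier-exclusion threshold against probe readings
#'
#' Voxels whose absolute temperature change exceeds a threshold p are
#' treated as corrupted by confounders (moving air, susceptibility) and
#' excluded. The threshold is chosen by grid search: for each candidate
#' p, G(p) is the mean over scans and probe locations of the absolute
#' difference between the surviving-voxel ROI mean and the aligned probe
#' mean; the smallest p attaining the minimum of G is returned.
#'
#' @param series A `thermo_series` at stage `drift_corrected`.
#' @param rois A [roi_set()].
#' @param probes Probe trace tibble (as from [sample_probe_readings()]).
#' @param bounds Search interval, degC (default `c(0, 20)`).
#' @param grid_step_C Grid spacing (default 0.1 degC).
#' @param max_offset_s Maximum probe-cycle-to-scan-midpoint offset.
#' @return An object of class `exclusion_threshold`: `threshold_C`, the
#'   sampled objective `curve` (tibble `p`, `G`), and `bounds`.
#' @export
optimize_exclusion_threshold <- function(series, rois, probes,
                                         bounds = c(0, 20),
                                         grid_step_C = 0.1,
                                         max_offset_s = 150) {
  require_stage(series, "drift_corrected")
  grid <- seq(bounds[1], bounds[2], by = grid_step_C)
  terms <- roi_probe_terms(series, rois, probes, max_offset_s)

  g_sum <- numeric(length(grid))
  g_n <- numeric(length(grid))
  for (term in terms) {
    av <- sort(abs(term$vals))
    cs <- cumsum(term$vals[order(abs(term$vals))])
    cnt <- findInterval(grid, av)
    ok <- cnt > 0
    g_sum[ok] <- g_sum[ok] + abs(cs[cnt[ok]] / cnt[ok] - term$probe)
    g_n[ok] <- g_n[ok] + 1
  }
  G <- ifelse(g_n > 0, g_sum / pmax(g_n, 1), Inf)
  structure(
    list(threshold_C = grid[which.min(G)],
         curve = tibble::tibble(p = grid, G = G),
         bounds = bounds),
    class = "exclusion_threshold"
  )
}

# One term per (scan, location): the valid ROI voxel values and the
# aligned probe mean. Terms without a probe cycle within max_offset_s
# or without valid voxels are dropped.
roi_probe_terms <- function(series, rois, probes, max_offset_s = 150) {
  pm <- probe_cycle_means(probes)
  cyc <- sort(unique(pm$time_s))
  mids <- series$scan_times_s + series$scan_duration_s / 2
  terms <- list()
  for (n in seq_along(series$maps)) {
    i <- which.min(abs(cyc - mids[n]))
    if (abs(cyc[i] - mids[n]) > max_offset_s) next
    for (loc in unique(rois$location)) {
      rv <- rois[rois$location == loc, ]
      lin <- cbind(rv$ix, rv$iy, rv$slice)
      keep <- series$valid[[n]][lin]
      if (!any(keep)) next
      probe <- pm$probe_C[pm$location == loc & pm$time_s == cyc[i]]
      if (length(probe) != 1 || is.na(probe)) next
      terms[[length(terms) + 1]] <- list(
        scan = n, location = loc,
        vals = series$maps[[n]][lin][keep], probe = probe
      )
    }
  }
  terms
}

# Mean probe reading over the mapped positions, per location and cycle.
probe_cycle_means <- function(probes) {
  probes |>
    dplyr::group_by(.data$location, .data$time_s) |>
    dplyr::summarise(probe_C = mean(.data$temp_C), .groups = "drop")
}

#' Apply the outlier-exclusion threshold
#'
#' @param series A `thermo_series` at stage `drift_corrected`.
#' @param threshold_C Exclusion threshold p: voxels with
#'   `|dT| > threshold_C` are invalidated. The clinical optimum found on
#'   patient data is 7 degC, the package default where no probes are
#'   available to re-optimize.
#' @return The series at stage `filtered`.
#' @export
apply_exclusion <- function(series, threshold_C = 7) {
  require_stage(series, "drift_corrected")
  for (n in seq_along(series$maps)) {
    series$valid[[n]] <- series$valid[[n]] &
      (abs(series$maps[[n]]) <= threshold_C)
  }
  series$threshold_C <- threshold_C
  series$stage <- "filtered"
  series
}

#' ROI mean temperature series
#'
#' For every probe location and scan, the mean temperature change over
#' the valid ROI voxels pooled across the location's slices. Entries with
#' no surviving voxel are flagged `NA`, never fabricated.
#'
#' @param series A `thermo_series` at stage `filtered`.
#' @param rois A [roi_set()].
#' @return A tibble: `location`, `time_s`, `mean_C`, `n_voxels`,
#'   `fraction_surviving`.
#' @export
roi_mean_series <- function(series, rois) {
  require_stage(series, "filtered")
  out <- list()
  for (loc in unique(rois$location)) {
    rv <- rois[rois$location == loc, ]
    lin <- cbind(rv$ix, rv$iy, rv$slice)
    for (n in seq_along(series$maps)) {
      keep <- series$valid[[n]][lin]
      out[[length(out) + 1]] <- tibble::tibble(
        location = loc, time_s = series$scan_times_s[n],
        mean_C = if (any(keep)) mean(series$maps[[n]][lin][keep])
                 else NA_real_,
        n_voxels = sum(keep),
        fraction_surviving = mean(keep)
      )
    }
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$location, .data$time_s)
}

#' Reconstruct a session end to end
#'
#' Runs the whole processing chain on a session: phase-difference maps,
#' low-SNR masking, fat-referenced drift correction, outlier exclusion
#' (fixed threshold or re-optimized against the session's probes) and
#' ROI averaging.
#'
#' @param session A `hyperthermia_session`.
#' @param threshold_C Exclusion threshold when `optimize_threshold` is
#'   `FALSE` (default 7 degC, the clinical optimum).
#' @param optimize_threshold If `TRUE`, re-run the grid optimization
#'   against this session's probe traces.
#' @param poly_order Drift polynomial degree.
#' @param deviation_C Low-SNR masking threshold.
#' @return A list of class `session_reconstruction`: the filtered
#'   `series`, the `roi_series` tibble, `threshold_used` and (when
#'   optimized) the `threshold_result`.
#' @export
reconstruct_session <- function(session, threshold_C = 7,
                                optimize_threshold = FALSE,
                                poly_order = 2, deviation_C = 3) {
  rois <- roi_set(session$anatomy$tracks, session$geometry)
  series <- session_delta_t(session) |>
    mask_low_snr(deviation_C = deviation_C) |>
    correct_drift(session$anatomy$fat_mask, poly_order = poly_order)
  thr_res <- NULL
  if (optimize_threshold) {
    thr_res <- optimize_exclusion_threshold(series, rois,
                                            session$probe_traces)
    threshold_C <- thr_res$threshold_C
  }
  series <- apply_exclusion(series, threshold_C)
  structure(
    list(series = series, roi_series = roi_mean_series(series, rois),
         rois = rois, threshold_used = threshold_C,
         threshold_result = thr_res),
    class = "session_reconstruction"
  )
}

#' @export
print.session_reconstruction <- function(x, ...) {
  cat(sprintf("<session_reconstruction> threshold %.1f degC, %d ROI means\n",
              x$threshold_used, nrow(x$roi_series)))
  invisible(x)
}
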