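#' Generate the ground-truth temperature evolution of a session
#'
#' The heating focus is a 3D Gaussian in space with a saturating
#' exponential ramp in time, switched on after the second baseline scan.
#' Fat is kept thermally inert (exactly zero temperature change) so that
#' the fat-referenced drift correction remains valid by construction;
#' clinically, fat heats little and its proton frequency does not shift
#' with temperature.
#'
#' @param anatomy An [generate_anatomy()] result.
#' @param heating List with `center_cm` (in-plane focus centre, cm from the
#'   FOV centre), `sigma_cm` (Gaussian width), `peak_C` (saturation peak,
#'   degC, in `[0, 10]`) and `ramp_min` (ramp time constant, minutes).
#' @param n_scans Number of treatment scans (after the two baselines).
#' @param seed Integer seed (kept for interface symmetry; the truth is
#'   deterministic given the anatomy and heating).
#' @param baseline_interval_s Time between the starts of the two baseline
#'   scans (default 97 s, the clinical mean).
#' @param scan_interval_s Spacing of treatment scans. The default start
#'   times `n * 600 - 41.5` put each scan's midpoint exactly on a 5-min
#'   probe mapping cycle.
#' @param scan_duration_s Duration of one thermometry scan (83 s).
#' @param heat_on_s Time at which RF power is switched on.
#'
#' @return An object of class `truth_series`: the saturation temperature
#'   field `focus_field` (degC), ramp parameters, `scan_times_s`, and
#'   `dt_true`, a list with the true temperature-change volume at every
#'   scan time (identically zero at both baselines).
#' @export
generate_truth <- function(anatomy,
                           heating = list(center_cm = c(0, 0), sigma_cm = 3,
                                          peak_C = 4, ramp_min = 15),
                           n_scans = 9L, seed = 1L,
                           baseline_interval_s = 97,
                           scan_interval_s = 600,
                           scan_duration_s = 83,
                           heat_on_s = 180) {
  stopifnot(inherits(anatomy, "anatomy_model"),
            heating$peak_C >= 0, heating$peak_C <= 10, n_scans >= 1)
  g <- anatomy$geometry
  xs <- axis_coords_cm(g)
  zs <- slice_offsets_cm(g)
  zc <- zs[ceiling(g$n_slices / 2)]

  cix <- which.min(abs(xs - heating$center_cm[1]))
  ciy <- which.min(abs(xs - heating$center_cm[2]))
  if (!anatomy$body_mask[cix, ciy, ceiling(g$n_slices / 2)]) {
    stop("heating focus centre lies outside the body", call. = FALSE)
  }

  d2 <- ell_metric(xs, zs, center = c(heating$center_cm, zc),
                   aspect = c(1, 1, 1))
  focus <- heating$peak_C * exp(-d2 / (2 * heating$sigma_cm^2))
  focus[anatomy$fat_mask] <- 0
  focus[!anatomy$body_mask] <- 0

  scan_times <- c(0, baseline_interval_s,
                  seq_len(n_scans) * scan_interval_s - scan_duration_s / 2)
  tau_s <- heating$ramp_min * 60
  ramp <- heating_ramp(scan_times, heat_on_s, tau_s)
  dt_true <- lapply(ramp, function(r) focus * r)

  structure(
    list(
      focus_field = focus, heat_on_s = heat_on_s, tau_s = tau_s,
      scan_times_s = scan_times, scan_duration_s = scan_duration_s,
      dt_true = dt_true, drift_true = NULL, heating = heating
    ),
    class = "truth_series"
  )
}

heating_ramp <- function(t, heat_on_s, tau_s) {
  if (tau_s <= 0) return(as.numeric(t > heat_on_s))
  1 - exp(-pmax(0, t - heat_on_s) / tau_s)
}

#' Sample intraluminal probe traces from the ground truth
#'
#' Emulates the clinical thermal mapping: every `mapping_interval_s`
#' seconds each probe is stepped along its catheter (one position per
#' slice, 1 cm steps, at most 14 positions) and a temperature reading is
#' taken at each position.
#'
#' @param truth A [generate_truth()] result.
#' @param anatomy The matching anatomy.
#' @param mapping_interval_s Mapping cycle period (default 300 s).
#' @param duration_s End of the mapping window; defaults to the end of the
#'   last thermometry scan.
#' @param noise_sd_C Gaussian reading noise, degC.
#' @param seed Integer seed for the noise.
#'
#' @return A tibble with one row per reading: `location`, `time_s`
#'   (cycle start), `position_index`, `slice_offset_cm`, `temp_C`
#'   (temperature change relative to the session start).
#' @export
sample_probe_readings <- function(truth, anatomy, mapping_interval_s = 300,
                                  duration_s = NULL, noise_sd_C = 0.05,
                                  seed = 1L) {
  stopifnot(mapping_interval_s > 0, noise_sd_C >= 0)
  set.seed(as.integer(seed))
  if (is.null(duration_s)) {
    duration_s <- max(truth$scan_times_s) + truth$scan_duration_s
  }
  cycles <- seq(0, duration_s, by = mapping_interval_s)

  tracks <- anatomy$tracks
  if (any(tracks$slice > dim(truth$focus_field)[3])) {
    stop("probe track lies outside the imaged volume", call. = FALSE)
  }
  tracks <- tracks |>
    dplyr::group_by(.data$location) |>
    dplyr::mutate(position_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$position_index <= 14)

  base <- tidyr::expand_grid(time_s = cycles, tracks)
  ramp <- heating_ramp(base$time_s, truth$heat_on_s, truth$tau_s)
  lin <- cbind(base$ix, base$iy, base$slice)
  base$temp_C <- truth$focus_field[lin] * ramp +
    stats::rnorm(nrow(base), sd = noise_sd_C)
  base[, c("location", "time_s", "position_index", "slice_offset_cm",
           "temp_C")]
}

#' Encode a ground-truth series into phase and magnitude scans
#'
#' Applies the forward PRFS model: each scan's phase is the baseline
#' phase plus `rad_per_C * dT_true`, plus a smooth polynomial B0 drift
#' field growing in time, plus a susceptibility-like perturbation in a
#' two-voxel shell around the gastrointestinal air (scaled by the air
#' displacement between the baselines and varying between scans), plus
#' white phase noise. Phases are wrapped to `(-pi, pi]`.
#'
#' @param truth A [generate_truth()] result.
#' @param anatomy The matching anatomy.
#' @param constants A [prfs_constants()].
#' @param drift Either `NULL` (no drift) or a list with
#'   `coef_rad_per_h`, six coefficients of an in-plane quadratic
#'   `c(1, x, y, x^2, x*y, y^2)` (x, y in cm from the FOV centre) whose
#'   field accumulates linearly with time.
#' @param noise_sd_rad Phase noise standard deviation, rad.
#' @param air_artifact_rad Susceptibility artifact scale, rad; the shell
#'   amplitude at scan n is `air_artifact_rad * (1 - J) * u_n` with
#'   `u_n` standard normal (zero at the reference scan) and `J` the
#'   realised inter-baseline air Jaccard coefficient.
#' @param probe_noise_sd_C Probe reading noise, degC.
#' @param seed Integer seed; the session is bit-identical given a seed.
#'
#' @return An object of class `hyperthermia_session` holding the scans
#'   (phase + magnitude volumes with timestamps), probe traces, the
#'   anatomy, the constants, and the ground truth (with the realised
#'   drift fields filled into `truth$drift_true`).
#' @export
encode_session <- function(truth, anatomy, constants = prfs_constants(),
                           drift = NULL, noise_sd_rad = 5e-4,
                           air_artifact_rad = 0.5,
                           probe_noise_sd_C = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "truth_series"),
            inherits(anatomy, "anatomy_model"),
            inherits(constants, "prfs_constants"),
            noise_sd_rad >= 0, air_artifact_rad >= 0)
  set.seed(as.integer(seed))
  g <- anatomy$geometry
  xs <- axis_coords_cm(g)
  n_scans <- length(truth$scan_times_s)

  # Smooth baseline phase: a gentle in-plane ramp, different per session.
  base_coef <- stats::rnorm(3, sd = c(0.5, 0.02, 0.02))
  phi00 <- poly2_field(g, c(base_coef, 0, 0, 0))

  jacc <- jaccard_coefficient(anatomy$air_s00, anatomy$air_s01)
  pattern <- air_artifact_pattern(anatomy)
  u <- c(0, stats::rnorm(n_scans - 1))

  drift_unit <- if (is.null(drift)) NULL else
    poly2_field(g, drift$coef_rad_per_h)

  scans <- vector("list", n_scans)
  drift_true <- vector("list", n_scans)
  for (n in seq_len(n_scans)) {
    t_n <- truth$scan_times_s[n]
    dfield <- if (is.null(drift_unit)) 0 else drift_unit * (t_n / 3600)
    drift_true[[n]] <- if (is.null(drift_unit)) empty_volume(g) else dfield
    phase <- phi00 + constants$rad_per_C * truth$dt_true[[n]] + dfield +
      air_artifact_rad * (1 - jacc) * u[n] * pattern
    if (noise_sd_rad > 0) {
      phase <- phase + array(stats::rnorm(length(phase), sd = noise_sd_rad),
                             dim = dim(phase))
    }
    air_n <- if (n == 1) anatomy$air_s00 else anatomy$air_s01
    magnitude <- 2 + 98 * anatomy$body_mask - 95 * (anatomy$body_mask & air_n) +
      array(abs(stats::rnorm(length(phase), sd = 1)), dim = dim(phase))
    scans[[n]] <- list(phase = wrap_phase(phase), magnitude = magnitude,
                       time_s = t_n)
  }
  truth$drift_true <- drift_true

  probe_seed <- sample.int(.Machine$integer.max, 1)
  probes <- sample_probe_readings(truth, anatomy,
                                  noise_sd_C = probe_noise_sd_C,
                                  seed = probe_seed)

  structure(
    list(
      geometry = g, constants = constants, anatomy = anatomy,
      scans = scans, scan_times_s = truth$scan_times_s,
      scan_duration_s = truth$scan_duration_s,
      probe_traces = probes, truth = truth,
      jaccard_true = jacc, seed = as.integer(seed)
    ),
    class = "hyperthermia_session"
  )
}

# In-plane quadratic field from coefficients c(1, x, y, x^2, xy, y^2),
# x and y in cm from the FOV centre; constant across slices.
poly2_field <- function(geometry, coef) {
  stopifnot(length(coef) == 6)
  xs <- axis_coords_cm(geometry)
  nx <- geometry$matrix
  x <- matrix(xs, nx, nx)
  y <- matrix(xs, nx, nx, byrow = TRUE)
  f <- coef[1] + coef[2] * x + coef[3] * y + coef[4] * x^2 +
    coef[5] * x * y + coef[6] * y^2
  array(rep(f, geometry$n_slices), dim = c(nx, nx, geometry$n_slices))
}

# Dipole-like unit pattern: weight 2 inside air, decaying as exp(-d/2)
# over a four-voxel shell outside it, modulated by cos(2*theta) about
# the pocket centre (susceptibility perturbations change sign around a
# cavity).
air_artifact_pattern <- function(anatomy) {
  u <- anatomy$air_s00 | anatomy$air_s01
  w <- 2 * u
  ring <- u
  for (d in 1:4) {
    grown <- dilate6(ring)
    w <- w + exp(-d / 2) * (grown & !ring)
    ring <- grown
  }
  g <- anatomy$geometry
  xs <- axis_coords_cm(g)
  nx <- g$matrix
  x <- matrix(xs - anatomy$air_center_cm[1], nx, nx)
  y <- matrix(xs - anatomy$air_center_cm[2], nx, nx, byrow = TRUE)
  mod <- cos(2 * atan2(y, x))
  w * array(rep(mod, g$n_slices), dim = dim(w))
}

# 6-connected binary dilation of a 3D logical array.
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  if (d[3] > 1) {
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  }
  out
}

#' Simulate a complete synthetic treatment session
#'
#' Convenience wrapper chaining [generate_anatomy()], [generate_truth()],
#' and [encode_session()], deriving one sub-seed per stage from `seed`.
#'
#' @param seed Integer master seed.
#' @param geometry A [scan_geometry()]; the default 128 x 128 x 15 grid is
#'   the desk-scale counterpart of the clinical 256 x 256 x 25.
#' @param constants A [prfs_constants()].
#' @param air_motion_fraction,air_volume_ml,fat_thickness_cm Passed to
#'   [generate_anatomy()].
#' @param heating,n_scans Passed to [generate_truth()].
#' @param drift,noise_sd_rad,air_artifact_rad,probe_noise_sd_C Passed to
#'   [encode_session()].
#'
#' @return A `hyperthermia_session`.
#' @export
#' @examples
#' s <- simulate_session(seed = 1, geometry = scan_geometry(9, 64),
#'                       noise_sd_rad = 0)
#' length(s$scans)
simulate_session <- function(seed = 1L,
                             geometry = scan_geometry(n_slices = 15L,
                                                      matrix = 128L),
                             constants = prfs_constants(),
                             air_motion_fraction = 0.1,
                             air_volume_ml = 200,
                             fat_thickness_cm = 1.5,
                             heating = list(center_cm = c(0, 0),
                                            sigma_cm = 3, peak_C = 4,
                                            ramp_min = 15),
                             n_scans = 9L,
                             drift = list(coef_rad_per_h =
                                            c(0.05, 0.002, -0.002,
                                              2e-4, -1e-4, 1e-4)),
                             noise_sd_rad = 5e-4,
                             air_artifact_rad = 0.5,
                             probe_noise_sd_C = 0.05) {
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max, 3)
  anatomy <- generate_anatomy(geometry, air_motion_fraction, air_volume_ml,
                              seed = sub[1],
                              fat_thickness_cm = fat_thickness_cm)
  truth <- generate_truth(anatomy, heating = heating, n_scans = n_scans,
                          seed = sub[2])
  encode_session(truth, anatomy, constants, drift = drift,
                 noise_sd_rad = noise_sd_rad,
                 air_artifact_rad = air_artifact_rad,
                 probe_noise_sd_C = probe_noise_sd_C, seed = sub[3])
}

#' @export
print.hyperthermia_session <- function(x, ...) {
  cat(sprintf(
    "<hyperthermia_session> %d scans (2 baselines + %d), %dx%dx%d, Jaccard %.3f, seed %d\n",
    length(x$scans), length(x$scans) - 2, x$geometry$matrix,
    x$geometry$matrix, x$geometry$n_slices, x$jaccard_true, x$seed
  ))
  invisible(x)
}
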