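#' Write a session to disk (NIfTI + CSV + JSON)
#'
#' Serializes a session the way a scanner export would be organised:
#' one NIfTI phase and magnitude volume per scan, NIfTI label volumes
#' for the masks, the probe traces as CSV and a JSON manifest carrying
#' geometry, constants, timestamps and the seed.
#'
#' @param session A `hyperthermia_session`.
#' @param dir Output directory (created if missing).
#' @param include_truth Also write the ground truth (saturation field as
#'   NIfTI, ramp parameters in the manifest).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, include_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (n in seq_along(session$scans)) {
    RNifti::writeNifti(session$scans[[n]]$phase,
                       file.path(dir, sprintf("scan_%02d_phase.nii.gz", n)))
    RNifti::writeNifti(session$scans[[n]]$magnitude,
                       file.path(dir, sprintf("scan_%02d_magnitude.nii.gz",
                                              n)))
  }
  a <- session$anatomy
  RNifti::writeNifti(a$body_mask * 1L, file.path(dir, "mask_body.nii.gz"))
  RNifti::writeNifti(a$fat_mask * 1L, file.path(dir, "mask_fat.nii.gz"))
  RNifti::writeNifti(a$air_s00 * 1L, file.path(dir, "mask_air_s00.nii.gz"))
  RNifti::writeNifti(a$air_s01 * 1L, file.path(dir, "mask_air_s01.nii.gz"))
  readr::write_csv(session$probe_traces, file.path(dir, "probes.csv"))
  readr::write_csv(a$tracks, file.path(dir, "tracks.csv"))

  g <- session$geometry
  k <- session$constants
  manifest <- list(
    geometry = list(n_slices = g$n_slices, matrix = g$matrix,
                    fov_cm = g$fov_cm,
                    slice_thickness_cm = g$slice_thickness_cm),
    constants = list(gamma_rad_per_T_s = k$gamma_rad_per_T_s,
                     alpha_ppm_per_C = k$alpha_ppm_per_C,
                     b0_T = k$b0_T, te_s = k$te_s),
    scan_times_s = session$scan_times_s,
    scan_duration_s = session$scan_duration_s,
    jaccard_true = session$jaccard_true,
    seed = session$seed,
    air_center_cm = a$air_center_cm
  )
  if (include_truth && !is.null(session$truth)) {
    RNifti::writeNifti(session$truth$focus_field,
                       file.path(dir, "truth_focus.nii.gz"))
    manifest$truth <- list(heat_on_s = session$truth$heat_on_s,
                           tau_s = session$truth$tau_s)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @return A `hyperthermia_session`. The ground truth is restored when it
#'   was written; otherwise `truth` is `NULL` (as for non-synthetic
#'   data).
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- scan_geometry(manifest$geometry$n_slices, manifest$geometry$matrix,
                     manifest$geometry$fov_cm,
                     manifest$geometry$slice_thickness_cm)
  k <- do.call(prfs_constants, manifest$constants)
  read_vol <- function(f) {
    v <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(v), dim = dim(v))
  }
  scan_files <- sort(list.files(dir, pattern = "^scan_\\d+_phase"))
  scans <- lapply(seq_along(scan_files), function(n) {
    list(phase = read_vol(sprintf("scan_%02d_phase.nii.gz", n)),
         magnitude = read_vol(sprintf("scan_%02d_magnitude.nii.gz", n)),
         time_s = manifest$scan_times_s[n])
  })
  anatomy <- structure(
    list(geometry = g,
         body_mask = read_vol("mask_body.nii.gz") > 0,
         fat_mask = read_vol("mask_fat.nii.gz") > 0,
         air_s00 = read_vol("mask_air_s00.nii.gz") > 0,
         air_s01 = read_vol("mask_air_s01.nii.gz") > 0,
         tracks = readr::read_csv(file.path(dir, "tracks.csv"),
                                  show_col_types = FALSE),
         air_center_cm = manifest$air_center_cm,
         seed = manifest$seed),
    class = "anatomy_model"
  )
  truth <- NULL
  if (file.exists(file.path(dir, "truth_focus.nii.gz"))) {
    focus <- read_vol("truth_focus.nii.gz")
    ramp <- heating_ramp(manifest$scan_times_s, manifest$truth$heat_on_s,
                         manifest$truth$tau_s)
    truth <- structure(
      list(focus_field = focus, heat_on_s = manifest$truth$heat_on_s,
           tau_s = manifest$truth$tau_s,
           scan_times_s = manifest$scan_times_s,
           scan_duration_s = manifest$scan_duration_s,
           dt_true = lapply(ramp, function(r) focus * r),
           drift_true = NULL, heating = NULL),
      class = "truth_series"
    )
  }
  structure(
    list(geometry = g, constants = k, anatomy = anatomy, scans = scans,
         scan_times_s = manifest$scan_times_s,
         scan_duration_s = manifest$scan_duration_s,
         probe_traces = readr::read_csv(file.path(dir, "probes.csv"),
                                        show_col_types = FALSE),
         truth = truth, jaccard_true = manifest$jaccard_true,
         seed = manifest$seed),
    class = "hyperthermia_session"
  )
}
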