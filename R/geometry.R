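#' Acquisition geometry of a thermometry scan series
#'
#' Describes the voxel grid of the gradient-echo thermometry acquisition:
#' axial slices of fixed thickness over a square in-plane field of view.
#' The clinical protocol uses 25 slices of 1 cm over a 50 x 50 cm FOV
#' reconstructed at 256 x 256; synthetic work typically uses a coarser
#' in-plane matrix for speed.
#'
#' @param n_slices Number of axial slices.
#' @param matrix In-plane matrix size (voxels per axis; the grid is square).
#' @param fov_cm In-plane field of view per axis, in cm.
#' @param slice_thickness_cm Slice thickness, in cm.
#'
#' @return An object of class `scan_geometry`: a list with the arguments
#'   plus `voxel_cm` (in-plane voxel size, `fov_cm / matrix`) and
#'   `voxel_volume_ml` (voxel volume in mL; 1 cm^3 == 1 mL).
#' @export
#' @examples
#' g <- scan_geometry(matrix = 128)
#' g$voxel_volume_ml
scan_geometry <- function(n_slices = 25L, matrix = 256L, fov_cm = 50,
                          slice_thickness_cm = 1) {
  stopifnot(n_slices >= 1, matrix >= 8, fov_cm > 0, slice_thickness_cm > 0)
  voxel_cm <- fov_cm / matrix
  structure(
    list(
      n_slices = as.integer(n_slices),
      matrix = as.integer(matrix),
      fov_cm = fov_cm,
      slice_thickness_cm = slice_thickness_cm,
      voxel_cm = voxel_cm,
      voxel_volume_ml = voxel_cm^2 * slice_thickness_cm
    ),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %d x %d x %d voxels, FOV %.1f cm, slice %.1f cm (voxel %.3f cm)\n",
    x$matrix, x$matrix, x$n_slices, x$fov_cm, x$slice_thickness_cm, x$voxel_cm
  ))
  invisible(x)
}

#' PRFS constants of the thermometry equation
#'
#' Physical constants entering the phase-to-temperature conversion
#' \eqn{\Delta T = \Delta\phi / (\gamma \alpha B_0 TE)}. The default PRF
#' change coefficient follows the clinical processing description
#' (-0.001 ppm/degC); the conventional literature value (-0.01 ppm/degC)
#' can be selected instead via `alpha_ppm_per_C`.
#'
#' @param gamma_rad_per_T_s Gyromagnetic ratio in rad/(T s).
#' @param alpha_ppm_per_C PRF change coefficient in ppm per degC (non-zero).
#' @param b0_T Static field strength in tesla.
#' @param te_s Echo time in seconds.
#'
#' @return An object of class `prfs_constants` with the arguments plus
#'   `rad_per_C`, the net phase change per degC:
#'   `gamma * alpha * 1e-6 * b0 * te`.
#' @export
#' @examples
#' k <- prfs_constants()
#' k$rad_per_C # about -7.664e-3 rad per degC
prfs_constants <- function(gamma_rad_per_T_s = 267.5e6,
                           alpha_ppm_per_C = -0.001,
                           b0_T = 1.5, te_s = 0.0191) {
  stopifnot(gamma_rad_per_T_s > 0, b0_T > 0, te_s > 0, alpha_ppm_per_C != 0)
  structure(
    list(
      gamma_rad_per_T_s = gamma_rad_per_T_s,
      alpha_ppm_per_C = alpha_ppm_per_C,
      b0_T = b0_T,
      te_s = te_s,
      rad_per_C = gamma_rad_per_T_s * alpha_ppm_per_C * 1e-6 * b0_T * te_s
    ),
    class = "prfs_constants"
  )
}

#' @export
print.prfs_constants <- function(x, ...) {
  cat(sprintf(
    "<prfs_constants> gamma %.4g rad/T.s, alpha %.4g ppm/C, B0 %.2f T, TE %.1f ms (%.4g rad/C)\n",
    x$gamma_rad_per_T_s, x$alpha_ppm_per_C, x$b0_T, x$te_s * 1000, x$rad_per_C
  ))
  invisible(x)
}

# In-plane physical coordinate (cm) of voxel centres, measured from the
# FOV centre. Voxel i (1-based) sits at (i - 0.5) * voxel - fov/2.
axis_coords_cm <- function(geometry) {
  (seq_len(geometry$matrix) - 0.5) * geometry$voxel_cm - geometry$fov_cm / 2
}

# Physical slice offsets mirroring the clinical labelling: the first slice
# is at -2 cm and offsets decrease by one slice thickness per slice.
slice_offsets_cm <- function(geometry) {
  -2 - (seq_len(geometry$n_slices) - 1) * geometry$slice_thickness_cm
}

# Wrap phase values into (-pi, pi].
wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

empty_volume <- function(geometry, value = 0) {
  array(value, dim = c(geometry$matrix, geometry$matrix, geometry$n_slices))
}

stopifnot_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have mismatching shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}
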