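#' Rasterize the circular probe ROIs of a session
#'
#' For every probe location and every slice its track crosses, a circular
#' region of interest of fixed diameter (1.37 cm, area 1.47 cm^2) is
#' centred on the track's in-plane position. A voxel belongs to the ROI
#' iff its centre lies inside the circle, which makes the rasterization
#' reproducible and grid-independent.
#'
#' @param tracks A tibble of probe-track stations (`location`, `slice`,
#'   `ix`, `iy`), e.g. `anatomy$tracks` from [generate_anatomy()].
#' @param geometry The matching [scan_geometry()].
#' @param diameter_cm ROI diameter (default 1.37 cm).
#'
#' @return An object of class `roi_set`: a tibble with one row per ROI
#'   voxel (`location`, `slice`, `ix`, `iy`) and attributes `geometry`
#'   and `diameter_cm`.
#' @export
roi_set <- function(tracks, geometry, diameter_cm = 1.37) {
  stopifnot(inherits(geometry, "scan_geometry"), diameter_cm > 0)
  r_vox <- (diameter_cm / 2) / geometry$voxel_cm
  reach <- floor(r_vox)
  offs <- expand.grid(di = -reach:reach, dj = -reach:reach)
  offs <- offs[offs$di^2 + offs$dj^2 <= r_vox^2, ]
  if (nrow(offs) == 0) {
    stop("ROI rasterizes to zero voxels at this grid resolution",
         call. = FALSE)
  }
  per_loc <- tracks |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(n_slices = dplyr::n()) |>
    dplyr::ungroup()
  if (any(per_loc$n_slices < 2 | per_loc$n_slices > 8)) {
    stop("each probe location must span 2-8 slices", call. = FALSE)
  }

  vox <- tidyr::expand_grid(tracks[, c("location", "slice", "ix", "iy")],
                            offs) |>
    dplyr::mutate(ix = .data$ix + .data$di, iy = .data$iy + .data$dj) |>
    dplyr::select(!dplyr::all_of(c("di", "dj")))
  if (any(vox$ix < 1 | vox$ix > geometry$matrix |
            vox$iy < 1 | vox$iy > geometry$matrix)) {
    stop("ROI extends outside the image grid", call. = FALSE)
  }
  structure(vox, class = c("roi_set", class(vox)),
            geometry = geometry, diameter_cm = diameter_cm)
}

#' In-plane area of the rasterized ROI
#'
#' @param rois A [roi_set()].
#' @return Area in cm^2 of one per-slice ROI disc.
#' @export
roi_area_cm2 <- function(rois) {
  g <- attr(rois, "geometry")
  n <- nrow(rois[rois$location == rois$location[1] &
                   rois$slice == rois$slice[1], ])
  n * g$voxel_cm^2
}
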