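#' Jaccard overlap coefficient of two masks
#'
#' \eqn{J(A,B) = |A \cap B| / |A \cup B|}. Used here to quantify
#' gastrointestinal air displacement between the two baseline scans:
#' 1 means no motion, 0 complete displacement. When both masks are empty
#' there is no air and hence no motion, so J is defined as 1.
#'
#' @param mask_a,mask_b Logical volumes of identical shape.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE), dim = c(3, 1, 1))
#' b <- array(c(TRUE, FALSE, TRUE), dim = c(3, 1, 1))
#' jaccard_coefficient(a, b) # 1/3
jaccard_coefficient <- function(mask_a, mask_b) {
  stopifnot_same_shape(mask_a, mask_b, "masks")
  u <- sum(mask_a | mask_b)
  if (u == 0) return(1)
  sum(mask_a & mask_b) / u
}

#' Volume of a voxel mask in millilitres
#'
#' @param mask Logical volume.
#' @param geometry The matching [scan_geometry()].
#' @return Volume in mL (voxel count times voxel volume; 1 cm^3 = 1 mL).
#' @export
mask_volume_ml <- function(mask, geometry) {
  sum(mask) * geometry$voxel_volume_ml
}

#' Mean minimum distance from air to the probe ROIs
#'
#' For every slice in which a probe ROI is delineated, the minimum
#' in-plane Euclidean distance between any ROI circle boundary and the
#' nearest air voxel centre in that slice; the result is the mean over
#' those slices. Slices without air contribute a configurable cap
#' (default: the in-plane FOV diagonal) so that air-free sessions score
#' as "far" rather than dropping out of the ROC input.
#'
#' @param air_mask Logical air volume.
#' @param rois A [roi_set()].
#' @param geometry The matching [scan_geometry()].
#' @param cap_cm Distance assigned to slices with no air.
#' @return Distance in cm (>= 0).
#' @export
min_air_roi_distance <- function(air_mask, rois, geometry,
                                 cap_cm = sqrt(2) * geometry$fov_cm) {
  xs <- axis_coords_cm(geometry)
  radius <- attr(rois, "diameter_cm") / 2
  centers <- dplyr::distinct(
    tibble::as_tibble(rois)[, c("location", "slice", "ix", "iy")]
  ) |>
    dplyr::group_by(.data$location, .data$slice) |>
    dplyr::summarise(ix = round(mean(.data$ix)), iy = round(mean(.data$iy)),
                     .groups = "drop")

  per_slice <- vapply(sort(unique(centers$slice)), function(z) {
    air_idx <- which(air_mask[, , z], arr.ind = TRUE)
    if (nrow(air_idx) == 0) return(cap_cm)
    ctr <- centers[centers$slice == z, ]
    dmin <- Inf
    for (r in seq_len(nrow(ctr))) {
      d <- sqrt((xs[air_idx[, 1]] - xs[ctr$ix[r]])^2 +
                  (xs[air_idx[, 2]] - xs[ctr$iy[r]])^2) - radius
      dmin <- min(dmin, d)
    }
    max(0, dmin)
  }, numeric(1))
  mean(per_slice)
}

#' Imaging-based features of one session
#'
#' Computes the four pre-treatment imaging predictors of thermometry
#' reliability: the Jaccard coefficient of the two baseline air masks
#' (air motion), the initial gastrointestinal air volume (first baseline
#' only), the fat volume, and the mean minimum air-to-ROI distance.
#'
#' @param session A `hyperthermia_session`.
#' @return A one-row tibble: `session_id`, `jaccard`, `air_volume_ml`,
#'   `fat_volume_ml`, `min_distance_cm`.
#' @export
session_features <- function(session) {
  stopifnot(inherits(session, "hyperthermia_session"))
  g <- session$geometry
  a <- session$anatomy
  rois <- roi_set(a$tracks, g)
  tibble::tibble(
    session_id = session$seed,
    jaccard = jaccard_coefficient(a$air_s00, a$air_s01),
    air_volume_ml = mask_volume_ml(a$air_s00, g),
    fat_volume_ml = mask_volume_ml(a$fat_mask, g),
    min_distance_cm = min_air_roi_distance(a$air_s00, rois, g)
  )
}
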