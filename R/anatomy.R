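#' Generate a synthetic pelvic anatomy for one treatment session
#'
#' Builds the label volumes a session needs: an elliptical body, a
#' subcutaneous fat ring (the drift reference), gastrointestinal air
#' pockets for the two baseline scans, and three intraluminal probe
#' tracks (bladder, vagina, rectum) running along the slice axis.
#'
#' Air motion between the baselines is controlled exactly: the second
#' baseline's air mask is derived from the first by removing voxels on
#' one side and accreting the same number on the opposite side, so that
#' the Jaccard overlap of the two masks equals `1 - air_motion_fraction`
#' (up to the one-voxel rounding of the construction).
#'
#' @param geometry A [scan_geometry()].
#' @param air_motion_fraction Requested inter-baseline air motion in
#'   `[0, 1]`; `0` gives identical masks (Jaccard 1), `1` disjoint masks.
#' @param air_volume_ml Gastrointestinal air volume of the first baseline
#'   in mL; `0` gives an air-free session.
#' @param seed Integer seed; the anatomy is a deterministic function of it.
#' @param fat_thickness_cm Thickness of the subcutaneous fat ring in cm.
#' @param air_center_cm In-plane centre of the air pocket, in cm from the
#'   FOV centre. The default places it abutting the vagina/rectum tracks
#'   so that moving air corrupts nearby ROIs, as it does clinically.
#'
#' @return An object of class `anatomy_model`: body/fat masks, the two
#'   baseline air masks (`air_s00`, `air_s01`), and a `tracks` tibble
#'   (`location`, `slice`, `ix`, `iy`, `x_cm`, `y_cm`, `slice_offset_cm`)
#'   whose in-plane positions double as the per-slice probe ROI centres.
#' @export
generate_anatomy <- function(geometry, air_motion_fraction = 0,
                             air_volume_ml = 200, seed = 1L,
                             fat_thickness_cm = 1.5,
                             air_center_cm = c(4, -3)) {
  stopifnot(inherits(geometry, "scan_geometry"),
            air_motion_fraction >= 0, air_motion_fraction <= 1,
            air_volume_ml >= 0, fat_thickness_cm > 0)
  set.seed(as.integer(seed))

  nx <- geometry$matrix
  nz <- geometry$n_slices
  xs <- axis_coords_cm(geometry)
  zs <- slice_offsets_cm(geometry)

  # Body: in-plane ellipse, constant across slices.
  a <- 0.42 * geometry$fov_cm
  b <- 0.34 * geometry$fov_cm
  e2d <- outer(xs^2 / a^2, xs^2 / b^2, `+`)
  body2d <- e2d <= 1
  # Fat ring: between the body boundary and an inner scaled ellipse.
  inner <- (1 - fat_thickness_cm / ((a + b) / 2))^2
  fat2d <- body2d & e2d > inner

  body_mask <- array(body2d, dim = c(nx, nx, nz))
  fat_mask <- array(fat2d, dim = c(nx, nx, nz))

  # Probe tracks: fixed in-plane stations, 2-8 consecutive slices each.
  track_xy <- list(bladder = c(0, 7), vagina = c(0, -1), rectum = c(0, -5))
  spans <- sample(2:8, 3, replace = TRUE)
  spans <- pmin(spans, nz)
  tracks <- purrr::imap(track_xy, function(xy, loc) {
    span <- spans[[match(loc, names(track_xy))]]
    lo_max <- nz - span + 1
    start <- max(1L, min(lo_max, floor((nz - span) / 2) + 1L))
    slices <- seq(start, length.out = span)
    tibble::tibble(
      location = loc, slice = as.integer(slices),
      ix = which.min(abs(xs - xy[1])), iy = which.min(abs(xs - xy[2])),
      x_cm = xs[which.min(abs(xs - xy[1]))],
      y_cm = xs[which.min(abs(xs - xy[2]))],
      slice_offset_cm = zs[slices]
    )
  })
  tracks <- dplyr::bind_rows(tracks)

  # Air pockets: the requested_vox body voxels (excluding fat and a guard
  # cylinder around each track) closest in an ellipsoidal metric to the
  # air centre. Taking voxels in metric order pins the count exactly.
  vox_ml <- geometry$voxel_volume_ml
  requested_vox <- round(air_volume_ml / vox_ml)
  air_a <- array(FALSE, dim = c(nx, nx, nz))
  air_b <- air_a
  if (requested_vox > 0) {
    guard <- matrix(TRUE, nx, nx)
    for (loc in unique(tracks$location)) {
      tr <- tracks[tracks$location == loc, ][1, ]
      d2 <- outer((xs - tr$x_cm)^2, (xs - tr$y_cm)^2, `+`)
      guard <- guard & d2 > 1.0^2
    }
    allowed <- body_mask & !fat_mask & array(guard, dim = c(nx, nx, nz))
    if (requested_vox > sum(allowed)) {
      stop("requested air volume exceeds the available body volume",
           call. = FALSE)
    }
    zc <- zs[ceiling(nz / 2)]
    dist2 <- ell_metric(xs, zs, center = c(air_center_cm, zc),
                        aspect = c(1.3, 1.0, 0.9))
    ord <- order(ifelse(allowed, dist2, Inf))
    air_a[ord[seq_len(requested_vox)]] <- TRUE

    air_b <- displace_air(air_a, allowed, air_motion_fraction,
                          xs, zs, air_center_cm, zc)
  }

  structure(
    list(
      geometry = geometry, body_mask = body_mask, fat_mask = fat_mask,
      air_s00 = air_a, air_s01 = air_b, tracks = tracks,
      air_center_cm = air_center_cm, seed = as.integer(seed)
    ),
    class = "anatomy_model"
  )
}

# Ellipsoidal squared metric around `center` (cm), anisotropy by `aspect`.
ell_metric <- function(xs, zs, center, aspect) {
  nx <- length(xs)
  nz <- length(zs)
  dx2 <- (xs - center[1])^2 / aspect[1]^2
  dy2 <- (xs - center[2])^2 / aspect[2]^2
  dz2 <- (zs - center[3])^2 / aspect[3]^2
  inplane <- outer(dx2, dy2, `+`)
  array(rep(inplane, nz), dim = c(nx, nx, nz)) +
    rep(dz2, each = nx * nx)
}

# Build the second baseline's air mask from the first so that
# J(A, B) = (V - m) / (V + m) with m chosen from the requested motion.
# Voxels leave from the low-x flank and accrete on the high-x flank,
# mimicking a lateral displacement of the pocket.
displace_air <- function(air_a, allowed, motion, xs, zs, center_cm, zc) {
  v <- sum(air_a)
  j_req <- 1 - motion
  m <- round(v * (1 - j_req) / (1 + j_req))
  if (m == 0) return(air_a)

  idx <- which(air_a, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  drop_lin <- which(air_a)[ord][seq_len(m)]
  air_b <- air_a
  air_b[drop_lin] <- FALSE

  shift_cm <- 1 + 2 * motion
  cand <- allowed & !air_a
  dist2 <- ell_metric(xs, zs, center = c(center_cm[1] + shift_cm,
                                         center_cm[2], zc),
                      aspect = c(1.3, 1.0, 0.9))
  cand_ord <- order(ifelse(cand, dist2, Inf))
  add <- cand_ord[seq_len(m)]
  if (sum(cand) < m) {
    stop("not enough room to displace the air pocket", call. = FALSE)
  }
  air_b[add] <- TRUE
  air_b
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat(sprintf(
    "<anatomy_model> %d air voxels (S00), %d (S01), Jaccard %.3f, %d fat voxels\n",
    sum(x$air_s00), sum(x$air_s01),
    jaccard_coefficient(x$air_s00, x$air_s01), sum(x$fat_mask)
  ))
  invisible(x)
}
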