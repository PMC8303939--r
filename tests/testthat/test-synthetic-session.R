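test_that("ground truth follows the Gaussian focus and saturating ramp", {
  # odd matrix puts voxel centres exactly on 0 cm and 3 cm
  a <- generate_anatomy(scan_geometry(9, 49, fov_cm = 24.5), 0, 60,
                        seed = 2)
  tr <- generate_truth(a, heating = list(center_cm = c(0, 0), sigma_cm = 3,
                                         peak_C = 4, ramp_min = 15),
                       n_scans = 9)
  # both baselines are exactly unheated
  expect_true(all(tr$dt_true[[1]] == 0))
  expect_true(all(tr$dt_true[[2]] == 0))
  expect_true(all(diff(tr$scan_times_s) > 0))
  # closed form: 3 cm from the centre at saturation = 4 exp(-1/2)
  xs <- pelvitherm:::axis_coords_cm(a$geometry)
  ix <- which.min(abs(xs - 3))
  iy <- which.min(abs(xs - 0))
  zc <- ceiling(a$geometry$n_slices / 2)
  expect_equal(xs[ix], 3)
  expect_equal(tr$focus_field[ix, iy, zc], 4 * exp(-0.5),
               tolerance = 1e-10)
  # fat stays thermally inert
  expect_true(all(tr$focus_field[a$fat_mask] == 0))
  # zero peak means zero truth everywhere, always
  tr0 <- generate_truth(a, heating = list(center_cm = c(0, 0), sigma_cm = 3,
                                          peak_C = 0, ramp_min = 15))
  expect_true(all(vapply(tr0$dt_true, function(m) all(m == 0), logical(1))))
})

test_that("heating ramp saturates at the peak", {
  expect_equal(pelvitherm:::heating_ramp(1e9, 180, 900), 1)
  expect_equal(pelvitherm:::heating_ramp(180, 180, 900), 0)
  expect_equal(pelvitherm:::heating_ramp(0, 180, 900), 0)
  # instantaneous ramp limit
  expect_equal(pelvitherm:::heating_ramp(c(100, 200), 180, 0), c(0, 1))
})

test_that("a focus outside the body is rejected", {
  a <- generate_anatomy(fast_geometry(), 0, 0, seed = 2)
  expect_error(
    generate_truth(a, heating = list(center_cm = c(12, 8), sigma_cm = 3,
                                     peak_C = 4, ramp_min = 15)),
    "outside the body"
  )
})

test_that("confounder-free encoding decodes exactly (round trip)", {
  s <- fast_session(seed = 5, motion = 0, noise_sd_rad = 0, drift = NULL,
                    air_artifact_rad = 0, probe_noise_sd_C = 0)
  series <- session_delta_t(s)
  for (n in seq_along(series$maps)) {
    truth <- s$truth$dt_true[[n + 2]]
    expect_lt(max(abs(series$maps[[n]] - truth)), 1e-6)
  }
})

test_that("a uniform +1 degC step shifts phase by gamma alpha B0 TE", {
  g <- fast_geometry()
  a <- generate_anatomy(g, 0, 0, seed = 7)
  tr <- generate_truth(a, heating = list(center_cm = c(0, 0), sigma_cm = 3,
                                         peak_C = 4, ramp_min = 15),
                       n_scans = 2)
  # overwrite the truth with a uniform +1 degC in non-fat body
  step <- 1 * (a$body_mask & !a$fat_mask)
  tr$dt_true <- lapply(tr$dt_true, function(m) step)
  tr$dt_true[[1]] <- step * 0
  s <- encode_session(tr, a, prfs_constants(), drift = NULL,
                      noise_sd_rad = 0, air_artifact_rad = 0, seed = 1)
  dphi <- pelvitherm:::wrap_phase(s$scans[[3]]$phase - s$scans[[1]]$phase)
  inside <- a$body_mask & !a$fat_mask
  expect_equal(unique(round(dphi[inside], 9)), round(-7.663875e-3, 9))
})

test_that("a constant drift phase decodes as a uniform apparent
           temperature and is removed by fat referencing", {
  g <- fast_geometry()
  a <- generate_anatomy(g, 0, 0, seed = 8)
  tr <- generate_truth(a, heating = list(center_cm = c(0, 0), sigma_cm = 3,
                                         peak_C = 0, ramp_min = 15),
                       n_scans = 2)
  cdrift <- list(coef_rad_per_h = c(0.02, 0, 0, 0, 0, 0))
  s <- encode_session(tr, a, prfs_constants(), drift = cdrift,
                      noise_sd_rad = 0, air_artifact_rad = 0, seed = 1)
  series <- session_delta_t(s)
  k <- prfs_constants()$rad_per_C
  t1 <- series$scan_times_s[1]
  expected <- 0.02 * (t1 / 3600) / k
  expect_equal(mean(series$maps[[1]]), expected, tolerance = 1e-9)
  expect_lt(stats::sd(series$maps[[1]]), 1e-9)
  # fat-referenced correction restores zero everywhere
  corrected <- series |>
    mask_low_snr() |>
    correct_drift(a$fat_mask)
  expect_lt(max(abs(corrected$maps[[1]])), 1e-9)
})

test_that("probe mapping yields one reading per position every cycle", {
  a <- generate_anatomy(fast_geometry(), 0, 0, seed = 4)
  tr <- generate_truth(a, heating = list(center_cm = c(0, 0), sigma_cm = 3,
                                         peak_C = 2, ramp_min = 15),
                       n_scans = 9)
  probes <- sample_probe_readings(tr, a, duration_s = 5400, noise_sd_C = 0,
                                  seed = 1)
  # 90-min session mapped every 5 min: floor(5400/300) + 1 = 19 cycles
  expect_equal(length(unique(probes$time_s)), 19)
  counts <- table(probes$location, probes$time_s)
  spans <- table(a$tracks$location)
  for (loc in rownames(counts)) {
    expect_true(all(counts[loc, ] == spans[[loc]]))
  }
  # noise-free readings equal the truth sampled on the track
  row1 <- probes[probes$time_s == 5400, ][1, ]
  tr_row <- a$tracks[a$tracks$location == row1$location, ][1, ]
  ramp <- pelvitherm:::heating_ramp(5400, tr$heat_on_s, tr$tau_s)
  expect_equal(row1$temp_C,
               tr$focus_field[tr_row$ix, tr_row$iy, tr_row$slice] * ramp)
})

test_that("identical seeds reproduce a bit-identical session", {
  s1 <- fast_session(seed = 123)
  s2 <- fast_session(seed = 123)
  expect_identical(s1, s2)
  s3 <- fast_session(seed = 124)
  expect_false(identical(s1$scans[[3]]$phase, s3$scans[[3]]$phase))
})

test_that("encoded phases are wrapped into (-pi, pi]", {
  s <- fast_session(seed = 9, motion = 0.5,
                    drift = list(coef_rad_per_h = c(3, 0.1, -0.1,
                                                    0.003, 0, 0.003)))
  for (sc in s$scans) {
    expect_true(all(sc$phase > -pi & sc$phase <= pi))
  }
})
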