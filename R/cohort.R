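#' Configuration of a synthetic cohort experiment
#'
#' One flat list of scalars drives the whole simulate -> reconstruct ->
#' features -> evaluate -> select chain, so a cohort run is reproducible
#' from the config plus its seed alone. The defaults are the package's
#' study conditions (see the methods vignette): a 96 x 96 x 9 grid, nine
#' treatment scans, heating peaking at 4 degC, air motion graded over
#' 0-0.5, quadratic drift of ~0.05 rad/h and a susceptibility artifact
#' of 0.2 rad scaled by the realised air motion.
#'
#' @param n_sessions Number of sessions in the cohort.
#' @param matrix,n_slices Grid of the synthetic scans.
#' @param alpha_ppm_per_C PRF change coefficient.
#' @param motion_max Air-motion fractions are evenly graded over
#'   `[0, motion_max]` with small seeded jitter.
#' @param air_volume_range_ml,fat_thickness_range_cm Per-session uniform
#'   ranges.
#' @param peak_C,sigma_cm,ramp_min Heating focus parameters.
#' @param n_scans Treatment scans per session.
#' @param drift_rad_per_h Scale of the per-session random quadratic
#'   drift field (rad per hour at the FOV centre).
#' @param noise_sd_rad,air_artifact_rad,probe_noise_sd_C Confounder
#'   levels.
#' @param threshold_C Fixed exclusion threshold (the clinical 7 degC).
#' @param optimize_threshold Re-optimize the threshold per session
#'   against the session's probes instead of using `threshold_C`.
#' @param selection_feature,selection_cutoff Feature used for session
#'   selection; `selection_cutoff = "roc"` derives the cut-off from the
#'   cohort's own ROC curve, a number fixes it.
#' @param n_boot,n_perm Resampling effort for AUC inference.
#' @param seed Root seed; every downstream random draw derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_sessions = 30L, matrix = 96L, n_slices = 9L,
                          alpha_ppm_per_C = -0.001,
                          motion_max = 0.5,
                          air_volume_range_ml = c(80, 250),
                          fat_thickness_range_cm = c(1.0, 2.2),
                          peak_C = 4, sigma_cm = 3, ramp_min = 15,
                          n_scans = 9L,
                          drift_rad_per_h = 0.05,
                          noise_sd_rad = 5e-4,
                          air_artifact_rad = 0.5,
                          probe_noise_sd_C = 0.05,
                          threshold_C = 7,
                          optimize_threshold = FALSE,
                          selection_feature = "jaccard",
                          selection_cutoff = "roc",
                          n_boot = 500L, n_perm = 500L,
                          seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' Read / write a cohort configuration as YAML
#'
#' @param path File path.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cohort_config, vals)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a full synthetic cohort experiment
#'
#' Generates `n_sessions` synthetic treatment sessions with graded
#' gastrointestinal air motion, reconstructs each one through the full
#' thermometry chain, benchmarks it against its probe traces, computes
#' the imaging features, evaluates every feature's ROC against the
#' acceptability labels, selects sessions by the configured feature and
#' cut-off, and aggregates an all-versus-selected summary table.
#'
#' @param config A [cohort_config()].
#' @param progress Print one line per session.
#' @return An object of class `cohort_experiment`: `config`, `features`
#'   and `metrics` tibbles, `labels`, the `roc` analysis, the applied
#'   `cutoff`, `selected_ids`, and the `summary` ([summarize_cohort()]).
#' @export
run_cohort_experiment <- function(config = cohort_config(),
                                  progress = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(config$seed))
  n <- config$n_sessions
  session_seeds <- sample.int(.Machine$integer.max, n)
  spacing <- config$motion_max / max(1, n - 1)
  motions <- pmin(config$motion_max,
                  seq(0, config$motion_max, length.out = n) +
                    stats::runif(n, 0, spacing / 2))
  air_vols <- stats::runif(n, config$air_volume_range_ml[1],
                           config$air_volume_range_ml[2])
  fat_thick <- stats::runif(n, config$fat_thickness_range_cm[1],
                            config$fat_thickness_range_cm[2])
  drift_coefs <- lapply(seq_len(n), function(i) {
    s <- config$drift_rad_per_h
    stats::rnorm(6) * c(s, s / 25, s / 25, s / 625, s / 625, s / 625)
  })

  geometry <- scan_geometry(n_slices = config$n_slices,
                            matrix = config$matrix)
  constants <- prfs_constants(alpha_ppm_per_C = config$alpha_ppm_per_C)
  heating <- list(center_cm = c(0, 0), sigma_cm = config$sigma_cm,
                  peak_C = config$peak_C, ramp_min = config$ramp_min)

  features <- vector("list", n)
  metrics <- vector("list", n)
  for (i in seq_len(n)) {
    session <- simulate_session(
      seed = session_seeds[i], geometry = geometry, constants = constants,
      air_motion_fraction = motions[i], air_volume_ml = air_vols[i],
      fat_thickness_cm = fat_thick[i], heating = heating,
      n_scans = config$n_scans,
      drift = list(coef_rad_per_h = drift_coefs[[i]]),
      noise_sd_rad = config$noise_sd_rad,
      air_artifact_rad = config$air_artifact_rad,
      probe_noise_sd_C = config$probe_noise_sd_C
    )
    rec <- reconstruct_session(session, threshold_C = config$threshold_C,
                               optimize_threshold =
                                 config$optimize_threshold)
    features[[i]] <- dplyr::mutate(session_features(session),
                                   session_id = i)
    metrics[[i]] <- session_metrics(rec$roi_series, session$probe_traces,
                                    session_id = i)
    if (progress) {
      cat(sprintf("session %d/%d: motion %.2f, accuracy %.2f degC\n",
                  i, n, motions[i],
                  mean(metrics[[i]]$accuracy_C, na.rm = TRUE)))
    }
  }
  features <- dplyr::bind_rows(features)
  metrics <- dplyr::bind_rows(metrics)

  labels <- metrics |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(acceptable = mean(.data$accuracy_C, na.rm = TRUE) <= 1)

  both_classes <- length(unique(labels$acceptable)) == 2
  roc <- if (both_classes) {
    cohort_roc(features, labels, n_boot = config$n_boot,
               n_perm = config$n_perm, seed = config$seed)
  } else {
    NULL
  }
  cutoff <- if (identical(config$selection_cutoff, "roc")) {
    if (is.null(roc)) {
      stop("single-class acceptability labels: a ROC-derived cut-off is ",
           "unavailable; set a numeric selection_cutoff", call. = FALSE)
    }
    roc$results[[config$selection_feature]]$cutoff_opt
  } else {
    as.numeric(config$selection_cutoff)
  }
  selected <- select_sessions(features, cutoff = cutoff,
                              feature = config$selection_feature)
  summary <- summarize_cohort(metrics, selected)

  structure(
    list(config = config, session_seeds = session_seeds,
         motions = motions, features = features, metrics = metrics,
         labels = labels, roc = roc, cutoff = cutoff,
         selected_ids = selected, summary = summary),
    class = "cohort_experiment"
  )
}

#' @export
print.cohort_experiment <- function(x, ...) {
  ov <- x$summary$overall
  acc <- function(ds) ov$overall[ov$dataset == ds & ov$metric == "accuracy"]
  cat(sprintf(
    "<cohort_experiment> %d sessions, %d selected (%s >= %.3g)\n",
    x$config$n_sessions, length(x$selected_ids),
    x$config$selection_feature, x$cutoff))
  cat(sprintf("  overall accuracy: %.2f degC (all) -> %.2f degC (selected)\n",
              acc("all"), acc("selected")))
  invisible(x)
}

#' Tidy per-session metrics of a cohort experiment
#'
#' @param x A `cohort_experiment`.
#' @param ... Unused.
#' @return The per-session, per-location metrics tibble with the
#'   session's feature values and selection flag joined on.
#' @method tidy cohort_experiment
#' @export
tidy.cohort_experiment <- function(x, ...) {
  x$metrics |>
    dplyr::left_join(x$features, by = "session_id") |>
    dplyr::mutate(selected = .data$session_id %in% x$selected_ids)
}

#' One-row summary of a cohort experiment
#'
#' @param x A `cohort_experiment`.
#' @param ... Unused.
#' @return Tibble with overall accuracies, the selection cut-off and the
#'   Jaccard AUC.
#' @method glance cohort_experiment
#' @export
glance.cohort_experiment <- function(x, ...) {
  ov <- x$summary$overall
  pick <- function(ds, m) ov$overall[ov$dataset == ds & ov$metric == m]
  tibble::tibble(
    n_sessions = x$config$n_sessions,
    n_selected = length(x$selected_ids),
    cutoff = x$cutoff,
    auc_jaccard = x$roc$results$jaccard$auc %||% NA_real_,
    accuracy_all = pick("all", "accuracy"),
    accuracy_selected = pick("selected", "accuracy"),
    precision_all = pick("all", "precision"),
    precision_selected = pick("selected", "precision"),
    bias_all = pick("all", "bias"),
    bias_selected = pick("selected", "bias")
  )
}

#' Aggregation arithmetic of the clinical benchmarking table
#'
#' Reproduces, from printed per-location means alone, the derived
#' quantities of the clinical all-versus-selected comparison: overall
#' (cross-location) means, their deviations from the acceptability
#' thresholds, and the improvement percentages between datasets. Serves
#' as the worked-example surface for the aggregation conventions.
#'
#' @param per_location_means Tibble with columns `dataset`
#'   (`all`/`selected`), `metric` (`accuracy`/`precision`/`bias`),
#'   `location`, `mean`. Defaults to the published clinical values,
#'   [clinical_table2()].
#' @return A list of class `table2_arithmetic`: `overall` (tibble with
#'   `overall`, `overall_rounded`, `deviation_C`) and `improvement`
#'   (tibble with `improvement_pct`).
#' @export
#' @examples
#' t2 <- reproduce_table2_arithmetic()
#' t2$improvement
reproduce_table2_arithmetic <- function(per_location_means =
                                          clinical_table2()) {
  needed <- c("dataset", "metric", "location", "mean")
  stopifnot(all(needed %in% names(per_location_means)))
  by_loc <- per_location_means
  overall <- table2_overall(by_loc)
  improvement <- cohort_improvements(by_loc, overall)
  structure(list(overall = overall, improvement = improvement),
            class = "table2_arithmetic")
}

#' @export
print.table2_arithmetic <- function(x, ...) {
  print(x$overall)
  print(x$improvement)
  invisible(x)
}

#' Published per-location clinical benchmarking means
#'
#' The per-location mean accuracy, precision and bias of the clinical
#' study, for all treatment sessions and for the air-motion-selected
#' subset (Jaccard >= 0.91). These printed values are the inputs of the
#' worked-example aggregation in [reproduce_table2_arithmetic()].
#'
#' @return A tibble: `dataset`, `metric`, `location`, `mean` (degC).
#' @export
clinical_table2 <- function() {
  loc <- c("bladder", "rectum", "vagina")
  tibble::tibble(
    dataset = rep(c("all", "selected"), each = 9),
    metric = rep(rep(c("accuracy", "precision", "bias"), each = 3), 2),
    location = rep(loc, 6),
    mean = c(2.2, 1.9, 2.0, 1.7, 1.6, 1.7, -1.5, -1.2, -1.2,
             1.1, 1.1, 0.9, 1.2, 1.2, 1.3, -0.4, -0.4, 0.0)
  )
}
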