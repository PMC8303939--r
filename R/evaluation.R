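#' Accuracy, precision and bias of an MR-probe temperature pair
#'
#' The three benchmarking metrics comparing the ROI-mean MR thermometry
#' series with the aligned intraluminal probe series:
#' * accuracy — mean absolute difference (degC),
#' * precision — sample standard deviation of the MR series over time
#'   (temporal reproducibility; probe-free),
#' * bias — signed mean difference (negative means MR underestimates).
#'
#' Missing pairs are dropped pairwise before computation.
#'
#' @param mr Numeric vector of ROI-mean MR temperatures.
#' @param probe Numeric vector of aligned probe means (same length).
#' @return A single number, or `NA` when no pairs remain (accuracy and
#'   bias) / fewer than two values remain (precision).
#' @export
#' @examples
#' mrt_accuracy(c(1, 4), c(2, 2)) # 1.5
#' mrt_bias(c(1, 3), c(2, 2))    # 0 while accuracy is 1
#' mrt_precision(c(1, 2, 3))     # 1
mrt_accuracy <- function(mr, probe) {
  stopifnot(length(mr) == length(probe))
  keep <- !is.na(mr) & !is.na(probe)
  if (!any(keep)) return(NA_real_)
  mean(abs(mr[keep] - probe[keep]))
}

#' @rdname mrt_accuracy
#' @export
mrt_bias <- function(mr, probe) {
  stopifnot(length(mr) == length(probe))
  keep <- !is.na(mr) & !is.na(probe)
  if (!any(keep)) return(NA_real_)
  mean(mr[keep] - probe[keep])
}

#' @rdname mrt_accuracy
#' @export
mrt_precision <- function(mr) {
  mr <- mr[!is.na(mr)]
  if (length(mr) < 2) return(NA_real_)
  stats::sd(mr)
}

#' Align ROI means with probe cycle means
#'
#' For each scan, the probe mapping cycle whose start time is nearest to
#' the scan midpoint (within `max_offset_s`) provides the reference
#' reading; its per-location mean over the mapped positions is paired
#' with the ROI mean of that scan.
#'
#' @param roi_series ROI mean tibble from [roi_mean_series()].
#' @param probes Probe trace tibble.
#' @param scan_duration_s Scan duration used to compute midpoints.
#' @param max_offset_s Maximal admissible cycle-to-midpoint offset.
#' @return A tibble: `location`, `time_s`, `mr_C`, `probe_C`,
#'   `fraction_surviving`.
#' @export
align_mr_probe <- function(roi_series, probes, scan_duration_s = 83,
                           max_offset_s = 150) {
  pm <- probe_cycle_means(probes)
  cyc <- sort(unique(pm$time_s))
  roi_series |>
    dplyr::mutate(
      cycle_s = cyc[vapply(.data$time_s + scan_duration_s / 2,
                           function(m) which.min(abs(cyc - m)), integer(1))],
      offset_s = abs(.data$cycle_s - (.data$time_s + scan_duration_s / 2))
    ) |>
    dplyr::filter(.data$offset_s <= max_offset_s) |>
    dplyr::left_join(pm, by = c(location = "location", cycle_s = "time_s")) |>
    dplyr::transmute(.data$location, .data$time_s, mr_C = .data$mean_C,
                     probe_C = .data$probe_C,
                     fraction_surviving = .data$fraction_surviving)
}

#' Benchmark one session against its probe traces
#'
#' @param roi_series ROI mean tibble from [roi_mean_series()].
#' @param probes Probe trace tibble for the same session.
#' @param session_id Identifier carried into the output.
#' @param scan_duration_s,max_offset_s Passed to [align_mr_probe()].
#' @return A tibble with one row per probe location: `session_id`,
#'   `location`, `accuracy_C`, `precision_C`, `bias_C`, `n_timepoints`,
#'   `surviving_fraction`.
#' @export
session_metrics <- function(roi_series, probes, session_id = NA_integer_,
                            scan_duration_s = 83, max_offset_s = 150) {
  align_mr_probe(roi_series, probes, scan_duration_s, max_offset_s) |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(
      accuracy_C = mrt_accuracy(.data$mr_C, .data$probe_C),
      precision_C = mrt_precision(.data$mr_C),
      bias_C = mrt_bias(.data$mr_C, .data$probe_C),
      n_timepoints = sum(!is.na(.data$mr_C) & !is.na(.data$probe_C)),
      surviving_fraction = mean(.data$fraction_surviving, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(session_id = session_id, .before = 1)
}

#' Session-level acceptability for the ROC true condition
#'
#' A session's thermometry is acceptable when the session-level accuracy
#' (the mean of the available per-location accuracies) is at or below
#' the cut-off; the boundary is inclusive.
#'
#' @param metrics Per-location metrics tibble from [session_metrics()]
#'   (one session).
#' @param cutoff_C Acceptability cut-off (default 1 degC).
#' @return `TRUE`/`FALSE`, or `NA` when no location has a defined
#'   accuracy.
#' @export
session_acceptability <- function(metrics, cutoff_C = 1) {
  acc <- metrics$accuracy_C[!is.na(metrics$accuracy_C)]
  if (length(acc) == 0) return(NA)
  mean(acc) <= cutoff_C
}

#' One-way ANOVA comparison of a metric across probe locations
#'
#' @param data Tibble with a grouping column and a value column.
#' @param value,group Column names (strings) of the metric and the group.
#' @return A one-row tibble: `f_statistic`, `p_value`, `df_between`,
#'   `df_within`, `degenerate` (TRUE when the within-group variance is
#'   zero and the classical F is unbounded).
#' @export
compare_locations <- function(data, value = "accuracy_C",
                              group = "location") {
  df <- data.frame(y = data[[value]], g = factor(data[[group]]))
  df <- df[!is.na(df$y), ]
  tab <- table(df$g)
  if (sum(tab >= 2) < 2 || nlevels(droplevels(df$g)) < 2) {
    stop("need at least two groups with at least two values each",
         call. = FALSE)
  }
  aov_tab <- stats::anova(stats::lm(y ~ g, data = df))
  ssw <- aov_tab[["Sum Sq"]][2]
  degenerate <- ssw <= .Machine$double.eps * sum(df$y^2 + 1)
  tibble::tibble(
    f_statistic = aov_tab[["F value"]][1],
    p_value = aov_tab[["Pr(>F)"]][1],
    df_between = aov_tab[["Df"]][1],
    df_within = aov_tab[["Df"]][2],
    degenerate = degenerate
  )
}

#' Cohort summary in the style of the clinical benchmarking table
#'
#' Aggregates per-session, per-location metrics over two datasets — all
#' sessions and a selected subset — into per-location mean +/- sd rows,
#' overall (cross-location) values, deviations from the acceptability
#' thresholds (accuracy 1 degC, precision 1 degC, bias +/-0.5 degC) and
#' improvement percentages between the datasets.
#'
#' Conventions (documented in the methods vignette): the overall value of
#' a metric is the unrounded mean of its three per-location means;
#' deviations compare the overall value rounded to one decimal with the
#' threshold (absolute value for bias); the accuracy improvement is
#' computed from the rounded overalls, while precision and bias
#' improvements are means of per-location relative improvements
#' (absolute values for bias).
#'
#' @param metrics Tibble from [session_metrics()] over all sessions.
#' @param selected_ids Session ids of the selected subset.
#' @param patients Optional tibble `session_id`, `patient_id` to count
#'   patients; if absent each session counts as its own patient.
#' @return An object of class `cohort_summary`: `by_location` (tibble),
#'   `overall` (tibble), `improvement` (tibble), `counts` (tibble).
#' @export
summarize_cohort <- function(metrics, selected_ids, patients = NULL) {
  stopifnot(all(selected_ids %in% metrics$session_id))
  datasets <- list(all = metrics,
                   selected = metrics[metrics$session_id %in% selected_ids, ])

  by_loc <- purrr::imap(datasets, function(m, nm) {
    m |>
      tidyr::pivot_longer(dplyr::all_of(c("accuracy_C", "precision_C",
                                          "bias_C")),
                          names_to = "metric", values_to = "value") |>
      dplyr::mutate(metric = sub("_C$", "", .data$metric)) |>
      dplyr::group_by(.data$metric, .data$location) |>
      dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                       sd = stats::sd(.data$value, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(dataset = nm, .before = 1)
  }) |> dplyr::bind_rows()

  overall <- table2_overall(by_loc)
  improvement <- cohort_improvements(by_loc, overall)

  n_all <- length(unique(metrics$session_id))
  n_sel <- length(unique(selected_ids))
  if (is.null(patients)) {
    p_all <- n_all
    p_sel <- n_sel
  } else {
    p_all <- length(unique(patients$patient_id))
    p_sel <- length(unique(
      patients$patient_id[patients$session_id %in% selected_ids]))
  }
  counts <- tibble::tibble(
    dataset = c("all", "selected"),
    sessions = c(n_all, n_sel),
    sessions_pct = 100 * c(1, if (n_all > 0) n_sel / n_all else NA),
    patients = c(p_all, p_sel),
    patients_pct = 100 * c(1, if (p_all > 0) p_sel / p_all else NA)
  )

  structure(list(by_location = by_loc, overall = overall,
                 improvement = improvement, counts = counts),
            class = "cohort_summary")
}

# Overall (cross-location) value per dataset and metric, its one-decimal
# rounding, and the deviation from the acceptability threshold
# (accuracy 1, precision 1, bias +/-0.5 degC; absolute value for bias).
table2_overall <- function(by_loc) {
  thresholds <- c(accuracy = 1, precision = 1, bias = 0.5)
  by_loc |>
    dplyr::group_by(.data$dataset, .data$metric) |>
    dplyr::summarise(overall = mean(.data$mean), .groups = "drop") |>
    dplyr::mutate(
      overall_rounded = round(.data$overall, 1),
      deviation_C = round(
        ifelse(.data$metric == "bias",
               abs(.data$overall_rounded) - thresholds["bias"],
               .data$overall_rounded - thresholds[.data$metric]), 1)
    )
}

cohort_improvements <- function(by_loc, overall) {
  ov <- function(ds, m) {
    overall$overall[overall$dataset == ds & overall$metric == m]
  }
  ovr <- function(ds, m) {
    overall$overall_rounded[overall$dataset == ds & overall$metric == m]
  }
  per_loc_impr <- function(m, absolute = FALSE) {
    a <- by_loc[by_loc$dataset == "all" & by_loc$metric == m, ]
    s <- by_loc[by_loc$dataset == "selected" & by_loc$metric == m, ]
    s <- s[match(a$location, s$location), ]
    va <- if (absolute) abs(a$mean) else a$mean
    vs <- if (absolute) abs(s$mean) else s$mean
    keep <- va != 0 # a location that is already exact has no relative gain
    if (!any(keep)) return(NA_real_)
    100 * mean((va[keep] - vs[keep]) / va[keep])
  }
  # Accuracy improvement from the one-decimal overalls (the quoted
  # convention); fall back to unrounded values when rounding collapses
  # the denominator to zero.
  acc_all <- if (ovr("all", "accuracy") != 0) ovr("all", "accuracy") else
    ov("all", "accuracy")
  acc_sel <- if (ovr("all", "accuracy") != 0) ovr("selected", "accuracy")
    else ov("selected", "accuracy")
  acc <- if (acc_all != 0) 100 * (acc_all - acc_sel) / acc_all else
    NA_real_
  tibble::tibble(
    metric = c("accuracy", "precision", "bias"),
    improvement_pct = c(acc, per_loc_impr("precision"),
                        per_loc_impr("bias", absolute = TRUE))
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$overall)
  print(x$improvement)
  invisible(x)
}

#' @export
format_cohort_markdown <- function(summary) {
  UseMethod("format_cohort_markdown")
}

#' Render a cohort summary as a Markdown table
#'
#' @param summary A [summarize_cohort()] result.
#' @return A character vector of Markdown lines (one table row each).
#' @export
format_cohort_markdown.cohort_summary <- function(summary) {
  wide <- summary$by_location |>
    dplyr::mutate(cell = sprintf("%.1f ± %.1f", .data$mean, .data$sd)) |>
    dplyr::select(dplyr::all_of(c("dataset", "metric", "location",
                                  "cell"))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of("location"),
                       values_from = dplyr::all_of("cell"))
  dev <- summary$overall |>
    dplyr::transmute(.data$dataset, .data$metric,
                     deviation = sprintf("%+.1f", .data$deviation_C))
  wide <- dplyr::left_join(wide, dev, by = c("dataset", "metric"))
  header <- paste("| dataset | metric |",
                  paste(setdiff(names(wide), c("dataset", "metric",
                                               "deviation")),
                        collapse = " | "), "| deviation |")
  sep <- gsub("[^|]", "-", header)
  rows <- apply(wide, 1, function(r) paste("|", paste(r, collapse = " | "),
                                           "|"))
  c(header, sep, rows)
}
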