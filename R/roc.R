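#' ROC curve of an imaging feature as a predictor of acceptability
#'
#' Builds the ROC curve of a score against binary labels. Thresholds are
#' placed at every observed score value plus `-Inf`/`Inf` sentinels; a
#' session is called positive when its score is at or beyond the
#' threshold in the declared orientation (inclusive on the positive
#' side), so any reported cut-off is an attainable data value.
#'
#' @param scores Numeric feature values, one per session.
#' @param labels Logical (or 0/1) acceptability labels.
#' @param orientation `"higher_is_positive"` (e.g. Jaccard, distance) or
#'   `"lower_is_positive"` (e.g. air volume).
#' @param feature_name Optional label carried into the result.
#' @return An object of class `pelvi_roc`: `points` (tibble `threshold`,
#'   `fpr`, `tpr`), `auc`, `cutoff_opt`, `orientation`, `feature_name`,
#'   and `n_pos`/`n_neg`.
#' @export
roc_curve <- function(scores, labels,
                      orientation = c("higher_is_positive",
                                      "lower_is_positive"),
                      feature_name = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be TRUE/FALSE", call. = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve",
         call. = FALSE)
  }

  s <- if (orientation == "higher_is_positive") scores else -scores
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & s >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & s >= t) / n_neg, numeric(1))
  points <- tibble::tibble(
    threshold = c(Inf, thr, -Inf) *
      if (orientation == "higher_is_positive") 1 else -1,
    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)
  )

  res <- structure(
    list(points = points, orientation = orientation,
         feature_name = feature_name, n_pos = n_pos, n_neg = n_neg,
         scores = scores, labels = labels),
    class = "pelvi_roc"
  )
  res$auc <- roc_auc(res)
  res$cutoff_opt <- optimal_cutoff(res)
  res
}

#' Area under the ROC curve
#'
#' Trapezoidal area of the curve; equal (to machine precision) to the
#' Mann-Whitney concordance probability with ties counted one half.
#'
#' @param result A `pelvi_roc`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(result) {
  p <- result$points[order(result$points$fpr, result$points$tpr), ]
  sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' Optimal cut-off by distance to the top-left corner
#'
#' The threshold whose operating point minimizes the Euclidean distance
#' to (FPR, TPR) = (0, 1). Ties are broken towards higher specificity
#' (lower FPR), then towards the more conservative (more positive-side)
#' threshold; the `+/-Inf` sentinels are never returned when a finite
#' threshold ties them.
#'
#' @param result A `pelvi_roc`.
#' @return The cut-off in feature units.
#' @export
optimal_cutoff <- function(result) {
  p <- result$points
  d2 <- p$fpr^2 + (1 - p$tpr)^2
  best <- which(d2 <= min(d2) + 1e-15)
  best <- best[order(p$fpr[best], -abs(is.finite(p$threshold[best])))]
  cand <- p$threshold[best]
  finite <- cand[is.finite(cand)]
  if (length(finite) > 0) finite[1] else cand[1]
}

#' Resampling inference for the AUC
#'
#' A stratified bootstrap (resampling positives and negatives
#' separately) gives a percentile 95% confidence interval for the AUC; a
#' label-permutation test gives the p-value for the null hypothesis that
#' the AUC equals 0.5 (two-sided, by the symmetry of the permutation
#' null around 0.5).
#'
#' @param scores,labels,orientation As in [roc_curve()].
#' @param n_boot Bootstrap replicates (default 2000).
#' @param n_perm Permutation replicates (default 2000).
#' @param seed Integer seed.
#' @return A one-row tibble: `auc`, `ci_low`, `ci_high`, `p_value`,
#'   `widened` (TRUE when a class was too small, < 3, to resample
#'   meaningfully; the CI is then the full `[0, 1]`).
#' @export
auc_inference <- function(scores, labels,
                          orientation = "higher_is_positive",
                          n_boot = 2000, n_perm = 2000, seed = 1L) {
  set.seed(as.integer(seed))
  labels <- as.logical(labels)
  obs <- roc_curve(scores, labels, orientation)$auc
  pos <- which(labels)
  neg <- which(!labels)

  widened <- length(pos) < 3 || length(neg) < 3
  if (widened) {
    ci <- c(0, 1)
  } else {
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      fast_auc(scores[idx], labels[idx], orientation)
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  }

  perm <- vapply(seq_len(n_perm), function(i) {
    fast_auc(scores, sample(labels), orientation)
  }, numeric(1))
  p <- (1 + sum(abs(perm - 0.5) >= abs(obs - 0.5) - 1e-12)) / (n_perm + 1)

  tibble::tibble(auc = obs, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, widened = widened)
}

# Mann-Whitney AUC (ties counted one half) without building the curve.
fast_auc <- function(scores, labels, orientation = "higher_is_positive") {
  s <- if (orientation == "higher_is_positive") scores else -scores
  r <- rank(s)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC analysis of every imaging feature in a cohort
#'
#' Data-frame-first wrapper: joins the feature table with per-session
#' acceptability labels and runs [roc_curve()] plus [auc_inference()]
#' per feature, with the declared physical orientations (higher Jaccard
#' and larger air distance favour reliability; larger air and fat
#' volumes disfavour it).
#'
#' @param features Tibble from [session_features()] rows.
#' @param labels Tibble `session_id`, `acceptable` (logical).
#' @param feature_names Features to analyse.
#' @param n_boot,n_perm,seed Passed to [auc_inference()].
#' @return A list with `results` (named list of `pelvi_roc`) and `table`
#'   (tibble `feature`, `auc`, `cutoff`, `ci_low`, `ci_high`, `p_value`).
#' @export
cohort_roc <- function(features, labels,
                       feature_names = c("jaccard", "air_volume_ml",
                                         "fat_volume_ml",
                                         "min_distance_cm"),
                       n_boot = 2000, n_perm = 2000, seed = 1L) {
  merged <- dplyr::inner_join(features, labels, by = "session_id")
  orientations <- feature_orientation(feature_names)
  results <- purrr::map2(feature_names, orientations, function(f, o) {
    r <- roc_curve(merged[[f]], merged$acceptable, o, feature_name = f)
    r$inference <- auc_inference(merged[[f]], merged$acceptable, o,
                                 n_boot = n_boot, n_perm = n_perm,
                                 seed = seed)
    r
  })
  names(results) <- feature_names
  table <- purrr::map_dfr(results, function(r) {
    dplyr::mutate(r$inference, feature = r$feature_name,
                  cutoff = r$cutoff_opt, .before = 1)
  })
  list(results = results, table = table)
}

#' Declared orientation of each imaging feature
#'
#' @param feature_names Character vector of feature names.
#' @return Character vector of orientations.
#' @export
feature_orientation <- function(feature_names) {
  defaults <- c(jaccard = "higher_is_positive",
                min_distance_cm = "higher_is_positive",
                air_volume_ml = "lower_is_positive",
                fat_volume_ml = "lower_is_positive")
  out <- defaults[feature_names]
  out[is.na(out)] <- "higher_is_positive"
  unname(out)
}

#' Select sessions by a feature cut-off
#'
#' Inclusive, orientation-aware selection: with `higher_is_positive` the
#' sessions with `feature >= cutoff` are retained (e.g. Jaccard >= 0.91,
#' the clinical cut-off), with `lower_is_positive` those with
#' `feature <= cutoff`.
#'
#' @param features Feature tibble with a `session_id` column.
#' @param cutoff Cut-off value (default 0.91, the clinical Jaccard
#'   optimum).
#' @param feature Feature column name (default `"jaccard"`).
#' @param orientation Defaults to the declared orientation of `feature`.
#' @return The selected `session_id`s.
#' @export
select_sessions <- function(features, cutoff = 0.91, feature = "jaccard",
                            orientation = NULL) {
  orientation <- orientation %||% feature_orientation(feature)
  v <- features[[feature]]
  keep <- if (orientation == "higher_is_positive") v >= cutoff else
    v <= cutoff
  features$session_id[keep]
}

#' @export
print.pelvi_roc <- function(x, ...) {
  cat(sprintf("<pelvi_roc> %s: AUC %.3f, cut-off %.3g (%s; %d+/%d-)\n",
              x$feature_name %||% "feature", x$auc, x$cutoff_opt,
              x$orientation, x$n_pos, x$n_neg))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the operating points of a ROC curve
#'
#' @param x A `pelvi_roc`.
#' @param ... Unused.
#' @return The `points` tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy pelvi_roc
#' @export
tidy.pelvi_roc <- function(x, ...) {
  x$points
}

#' One-row summary of a ROC analysis
#'
#' @param x A `pelvi_roc`.
#' @param ... Unused.
#' @return Tibble with `feature`, `auc`, `cutoff_opt`, `orientation` and,
#'   when inference was run, `ci_low`, `ci_high`, `p_value`.
#' @method glance pelvi_roc
#' @export
glance.pelvi_roc <- function(x, ...) {
  out <- tibble::tibble(
    feature = x$feature_name %||% NA_character_,
    auc = x$auc, cutoff_opt = x$cutoff_opt, orientation = x$orientation
  )
  if (!is.null(x$inference)) {
    out <- dplyr::bind_cols(
      out, x$inference[, c("ci_low", "ci_high", "p_value")])
  }
  out
}
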