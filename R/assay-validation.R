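#' Normalization policy
#'
#' The recombination and reversion readouts (intra-HR, inter-HR, GR) are
#' analyzed as fold of the wild-type control median, which puts all three
#' frequency assays on a common unitless scale; the small colony phenotype
#' is kept in raw cells-per-colony, where its cut-off lives naturally. Both
#' modes are available per assay.
#'
#' @return Named character vector mapping each assay to `"fold_of_control_median"`
#'   or `"raw"`.
#' @export
default_normalization <- function() {
  c(intra_hr = "fold_of_control_median", inter_hr = "fold_of_control_median",
    gr = "fold_of_control_median", scp = "raw")
}

#' Summarize one measurement into a median and interquartile range
#'
#' Under fold normalization every replicate is divided by the median of the
#' matched wild-type control replicates before summarizing. Quartiles use
#' linear interpolation between order statistics ([stats::quantile()] type 7).
#'
#' @param replicates Numeric vector of replicate readouts.
#' @param control_replicates Numeric vector of wild-type control readouts
#'   (required under fold normalization).
#' @param normalization `"fold_of_control_median"` or `"raw"`.
#' @return List with `median_value`, `q1`, `q3`, `n_replicates`, `values`
#'   (the normalized replicate vector).
#' @export
summarize_measurement <- function(replicates,
                                  control_replicates = numeric(0),
                                  normalization = c("fold_of_control_median",
                                                    "raw")) {
  normalization <- match.arg(normalization)
  stopifnot(length(replicates) >= 1)
  values <- normalize_replicates(replicates, control_replicates, normalization)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median_value = q[2], q1 = q[1], q3 = q[3],
       n_replicates = length(replicates), values = values)
}

normalize_replicates <- function(replicates, control_replicates,
                                 normalization) {
  if (normalization == "raw") return(replicates)
  if (length(control_replicates) == 0) {
    rlang::abort("fold normalization requested but no control replicates",
                 class = "ybrca1_validation_error")
  }
  ctl <- stats::median(control_replicates)
  if (ctl == 0) {
    rlang::abort("control median is zero; fold normalization is degenerate",
                 class = "ybrca1_degenerate_control_error")
  }
  replicates / ctl
}

#' Summarize every measurement of one assay across a panel
#'
#' @param panel An [assay_panel()].
#' @param assay One of [ybrca1_assays()].
#' @param normalization Per this assay; defaults to [default_normalization()].
#' @return Tibble: `variant_id`, `assay`, `prior_label`, `median_value`,
#'   `q1`, `q3`, `n_replicates`.
#' @export
summarize_assay <- function(panel, assay,
                            normalization = default_normalization()[[assay]]) {
  stopifnot(inherits(panel, "assay_panel"), assay %in% ybrca1_assays())
  m <- panel$measurements[panel$measurements$assay == assay, ]
  if (nrow(m) == 0) {
    rlang::abort(paste0("panel has no measurements for assay ", assay),
                 class = "ybrca1_consistency_error")
  }
  rows <- lapply(seq_len(nrow(m)), function(i) {
    s <- summarize_measurement(m$replicates[[i]], m$control_replicates[[i]],
                               normalization)
    tibble::tibble(variant_id = m$variant_id[i], assay = assay,
                   median_value = s$median_value, q1 = s$q1, q3 = s$q3,
                   n_replicates = s$n_replicates)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(out, panel$variants, by = "variant_id")[
    , c("variant_id", "assay", "prior_label",
        "median_value", "q1", "q3", "n_replicates")]
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c("pathogenic", "benign"))) {
    rlang::abort("labels must be pathogenic/benign (exclude VUS upstream)",
                 class = "ybrca1_validation_error")
  }
  if (length(unique(labels)) < 2) {
    rlang::abort("both classes required; ROC undefined on single-class input",
                 class = "ybrca1_undefined_roc_error")
  }
}

#' ROC sweep over per-variant medians
#'
#' Orientation is fixed "higher readout implies pathogenic" for all four
#' assays. Thresholds are swept over the distinct median values (a call is
#' pathogenic when `value > threshold`, so tied variants move across the
#' curve atomically); the curve is anchored at (0, 0) and (1, 1) and the
#' AUROC is its trapezoidal area, which equals the Mann-Whitney pairwise
#' probability with half credit for ties.
#'
#' @param medians Numeric vector of per-variant medians.
#' @param labels Character vector, `"pathogenic"` / `"benign"`, same length.
#' @return List: `roc_points` (tibble `threshold`, `fpr`, `tpr`, descending
#'   thresholds) and `auroc`.
#' @export
roc_sweep <- function(medians, labels) {
  stopifnot(length(medians) == length(labels))
  check_two_classes(labels)
  pos <- labels == "pathogenic"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  thresholds <- c(Inf, sort(unique(medians), decreasing = TRUE), -Inf)
  tpr <- vapply(thresholds, function(t) sum(medians[pos] > t) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(medians[!pos] > t) / n_neg,
                numeric(1))
  roc_points <- tibble::tibble(threshold = thresholds, fpr = fpr, tpr = tpr)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = roc_points, auroc = auroc)
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity = TP/(TP + FN), specificity = TN/(TN + FP), accuracy =
#' (TP + TN)/(TP + FN + TN + FP), Youden index = sensitivity +
#' specificity - 1. Values are kept at full precision; rounding happens only
#' at report time.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return List with `sensitivity`, `specificity`, `accuracy`,
#'   `youden_index`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0) {
    rlang::abort("metrics undefined with an empty class",
                 class = "ybrca1_undefined_metric_error")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / (tp + fn + tn + fp),
       youden_index = sens + spec - 1)
}

#' Best cut-off by Youden-index maximization
#'
#' Candidate thresholds sit at the midpoints between consecutive distinct
#' sorted medians (the published cut-offs fall between variant values, not
#' on them). A variant is called pathogenic when its median is strictly
#' above the cut-off; a median exactly at the cut-off is benign. Ties in the
#' Youden index are broken toward the candidate with higher specificity,
#' then toward the smaller threshold.
#'
#' @inheritParams roc_sweep
#' @param variant_ids Optional ids aligned with `medians`, used to populate
#'   the false-positive / false-negative lists.
#' @param assay Assay name recorded on the calibration.
#' @return An `assay_calibration`: list with `assay`, `best_cutoff`,
#'   `roc_points`, `auroc`, `sensitivity`, `specificity`, `accuracy`,
#'   `youden_index`, `fp_variants`, `fn_variants`, `counts` (tp/fp/tn/fn).
#' @export
best_cutoff <- function(medians, labels, variant_ids = NULL, assay = NA_character_) {
  check_two_classes(labels)
  if (is.null(variant_ids)) variant_ids <- as.character(seq_along(medians))
  sweep <- roc_sweep(medians, labels)

  distinct <- sort(unique(medians))
  if (length(distinct) < 2) {
    rlang::abort("all medians identical; no candidate cut-off exists",
                 class = "ybrca1_undefined_roc_error")
  }
  candidates <- (utils::head(distinct, -1) + utils::tail(distinct, -1)) / 2

  pos <- labels == "pathogenic"
  eval_at <- function(t) {
    called <- medians > t
    confusion_metrics(tp = sum(called & pos), fp = sum(called & !pos),
                      tn = sum(!called & !pos), fn = sum(!called & pos))
  }
  yi <- vapply(candidates, function(t) eval_at(t)$youden_index, numeric(1))
  spec <- vapply(candidates, function(t) eval_at(t)$specificity, numeric(1))
  best <- which(yi == max(yi))
  best <- best[spec[best] == max(spec[best])]
  cutoff <- min(candidates[best])

  called <- medians > cutoff
  counts <- list(tp = sum(called & pos), fp = sum(called & !pos),
                 tn = sum(!called & !pos), fn = sum(!called & pos))
  metrics <- confusion_metrics(counts$tp, counts$fp, counts$tn, counts$fn)

  structure(
    c(list(assay = assay, best_cutoff = cutoff,
           roc_points = sweep$roc_points, auroc = sweep$auroc),
      metrics,
      list(fp_variants = sort(variant_ids[called & !pos]),
           fn_variants = sort(variant_ids[!called & pos]),
           counts = counts)),
    class = "assay_calibration")
}

#' @export
print.assay_calibration <- function(x, ...) {
  cat("<assay_calibration> ", x$assay, ": cutoff ", signif(x$best_cutoff, 4),
      ", AUROC ", round(x$auroc, 3), ", sens ", round(x$sensitivity, 3),
      ", spec ", round(x$specificity, 3), ", acc ", round(x$accuracy, 3),
      ", YI ", round(x$youden_index, 3), "\n", sep = "")
  if (length(x$fp_variants))
    cat("  FP:", paste(x$fp_variants, collapse = " "), "\n")
  if (length(x$fn_variants))
    cat("  FN:", paste(x$fn_variants, collapse = " "), "\n")
  invisible(x)
}

#' Calibrate one assay on a panel's classified variants
#'
#' Summarizes every measurement of the assay, restricts to variants with a
#' pathogenic/benign prior label (VUS never enter calibration), and fits the
#' Youden-optimal cut-off.
#'
#' @inheritParams summarize_assay
#' @return An `assay_calibration` (see [best_cutoff()]) with the
#'   normalization mode recorded in `$normalization`.
#' @export
calibrate_assay <- function(panel, assay,
                            normalization = default_normalization()[[assay]]) {
  summaries <- summarize_assay(panel, assay, normalization)
  cls <- summaries[summaries$prior_label %in% c("pathogenic", "benign"), ]
  cal <- best_cutoff(cls$median_value, cls$prior_label, cls$variant_id,
                     assay = assay)
  cal$normalization <- normalization
  cal
}

#' Waterfall export for one calibrated assay
#'
#' One row per variant (VUS included), ordered by decreasing median, with
#' the interquartile range, the call against the fitted cut-off, and the
#' control median — the data behind a waterfall box-plot of the assay.
#'
#' @inheritParams summarize_assay
#' @param calibration The assay's `assay_calibration`.
#' @return Tibble: `variant_id`, `prior_label`, `median_value`, `q1`, `q3`,
#'   `n_replicates`, `call`, `above_cutoff`, `cutoff`, `control_median`.
#' @export
waterfall_table <- function(panel, assay, calibration,
                            normalization = calibration$normalization) {
  summaries <- summarize_assay(panel, assay, normalization)
  ctl <- panel$measurements$control_replicates[
    panel$measurements$assay == assay]
  ctl_median <- stats::median(unlist(ctl))
  if (normalization == "fold_of_control_median") {
    # on the fold scale the control sits at 1 by construction
    ctl_median <- 1
  }
  out <- summaries[order(-summaries$median_value), ]
  out$call <- functional_impact(out$median_value, calibration$best_cutoff)
  out$above_cutoff <- out$median_value > calibration$best_cutoff
  out$cutoff <- calibration$best_cutoff
  out$control_median <- ctl_median
  out
}
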