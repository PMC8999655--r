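#' Majority-voting integration of per-assay calls
#'
#' Each assay is an equal-weight classifier. The pathogenic votes (PV) for a
#' variant count its pathogenic calls across assays; the pathogenic
#' prediction score is PPS = PV / n_assays; the final label is pathogenic
#' exactly when PPS > 0.5, so a tie (PV = n_assays / 2) is benign, as is any
#' minority of pathogenic votes.
#'
#' In `"fi"` mode (the default) the votes are the functional-impact labels —
#' the reading consistent with every row of the published VUS table, where a
#' variant can vote pathogenic with a prediction score below 0.5. In
#' `"ps"` mode a vote is pathogenic when PS > 0.5 instead.
#'
#' @param impact_calls Tibble with `variant_id`, `assay`, `fi` and (for
#'   `"ps"` mode) `ps`; every variant must carry exactly `n_assays` calls.
#' @param n_assays Number of assays voting (>= 2; the validated instance
#'   is 4).
#' @param mode `"fi"` or `"ps"`.
#' @return Tibble of integrated calls: `variant_id`, `pv`, `pps`, `label`.
#' @export
integrate_calls <- function(impact_calls, n_assays = 4L,
                            mode = c("fi", "ps")) {
  mode <- match.arg(mode)
  stopifnot(n_assays >= 2)
  impact_calls <- tibble::as_tibble(impact_calls)
  counts <- table(impact_calls$variant_id)
  if (any(counts != n_assays) ||
      anyDuplicated(impact_calls[c("variant_id", "assay")])) {
    rlang::abort("every variant needs exactly one call per assay",
                 class = "ybrca1_consistency_error")
  }
  vote <- if (mode == "fi") {
    impact_calls$fi == "pathogenic"
  } else {
    impact_calls$ps > 0.5
  }
  out <- tibble::tibble(variant_id = impact_calls$variant_id, vote = vote) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(pv = sum(.data$vote), .groups = "drop")
  out$pps <- out$pv / n_assays
  out$label <- ifelse(out$pps > 0.5, "pathogenic", "benign")
  out
}

mcc_from_counts <- function(tp, fp, tn, fn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(NA_real_)
  (tp * tn - fp * fn) / denom
}

kappa_from_counts <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Performance of the integrated classifier
#'
#' Confusion-matrix statistics of the majority-vote labels against the prior
#' classification, restricted to classified (non-VUS) variants: accuracy with
#' its exact (Clopper-Pearson) binomial 95% confidence interval, sensitivity,
#' specificity, Matthews correlation coefficient, Cohen's kappa, and the
#' AUROC of PPS as a ranking score (PPS takes the five values 0, 0.25, 0.5,
#' 0.75, 1 over four assays; ties get half credit).
#'
#' @param integrated Tibble from [integrate_calls()] for the classified
#'   variants.
#' @param truth Named character vector (or tibble with `variant_id`,
#'   `prior_label`) giving the pathogenic/benign truth per variant.
#' @param conf_level Confidence level of the accuracy interval.
#' @return List: `counts` (tp/fp/tn/fn), `accuracy`, `accuracy_ci95`,
#'   `sensitivity`, `specificity`, `youden_index`, `auroc`, `mcc`, `kappa`,
#'   `n`.
#' @export
combined_performance <- function(integrated, truth, conf_level = 0.95) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$prior_label, truth$variant_id)
  }
  truth <- truth[integrated$variant_id]
  if (anyNA(truth)) {
    rlang::abort("truth labels missing for some integrated variants",
                 class = "ybrca1_consistency_error")
  }
  check_two_classes(truth)

  pos <- truth == "pathogenic"
  called <- integrated$label == "pathogenic"
  tp <- sum(called & pos); fp <- sum(called & !pos)
  tn <- sum(!called & !pos); fn <- sum(!called & pos)
  metrics <- confusion_metrics(tp, fp, tn, fn)
  n <- length(truth)
  ci <- stats::binom.test(tp + tn, n, conf.level = conf_level)$conf.int

  list(counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
       accuracy = metrics$accuracy,
       accuracy_ci95 = c(lower = ci[1], upper = ci[2]),
       sensitivity = metrics$sensitivity,
       specificity = metrics$specificity,
       youden_index = metrics$youden_index,
       auroc = roc_sweep(integrated$pps, unname(truth))$auroc,
       mcc = mcc_from_counts(tp, fp, tn, fn),
       kappa = kappa_from_counts(tp, fp, tn, fn),
       n = n)
}

#' Cross-assay concordance of per-assay calls
#'
#' Counts the classified variants whose call is correct in every assay and
#' annotates the discordant remainder with the assays that got them wrong.
#'
#' @param per_assay_calls Tibble with `variant_id`, `assay`, `fi` covering
#'   every (classified variant, assay) pair exactly once.
#' @param truth As in [combined_performance()].
#' @return List: `n_all_correct`, `n_variants`, `discordant` (tibble
#'   `variant_id`, `prior_label`, `n_wrong`, `wrong_assays`).
#' @export
concordance_report <- function(per_assay_calls, truth) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$prior_label, truth$variant_id)
  }
  calls <- tibble::as_tibble(per_assay_calls)
  calls <- calls[calls$variant_id %in% names(truth), ]
  n_assays <- length(unique(calls$assay))
  counts <- table(calls$variant_id)
  if (length(counts) != length(truth) || any(counts != n_assays)) {
    rlang::abort("incomplete call matrix for the classified variants",
                 class = "ybrca1_consistency_error")
  }
  calls$correct <- calls$fi == unname(truth[calls$variant_id])
  per_variant <- calls |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      n_wrong = sum(!.data$correct),
      wrong_assays = paste(.data$assay[!.data$correct], collapse = ","),
      .groups = "drop")
  per_variant$prior_label <- unname(truth[per_variant$variant_id])
  discordant <- per_variant[per_variant$n_wrong > 0,
                            c("variant_id", "prior_label",
                              "n_wrong", "wrong_assays")]
  list(n_all_correct = sum(per_variant$n_wrong == 0),
       n_variants = nrow(per_variant),
       discordant = discordant)
}
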