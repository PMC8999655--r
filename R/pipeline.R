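#' Validation phase: calibrate every assay on the classified panel
#'
#' Fits, per assay, the Youden-optimal cut-off on the classified
#' (pathogenic/benign) variants and collects the performance metrics in one
#' table; optionally writes the calibration summary and the per-assay
#' waterfall exports. Cut-offs are fitted here, once, and passed as an
#' artifact to [run_classify()], so they are never silently refit on
#' VUS-containing data.
#'
#' @param panel An [assay_panel()] with both classes present.
#' @param assays Assays to calibrate (default all four).
#' @param normalization Named vector of per-assay normalization modes;
#'   defaults to [default_normalization()].
#' @param out_dir Optional directory; when given, writes
#'   `calibration_summary.tsv` and `waterfall_<assay>.tsv`.
#' @param yi_warn Warn when an assay's Youden index is at or below this
#'   value (default 0.1), indicating no usable class separation.
#' @return List: `calibrations` (named list of `assay_calibration`),
#'   `summary` (one row per assay: cutoff, AUROC, sensitivity, specificity,
#'   accuracy, YI, FP/FN lists), `waterfalls` (named list of tibbles).
#' @export
run_validate <- function(panel, assays = ybrca1_assays(),
                         normalization = default_normalization(),
                         out_dir = NULL, yi_warn = 0.1) {
  stopifnot(inherits(panel, "assay_panel"))
  calibrations <- lapply(assays, function(a) {
    tryCatch(calibrate_assay(panel, a, normalization[[a]]),
             error = function(e) {
               rlang::abort(paste0("validate/", a, ": ", conditionMessage(e)),
                            parent = e, class = class(e)[1])
             })
  })
  names(calibrations) <- assays

  summary <- dplyr::bind_rows(lapply(calibrations, function(cal) {
    tibble::tibble(
      assay = cal$assay, normalization = cal$normalization,
      best_cutoff = cal$best_cutoff, auroc = cal$auroc,
      sensitivity = cal$sensitivity, specificity = cal$specificity,
      accuracy = cal$accuracy, youden_index = cal$youden_index,
      fp_variants = paste(cal$fp_variants, collapse = ","),
      fn_variants = paste(cal$fn_variants, collapse = ","))
  }))

  flat <- summary$assay[summary$youden_index <= yi_warn]
  if (length(flat)) {
    rlang::warn(paste0("Youden index near 0 (no discriminative signal) in: ",
                       paste(flat, collapse = ", ")))
  }

  waterfalls <- lapply(assays, function(a)
    waterfall_table(panel, a, calibrations[[a]]))
  names(waterfalls) <- assays

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- summary
    num <- vapply(report, is.numeric, logical(1))
    report[num] <- lapply(report[num], round, 3)
    readr::write_tsv(report, file.path(out_dir, "calibration_summary.tsv"))
    for (a in assays) {
      wf <- waterfalls[[a]]
      num <- vapply(wf, is.numeric, logical(1))
      wf[num] <- lapply(wf[num], round, 3)
      readr::write_tsv(wf, file.path(out_dir, paste0("waterfall_", a, ".tsv")))
    }
  }
  list(calibrations = calibrations, summary = summary, waterfalls = waterfalls)
}

#' Classification phase: score and integrate every variant
#'
#' Applies fitted calibrations to all variants of a panel (VUS included):
#' per-assay functional-impact calls and bootstrap prediction scores, then
#' equal-weight majority voting into the final label. Classified variants
#' are flagged correct/incorrect against their prior label.
#'
#' @param panel An [assay_panel()].
#' @param calibrations Named list of `assay_calibration` objects, from
#'   [run_validate()].
#' @param B Bootstrap resamples per measurement (default 4000).
#' @param seed Integer seed shared by all bootstrap draws.
#' @param vote_mode `"fi"` (default) or `"ps"`; see [integrate_calls()].
#' @param out_dir Optional directory; when given, writes
#'   `classification.tsv` (final table), `impact_calls.tsv` (per-assay
#'   scores) and `run_log.tsv` (seed, B, clamp bounds, vote mode, cut-offs).
#' @return List: `impact_calls` (per variant x assay), `integrated` (final
#'   calls with `prior_label` and `correct`), `performance`
#'   ([combined_performance()] on the classified variants, `NULL` when the
#'   panel has no classified variants), `concordance`
#'   ([concordance_report()], same caveat).
#' @export
run_classify <- function(panel, calibrations, B = 4000, seed = 1L,
                         vote_mode = c("fi", "ps"), out_dir = NULL) {
  vote_mode <- match.arg(vote_mode)
  stopifnot(inherits(panel, "assay_panel"))
  impact_calls <- score_panel(panel, calibrations, B = B, seed = seed)
  n_assays <- length(calibrations)
  integrated <- integrate_calls(impact_calls, n_assays = n_assays,
                                mode = vote_mode)
  integrated <- dplyr::left_join(integrated, panel$variants,
                                 by = "variant_id")
  integrated$correct <- ifelse(
    integrated$prior_label == "VUS", NA,
    integrated$label == integrated$prior_label)

  classified <- panel$variants[panel$variants$prior_label != "VUS", ]
  performance <- NULL
  concordance <- NULL
  if (nrow(classified) > 0 &&
      length(unique(classified$prior_label)) == 2) {
    idx <- integrated$variant_id %in% classified$variant_id
    performance <- combined_performance(integrated[idx, ], classified)
    concordance <- concordance_report(
      impact_calls[impact_calls$variant_id %in% classified$variant_id, ],
      classified)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_calls(integrated[c("variant_id", "pv", "pps", "label")],
                impact_calls, file.path(out_dir, "classification.tsv"),
                assays = names(calibrations))
    ic <- impact_calls
    ic$median_value <- round(ic$median_value, 3)
    ic$cutoff <- round(ic$cutoff, 3)
    readr::write_tsv(ic, file.path(out_dir, "impact_calls.tsv"))
    log <- tibble::tibble(
      key = c("seed", "bootstrap_B", "ps_clamp_lower", "ps_clamp_upper",
              "vote_mode",
              paste0("cutoff_", names(calibrations))),
      value = c(seed, B, 1 / B, 1 - 1 / B, vote_mode,
                vapply(calibrations, function(cal)
                  signif(cal$best_cutoff, 6), numeric(1))))
    readr::write_tsv(log, file.path(out_dir, "run_log.tsv"))
  }
  list(impact_calls = impact_calls, integrated = integrated,
       performance = performance, concordance = concordance)
}
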