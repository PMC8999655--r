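#' Functional-impact call from a median and a cut-off
#'
#' A variant is pathogenic in an assay when its summarized median readout is
#' strictly above the assay's best cut-off; a median exactly at the cut-off
#' is benign. Vectorized over `median_value`.
#'
#' @param median_value Numeric, summarized per-variant median(s) on the same
#'   scale (normalization) as the cut-off.
#' @param cutoff The assay's fitted best cut-off.
#' @return Character vector, `"pathogenic"` / `"benign"`.
#' @export
functional_impact <- function(median_value, cutoff) {
  ifelse(median_value > cutoff, "pathogenic", "benign")
}

#' Bootstrap prediction score
#'
#' The prediction score (PS) is the bootstrap probability that the
#' measurement's median exceeds the cut-off: replicates are resampled with
#' replacement `B` times, the median of each resample is compared with the
#' cut-off, and the exceedance fraction is clamped to `[1/B, 1 - 1/B]` so a
#' score is never exactly 0 or 1. With the default B = 4000 the score lives
#' on a 1/4000 grid with extremes 0.00025 and 0.99975.
#'
#' @param values Numeric replicate vector, already on the cut-off's scale
#'   (normalized if the assay is calibrated on folds).
#' @param cutoff The assay's best cut-off.
#' @param B Number of bootstrap resamples (>= 100; fewer gives unstable
#'   scores).
#' @param seed Optional integer seed for reproducible draws; when `NULL`
#'   the current RNG stream is used (so a caller can seed once for a whole
#'   run).
#' @return The prediction score in `(0, 1)`.
#' @export
bootstrap_ps <- function(values, cutoff, B = 4000, seed = NULL) {
  stopifnot(length(values) >= 1)
  if (B < 100) {
    rlang::abort("B must be >= 100; smaller bootstraps give unstable scores",
                 class = "ybrca1_config_error")
  }
  draw <- function() {
    exceed <- sum(boot_medians(values, B) > cutoff)
    min(max(exceed / B, 1 / B), 1 - 1 / B)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# B bootstrap medians, vectorized: one order() call sorts all resample
# columns at once, then the median is read off the middle sorted row(s)
boot_medians <- function(values, B) {
  n <- length(values)
  x <- matrix(values[sample.int(n, n * B, replace = TRUE)], nrow = n)
  xs <- matrix(x[order(col(x), x)], nrow = n)
  if (n %% 2 == 1) {
    xs[(n + 1) / 2, ]
  } else {
    (xs[n / 2, ] + xs[n / 2 + 1, ]) / 2
  }
}

#' Score every measurement of a panel against fitted calibrations
#'
#' Produces the per-variant, per-assay impact calls: the functional-impact
#' label from the summarized median versus the assay's cut-off, and the
#' bootstrap prediction score from the replicate vector. One shared seed
#' governs all bootstrap draws in the run; measurements are scored in the
#' panel's canonical order so the result is reproducible.
#'
#' @param panel An [assay_panel()].
#' @param calibrations Named list of `assay_calibration` objects (one per
#'   assay to score), e.g. from [run_validate()].
#' @param B Bootstrap resamples per measurement (default 4000).
#' @param seed Integer seed for the whole scoring run.
#' @return Tibble: `variant_id`, `assay`, `prior_label`, `median_value`,
#'   `cutoff`, `fi`, `ps`, `n_bootstrap`.
#' @export
score_panel <- function(panel, calibrations, B = 4000, seed = 1L) {
  stopifnot(inherits(panel, "assay_panel"))
  assays <- names(calibrations)
  missing <- setdiff(unique(panel$measurements$assay), assays)
  if (length(missing)) {
    rlang::abort(paste0("no calibration for assay(s): ",
                        paste(missing, collapse = ", ")),
                 class = "ybrca1_consistency_error")
  }
  withr::with_seed(as.integer(seed), {
    m <- panel$measurements
    rows <- lapply(seq_len(nrow(m)), function(i) {
      cal <- calibrations[[m$assay[i]]]
      s <- summarize_measurement(m$replicates[[i]],
                                 m$control_replicates[[i]],
                                 cal$normalization)
      tibble::tibble(
        variant_id = m$variant_id[i], assay = m$assay[i],
        median_value = s$median_value, cutoff = cal$best_cutoff,
        fi = functional_impact(s$median_value, cal$best_cutoff),
        ps = bootstrap_ps(s$values, cal$best_cutoff, B = B),
        n_bootstrap = as.integer(B))
    })
    out <- dplyr::bind_rows(rows)
    out <- dplyr::left_join(out, panel$variants, by = "variant_id")
    out[, c("variant_id", "assay", "prior_label", "median_value", "cutoff",
            "fi", "ps", "n_bootstrap")]
  })
}
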