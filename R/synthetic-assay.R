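#' Generator configuration for synthetic assay panels
#'
#' Describes a panel of variants with log-normally distributed replicate
#' readouts in each of the four yeast assays. Replicate noise is
#' parameterized by the coefficient of variation (CV) on the natural scale;
#' effect sizes are median fold-shifts relative to the wild-type control, so
#' `pathogenic_fold = 3` means a pathogenic variant's replicate distribution
#' has median three times the control median in that assay. VUS have no
#' fixed truth: in each assay a VUS behaves like a pathogenic variant with
#' probability `vus_mixture_prob`, independently per assay, and the drawn
#' ground truth is recorded on the generated panel so recovery tests can
#' score VUS calls.
#'
#' Per-assay `control_location` values are typical wild-type readouts in the
#' assay's native units: HIS3 colonies per 10^4 cells (intra-HR), ADE2
#' colonies per 10^5 cells (inter-HR), ILV1 colonies per 10^6 cells (GR),
#' and cells per colony (SCP).
#'
#' @param n_pathogenic,n_benign,n_vus Panel composition (defaults 23, 23, 10).
#' @param n_replicates Replicates per variant per assay (default 5, the
#'   minimum number of independent experiments the assays require).
#' @param n_control_replicates Pooled wild-type control replicates per assay.
#' @param seed Integer seed; the panel is fully reproducible from it.
#' @param assays Named list of per-assay parameter blocks, each a list with
#'   `control_location` (> 0), `replicate_cv` (> 0, default 0.3),
#'   `pathogenic_fold` (> 1, default 3), `benign_fold` (> 0, default 1),
#'   `vus_mixture_prob` (in \[0, 1\], default 0.5). Defaults from
#'   [default_assay_params()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_pathogenic = 23, n_benign = 23, n_vus = 10,
                             n_replicates = 5, n_control_replicates = 10,
                             seed = 1L, assays = default_assay_params()) {
  cfg <- list(n_pathogenic = n_pathogenic, n_benign = n_benign,
              n_vus = n_vus, n_replicates = n_replicates,
              n_control_replicates = n_control_replicates,
              seed = as.integer(seed), assays = assays)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' @rdname generator_config
#' @export
default_assay_params <- function() {
  base <- function(loc) list(control_location = loc, replicate_cv = 0.3,
                             pathogenic_fold = 3, benign_fold = 1,
                             vus_mixture_prob = 0.5)
  list(intra_hr = base(2.5), inter_hr = base(2.0), gr = base(1.5),
       scp = base(12))
}

validate_generator_config <- function(cfg) {
  counts <- c(cfg$n_pathogenic, cfg$n_benign, cfg$n_vus)
  if (any(counts < 0) || cfg$n_replicates < 1 || cfg$n_control_replicates < 1) {
    rlang::abort("counts must be non-negative and replicate counts >= 1",
                 class = "ybrca1_validation_error")
  }
  if (!setequal(names(cfg$assays), ybrca1_assays())) {
    rlang::abort("assay blocks must cover exactly the four assays",
                 class = "ybrca1_validation_error")
  }
  for (a in names(cfg$assays)) {
    p <- cfg$assays[[a]]
    if (p$control_location <= 0 || p$replicate_cv <= 0 ||
        p$pathogenic_fold <= 0 || p$benign_fold <= 0) {
      rlang::abort(paste0("non-positive generator parameter in assay ", a),
                   class = "ybrca1_validation_error")
    }
    if (p$vus_mixture_prob < 0 || p$vus_mixture_prob > 1) {
      rlang::abort("vus_mixture_prob must be in [0, 1]",
                   class = "ybrca1_validation_error")
    }
  }
  invisible(cfg)
}

# log-normal with median m and natural-scale CV:
# meanlog = log(m), sdlog = sqrt(log(1 + cv^2))
rlnorm_med_cv <- function(n, median, cv) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sqrt(log(1 + cv^2)))
}

#' Generate a synthetic assay panel
#'
#' Draws, for every variant x assay, `n_replicates` log-normal readouts with
#' median `control_location * fold` where the fold depends on the variant's
#' (possibly VUS-mixture-drawn) behavior in that assay, plus pooled
#' wild-type control replicates at fold 1. The generated panel carries a
#' `vus_truth` attribute recording, per VUS and assay, whether the VUS was
#' drawn to behave pathogenic there.
#'
#' @param config A [generator_config()].
#' @return An [assay_panel()] with attribute `vus_truth` (tibble:
#'   `variant_id`, `assay`, `behaves_pathogenic`).
#' @export
generate_panel <- function(config = generator_config()) {
  validate_generator_config(config)
  variants <- tibble::tibble(
    variant_id = c(sprintf("p.PATH%02d", seq_len0(config$n_pathogenic)),
                   sprintf("p.BEN%02d", seq_len0(config$n_benign)),
                   sprintf("p.VUS%02d", seq_len0(config$n_vus))),
    prior_label = rep(c("pathogenic", "benign", "VUS"),
                      c(config$n_pathogenic, config$n_benign, config$n_vus)))

  withr::with_seed(config$seed, {
    vus_ids <- variants$variant_id[variants$prior_label == "VUS"]
    vus_truth <- tidyr::expand_grid(variant_id = vus_ids,
                                    assay = ybrca1_assays())
    vus_truth$behaves_pathogenic <- logical(nrow(vus_truth))
    for (i in seq_len0(nrow(vus_truth))) {
      p <- config$assays[[vus_truth$assay[i]]]$vus_mixture_prob
      vus_truth$behaves_pathogenic[i] <- stats::runif(1) < p
    }

    meas <- vector("list", nrow(variants) * 4L)
    k <- 0L
    for (a in ybrca1_assays()) {
      p <- config$assays[[a]]
      control <- rlnorm_med_cv(config$n_control_replicates,
                               p$control_location, p$replicate_cv)
      for (i in seq_len0(nrow(variants))) {
        lab <- variants$prior_label[i]
        vid <- variants$variant_id[i]
        elevated <- lab == "pathogenic" ||
          (lab == "VUS" &&
             vus_truth$behaves_pathogenic[vus_truth$variant_id == vid &
                                            vus_truth$assay == a])
        fold <- if (elevated) p$pathogenic_fold else p$benign_fold
        k <- k + 1L
        meas[[k]] <- tibble::tibble(
          variant_id = vid, assay = a,
          replicates = list(rlnorm_med_cv(config$n_replicates,
                                          p$control_location * fold,
                                          p$replicate_cv)),
          control_replicates = list(control))
      }
    }
    panel <- assay_panel(variants, dplyr::bind_rows(meas[seq_len0(k)]))
    attr(panel, "vus_truth") <- vus_truth
    panel
  })
}

seq_len0 <- function(n) seq_len(max(n, 0L))

#' Generate the planted benchmark panel
#'
#' Builds a synthetic panel with the structure of the validated 56-variant
#' BRCA1 panel (23 pathogenic + 23 benign + 10 VUS): each classified variant
#' receives elevated replicates (fold `pathogenic_fold`) exactly in the
#' assays where the benchmark calls it pathogenic — so the benign variants in
#' the false-positive lists are elevated there, and pathogenic variants in
#' the false-negative lists are control-like there — and each VUS is elevated
#' exactly in the assays where its published functional-impact label is
#' pathogenic. With the default tight replicate noise (CV 0.05) the fitted
#' Youden cut-offs separate the elevated from the control-like group in every
#' assay at any seed, so the per-assay confusion lists and the integrated
#' misclassification set reproduce the benchmark deterministically.
#'
#' @param seed Integer seed.
#' @param n_replicates Replicates per measurement (default 5).
#' @param pathogenic_fold Median fold-shift of elevated measurements
#'   (default 3).
#' @param replicate_cv Natural-scale CV of replicate noise (default 0.05;
#'   keep <= 0.05 for deterministic reproduction of the planted pattern).
#' @param discordant_margin Extra fold factor (> 1) applied to planted
#'   discordant classified variants: a false-positive benign variant gets
#'   fold `pathogenic_fold * discordant_margin` (above the elevated
#'   cluster), a false-negative pathogenic variant gets
#'   `1 / discordant_margin` (below the control-like cluster). Without the
#'   margin the Youden criterion could trade a boundary false positive for
#'   a true positive at equal index and shift the cut-off inside a cluster;
#'   with it the between-cluster midpoint is the strict optimum and the
#'   planted confusion lists are recovered exactly.
#' @return An [assay_panel()] of 56 variants x 4 assays.
#' @examples
#' panel <- generate_benchmark_panel(seed = 1)
#' val <- run_validate(panel)
#' val$calibrations$scp
#' @export
generate_benchmark_panel <- function(seed = 1L, n_replicates = 5,
                                     pathogenic_fold = 3,
                                     replicate_cv = 0.05,
                                     discordant_margin = 1.3) {
  variants <- benchmark_variants()
  err <- benchmark_assay_errors()
  vus <- benchmark_vus_calls()
  params <- default_assay_params()

  # fold for one variant in one assay; discordant classified variants get
  # the margin so they sit strictly interior to the cluster they were
  # planted into (see Details)
  fold_in <- function(vid, lab, a) {
    i <- match(a, err$assay)
    if (lab == "pathogenic") {
      if (vid %in% err$fn[[i]]) return(1 / discordant_margin)
      return(pathogenic_fold)
    }
    if (lab == "benign") {
      if (vid %in% err$fp[[i]]) return(pathogenic_fold * discordant_margin)
      return(1)
    }
    if (vus$fi[vus$variant_id == vid & vus$assay == a] == "pathogenic") {
      pathogenic_fold
    } else {
      1
    }
  }

  withr::with_seed(as.integer(seed), {
    meas <- list()
    for (a in ybrca1_assays()) {
      p <- params[[a]]
      control <- rlnorm_med_cv(10, p$control_location, replicate_cv)
      for (i in seq_len(nrow(variants))) {
        vid <- variants$variant_id[i]
        fold <- fold_in(vid, variants$prior_label[i], a)
        meas[[length(meas) + 1L]] <- tibble::tibble(
          variant_id = vid, assay = a,
          replicates = list(rlnorm_med_cv(n_replicates,
                                          p$control_location * fold,
                                          replicate_cv)),
          control_replicates = list(control))
      }
    }
    assay_panel(variants, dplyr::bind_rows(meas))
  })
}
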