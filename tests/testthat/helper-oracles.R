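# Independent oracles used to cross-check the analytical implementations.
# These are deliberately naive (loops, full enumeration) so they share no
# code path with the package.

# AUROC as the Mann-Whitney pairwise probability: fraction of
# (pathogenic, benign) pairs ranked correctly, ties credited 0.5
oracle_auroc <- function(medians, labels) {
  pos <- medians[labels == "pathogenic"]
  neg <- medians[labels == "benign"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# best cut-off by brute force: evaluate the Youden index at every midpoint
# between consecutive distinct medians, with the package's documented
# tie-breaks (max YI, then max specificity, then min threshold)
oracle_best_cutoff <- function(medians, labels) {
  distinct <- sort(unique(medians))
  mids <- (distinct[-1] + distinct[-length(distinct)]) / 2
  best <- NULL
  for (t in mids) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(medians)) {
      called_path <- medians[i] > t
      truth_path <- labels[i] == "pathogenic"
      if (called_path && truth_path) tp <- tp + 1
      if (called_path && !truth_path) fp <- fp + 1
      if (!called_path && !truth_path) tn <- tn + 1
      if (!called_path && truth_path) fn <- fn + 1
    }
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    cand <- list(cutoff = t, yi = sens + spec - 1, spec = spec)
    if (is.null(best) ||
        cand$yi > best$yi ||
        (cand$yi == best$yi && cand$spec > best$spec) ||
        (cand$yi == best$yi && cand$spec == best$spec &&
           cand$cutoff < best$cutoff)) {
      best <- cand
    }
  }
  best
}

# exact bootstrap exceedance of the median by full enumeration of all n^n
# equally likely resamples (feasible for n <= 6)
oracle_exact_ps <- function(values, cutoff) {
  n <- length(values)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  exceed <- 0
  for (i in seq_len(nrow(grid))) {
    resample <- values[as.integer(grid[i, ])]
    if (median(resample) > cutoff) exceed <- exceed + 1
  }
  exceed / nrow(grid)
}

# for odd n the bootstrap median exceeds the cutoff iff more than half the
# draws do, so the exact exceedance is an upper binomial tail with
# p = (fraction of replicates above the cutoff)
oracle_exact_ps_odd <- function(values, cutoff) {
  n <- length(values)
  stopifnot(n %% 2 == 1)
  p <- mean(values > cutoff)
  1 - pbinom(floor(n / 2), n, p)
}

# a random two-class instance for the ROC/cut-off property suites; ties are
# injected on purpose by rounding
random_roc_instance <- function(max_n = 50) {
  n_pos <- sample(1:(max_n / 2), 1)
  n_neg <- sample(1:(max_n / 2), 1)
  shift <- runif(1, 0, 2)
  medians <- c(rnorm(n_pos, mean = shift), rnorm(n_neg))
  if (runif(1) < 0.5) medians <- round(medians, 1)  # force ties
  list(medians = medians,
       labels = rep(c("pathogenic", "benign"), c(n_pos, n_neg)))
}

# a small panel with every label class, for I/O round-trip checks
random_small_panel <- function() {
  n <- sample(3:8, 1)
  labels <- sample(ybrca1_labels(), n, replace = TRUE)
  variants <- tibble::tibble(
    variant_id = sprintf("p.X%02d", seq_len(n)),
    prior_label = labels)
  assays <- sample(ybrca1_assays(), sample(2:4, 1))
  meas <- dplyr::bind_rows(lapply(assays, function(a) {
    tibble::tibble(
      variant_id = variants$variant_id,
      assay = a,
      replicates = lapply(seq_len(n), function(i)
        round(rlnorm(sample(5:8, 1)), 6)),
      control_replicates = lapply(seq_len(n), function(i)
        round(rlnorm(5), 6)))
  }))
  assay_panel(variants, meas)
}
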