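test_that("majority voting reproduces the published VUS integration", {
  vus <- benchmark_vus_calls()
  ic <- integrate_calls(vus, n_assays = 4)

  expected <- tibble::tribble(
    ~variant_id, ~pv, ~pps, ~label,
    "p.A1669S", 1L, 0.25, "benign",
    "p.A1789T", 1L, 0.25, "benign",
    "p.E1352K", 3L, 0.75, "pathogenic",
    "p.N1730I", 3L, 0.75, "pathogenic",
    "p.N1819S", 2L, 0.50, "benign",
    "p.P1010S", 2L, 0.50, "benign",
    "p.S1164I", 3L, 0.75, "pathogenic",
    "p.S592N", 3L, 0.75, "pathogenic",
    "p.V1791L", 3L, 0.75, "pathogenic",
    "p.Y1703C", 4L, 1.00, "pathogenic")
  merged <- merge(ic, expected, by = "variant_id")
  expect_equal(merged$pv.x, merged$pv.y, ignore_attr = TRUE)
  expect_equal(merged$pps.x, merged$pps.y)
  expect_equal(merged$label.x, merged$label.y)
  expect_equal(sum(ic$label == "pathogenic"), 6)
  expect_equal(sum(ic$label == "benign"), 4)
})

test_that("FI labels drive the votes, not PS > 0.5", {
  # p.N1730I's intra-HR call has PS 0.43825 yet votes pathogenic via FI
  vus <- benchmark_vus_calls()
  row <- vus[vus$variant_id == "p.N1730I" & vus$assay == "intra_hr", ]
  expect_lt(row$ps, 0.5)
  expect_equal(row$fi, "pathogenic")

  fi_mode <- integrate_calls(vus, 4, mode = "fi")
  ps_mode <- integrate_calls(vus, 4, mode = "ps")
  expect_equal(fi_mode$pv[fi_mode$variant_id == "p.N1730I"], 3L)
  expect_equal(ps_mode$pv[ps_mode$variant_id == "p.N1730I"], 2L)
})

test_that("unanimous and tied votes resolve by the PPS > 0.5 rule", {
  calls <- tibble::tibble(
    variant_id = "p.X", assay = ybrca1_assays(),
    fi = rep("benign", 4), ps = rep(0.1, 4))
  ic <- integrate_calls(calls, 4)
  expect_equal(ic$pv, 0L)
  expect_equal(ic$pps, 0)
  expect_equal(ic$label, "benign")

  calls$fi <- c("pathogenic", "pathogenic", "benign", "benign")
  ic <- integrate_calls(calls, 4)
  expect_equal(ic$pps, 0.5)
  expect_equal(ic$label, "benign")  # tie goes to benign

  expect_error(integrate_calls(calls[1:3, ], 4),
               class = "ybrca1_consistency_error")
})

test_that("voting is symmetric in assay order and anti-symmetric under FI flips", {
  withr::local_seed(200)
  flip <- c(pathogenic = "benign", benign = "pathogenic")
  for (i in 1:20) {
    calls <- tibble::tibble(
      variant_id = "p.X", assay = ybrca1_assays(),
      fi = sample(c("pathogenic", "benign"), 4, replace = TRUE),
      ps = runif(4))
    ic <- integrate_calls(calls, 4)
    shuffled <- calls[sample(4), ]
    expect_equal(integrate_calls(shuffled, 4), ic)

    flipped <- calls
    flipped$fi <- unname(flip[calls$fi])
    ic_flip <- integrate_calls(flipped, 4)
    if (ic$pv != 2) {
      expect_false(ic_flip$label == ic$label)
    } else {
      expect_equal(ic_flip$label, "benign")  # both ties are benign
    }
  }
})

test_that("the reconstructed benchmark call matrix integrates to the published performance", {
  calls <- benchmark_call_matrix()
  truth <- calls[!duplicated(calls$variant_id),
                 c("variant_id", "prior_label")]
  ic <- integrate_calls(calls[c("variant_id", "assay", "fi")], 4)
  perf <- combined_performance(ic, truth)

  expect_equal(round(perf$accuracy, 4), 0.9565)
  expect_equal(round(perf$sensitivity, 4), 0.9565)
  expect_equal(round(perf$specificity, 4), 0.9565)
  expect_equal(round(unname(perf$accuracy_ci95["lower"]), 4), 0.8516)
  expect_equal(round(unname(perf$accuracy_ci95["upper"]), 4), 0.9947)

  wrong <- merge(ic, truth, by = "variant_id")
  wrong <- wrong$variant_id[wrong$label != wrong$prior_label]
  expect_setequal(wrong, c("p.R71K", "p.I1275V"))

  # MCC and kappa from the TP=TN=22, FP=FN=1 matrix
  expect_equal(round(perf$mcc, 4), 0.913)
  expect_equal(round(perf$kappa, 4), 0.913)
})

test_that("kappa matches an independent implementation", {
  skip_if_not_installed("e1071")
  calls <- benchmark_call_matrix()
  truth <- calls[!duplicated(calls$variant_id),
                 c("variant_id", "prior_label")]
  ic <- integrate_calls(calls[c("variant_id", "assay", "fi")], 4)
  perf <- combined_performance(ic, truth)
  tr <- setNames(truth$prior_label, truth$variant_id)[ic$variant_id]
  ref <- e1071::classAgreement(table(ic$label, tr))$kappa
  expect_equal(perf$kappa, ref)
})

test_that("perfect agreement yields MCC and kappa of 1", {
  calls <- tidyr::expand_grid(
    variant_id = sprintf("p.Z%02d", 1:10), assay = ybrca1_assays())
  truth <- tibble::tibble(
    variant_id = sprintf("p.Z%02d", 1:10),
    prior_label = rep(c("pathogenic", "benign"), each = 5))
  calls$fi <- truth$prior_label[match(calls$variant_id, truth$variant_id)]
  ic <- integrate_calls(calls, 4)
  perf <- combined_performance(ic, truth)
  expect_equal(perf$mcc, 1)
  expect_equal(perf$kappa, 1)
  expect_equal(perf$auroc, 1)

  one_class <- truth
  one_class$prior_label <- "benign"
  expect_error(combined_performance(ic, one_class),
               class = "ybrca1_undefined_roc_error")
})

test_that("concordance counts variants called correctly by every assay", {
  calls <- benchmark_call_matrix()
  truth <- calls[!duplicated(calls$variant_id),
                 c("variant_id", "prior_label")]
  rep_ <- concordance_report(calls[c("variant_id", "assay", "fi")], truth)
  expect_equal(rep_$n_all_correct, 35)
  expect_equal(rep_$n_variants, 46)
  expect_equal(nrow(rep_$discordant), 11)
  expect_equal(round(nrow(rep_$discordant) / rep_$n_variants, 2), 0.24)

  all_correct <- calls
  all_correct$fi <- truth$prior_label[
    match(all_correct$variant_id, truth$variant_id)]
  rep2 <- concordance_report(all_correct[c("variant_id", "assay", "fi")],
                             truth)
  expect_equal(rep2$n_all_correct, 46)
  expect_equal(nrow(rep2$discordant), 0)

  expect_error(
    concordance_report(calls[-1, c("variant_id", "assay", "fi")], truth),
    class = "ybrca1_consistency_error")
})
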