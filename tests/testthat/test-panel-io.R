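test_that("a single-variant file reads back as one measurement with its controls", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- data.frame(
    variant_id = "p.R71K", prior_label = "pathogenic", assay = "gr",
    replicate_index = c(1:5, 1:5),
    value = c(1.1, 2.2, 3.3, 4.4, 5.5, 0.9, 1.0, 1.1, 1.2, 1.3),
    is_control = rep(c(FALSE, TRUE), each = 5))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)

  panel <- read_panel(path, "tsv")
  expect_equal(nrow(panel$variants), 1)
  expect_equal(nrow(panel$measurements), 1)
  expect_equal(panel$measurements$replicates[[1]], c(1.1, 2.2, 3.3, 4.4, 5.5))
  expect_equal(panel$measurements$control_replicates[[1]],
               c(0.9, 1.0, 1.1, 1.2, 1.3))
})

test_that("malformed files fail with the right error class", {
  path <- withr::local_tempfile(fileext = ".tsv")
  base <- data.frame(
    variant_id = "p.R71K", prior_label = "pathogenic", assay = "gr",
    replicate_index = 1:5, value = 1:5 / 2, is_control = FALSE)

  bad_assay <- base
  bad_assay$assay <- "intraHR"
  write.table(bad_assay, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_panel(path), class = "ybrca1_validation_error")

  bad_label <- base
  bad_label$prior_label <- "likely_benign"
  write.table(bad_label, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_panel(path), class = "ybrca1_validation_error")

  write.table(base[, setdiff(names(base), "value")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_panel(path), "value", class = "ybrca1_format_error")

  dup <- rbind(base, base[1, ])
  write.table(dup, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_panel(path), "duplicate", class = "ybrca1_validation_error")

  expect_error(read_panel(file.path(tempdir(), "nope.tsv")),
               class = "ybrca1_format_error")
})

test_that("write_panel/read_panel round-trips randomized panels in both formats", {
  withr::local_seed(404)
  for (i in 1:10) {
    panel <- suppressWarnings(random_small_panel())
    for (fmt in c("tsv", "csv")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_panel(panel, path, fmt)
      back <- suppressWarnings(read_panel(path, fmt))
      expect_equal(back$variants, panel$variants)
      expect_equal(back$measurements, panel$measurements)
    }
  }
})

test_that("the reader is agnostic to row order", {
  withr::local_seed(405)
  panel <- suppressWarnings(random_small_panel())
  path <- withr::local_tempfile(fileext = ".tsv")
  shuffled <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  rows <- readLines(path)
  writeLines(c(rows[1], sample(rows[-1])), shuffled)
  expect_equal(suppressWarnings(read_panel(shuffled)),
               suppressWarnings(read_panel(path)))
})

test_that("a generated 46-variant 4-assay panel round-trips with full counts", {
  cfg <- generator_config(n_pathogenic = 23, n_benign = 23, n_vus = 0,
                          seed = 11)
  panel <- generate_panel(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)

  # brute-force counts straight from the file rows
  rows <- read.delim(path)
  expect_equal(length(unique(rows$variant_id)), 46)
  expect_equal(nrow(unique(rows[!rows$is_control, c("variant_id", "assay")])),
               184)
  expect_equal(nrow(back$variants), 46)
  expect_equal(nrow(back$measurements), 184)
})

test_that("constructor rejects inconsistent panels", {
  v <- tibble::tibble(variant_id = c("p.A1", "p.A1"),
                      prior_label = c("benign", "benign"))
  m <- tibble::tibble(variant_id = "p.A1", assay = "gr",
                      replicates = list(1:5 / 2),
                      control_replicates = list(1:5 / 2))
  expect_error(assay_panel(v, m), class = "ybrca1_validation_error")

  v <- tibble::tibble(variant_id = "p.A1", prior_label = "benign")
  orphan <- m
  orphan$variant_id <- "p.B9"
  expect_error(assay_panel(v, orphan), class = "ybrca1_validation_error")

  neg <- m
  neg$replicates <- list(c(-1, 2, 3, 4, 5))
  expect_error(assay_panel(v, neg), class = "ybrca1_validation_error")

  expect_warning(
    assay_panel(v, tibble::tibble(
      variant_id = "p.A1", assay = "gr",
      replicates = list(c(1, 2, 3)), control_replicates = list(numeric(0)))),
    "fewer than 5")
})

test_that("write_calls emits the classification-table layout", {
  per_assay <- tibble::tibble(
    variant_id = "p.X01",
    assay = ybrca1_assays(),
    ps = c(0.99975, 0.8, 0.6, 0.00025),
    fi = c("pathogenic", "pathogenic", "pathogenic", "benign"))
  calls <- tibble::tibble(variant_id = "p.X01", pv = 3L, pps = 0.75,
                          label = "pathogenic")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, per_assay, path)
  out <- read.delim(path)
  expect_equal(nrow(out), 1)
  expect_equal(ncol(out), 12)  # variant_id + 4 x (ps, fi) + pv + pps + label

  # mismatched variant sets are a consistency error
  expect_error(
    write_calls(calls, per_assay[per_assay$assay != "gr", ], path),
    class = "ybrca1_consistency_error")
})

test_that("re-serializing the published VUS table keeps its calls intact", {
  vus <- benchmark_vus_calls()
  ic <- integrate_calls(vus, n_assays = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(ic, vus, path)
  out <- read.delim(path)
  expect_equal(out$pv[out$variant_id == "p.Y1703C"], 4)
  expect_equal(out$label[out$variant_id == "p.Y1703C"], "pathogenic")
  expect_equal(out$scp_ps[out$variant_id == "p.A1789T"], 0.99975)
})

test_that("an empty call list writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(tibble::tibble(variant_id = character(0), pv = integer(0),
                             pps = numeric(0), label = character(0)),
              tibble::tibble(variant_id = character(0), assay = character(0),
                             ps = numeric(0), fi = character(0)),
              path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "^variant_id\t")
})
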