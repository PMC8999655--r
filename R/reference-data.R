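#' Benchmark discordance lists for the four yeast assays
#'
#' The validated 23 pathogenic + 23 benign BRCA1 panel is not called
#' perfectly by any single assay. This table records, for each assay, which
#' benign variants were scored above the best cut-off (false positives) and
#' which pathogenic variants fell below it (false negatives) in the
#' validation of the yBRCA1 assays. These lists, together with the 23 + 23
#' truth labels, determine every per-assay confusion matrix and the
#' integrated classifier's performance, and are the pattern the planted
#' synthetic panel reproduces.
#'
#' @return Tibble with columns `assay`, `fp` (list of benign variant ids
#'   called pathogenic), `fn` (list of pathogenic variant ids called benign).
#' @seealso [benchmark_call_matrix()], [generate_benchmark_panel()]
#' @export
benchmark_assay_errors <- function() {
  tibble::tibble(
    assay = ybrca1_assays(),
    fp = list(
      c("p.Y179C", "p.I1275V", "p.R1347G", "p.S1512I", "p.P1776H"),
      c("p.Y179C", "p.I1275V"),
      c("p.N132K", "p.I1275V", "p.T1675I"),
      c("p.I1275V", "p.S1512I")),
    fn = list(
      c("p.R71K"),
      c("p.R71K", "p.R1699W", "p.A1708E"),
      c("p.R71K", "p.R1495M"),
      character(0)))
}

#' Benchmark variant panel
#'
#' The 56-variant panel: 23 pathogenic, 23 benign, and 10 VUS. The
#' discordantly-called classified variants and all 10 VUS carry their real
#' HGVS protein identifiers; the remaining concordant classified variants are
#' synthetic placeholder ids (`p.PATH*`, `p.BEN*`) standing in for panel
#' members whose individual identities play no role in any computation
#' downstream of their truth label.
#'
#' @return Tibble with columns `variant_id`, `prior_label`.
#' @export
benchmark_variants <- function() {
  err <- benchmark_assay_errors()
  named_path <- sort(unique(unlist(err$fn)))
  named_ben <- sort(unique(unlist(err$fp)))
  path_ids <- c(named_path,
                sprintf("p.PATH%02d", seq_len(23 - length(named_path))))
  ben_ids <- c(named_ben,
               sprintf("p.BEN%02d", seq_len(23 - length(named_ben))))
  tibble::tibble(
    variant_id = c(path_ids, ben_ids, benchmark_vus_calls()$variant_id |> unique()),
    prior_label = rep(c("pathogenic", "benign", "VUS"), c(23, 23, 10)))
}

#' Published per-assay scores and calls for the 10 VUS
#'
#' Prediction scores (PS) and functional-impact labels (FI) for the ten
#' variants of uncertain significance in each of the four assays, as printed
#' in the published VUS classification table. The FI labels are the votes the
#' integrator consumes; the PS values are bootstrap exceedance scores on a
#' 1/4000 grid (B = 4000 resamples, clamped to [0.00025, 0.99975]).
#'
#' @return Tibble with columns `variant_id`, `assay`, `ps`, `fi` (long
#'   format, 40 rows).
#' @export
benchmark_vus_calls <- function() {
  # columns: inter_hr, intra_hr, gr, scp (ps then fi per assay)
  rows <- list(
    list("p.A1669S", 0.63575, "pathogenic", 0.00675, "benign",
         0.00075, "benign", 0.00025, "benign"),
    list("p.A1789T", 0.00025, "benign", 0.00025, "benign",
         0.00025, "benign", 0.99975, "pathogenic"),
    list("p.E1352K", 0.00025, "benign", 0.56025, "pathogenic",
         0.99925, "pathogenic", 0.99975, "pathogenic"),
    list("p.N1730I", 0.00025, "benign", 0.43825, "pathogenic",
         0.99925, "pathogenic", 0.88025, "pathogenic"),
    list("p.N1819S", 0.00125, "benign", 0.01725, "benign",
         0.99975, "pathogenic", 0.93575, "pathogenic"),
    list("p.P1010S", 0.40675, "pathogenic", 0.00025, "benign",
         0.54025, "pathogenic", 0.00025, "benign"),
    list("p.S1164I", 0.99975, "pathogenic", 0.90575, "pathogenic",
         0.75425, "pathogenic", 0.00025, "benign"),
    list("p.S592N", 0.00025, "benign", 0.89925, "pathogenic",
         0.99975, "pathogenic", 0.99975, "pathogenic"),
    list("p.V1791L", 0.99975, "pathogenic", 0.30975, "pathogenic",
         0.00275, "benign", 0.99975, "pathogenic"),
    list("p.Y1703C", 0.99975, "pathogenic", 0.32425, "pathogenic",
         0.54275, "pathogenic", 0.99975, "pathogenic"))
  assays <- c("inter_hr", "intra_hr", "gr", "scp")
  out <- lapply(rows, function(r) {
    tibble::tibble(
      variant_id = r[[1]],
      assay = assays,
      ps = unlist(r[c(2, 4, 6, 8)]),
      fi = unlist(r[c(3, 5, 7, 9)]))
  })
  dplyr::bind_rows(out)
}

#' Reconstructed per-assay call matrix for the classified benchmark panel
#'
#' Expands the discordance lists of [benchmark_assay_errors()] into the full
#' 46-variant x 4-assay matrix of functional-impact calls: a pathogenic
#' variant is called `pathogenic` everywhere except in the assays listing it
#' as a false negative, and a benign variant is called `benign` everywhere
#' except in the assays listing it as a false positive.
#'
#' @return Tibble with columns `variant_id`, `prior_label`, `assay`, `fi`
#'   (184 rows).
#' @export
benchmark_call_matrix <- function() {
  vars <- benchmark_variants()
  vars <- vars[vars$prior_label != "VUS", ]
  err <- benchmark_assay_errors()
  grid <- tidyr::expand_grid(vars, assay = err$assay)
  grid$fi <- vapply(seq_len(nrow(grid)), function(i) {
    a <- match(grid$assay[i], err$assay)
    v <- grid$variant_id[i]
    truth <- grid$prior_label[i]
    wrong <- (truth == "pathogenic" && v %in% err$fn[[a]]) ||
      (truth == "benign" && v %in% err$fp[[a]])
    if (xor(truth == "pathogenic", wrong)) "pathogenic" else "benign"
  }, character(1))
  grid
}
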