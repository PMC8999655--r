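#' @importFrom rlang .data .env abort warn
#' @importFrom tibble tibble as_tibble
NULL

#' Assay and label vocabularies
#'
#' The four yeast readouts handled by the pipeline, in their canonical order:
#' intra-chromosomal homologous recombination (`intra_hr`, HIS3 colonies per
#' 10^4 plated cells), inter-chromosomal homologous recombination (`inter_hr`,
#' ADE2 colonies per 10^5 cells), gene reversion (`gr`, ILV1 revertant
#' colonies per 10^6 cells), and the small colony phenotype (`scp`, cells per
#' colony). Prior clinical labels are `pathogenic`, `benign`, or `VUS`
#' (variant of uncertain significance).
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
ybrca1_assays <- function() c("intra_hr", "inter_hr", "gr", "scp")

#' @rdname vocabularies
#' @export
ybrca1_labels <- function() c("pathogenic", "benign", "VUS")

#' Construct a validated assay panel
#'
#' An `assay_panel` bundles the variant table (one row per variant with its
#' prior clinical label) with replicate-level measurements, one row per
#' (variant, assay) pair. Replicates and matched wild-type-control replicates
#' are stored as list columns so each measurement keeps its own vector of
#' readouts.
#'
#' @param variants Tibble with columns `variant_id` (non-empty, unique HGVS
#'   protein strings, treated as opaque identifiers) and `prior_label`
#'   (`pathogenic`, `benign`, or `VUS`).
#' @param measurements Tibble with columns `variant_id`, `assay` (one of
#'   [ybrca1_assays()]), `replicates` (list of numeric vectors, finite and
#'   non-negative), `control_replicates` (list of numeric vectors from the
#'   wild-type BRCA1 control, may be empty when only raw-scale analysis is
#'   intended).
#' @return An object of class `assay_panel`.
#' @export
assay_panel <- function(variants, measurements) {
  variants <- as_tibble(variants)
  measurements <- as_tibble(measurements)
  stopifnot(all(c("variant_id", "prior_label") %in% names(variants)))
  stopifnot(all(c("variant_id", "assay", "replicates", "control_replicates") %in%
                  names(measurements)))

  if (any(!nzchar(variants$variant_id)) || anyNA(variants$variant_id)) {
    abort("variant_id must be non-empty", class = "ybrca1_validation_error")
  }
  if (anyDuplicated(variants$variant_id)) {
    abort(
      paste0("duplicated variant_id: ",
             paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
                   collapse = ", ")),
      class = "ybrca1_validation_error")
  }
  bad_label <- setdiff(unique(variants$prior_label), ybrca1_labels())
  if (length(bad_label)) {
    abort(paste0("unknown prior_label: ", paste(bad_label, collapse = ", ")),
          class = "ybrca1_validation_error")
  }
  bad_assay <- setdiff(unique(measurements$assay), ybrca1_assays())
  if (length(bad_assay)) {
    abort(paste0("unknown assay: ", paste(bad_assay, collapse = ", ")),
          class = "ybrca1_validation_error")
  }
  orphan <- setdiff(measurements$variant_id, variants$variant_id)
  if (length(orphan)) {
    abort(paste0("measurement for unknown variant: ",
                 paste(orphan, collapse = ", ")),
          class = "ybrca1_validation_error")
  }
  if (anyDuplicated(measurements[c("variant_id", "assay")])) {
    abort("at most one measurement per (variant, assay)",
          class = "ybrca1_validation_error")
  }
  for (r in measurements$replicates) {
    if (length(r) < 1 || !is.numeric(r) || anyNA(r) || any(!is.finite(r)) ||
        any(r < 0)) {
      abort("replicates must be non-empty, finite and >= 0",
            class = "ybrca1_validation_error")
    }
  }
  for (r in measurements$control_replicates) {
    if (length(r) && (anyNA(r) || any(!is.finite(r)) || any(r < 0))) {
      abort("control replicates must be finite and >= 0",
            class = "ybrca1_validation_error")
    }
  }
  n_rep <- vapply(measurements$replicates, length, integer(1))
  if (any(n_rep < 5)) {
    warn(paste0(sum(n_rep < 5),
                " measurement(s) have fewer than 5 replicates;",
                " at least five independent experiments are recommended"))
  }

  # canonical ordering, so equal panels compare equal regardless of row order
  variants <- variants[order(variants$variant_id),
                       c("variant_id", "prior_label")]
  measurements <- measurements[order(measurements$variant_id,
                                     match(measurements$assay, ybrca1_assays())),
                               c("variant_id", "assay",
                                 "replicates", "control_replicates")]
  structure(
    list(variants = as_tibble(variants), measurements = as_tibble(measurements)),
    class = "assay_panel")
}

#' @export
print.assay_panel <- function(x, ...) {
  tab <- table(x$variants$prior_label)
  cat("<assay_panel> ", nrow(x$variants), " variants (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "), ",
      nrow(x$measurements), " measurements across ",
      length(unique(x$measurements$assay)), " assay(s)\n", sep = "")
  invisible(x)
}

panel_delim <- function(format = c("tsv", "csv")) {
  switch(match.arg(format), tsv = "\t", csv = ",")
}

#' Read a replicate-level panel from a tidy TSV/CSV file
#'
#' The interchange format is long: one row per replicate, with columns
#' `variant_id`, `prior_label`, `assay`, `replicate_index`, `value`,
#' `is_control`. Control rows (`is_control = TRUE`) carry the wild-type
#' BRCA1 readouts measured under the same conditions as the variant they are
#' attached to. Decimal point is `.`; the field separator follows `format`.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"csv"`.
#' @return A validated [assay_panel()]; replicate order within each
#'   measurement follows `replicate_index`, so shuffled row order reads back
#'   to an identical panel.
#' @examples
#' path <- system.file("extdata", "example_panel.tsv", package = "ybrca1")
#' read_panel(path)
#' @export
read_panel <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ybrca1_format_error")
  }
  raw <- readr::read_delim(
    path, delim = panel_delim(format), show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()))

  required <- c("variant_id", "prior_label", "assay", "replicate_index",
                "value", "is_control")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
          class = "ybrca1_format_error")
  }
  raw$.row <- seq_len(nrow(raw))

  bad <- which(!raw$assay %in% ybrca1_assays())
  if (length(bad)) {
    abort(paste0("unknown assay token '", raw$assay[bad[1]],
                 "' at data row ", bad[1]),
          class = "ybrca1_validation_error")
  }
  bad <- which(!raw$prior_label %in% ybrca1_labels())
  if (length(bad)) {
    abort(paste0("unknown prior_label token '", raw$prior_label[bad[1]],
                 "' at data row ", bad[1]),
          class = "ybrca1_validation_error")
  }
  raw$value <- suppressWarnings(as.numeric(raw$value))
  if (anyNA(raw$value)) {
    abort(paste0("non-numeric value at data row ",
                 which(is.na(raw$value))[1]),
          class = "ybrca1_validation_error")
  }
  raw$replicate_index <- suppressWarnings(as.integer(raw$replicate_index))
  if (anyNA(raw$replicate_index)) {
    abort("replicate_index must be integer", class = "ybrca1_validation_error")
  }
  ctl <- toupper(trimws(raw$is_control))
  if (!all(ctl %in% c("TRUE", "FALSE", "T", "F", "0", "1"))) {
    abort("is_control must be logical (TRUE/FALSE or 0/1)",
          class = "ybrca1_validation_error")
  }
  raw$is_control <- ctl %in% c("TRUE", "T", "1")

  dup <- duplicated(raw[c("variant_id", "assay", "replicate_index",
                          "is_control")])
  if (any(dup)) {
    abort(paste0("duplicate (variant, assay, replicate_index, is_control) ",
                 "at data row ", which(dup)[1]),
          class = "ybrca1_validation_error")
  }

  label_map <- unique(raw[c("variant_id", "prior_label")])
  if (anyDuplicated(label_map$variant_id)) {
    v <- label_map$variant_id[duplicated(label_map$variant_id)][1]
    abort(paste0("conflicting prior_label for variant ", v),
          class = "ybrca1_validation_error")
  }

  raw <- raw[order(raw$replicate_index), ]
  meas <- raw |>
    dplyr::group_by(.data$variant_id, .data$assay) |>
    dplyr::summarise(
      replicates = list(.data$value[!.data$is_control]),
      control_replicates = list(.data$value[.data$is_control]),
      .groups = "drop")
  empty <- vapply(meas$replicates, length, integer(1)) == 0
  if (any(empty)) {
    abort(paste0("measurement with only control rows: ",
                 meas$variant_id[empty][1], " / ", meas$assay[empty][1]),
          class = "ybrca1_validation_error")
  }

  variants <- label_map[match(sort(unique(raw$variant_id)),
                              label_map$variant_id), ]
  meas <- meas[order(meas$variant_id, match(meas$assay, ybrca1_assays())), ]
  assay_panel(as_tibble(variants), as_tibble(meas))
}

#' Write a panel to the tidy interchange format
#'
#' Inverse of [read_panel()]: emits one row per replicate (variant rows first,
#' then control rows) with 1-based `replicate_index` within each block.
#'
#' @param panel An [assay_panel()].
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(panel, "assay_panel"))
  label <- stats::setNames(panel$variants$prior_label,
                           panel$variants$variant_id)
  rows <- lapply(seq_len(nrow(panel$measurements)), function(i) {
    m <- panel$measurements[i, ]
    v <- m$replicates[[1]]
    ctl <- m$control_replicates[[1]]
    tibble(
      variant_id = m$variant_id,
      prior_label = unname(label[m$variant_id]),
      assay = m$assay,
      replicate_index = c(seq_along(v), seq_along(ctl)),
      value = c(v, ctl),
      is_control = rep(c(FALSE, TRUE), c(length(v), length(ctl))))
  })
  out <- dplyr::bind_rows(rows)
  readr::write_delim(out, path, delim = panel_delim(format))
  invisible(path)
}

#' Write the final classification table
#'
#' One row per variant with per-assay prediction score (PS) and functional
#' impact (FI) columns, followed by pathogenic votes (PV), pathogenic
#' prediction score (PPS) and the final label — the layout of the published
#' VUS classification table.
#'
#' @param calls Tibble of integrated calls: `variant_id`, `pv`, `pps`,
#'   `label` (see [integrate_calls()]).
#' @param per_assay Tibble of per-assay impact calls: `variant_id`, `assay`,
#'   `ps`, `fi` (see [score_panel()]).
#' @param path Output path (TSV).
#' @param assays Assay column order; defaults to [ybrca1_assays()].
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, per_assay, path, assays = ybrca1_assays()) {
  calls <- as_tibble(calls)
  per_assay <- as_tibble(per_assay)
  per_assay <- per_assay[per_assay$assay %in% assays, ]
  if (!setequal(calls$variant_id, per_assay$variant_id) && nrow(calls) > 0) {
    abort("integrated calls and per-assay calls cover different variants",
          class = "ybrca1_consistency_error")
  }
  counts <- table(per_assay$variant_id)
  if (nrow(calls) > 0 && any(counts != length(assays))) {
    abort("every variant needs one impact call per configured assay",
          class = "ybrca1_consistency_error")
  }

  wide <- if (nrow(calls) == 0) {
    tibble(variant_id = character(0))
  } else {
    per_assay |>
      dplyr::mutate(assay = factor(.data$assay, levels = assays)) |>
      tidyr::pivot_wider(id_cols = "variant_id", names_from = "assay",
                         values_from = c("ps", "fi"), names_glue = "{assay}_{.value}",
                         names_vary = "slowest")
  }
  col_order <- c("variant_id",
                 as.vector(rbind(paste0(assays, "_ps"), paste0(assays, "_fi"))),
                 "pv", "pps", "label")
  out <- dplyr::left_join(calls, wide, by = "variant_id")
  out <- out[intersect(col_order, names(out))]
  # keep a header even for an empty call list
  if (nrow(calls) == 0) {
    out <- as_tibble(stats::setNames(
      rep(list(character(0)), length(col_order)), col_order))
  }
  readr::write_tsv(out, path)
  invisible(path)
}
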