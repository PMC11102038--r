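#' Build the drug-ADR pair table
#'
#' For every observed (canonical drug, preferred term) combination, counts
#' the distinct reports mentioning both (`n_reports`), tallies the per-ADR
#' treatment-outcome codes within those reports (`o1`..`o5`; missing
#' outcomes count in `n_reports` but not in the tallies), and fills the
#' report-granularity 2x2 contingency table:
#' `a` = reports with both drug and ADR (= `n_reports`), `b` = reports with
#' the drug but not the ADR, `c` = reports with the ADR but not the drug,
#' `d` = the remaining qualified reports, so `a + b + c + d` equals the
#' qualified-report count for every pair. A report mentioning one drug with
#' several ADRs contributes once to each pair's `a` cell.
#'
#' @param x A qualified, normalized [ade_reports] collection (drug mentions
#'   carry `drug_id`, ADR mentions carry `pt_id`; unresolved mentions are
#'   ignored here but reports still count in the contingency total).
#' @return Tibble with columns `drug_id`, `adr_id`, `n_reports`, `o1`..`o5`,
#'   `a`, `b`, `c`, `d`, `drug_total`, `adr_total`.
#' @export
build_pair_table <- function(x) {
  stopifnot(inherits(x, "ade_reports"))
  if (!"drug_id" %in% names(x$drugs) || !"pt_id" %in% names(x$adrs)) {
    stop("reports must be normalized first (see normalize_drugs(), ",
         "normalize_adrs())", call. = FALSE)
  }
  n_total <- nrow(x$reports)
  empty <- tibble::tibble(drug_id = character(), adr_id = character(),
                          n_reports = integer(),
                          o1 = integer(), o2 = integer(), o3 = integer(),
                          o4 = integer(), o5 = integer(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(),
                          drug_total = integer(), adr_total = integer())
  if (n_total == 0) return(empty)

  drug_hits <- dplyr::distinct(
    dplyr::filter(x$drugs, !is.na(.data$drug_id)),
    .data$report_id, .data$drug_id)
  # one outcome per (report, PT): first mention wins
  adr_hits <- dplyr::filter(x$adrs, !is.na(.data$pt_id)) |>
    dplyr::distinct(.data$report_id, .data$pt_id, .keep_all = TRUE) |>
    dplyr::select("report_id", "pt_id", "outcome")
  if (nrow(drug_hits) == 0 || nrow(adr_hits) == 0) return(empty)

  joint <- dplyr::inner_join(drug_hits, adr_hits, by = "report_id",
                             relationship = "many-to-many")
  if (nrow(joint) == 0) return(empty)

  pair <- joint |>
    dplyr::group_by(.data$drug_id, adr_id = .data$pt_id) |>
    dplyr::summarise(
      n_reports = dplyr::n_distinct(.data$report_id),
      o1 = sum(.data$outcome %in% "O1"),
      o2 = sum(.data$outcome %in% "O2"),
      o3 = sum(.data$outcome %in% "O3"),
      o4 = sum(.data$outcome %in% "O4"),
      o5 = sum(.data$outcome %in% "O5"),
      .groups = "drop")

  drug_tot <- drug_hits |>
    dplyr::count(.data$drug_id, name = "drug_total")
  adr_tot <- adr_hits |>
    dplyr::distinct(.data$report_id, .data$pt_id) |>
    dplyr::count(.data$pt_id, name = "adr_total") |>
    dplyr::rename(adr_id = "pt_id")

  pair |>
    dplyr::left_join(drug_tot, by = "drug_id") |>
    dplyr::left_join(adr_tot, by = "adr_id") |>
    dplyr::mutate(
      a = .data$n_reports,
      b = .data$drug_total - .data$a,
      c = .data$adr_total - .data$a,
      d = n_total - .data$a - .data$b - .data$c
    ) |>
    dplyr::select("drug_id", "adr_id", "n_reports",
                  "o1", "o2", "o3", "o4", "o5",
                  "a", "b", "c", "d", "drug_total", "adr_total") |>
    dplyr::arrange(.data$drug_id, .data$adr_id)
}

#' Apply support thresholds to the pair table
#'
#' Keeps pairs whose ADR, drug and pair report totals meet the minimum
#' thresholds. All three conditions are evaluated on the pre-filter totals
#' (`drug_total`, `adr_total` from [build_pair_table()]), so the filter
#' order is irrelevant. The attrition count is attached as the `attrition`
#' attribute.
#'
#' @param pairs A pair table from [build_pair_table()].
#' @param rules A [qualification_rules()] object (the `min_*` thresholds).
#' @return The retained pairs.
#' @export
filter_by_support <- function(pairs, rules = qualification_rules()) {
  stopifnot(inherits(rules, "qualification_rules"))
  keep <- pairs$adr_total >= rules$min_adr_reports &
    pairs$drug_total >= rules$min_drug_reports &
    pairs$n_reports >= rules$min_pair_reports
  out <- pairs[keep, , drop = FALSE]
  attr(out, "attrition") <- tibble::tibble(
    rule = "support_thresholds",
    removed = as.integer(sum(!keep)))
  out
}
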