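#' Qualification rules for spontaneous reports
#'
#' Controls which reports and mentions enter the analysis. Defaults follow
#' standard pharmacovigilance screening practice: only reports from health
#' professionals; ADR mentions under five drug-unrelated system organ
#' classes removed; only single-ingredient small-molecule drugs; support
#' thresholds of at least 2 reports per ADR, 26 per drug and 2 per
#' drug-ADR pair (all inclusive, i.e. "fewer than" is discarded).
#'
#' @param excluded_socs Character vector of SOC labels whose ADR mentions
#'   are dropped (matched case-insensitively).
#' @param professional_only Drop reports from nonprofessional reporters?
#' @param single_ingredient_small_molecule_only Keep only reports whose
#'   drug mentions all carry both flags?
#' @param min_adr_reports,min_drug_reports,min_pair_reports Minimum distinct
#'   report counts for an ADR, a drug, and a pair to be retained by
#'   [filter_by_support()].
#' @return An object of class `qualification_rules`.
#' @export
qualification_rules <- function(excluded_socs = excluded_soc_names(),
                                professional_only = TRUE,
                                single_ingredient_small_molecule_only = TRUE,
                                min_adr_reports = 2,
                                min_drug_reports = 26,
                                min_pair_reports = 2) {
  stopifnot(min_adr_reports >= 0, min_drug_reports >= 0,
            min_pair_reports >= 0)
  structure(list(
    excluded_socs = tolower(excluded_socs),
    professional_only = isTRUE(professional_only),
    single_ingredient_small_molecule_only =
      isTRUE(single_ingredient_small_molecule_only),
    min_adr_reports = min_adr_reports,
    min_drug_reports = min_drug_reports,
    min_pair_reports = min_pair_reports
  ), class = "qualification_rules")
}

#' Filter raw reports to qualified reports
#'
#' Applies, in order: reporter-class screening, excluded-SOC removal of ADR
#' mentions (a report is dropped only when no ADR mention survives), and
#' the single-ingredient small-molecule drug requirement. Per-rule attrition
#' counts are attached as the `attrition` attribute and returned in the
#' audit of [run_pipeline()].
#'
#' ADR mentions with an unknown (missing) SOC label raise a warning and are
#' retained: only the explicitly listed SOCs are excluded.
#'
#' @param x An [ade_reports] collection.
#' @param rules A [qualification_rules()] object.
#' @return The qualified `ade_reports` collection, with an `attrition`
#'   attribute (tibble of rule / reports removed).
#' @export
qualify_reports <- function(x, rules = qualification_rules()) {
  stopifnot(inherits(x, "ade_reports"),
            inherits(rules, "qualification_rules"))
  attrition <- tibble::tibble(rule = character(), removed = integer())
  note <- function(rule, removed) {
    attrition <<- dplyr::bind_rows(attrition,
                                   tibble::tibble(rule = rule,
                                                  removed = as.integer(removed)))
  }
  keep <- x$reports$report_id

  if (rules$professional_only) {
    prof <- x$reports$report_id[x$reports$reporter_class == "professional"]
    note("nonprofessional_reporter", length(keep) - length(intersect(keep, prof)))
    keep <- intersect(keep, prof)
  }

  adrs <- x$adrs[x$adrs$report_id %in% keep, , drop = FALSE]
  if (anyNA(adrs$soc)) {
    warning("ADR mention(s) with unknown SOC label retained ",
            "(only listed SOCs are excluded)", call. = FALSE)
  }
  adrs <- adrs[is.na(adrs$soc) |
                 !(tolower(adrs$soc) %in% rules$excluded_socs), ,
               drop = FALSE]
  with_adr <- unique(adrs$report_id)
  note("no_adr_outside_excluded_socs", length(keep) - length(intersect(keep, with_adr)))
  keep <- intersect(keep, with_adr)

  if (rules$single_ingredient_small_molecule_only) {
    drugs <- x$drugs[x$drugs$report_id %in% keep, , drop = FALSE]
    bad <- unique(drugs$report_id[!(drugs$single_ingredient %in% TRUE) |
                                    !(drugs$small_molecule %in% TRUE)])
    note("multi_ingredient_or_biologic_drug", length(intersect(keep, bad)))
    keep <- setdiff(keep, bad)
  }

  out <- ade_reports(
    reports = x$reports[x$reports$report_id %in% keep, , drop = FALSE],
    drugs = x$drugs[x$drugs$report_id %in% keep, , drop = FALSE],
    adrs = adrs[adrs$report_id %in% keep, , drop = FALSE]
  )
  attr(out, "attrition") <- attrition
  out
}
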