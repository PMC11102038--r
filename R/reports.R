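#' Spontaneous adverse-drug-event report collection
#'
#' Container for a collection of spontaneous ADE reports, held as three
#' linked tibbles: one row per report (`reports`), one row per drug mention
#' (`drugs`), one row per ADR mention (`adrs`). This long layout mirrors how
#' the downstream contingency counting works: every statistic is computed at
#' report granularity by joining mentions back to `report_id`.
#'
#' @param reports Tibble with columns `report_id` (unique) and
#'   `reporter_class` (`"professional"` or `"nonprofessional"`).
#' @param drugs Tibble with columns `report_id`, `raw_name`, `product_code`
#'   (may be `NA`), `single_ingredient` and `small_molecule` (logical flags).
#' @param adrs Tibble with columns `report_id`, `raw_term`, `soc` (system
#'   organ class label, may be `NA`) and `outcome` (`"O1"`..`"O5"` or `NA`).
#'
#' Reports with duplicated `report_id` are deduplicated keeping the first
#' occurrence (redundant submissions are excluded from counting).
#'
#' @return An object of class `ade_reports`.
#' @export
ade_reports <- function(reports, drugs, adrs) {
  reports <- tibble::as_tibble(reports)
  drugs <- tibble::as_tibble(drugs)
  adrs <- tibble::as_tibble(adrs)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(sprintf("`%s` is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(reports, c("report_id", "reporter_class"), "reports")
  need(drugs, c("report_id", "raw_name"), "drugs")
  need(adrs, c("report_id", "raw_term", "soc", "outcome"), "adrs")

  if (!"product_code" %in% names(drugs)) drugs$product_code <- NA_character_
  if (!"single_ingredient" %in% names(drugs)) drugs$single_ingredient <- TRUE
  if (!"small_molecule" %in% names(drugs)) drugs$small_molecule <- TRUE

  bad_class <- setdiff(unique(reports$reporter_class),
                       c("professional", "nonprofessional"))
  if (length(bad_class) > 0) {
    stop("unknown reporter_class value(s): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  bad_out <- setdiff(stats::na.omit(unique(adrs$outcome)), outcome_codes())
  if (length(bad_out) > 0) {
    stop("outcome codes must be one of O1..O5; found: ",
         paste(bad_out, collapse = ", "), call. = FALSE)
  }

  dup <- duplicated(reports$report_id)
  if (any(dup)) {
    message(sum(dup), " duplicated report id(s) removed (first kept)")
    keep_first <- !dup
    kept_ids <- reports$report_id[keep_first]
    reports <- reports[keep_first, ]
    drugs <- drugs[drugs$report_id %in% kept_ids, ]
    adrs <- adrs[adrs$report_id %in% kept_ids, ]
  }

  orphan <- setdiff(c(drugs$report_id, adrs$report_id), reports$report_id)
  if (length(orphan) > 0) {
    stop("drug/ADR mentions reference unknown report id(s): ",
         paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
  }

  structure(list(reports = reports, drugs = drugs, adrs = adrs),
            class = "ade_reports")
}

#' @rdname ade_reports
#' @export
empty_ade_reports <- function() {
  ade_reports(
    reports = tibble::tibble(report_id = character(),
                             reporter_class = character()),
    drugs = tibble::tibble(report_id = character(), raw_name = character(),
                           product_code = character(),
                           single_ingredient = logical(),
                           small_molecule = logical()),
    adrs = tibble::tibble(report_id = character(), raw_term = character(),
                          soc = character(), outcome = character())
  )
}

#' @export
print.ade_reports <- function(x, ...) {
  cat(sprintf("<ade_reports> %d reports, %d drug mentions, %d ADR mentions\n",
              nrow(x$reports), nrow(x$drugs), nrow(x$adrs)))
  invisible(x)
}

#' Number of reports in a collection
#' @param x An `ade_reports` object.
#' @return Integer count of distinct reports.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "ade_reports"))
  nrow(x$reports)
}
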