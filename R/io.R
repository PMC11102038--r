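#' Read and write report collections
#'
#' Reports are serialized as JSON Lines: one JSON object per report with a
#' `schema_version` field, scalar `report_id` and `reporter_class`, and
#' arrays `drugs` / `adrs` carrying the mention-level fields. An
#' openFDA-dialect reader accepts a JSON array (or an object with a
#' `results` array) of safety reports and maps the fields the pipeline
#' consumes: `safetyreportid`, `primarysource.qualification` (codes 1-3 are
#' health professionals), `patient.drug[].medicinalproduct` and
#' `openfda.product_ndc`, `patient.reaction[].reactionmeddrapt`,
#' `reactionsoc` and `reactionoutcome` (codes 1-5; 6/unknown becomes `NA`).
#'
#' @param x An `ade_reports` object.
#' @param path File path.
#' @return `write_reports_jsonl()` returns `path` invisibly; the readers
#'   return an `ade_reports` object.
#' @export
write_reports_jsonl <- function(x, path) {
  stopifnot(inherits(x, "ade_reports"))
  drugs_by <- split(x$drugs[setdiff(names(x$drugs), "report_id")],
                    factor(x$drugs$report_id, levels = x$reports$report_id))
  adrs_by <- split(x$adrs[setdiff(names(x$adrs), "report_id")],
                   factor(x$adrs$report_id, levels = x$reports$report_id))
  lines <- vapply(seq_len(nrow(x$reports)), function(i) {
    rid <- x$reports$report_id[i]
    jsonlite::toJSON(list(
      schema_version = adrquant_schema_version,
      report_id = rid,
      reporter_class = x$reports$reporter_class[i],
      drugs = drugs_by[[rid]],
      adrs = adrs_by[[rid]]
    ), auto_unbox = TRUE, na = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reports_jsonl
#' @export
read_reports_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_ade_reports())
  objs <- lapply(lines, jsonlite::fromJSON, simplifyDataFrame = TRUE)
  reports <- tibble::tibble(
    report_id = vapply(objs, function(o) as.character(o$report_id),
                       character(1)),
    reporter_class = vapply(objs, function(o) as.character(o$reporter_class),
                            character(1))
  )
  grab <- function(field) {
    dplyr::bind_rows(lapply(seq_along(objs), function(i) {
      df <- objs[[i]][[field]]
      if (is.null(df) || length(df) == 0) return(NULL)
      df <- tibble::as_tibble(df)
      df$report_id <- reports$report_id[i]
      df
    }))
  }
  drugs <- grab("drugs")
  adrs <- grab("adrs")
  if (nrow(drugs) == 0) drugs <- empty_ade_reports()$drugs
  if (nrow(adrs) == 0) adrs <- empty_ade_reports()$adrs
  chr <- function(x) if (is.logical(x)) as.character(x) else x
  drugs <- dplyr::relocate(
    dplyr::mutate(drugs, product_code = chr(.data$product_code)),
    "report_id")
  adrs <- dplyr::relocate(
    dplyr::mutate(adrs, soc = chr(.data$soc), outcome = chr(.data$outcome)),
    "report_id")
  ade_reports(reports, drugs, adrs)
}

#' @rdname write_reports_jsonl
#' @export
read_reports_openfda <- function(path) {
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(parsed$results)) parsed <- parsed$results
  if (length(parsed) == 0) return(empty_ade_reports())

  pluck_chr <- function(x, ...) {
    v <- purrr::pluck(x, ..., .default = NA)
    if (is.null(v) || length(v) == 0) NA_character_ else as.character(v[[1]])
  }
  rows <- lapply(seq_along(parsed), function(i) {
    rep <- parsed[[i]]
    rid <- pluck_chr(rep, "safetyreportid")
    if (is.na(rid)) rid <- sprintf("openfda-%06d", i)
    qual <- pluck_chr(rep, "primarysource", "qualification")
    klass <- if (!is.na(qual) && qual %in% c("1", "2", "3")) {
      "professional"
    } else {
      "nonprofessional"
    }
    drugs <- purrr::map_dfr(rep$patient$drug %||% list(), function(d) {
      tibble::tibble(
        report_id = rid,
        raw_name = pluck_chr(d, "medicinalproduct"),
        product_code = pluck_chr(d, "openfda", "product_ndc"),
        single_ingredient = length(d$activesubstance %||% list()) <= 1,
        small_molecule = TRUE
      )
    })
    adrs <- purrr::map_dfr(rep$patient$reaction %||% list(), function(r) {
      out_code <- pluck_chr(r, "reactionoutcome")
      tibble::tibble(
        report_id = rid,
        raw_term = pluck_chr(r, "reactionmeddrapt"),
        soc = pluck_chr(r, "reactionsoc"),
        outcome = if (!is.na(out_code) && out_code %in% as.character(1:5)) {
          paste0("O", out_code)
        } else {
          NA_character_
        }
      )
    })
    list(report = tibble::tibble(report_id = rid, reporter_class = klass),
         drugs = drugs, adrs = adrs)
  })
  ade_reports(
    reports = dplyr::bind_rows(lapply(rows, `[[`, "report")),
    drugs = dplyr::bind_rows(lapply(rows, `[[`, "drugs")),
    adrs = dplyr::bind_rows(lapply(rows, `[[`, "adrs"))
  )
}

#' Read and write prescription records
#'
#' CSV with columns `raw_name`, `product_code`, `year`, `person_weight` and
#' a `schema_version` header comment line.
#'
#' @param x Tibble of prescription records.
#' @param path File path.
#' @return The tibble of records (readers) or `path` invisibly (writer).
#' @export
write_prescriptions_csv <- function(x, path) {
  stopifnot(all(c("raw_name", "year", "person_weight") %in% names(x)))
  writeLines(sprintf("# schema_version: %s", adrquant_schema_version), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_prescriptions_csv
#' @export
read_prescriptions_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    raw_name = readr::col_character(),
                    product_code = readr::col_character(),
                    year = readr::col_integer(),
                    person_weight = readr::col_double()
                  ))
}
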