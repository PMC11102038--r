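#' Average annual prescriptions (AAP) from person-weighted records
#'
#' Resolves the raw drug names of prescription records through the same
#' three-route dictionary resolver used for reports, then computes each
#' drug's AAP as the person-weight sum over the period divided by the
#' number of years in the period. Dictionary drugs with no resolved
#' records are emitted with `source = "unavailable"` so that ATC inference
#' can complete them.
#'
#' @param prescriptions Tibble with columns `raw_name`, `product_code`
#'   (optional), `year`, `person_weight`.
#' @param dictionary A [drug_dictionary()].
#' @param period Calendar years of the estimation window (records outside
#'   it are ignored).
#' @return Tibble with columns `drug_id`, `aap`, `source` (`"direct"` or
#'   `"unavailable"`); unresolved record counts attached as attribute
#'   `n_unresolved`.
#' @export
compute_aap <- function(prescriptions, dictionary, period) {
  stopifnot(inherits(dictionary, "drug_dictionary"))
  period <- as.integer(period)
  if (length(period) == 0) stop("period must contain at least one year",
                                call. = FALSE)
  stopifnot(all(c("raw_name", "year", "person_weight") %in%
                  names(prescriptions)))
  if (!"product_code" %in% names(prescriptions)) {
    prescriptions$product_code <- NA_character_
  }
  res <- resolve_drug_names(prescriptions[c("raw_name", "product_code")],
                            dictionary)
  prescriptions$drug_id <- res$drug_id
  n_unresolved <- sum(is.na(res$drug_id))

  direct <- prescriptions |>
    dplyr::filter(!is.na(.data$drug_id), .data$year %in% period) |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(aap = sum(.data$person_weight) / length(period),
                     .groups = "drop") |>
    dplyr::mutate(source = "direct")

  all_drugs <- unique(dictionary$synonyms$drug_id)
  missing <- setdiff(all_drugs, direct$drug_id)
  out <- dplyr::bind_rows(
    direct,
    tibble::tibble(drug_id = missing, aap = NA_real_,
                   source = "unavailable")
  ) |>
    dplyr::arrange(.data$drug_id)
  attr(out, "n_unresolved") <- n_unresolved
  out
}

#' Complete missing AAPs by ATC level-2 inference
#'
#' Drugs without direct prescription volumes inherit the central tendency
#' (mean by default, median by option) of the direct AAPs of drugs sharing
#' their ATC level-2 therapeutic subgroup (the first three characters of
#' the ATC code). Drugs without an ATC code, or whose subgroup has no
#' directly estimated member, remain `"unavailable"`.
#'
#' @param aap_table Output of [compute_aap()].
#' @param dictionary A [drug_dictionary()] carrying ATC codes.
#' @param method `"mean"` (default) or `"median"`.
#' @return The completed AAP table (`source` gains `"atc_inferred"`).
#' @export
infer_aap_by_atc <- function(aap_table, dictionary,
                             method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(dictionary, "drug_dictionary"))
  centre <- if (method == "mean") mean else stats::median
  atc2 <- dictionary$atc |>
    dplyr::mutate(atc2 = substr(.data$atc_code, 1, 3)) |>
    dplyr::distinct(.data$drug_id, .data$atc2)

  tab <- dplyr::left_join(aap_table, atc2, by = "drug_id",
                          relationship = "many-to-many")
  class_aap <- tab |>
    dplyr::filter(.data$source == "direct", !is.na(.data$atc2)) |>
    dplyr::group_by(.data$atc2) |>
    dplyr::summarise(class_aap = centre(.data$aap), .groups = "drop")

  tab <- dplyr::left_join(tab, class_aap, by = "atc2")
  inferred <- tab$source == "unavailable" & !is.na(tab$class_aap)
  tab$aap[inferred] <- tab$class_aap[inferred]
  tab$source[inferred] <- "atc_inferred"
  # a drug with several ATC codes: average its candidate class AAPs
  tab |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(aap = if (all(is.na(.data$aap))) NA_real_ else
                       mean(.data$aap, na.rm = TRUE),
                     source = .data$source[1], .groups = "drop") |>
    dplyr::arrange(.data$drug_id)
}

#' Underreporting-corrected ADR frequency
#'
#' `frequency = n_reports / ((1 - URR) * AAP * yr)`: the reported pair
#' count scaled up by the reporting rate `(1 - URR)` and divided by the
#' total prescriptions over the estimation window. The underreporting rate
#' is keyed to the pair's assigned severity grade - 0.77 for very serious
#' ADRs (life-threatening, death) and 0.94 otherwise - which makes
#' severity a declared upstream dependency of frequency. Estimates above 1
#' are clamped to 1 with a warning (the estimator is not
#' probability-bounded).
#'
#' @param n_reports Reported count(s) of the drug-ADR pair.
#' @param grade Severity grade label(s) of the pair.
#' @param aap Average annual prescriptions of the drug (`NA` gives `NA`
#'   frequency).
#' @param yr Length of the estimation window in years (default 8).
#' @param urr_serious,urr_other Underreporting rates for fatal-group vs
#'   other grades.
#' @return Numeric frequency vector.
#' @examples
#' estimate_frequency(24, "mild", aap = 50000)        # 0.001
#' estimate_frequency(5, "death", aap = 10000)        # ~2.72e-4
#' @export
estimate_frequency <- function(n_reports, grade, aap, yr = 8,
                               urr_serious = 0.77, urr_other = 0.94) {
  stopifnot(yr > 0, urr_serious >= 0, urr_serious < 1,
            urr_other >= 0, urr_other < 1)
  urr <- ifelse(grade %in% fatal_grades(), urr_serious, urr_other)
  freq <- n_reports / ((1 - urr) * aap * yr)
  freq[is.na(grade) & !(!is.na(n_reports) & n_reports == 0)] <- NA_real_
  over <- !is.na(freq) & freq > 1
  if (any(over)) {
    warning(sum(over), " frequency estimate(s) above 1 clamped to 1",
            call. = FALSE)
    freq[over] <- 1
  }
  freq
}

#' Conventional frequency classes
#'
#' Left-closed/right-open bins on the per-prescription occurrence rate:
#' very rare `[0, 1e-4)`, rare `[1e-4, 1e-3)`, uncommon `[1e-3, 1e-2)`,
#' common `[1e-2, 1e-1)`, very common `[1e-1, Inf)`.
#'
#' @param frequency Non-negative frequency vector (`NA` passes through).
#' @return Character vector of class labels.
#' @export
frequency_class <- function(frequency) {
  if (any(!is.na(frequency) & frequency < 0)) {
    stop("frequencies must be non-negative", call. = FALSE)
  }
  labs <- c("very_rare", "rare", "uncommon", "common", "very_common")
  idx <- findInterval(frequency, c(0, 1e-4, 1e-3, 1e-2, 1e-1))
  out <- labs[idx]
  out[is.na(frequency)] <- NA_character_
  out
}

#' Append frequency columns to a scored pair table
#'
#' @param pairs A scored pair table (`drug_id`, `n_reports`,
#'   `severity_grade`).
#' @param aap_table AAP table from [compute_aap()] /
#'   [infer_aap_by_atc()].
#' @param ... Passed to [estimate_frequency()].
#' @return `pairs` with `aap`, `aap_source`, `frequency`, `freq_class`
#'   added; pairs of drugs with unavailable AAP get `NA` frequency.
#' @export
add_frequency <- function(pairs, aap_table, ...) {
  stopifnot(all(c("drug_id", "n_reports", "severity_grade") %in%
                  names(pairs)))
  joined <- dplyr::left_join(
    pairs,
    dplyr::rename(aap_table, aap_source = "source"),
    by = "drug_id")
  joined$frequency <- estimate_frequency(joined$n_reports,
                                         joined$severity_grade,
                                         joined$aap, ...)
  joined$freq_class <- frequency_class(joined$frequency)
  joined
}
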