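#' Build distinct drug-ADR-target entries
#'
#' Cross-joins the scored pair table with each drug's therapeutic targets
#' and removes singleton entries: ADRs associated with exactly one target,
#' and targets associated with exactly one ADR. Both exclusions are
#' evaluated on the pre-exclusion counts in a single pass.
#'
#' @param pairs A scored pair table (`drug_id`, `adr_id`,
#'   `severity_grade`; `frequency` carried through when present).
#' @param target_map Tibble with columns `drug_id`, `target_id`.
#' @return Tibble of distinct entries: `drug_id`, `adr_id`, `target_id`,
#'   `grade`, `frequency`.
#' @export
build_target_entries <- function(pairs, target_map) {
  stopifnot(all(c("drug_id", "adr_id", "severity_grade") %in% names(pairs)),
            all(c("drug_id", "target_id") %in% names(target_map)))
  if (nrow(target_map) == 0) {
    return(tibble::tibble(drug_id = character(), adr_id = character(),
                          target_id = character(), grade = character(),
                          frequency = double()))
  }
  if (!"frequency" %in% names(pairs)) pairs$frequency <- NA_real_
  entries <- pairs |>
    dplyr::select("drug_id", "adr_id", grade = "severity_grade",
                  "frequency") |>
    dplyr::inner_join(tibble::as_tibble(target_map), by = "drug_id",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$drug_id, .data$adr_id, .data$target_id,
                    .keep_all = TRUE)

  adr_deg <- entries |>
    dplyr::group_by(.data$adr_id) |>
    dplyr::summarise(n_targets = dplyr::n_distinct(.data$target_id),
                     .groups = "drop")
  tgt_deg <- entries |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(n_adrs = dplyr::n_distinct(.data$adr_id),
                     .groups = "drop")
  singleton_adrs <- adr_deg$adr_id[adr_deg$n_targets == 1]
  singleton_tgts <- tgt_deg$target_id[tgt_deg$n_adrs == 1]
  entries |>
    dplyr::filter(!(.data$adr_id %in% singleton_adrs),
                  !(.data$target_id %in% singleton_tgts)) |>
    dplyr::select("drug_id", "adr_id", "target_id", "grade", "frequency")
}

#' Odds ratio between an ADR (or the fatal group) and a target
#'
#' Over the entry list, `a` = entries with both the ADR (group) and the
#' target, `b` = target without the ADR, `c` = ADR without the target,
#' `d` = neither; `OR = ad/bc` with Woolf 95% CI, 0.5 added to all cells
#' of tables containing a zero. Significance is two-sided: the 95% CI
#' excludes 1.
#'
#' @param entries Entry table from [build_target_entries()].
#' @param target_id Target evaluated.
#' @param adr_id Single ADR selector; ignored when `fatal = TRUE`.
#' @param fatal If `TRUE`, the selector is the fatal ADR group (grades
#'   life-threatening or death).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `target_id`, `a`..`d`, `or`, `ci_low`,
#'   `ci_high`, `significant`.
#' @export
target_or <- function(entries, target_id, adr_id = NULL, fatal = FALSE,
                      conf_level = 0.95) {
  if (!fatal && is.null(adr_id)) {
    stop("supply adr_id or set fatal = TRUE", call. = FALSE)
  }
  in_group <- if (fatal) {
    entries$grade %in% fatal_grades()
  } else {
    entries$adr_id == adr_id
  }
  has_tgt <- entries$target_id == target_id
  a <- sum(in_group & has_tgt)
  b <- sum(!in_group & has_tgt)
  c <- sum(in_group & !has_tgt)
  d <- sum(!in_group & !has_tgt)
  res <- woolf_or(a, b, c, d, conf_level = conf_level,
                  zero_correction = TRUE, alternative = "two.sided")
  dplyr::bind_cols(tibble::tibble(target_id = target_id,
                                  a = a, b = b, c = c, d = d), res)
}

#' Mechanism zones on the OR-frequency plane
#'
#' Classifies ADR-target relations into four mechanism zones by
#' association strength and ADR frequency: zone 1 high OR & low frequency
#' (on-target, controlled by a well-designed dosage), zone 2 high OR &
#' high frequency (dose-dependent), zone 3 low OR & low frequency, zone 4
#' low OR & high frequency (off-target). "High" means `>= or_threshold`
#' and `>= freq_threshold`. The thresholds have no published numeric
#' values; the defaults (`or_threshold = 2`, `freq_threshold = 1e-3`) are
#' artifact defaults of this package and should be set by the analyst.
#'
#' @param or_value,frequency Numeric vectors.
#' @param or_threshold,freq_threshold Positive zone thresholds.
#' @return Integer zone 1..4 (`NA` propagates).
#' @export
zone_assign <- function(or_value, frequency, or_threshold = 2,
                        freq_threshold = 1e-3) {
  if (or_threshold <= 0 || freq_threshold <= 0) {
    stop("zone thresholds must be positive", call. = FALSE)
  }
  high_or <- or_value >= or_threshold
  high_fr <- frequency >= freq_threshold
  dplyr::case_when(
    high_or & !high_fr ~ 1L,
    high_or & high_fr ~ 2L,
    !high_or & !high_fr ~ 3L,
    !high_or & high_fr ~ 4L
  )
}

#' Screen targets for fatal-ADR risk
#'
#' Computes, for every target in the entry list, the odds ratio against
#' the fatal ADR group (grades life-threatening and death) and returns the
#' targets exceeding the OR threshold (default 2), ranked by OR descending
#' with ties broken by target id. Each row carries the drugs whose fatal
#' entries involve the target.
#'
#' @param entries Entry table from [build_target_entries()].
#' @param or_threshold Minimum OR (exclusive).
#' @return Tibble: `target_id`, `or`, `ci_low`, `ci_high`, `significant`,
#'   `drugs` (list-column).
#' @export
fatal_risk_targets <- function(entries, or_threshold = 2) {
  empty <- tibble::tibble(target_id = character(), or = double(),
                          ci_low = double(), ci_high = double(),
                          significant = logical(), drugs = list())
  fatal <- entries$grade %in% fatal_grades()
  if (!any(fatal)) {
    message("no entries in the fatal ADR group; empty fatal-risk list")
    return(empty)
  }
  per_target <- purrr::map_dfr(sort(unique(entries$target_id)),
                               function(t) {
    target_or(entries, target_id = t, fatal = TRUE)
  })
  hits <- per_target |>
    dplyr::filter(!is.na(.data$or), .data$or > or_threshold) |>
    dplyr::arrange(dplyr::desc(.data$or), .data$target_id)
  if (nrow(hits) == 0) return(empty)
  drug_lists <- entries |>
    dplyr::filter(.data$grade %in% fatal_grades(),
                  .data$target_id %in% hits$target_id) |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(drugs = list(sort(unique(.data$drug_id))),
                     .groups = "drop")
  hits |>
    dplyr::left_join(drug_lists, by = "target_id") |>
    dplyr::select("target_id", "or", "ci_low", "ci_high", "significant",
                  "drugs")
}
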