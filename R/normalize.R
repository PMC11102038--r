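#' Resolve raw drug mentions to canonical ids
#'
#' Resolution routes, in order: (1) product-code lookup; (2) exact
#' (case-folded) name match against the dictionary synonyms; (3) match of
#' the cleaned name after stripping dosage/form stop tokens and numeric
#' tokens. A cleaned name matching two or more canonical ids is flagged
#' ambiguous and left unresolved; unknown names are flagged unresolved and
#' the report is retained for audit, never silently dropped.
#'
#' @param x An [ade_reports] collection.
#' @param dictionary A [drug_dictionary()].
#' @param stop_tokens Tokens stripped during cleaning;
#'   see [default_stop_tokens()].
#' @return `x` with drug-mention columns `drug_id`, `resolution_route`
#'   (`"product_code"`, `"exact"`, `"cleaned"`, or `NA`) and
#'   `unresolved_reason` added.
#' @export
normalize_drugs <- function(x, dictionary,
                            stop_tokens = default_stop_tokens()) {
  stopifnot(inherits(x, "ade_reports"), inherits(dictionary, "drug_dictionary"))
  res <- resolve_drug_names(
    tibble::tibble(raw_name = x$drugs$raw_name,
                   product_code = x$drugs$product_code),
    dictionary, stop_tokens)
  x$drugs$drug_id <- res$drug_id
  x$drugs$resolution_route <- res$resolution_route
  x$drugs$unresolved_reason <- res$unresolved_reason
  x
}

# shared name resolver; also used for prescription records
resolve_drug_names <- function(mentions, dictionary,
                               stop_tokens = default_stop_tokens()) {
  syn <- dictionary$synonyms
  exact_map <- syn |>
    dplyr::group_by(.data$synonym_key) |>
    dplyr::summarise(ids = list(unique(.data$drug_id)), .groups = "drop")
  code_map <- dictionary$product_codes |>
    dplyr::group_by(.data$product_code) |>
    dplyr::summarise(ids = list(unique(.data$drug_id)), .groups = "drop")

  lookup <- function(keys, map, key_col) {
    map$ids[match(keys, map[[key_col]])]
  }
  pick <- function(ids) {
    # NULL -> no match; >1 id -> ambiguous
    n <- vapply(ids, length, integer(1))
    list(id = ifelse(n == 1, vapply(ids, function(v) v[1] %||% NA_character_,
                                    character(1)), NA_character_),
         ambiguous = n > 1)
  }

  n <- nrow(mentions)
  drug_id <- rep(NA_character_, n)
  route <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  # route 1: product code
  by_code <- pick(lookup(mentions$product_code, code_map, "product_code"))
  hit <- !is.na(by_code$id)
  drug_id[hit] <- by_code$id[hit]
  route[hit] <- "product_code"

  # route 2: exact folded name
  todo <- is.na(drug_id)
  by_exact <- pick(lookup(fold_name(mentions$raw_name[todo]), exact_map,
                          "synonym_key"))
  drug_id[todo][!is.na(by_exact$id)] <- by_exact$id[!is.na(by_exact$id)]
  route[todo][!is.na(by_exact$id)] <- "exact"

  # route 3: cleaned name
  todo <- is.na(drug_id)
  cleaned <- clean_drug_name(mentions$raw_name[todo], stop_tokens)
  by_clean <- pick(lookup(cleaned, exact_map, "synonym_key"))
  drug_id[todo][!is.na(by_clean$id)] <- by_clean$id[!is.na(by_clean$id)]
  route[todo][!is.na(by_clean$id)] <- "cleaned"
  reason[todo][by_clean$ambiguous] <- "ambiguous_cleaned_match"

  reason[is.na(drug_id) & is.na(reason)] <- "no_match"
  reason[!is.na(drug_id)] <- NA_character_
  tibble::tibble(drug_id = drug_id, resolution_route = route,
                 unresolved_reason = reason)
}

#' Resolve raw ADR terms to preferred-term ids
#'
#' Case-insensitive synonym resolution against an [adr_ontology()];
#' preferred terms map to themselves. Unresolved terms are flagged and
#' retained.
#'
#' @param x An [ade_reports] collection.
#' @param ontology An [adr_ontology()].
#' @return `x` with ADR-mention columns `pt_id` and `unresolved_reason`
#'   added.
#' @export
normalize_adrs <- function(x, ontology) {
  stopifnot(inherits(x, "ade_reports"), inherits(ontology, "adr_ontology"))
  keys <- fold_name(x$adrs$raw_term)
  idx <- match(keys, ontology$synonyms$synonym_key)
  x$adrs$pt_id <- ontology$synonyms$pt_id[idx]
  x$adrs$unresolved_reason <- ifelse(is.na(x$adrs$pt_id), "no_match",
                                     NA_character_)
  x
}
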