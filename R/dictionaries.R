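#' Drug dictionary
#'
#' Maps raw drug mentions to canonical drug ids by product code, by exact
#' synonym, or by cleaned-name synonym, and carries ATC codes used for
#' prescription-volume inference.
#'
#' @param synonyms Tibble with columns `drug_id`, `synonym`. Synonyms are
#'   matched case-insensitively.
#' @param product_codes Optional tibble with columns `drug_id`,
#'   `product_code`.
#' @param atc Optional tibble with columns `drug_id`, `atc_code` (full ATC
#'   code, e.g. `"N02BE01"`; the level-2 therapeutic subgroup is its first
#'   three characters).
#' @return An object of class `drug_dictionary`.
#' @export
drug_dictionary <- function(synonyms, product_codes = NULL, atc = NULL) {
  synonyms <- tibble::as_tibble(synonyms)
  stopifnot(all(c("drug_id", "synonym") %in% names(synonyms)))
  synonyms$synonym_key <- fold_name(synonyms$synonym)
  if (is.null(product_codes)) {
    product_codes <- tibble::tibble(drug_id = character(),
                                    product_code = character())
  }
  product_codes <- tibble::as_tibble(product_codes)
  stopifnot(all(c("drug_id", "product_code") %in% names(product_codes)))
  if (is.null(atc)) {
    atc <- tibble::tibble(drug_id = character(), atc_code = character())
  }
  atc <- tibble::as_tibble(atc)
  stopifnot(all(c("drug_id", "atc_code") %in% names(atc)))
  structure(list(synonyms = synonyms, product_codes = product_codes,
                 atc = atc),
            class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat(sprintf(
    "<drug_dictionary> %d drugs, %d synonyms, %d product codes, %d ATC codes\n",
    dplyr::n_distinct(x$synonyms$drug_id), nrow(x$synonyms),
    nrow(x$product_codes), nrow(x$atc)))
  invisible(x)
}

#' ADR ontology
#'
#' Maps raw ADR terms to preferred-term (PT) ids, MedDRA-style: each PT has
#' a canonical term, a system organ class (SOC), and any number of synonyms.
#' The PT term itself always resolves to its own id.
#'
#' @param terms Tibble with columns `pt_id`, `pt_term`, `soc`, and
#'   optionally `synonym` (one row per synonym; rows without a `synonym`
#'   contribute only the PT term).
#' @return An object of class `adr_ontology`.
#' @export
adr_ontology <- function(terms) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("pt_id", "pt_term", "soc") %in% names(terms)))
  if (!"synonym" %in% names(terms)) terms$synonym <- NA_character_

  pts <- dplyr::distinct(terms, .data$pt_id, .data$pt_term, .data$soc)
  syn <- dplyr::bind_rows(
    dplyr::transmute(pts, pt_id = .data$pt_id, synonym = .data$pt_term),
    dplyr::filter(dplyr::select(terms, "pt_id", "synonym"),
                  !is.na(.data$synonym))
  )
  syn$synonym_key <- fold_name(syn$synonym)
  syn <- dplyr::distinct(syn, .data$pt_id, .data$synonym_key,
                         .keep_all = TRUE)
  structure(list(pts = pts, synonyms = syn), class = "adr_ontology")
}

#' @export
print.adr_ontology <- function(x, ...) {
  cat(sprintf("<adr_ontology> %d preferred terms, %d synonyms\n",
              nrow(x$pts), nrow(x$synonyms)))
  invisible(x)
}

# case-fold and collapse whitespace; the shared matching key
fold_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Default stop tokens stripped during drug-name cleaning
#'
#' Dosage-form and unit tokens removed before the cleaned-name dictionary
#' match (route 3 of drug resolution). Purely numeric tokens are always
#' removed in addition to this list. Editable: pass your own vector to
#' [normalize_drugs()].
#'
#' @return Character vector of lowercase tokens.
#' @export
default_stop_tokens <- function() {
  c("mg", "mcg", "ml", "g", "iu", "tablet", "tablets", "capsule",
    "capsules", "chewable", "ophthalmic", "oral", "topical", "solution",
    "suspension", "injection", "cream", "ointment", "gel", "spray",
    "extended", "release", "er", "xr", "sr", "hcl", "hydrochloride")
}

# strip stop tokens + numeric tokens from a folded name
clean_drug_name <- function(x, stop_tokens = default_stop_tokens()) {
  x <- fold_name(x)
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    tok <- tok[!(tok %in% stop_tokens) & !grepl("^[0-9.,/%-]+$", tok)]
    paste(tok, collapse = " ")
  }, character(1))
}
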