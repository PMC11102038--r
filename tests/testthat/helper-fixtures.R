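# Fixtures shared across the suite; everything is built in code.

# toy dictionary: two drugs with synonyms, product codes and ATC codes
toy_dictionary <- function() {
  drug_dictionary(
    synonyms = tibble::tibble(
      drug_id = c("DB1", "DB1", "DB2", "DB3"),
      synonym = c("aspirin", "acetylsalicylic acid", "ibuprofen",
                  "metformin")),
    product_codes = tibble::tibble(
      drug_id = c("DB1", "DB2"),
      product_code = c("NDC-1", "NDC-2")),
    atc = tibble::tibble(
      drug_id = c("DB1", "DB2", "DB3"),
      atc_code = c("N02BA01", "M01AE01", "A10BA02"))
  )
}

toy_ontology <- function() {
  adr_ontology(tibble::tibble(
    pt_id = c("PT1", "PT1", "PT2", "PT3"),
    pt_term = c("Headache", "Headache", "Nausea", "Rash"),
    soc = c("nervous system disorders", "nervous system disorders",
            "gastrointestinal disorders",
            "skin and subcutaneous tissue disorders"),
    synonym = c("head ache", NA, NA, NA)
  ))
}

# minimal professional single-ingredient report
mk_report <- function(id, drug, adr, outcome = NA_character_,
                      soc = "nervous system disorders",
                      reporter = "professional",
                      single_ingredient = TRUE) {
  list(
    reports = tibble::tibble(report_id = id, reporter_class = reporter),
    drugs = tibble::tibble(report_id = rep(id, length(drug)),
                           raw_name = drug,
                           product_code = NA_character_,
                           single_ingredient = single_ingredient,
                           small_molecule = TRUE),
    adrs = tibble::tibble(report_id = rep(id, length(adr)),
                          raw_term = adr,
                          soc = rep_len(soc, length(adr)),
                          outcome = rep_len(outcome, length(adr)))
  )
}

bind_reports <- function(...) {
  parts <- list(...)
  ade_reports(
    reports = dplyr::bind_rows(lapply(parts, `[[`, "reports")),
    drugs = dplyr::bind_rows(lapply(parts, `[[`, "drugs")),
    adrs = dplyr::bind_rows(lapply(parts, `[[`, "adrs"))
  )
}

# the hand-counted qualification fixture: 10 reports of which 4 survive
# (3 nonprofessional, 2 whose only ADR sits under "product issues",
#  1 with a multi-ingredient drug)
qualification_fixture <- function() {
  bind_reports(
    mk_report("q01", "aspirin", "Headache"),
    mk_report("q02", "ibuprofen", "Nausea"),
    mk_report("q03", "metformin", "Rash"),
    mk_report("q04", "aspirin", "Nausea"),
    mk_report("q05", "aspirin", "Headache", reporter = "nonprofessional"),
    mk_report("q06", "ibuprofen", "Nausea", reporter = "nonprofessional"),
    mk_report("q07", "metformin", "Rash", reporter = "nonprofessional"),
    mk_report("q08", "aspirin", "Device leak", soc = "product issues"),
    mk_report("q09", "ibuprofen", "Device leak", soc = "product issues"),
    mk_report("q10", "aspirin", "Headache", single_ingredient = FALSE)
  )
}

# a normalized random fixture of <= 100 reports for oracle comparisons
random_fixture <- function(n = 60, seed = 11) {
  withr::with_seed(seed, {
    parts <- lapply(seq_len(n), function(i) {
      drugs <- sample(c("aspirin", "ibuprofen", "metformin"),
                      sample(1:2, 1))
      adrs <- sample(c("Headache", "Nausea", "Rash"), sample(1:2, 1))
      outs <- sample(c(outcome_codes(), NA), length(adrs), replace = TRUE)
      socs <- c(Headache = "nervous system disorders",
                Nausea = "gastrointestinal disorders",
                Rash = "skin and subcutaneous tissue disorders")[adrs]
      mk_report(sprintf("r%03d", i), drugs, adrs, outcome = outs,
                soc = unname(socs))
    })
    do.call(bind_reports, parts)
  })
}

# naive double-loop recount of the pair contingency cells
naive_pair_oracle <- function(x) {
  ids <- x$reports$report_id
  drug_sets <- lapply(ids, function(r) {
    unique(stats::na.omit(x$drugs$drug_id[x$drugs$report_id == r]))
  })
  adr_sets <- lapply(ids, function(r) {
    unique(stats::na.omit(x$adrs$pt_id[x$adrs$report_id == r]))
  })
  combos <- unique(do.call(rbind, lapply(seq_along(ids), function(i) {
    if (length(drug_sets[[i]]) == 0 || length(adr_sets[[i]]) == 0) {
      return(NULL)
    }
    expand.grid(drug_id = drug_sets[[i]], adr_id = adr_sets[[i]],
                stringsAsFactors = FALSE)
  })))
  res <- lapply(seq_len(nrow(combos)), function(k) {
    di <- combos$drug_id[k]; aj <- combos$adr_id[k]
    has_d <- vapply(drug_sets, function(s) di %in% s, logical(1))
    has_a <- vapply(adr_sets, function(s) aj %in% s, logical(1))
    tibble::tibble(drug_id = di, adr_id = aj,
                   a = sum(has_d & has_a), b = sum(has_d & !has_a),
                   c = sum(!has_d & has_a), d = sum(!has_d & !has_a))
  })
  dplyr::arrange(dplyr::bind_rows(res), drug_id, adr_id)
}

# one-configuration model grading table for evaluation tests
mk_model_grading <- function(n = 100, seed = 5, k = 2) {
  withr::with_seed(seed, {
    tibble::tibble(
      pt_id = sprintf("PT%03d", seq_len(n)),
      grades = lapply(seq_len(n), function(i) {
        sample(grade_levels(), sample(seq_len(k), 1))
      })
    )
  })
}
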