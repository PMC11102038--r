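#' Simulation configuration
#'
#' Defines one synthetic study scenario: a panel of drugs and ADR preferred
#' terms, per-pair true ADR incidence per prescription, per-pair treatment
#' outcome profiles, severity-stratified reporting rates, and the
#' prescription-volume scheme. Everything downstream (reports, prescription
#' records, ground truth) is a deterministic function of this object.
#'
#' Defaults encode the study conditions the simulator emulates: reporting
#' rate 0.23 for events whose drawn outcome is very serious (O4/O5) and
#' 0.06 otherwise (the 77%/94% underreporting split of spontaneous-report
#' systems), an eight-year 2012-2019 window, per-pair incidence log-uniform
#' on 1e-4..1e-2 (most ADRs are rare), and recovery-dominant outcome
#' profiles drawn from a Dirichlet(8, 4, 2, 1, 0.5).
#'
#' @param n_drugs,n_adrs Panel sizes.
#' @param n_patients_per_drug_year Prescriptions (equivalently, exposed
#'   patients) per drug per year; also the per-drug annual person-weight sum
#'   of the prescription generator.
#' @param years Calendar years simulated.
#' @param incidence_matrix `n_drugs x n_adrs` matrix of true per-prescription
#'   ADR probabilities in `[0, 1]`; defaults drawn from the seed.
#' @param outcome_profile Either a probability 5-vector applied to every
#'   pair or an `n_drugs x n_adrs x 5` array; rows must sum to 1. Defaults
#'   drawn from the seed.
#' @param reporting_rate_serious,reporting_rate_other Per-event reporting
#'   probabilities for events with outcome O4/O5 vs others.
#' @param nonprofessional_fraction Fraction of reports filed by
#'   nonprofessional reporters.
#' @param excluded_soc_fraction Fraction of ADR terms assigned to a
#'   drug-unrelated system organ class (one of the five conventionally
#'   excluded SOCs).
#' @param name_noise If `TRUE`, prescription drug names carry appended
#'   dosage/form tokens ("500 mg tablets", ...) on a subset of records.
#' @param prescription_records_per_year Records the annual volume of each
#'   drug is split into (1 = a single record holding the full weight).
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_drugs = 20,
                       n_adrs = 30,
                       n_patients_per_drug_year = 10000,
                       years = 2012:2019,
                       incidence_matrix = NULL,
                       outcome_profile = NULL,
                       reporting_rate_serious = 0.23,
                       reporting_rate_other = 0.06,
                       nonprofessional_fraction = 0.25,
                       excluded_soc_fraction = 0.1,
                       name_noise = TRUE,
                       prescription_records_per_year = 4,
                       seed = 1L) {
  stopifnot(n_drugs >= 0, n_adrs >= 0, n_patients_per_drug_year >= 0,
            prescription_records_per_year >= 1)
  probs <- c(reporting_rate_serious, reporting_rate_other,
             nonprofessional_fraction, excluded_soc_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all rate/fraction parameters must lie in [0, 1]", call. = FALSE)
  }
  seed <- as.integer(seed)

  if (is.null(incidence_matrix) && n_drugs > 0 && n_adrs > 0) {
    incidence_matrix <- withr::with_seed(seed + 101L, {
      matrix(10^stats::runif(n_drugs * n_adrs, -4, -2), n_drugs, n_adrs)
    })
  }
  if (n_drugs > 0 && n_adrs > 0) {
    incidence_matrix <- as.matrix(incidence_matrix)
    if (!all(dim(incidence_matrix) == c(n_drugs, n_adrs))) {
      stop("incidence_matrix must be n_drugs x n_adrs", call. = FALSE)
    }
    if (any(incidence_matrix < 0 | incidence_matrix > 1)) {
      stop("incidence probabilities must lie in [0, 1]", call. = FALSE)
    }
  }

  if (is.null(outcome_profile) && n_drugs > 0 && n_adrs > 0) {
    outcome_profile <- withr::with_seed(seed + 202L, {
      n <- n_drugs * n_adrs
      g <- matrix(stats::rgamma(n * 5, shape = rep(c(8, 4, 2, 1, 0.5),
                                                   each = n)), n, 5)
      array(g / rowSums(g), dim = c(n_drugs, n_adrs, 5))
    })
  }
  if (n_drugs > 0 && n_adrs > 0) {
    if (is.numeric(outcome_profile) && is.null(dim(outcome_profile))) {
      stopifnot(length(outcome_profile) == 5)
      outcome_profile <- array(rep(outcome_profile,
                                   each = n_drugs * n_adrs),
                               dim = c(n_drugs, n_adrs, 5))
    }
    if (!all(dim(outcome_profile) == c(n_drugs, n_adrs, 5))) {
      stop("outcome_profile must be a 5-vector or n_drugs x n_adrs x 5 array",
           call. = FALSE)
    }
    if (any(outcome_profile < 0)) {
      stop("outcome probabilities must be non-negative", call. = FALSE)
    }
    sums <- apply(outcome_profile, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-8)) {
      stop("each outcome profile must sum to 1", call. = FALSE)
    }
  }

  structure(list(
    n_drugs = as.integer(n_drugs),
    n_adrs = as.integer(n_adrs),
    n_patients_per_drug_year = n_patients_per_drug_year,
    years = as.integer(years),
    incidence_matrix = incidence_matrix,
    outcome_profile = outcome_profile,
    reporting_rate_serious = reporting_rate_serious,
    reporting_rate_other = reporting_rate_other,
    nonprofessional_fraction = nonprofessional_fraction,
    excluded_soc_fraction = excluded_soc_fraction,
    name_noise = isTRUE(name_noise),
    prescription_records_per_year = as.integer(prescription_records_per_year),
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d drugs x %d ADRs, %s patients/drug/year, years %s-%s,\n",
    "  reporting rates %.2f (O4/O5) / %.2f (other), seed %d\n"),
    x$n_drugs, x$n_adrs, format(x$n_patients_per_drug_year, big.mark = ","),
    min(x$years), max(x$years),
    x$reporting_rate_serious, x$reporting_rate_other, x$seed))
  invisible(x)
}

excluded_soc_names <- function() {
  c("congenital, familial and genetic disorders",
    "surgical and medical procedures",
    "social circumstances",
    "product issues",
    "injury, poisoning and procedural complications")
}

benign_soc_names <- function() {
  c("nervous system disorders", "gastrointestinal disorders",
    "cardiac disorders", "skin and subcutaneous tissue disorders",
    "psychiatric disorders", "renal and urinary disorders",
    "respiratory, thoracic and mediastinal disorders",
    "hepatobiliary disorders", "blood and lymphatic system disorders",
    "musculoskeletal and connective tissue disorders")
}

sim_drug_ids <- function(config) sprintf("D%03d", seq_len(config$n_drugs))
sim_pt_ids <- function(config) sprintf("ADR%04d", seq_len(config$n_adrs))

#' Dictionary and ontology implied by a simulation scenario
#'
#' Deterministic companions to the simulated data: every simulated drug has
#' a canonical name `drug<i>`, a brand-style synonym, a product code and an
#' ATC code cycling over eight level-2 therapeutic subgroups; every ADR has
#' a preferred term, one synonym and a SOC assignment (the first
#' `excluded_soc_fraction` of terms sit under conventionally excluded SOCs).
#'
#' @param config A [sim_config()].
#' @return A `drug_dictionary` / `adr_ontology`.
#' @export
sim_dictionary <- function(config) {
  i <- seq_len(config$n_drugs)
  if (length(i) == 0) {
    return(drug_dictionary(tibble::tibble(drug_id = character(),
                                          synonym = character())))
  }
  ids <- sim_drug_ids(config)
  canon <- sprintf("drug%03d", i)
  brand <- sprintf("bravex%03d", i)
  atc2 <- c("A02", "C07", "J01", "L01", "M01", "N02", "N05", "R03")
  drug_dictionary(
    synonyms = tibble::tibble(drug_id = rep(ids, 2),
                              synonym = c(canon, brand)),
    product_codes = tibble::tibble(drug_id = ids,
                                   product_code = sprintf("NDC-%05d", i)),
    atc = tibble::tibble(drug_id = ids,
                         atc_code = sprintf("%sB%03d",
                                            atc2[(i - 1) %% length(atc2) + 1],
                                            i))
  )
}

#' @rdname sim_dictionary
#' @export
sim_ontology <- function(config) {
  j <- seq_len(config$n_adrs)
  if (length(j) == 0) {
    return(adr_ontology(tibble::tibble(pt_id = character(),
                                       pt_term = character(),
                                       soc = character())))
  }
  n_excluded <- round(config$excluded_soc_fraction * config$n_adrs)
  socs <- c(
    excluded_soc_names()[(seq_len(n_excluded) - 1) %%
                           length(excluded_soc_names()) + 1],
    benign_soc_names()[(seq_len(config$n_adrs - n_excluded) - 1) %%
                         length(benign_soc_names()) + 1]
  )
  terms <- sprintf("adr term %04d", j)
  adr_ontology(dplyr::bind_rows(
    tibble::tibble(pt_id = sim_pt_ids(config), pt_term = terms, soc = socs,
                   synonym = NA_character_),
    tibble::tibble(pt_id = sim_pt_ids(config), pt_term = terms, soc = socs,
                   synonym = sprintf("reported %s", terms))
  ))
}
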