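#' Simulate a FAERS-like spontaneous report collection
#'
#' Draws true ADR events per (drug, ADR, year) from the configured incidence,
#' assigns each event one treatment outcome from the pair's outcome profile,
#' and thins events into reports with the severity-stratified reporting
#' rates: events whose drawn outcome is O4 or O5 report with
#' `reporting_rate_serious`, all others with `reporting_rate_other`. Each
#' reported event becomes one report carrying a reporter class, the drug
#' mention (canonical name + product code) and the ADR mention (preferred
#' term, SOC label, outcome code).
#'
#' @param config A [sim_config()].
#' @return A list with elements `reports` (an [ade_reports] collection),
#'   `truth` (ground-truth tibbles: `true_incidence`, `true_outcome_profile`,
#'   `true_annual_prescriptions`, plus event/report tallies per pair),
#'   `dictionary` and `ontology` (the [sim_dictionary()] companions).
#' @export
simulate_ade_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_ground_truth(config)
  if (config$n_drugs == 0 || config$n_adrs == 0 ||
      length(config$years) == 0) {
    message("degenerate scenario (no drugs, ADRs or years): zero reports")
    return(list(reports = empty_ade_reports(), truth = truth,
                dictionary = sim_dictionary(config),
                ontology = sim_ontology(config)))
  }
  withr::local_seed(config$seed)

  dict <- sim_dictionary(config)
  ont <- sim_ontology(config)
  drug_ids <- sim_drug_ids(config)
  pt_ids <- sim_pt_ids(config)
  canon_names <- sprintf("drug%03d", seq_len(config$n_drugs))
  prod_codes <- sprintf("NDC-%05d", seq_len(config$n_drugs))

  grid <- expand.grid(d = seq_len(config$n_drugs),
                      a = seq_len(config$n_adrs),
                      year = config$years, KEEP.OUT.ATTRS = FALSE)
  q <- config$incidence_matrix[cbind(grid$d, grid$a)]
  grid$events <- stats::rbinom(nrow(grid), config$n_patients_per_drug_year, q)

  # outcome split then severity-stratified thinning, per grid cell
  active <- which(grid$events > 0)
  per_cell <- lapply(active, function(r) {
    p <- config$outcome_profile[grid$d[r], grid$a[r], ]
    ok <- stats::rmultinom(1, grid$events[r], p)[, 1]
    rate <- ifelse(seq_len(5) >= 4, config$reporting_rate_serious,
                   config$reporting_rate_other)
    rep_k <- stats::rbinom(5, ok, rate)
    tibble::tibble(d = grid$d[r], a = grid$a[r], year = grid$year[r],
                   outcome = outcome_codes(), n_events = ok,
                   n_reported = rep_k)
  })
  cells <- dplyr::bind_rows(per_cell)

  tallies <- if (nrow(cells) == 0) {
    tibble::tibble(drug_id = character(), adr_id = character(),
                   n_events = integer(), n_reported = integer())
  } else {
    cells |>
      dplyr::group_by(drug_id = drug_ids[.data$d], adr_id = pt_ids[.data$a]) |>
      dplyr::summarise(n_events = sum(.data$n_events),
                       n_reported = sum(.data$n_reported), .groups = "drop")
  }
  truth$event_tallies <- tallies

  reported <- if (nrow(cells) == 0) cells else
    cells[cells$n_reported > 0, , drop = FALSE]
  if (nrow(reported) == 0) {
    return(list(reports = empty_ade_reports(), truth = truth,
                dictionary = dict, ontology = ont))
  }
  rows <- tidyr::uncount(reported, weights = .data$n_reported)
  n <- nrow(rows)
  rows$report_id <- sprintf("R%07d", seq_len(n))
  rows$reporter_class <- ifelse(
    stats::runif(n) < config$nonprofessional_fraction,
    "nonprofessional", "professional")

  soc_by_pt <- stats::setNames(ont$pts$soc, ont$pts$pt_id)
  reports <- ade_reports(
    reports = tibble::tibble(report_id = rows$report_id,
                             reporter_class = rows$reporter_class),
    drugs = tibble::tibble(report_id = rows$report_id,
                           raw_name = canon_names[rows$d],
                           product_code = prod_codes[rows$d],
                           single_ingredient = TRUE,
                           small_molecule = TRUE),
    adrs = tibble::tibble(report_id = rows$report_id,
                          raw_term = ont$pts$pt_term[rows$a],
                          soc = unname(soc_by_pt[pt_ids[rows$a]]),
                          outcome = rows$outcome)
  )
  list(reports = reports, truth = truth, dictionary = dict, ontology = ont)
}

sim_ground_truth <- function(config) {
  if (config$n_drugs == 0 || config$n_adrs == 0) {
    return(list(
      true_incidence = tibble::tibble(drug_id = character(),
                                      adr_id = character(),
                                      incidence = double()),
      true_outcome_profile = tibble::tibble(drug_id = character(),
                                            adr_id = character()),
      true_annual_prescriptions = tibble::tibble(drug_id = character(),
                                                 n_prescriptions = double())
    ))
  }
  drug_ids <- sim_drug_ids(config)
  pt_ids <- sim_pt_ids(config)
  grid <- expand.grid(d = seq_len(config$n_drugs),
                      a = seq_len(config$n_adrs), KEEP.OUT.ATTRS = FALSE)
  prof <- t(apply(grid, 1, function(r) config$outcome_profile[r[1], r[2], ]))
  colnames(prof) <- paste0("p", 1:5)
  list(
    true_incidence = tibble::tibble(
      drug_id = drug_ids[grid$d], adr_id = pt_ids[grid$a],
      incidence = config$incidence_matrix[cbind(grid$d, grid$a)]),
    true_outcome_profile = dplyr::bind_cols(
      tibble::tibble(drug_id = drug_ids[grid$d], adr_id = pt_ids[grid$a]),
      tibble::as_tibble(prof)),
    true_annual_prescriptions = tibble::tibble(
      drug_id = drug_ids,
      n_prescriptions = rep(config$n_patients_per_drug_year, config$n_drugs))
  )
}

#' Simulate MEPS-like person-weighted prescription records
#'
#' Each drug-year's annual prescription volume
#' (`n_patients_per_drug_year`) is split across
#' `prescription_records_per_year` records whose person weights sum exactly
#' to the volume. With `name_noise` on, half of the records carry appended
#' dosage/form tokens on the raw drug name and a subset lack product codes,
#' exercising all three name-resolution routes downstream.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `raw_name`, `product_code`, `year`,
#'   `person_weight`.
#' @export
simulate_prescriptions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_drugs == 0 || length(config$years) == 0) {
    message("degenerate scenario: zero prescription records")
    return(tibble::tibble(raw_name = character(), product_code = character(),
                          year = integer(), person_weight = double()))
  }
  withr::local_seed(config$seed + 1L)
  k <- config$prescription_records_per_year
  canon <- sprintf("drug%03d", seq_len(config$n_drugs))
  codes <- sprintf("NDC-%05d", seq_len(config$n_drugs))
  grid <- expand.grid(d = seq_len(config$n_drugs), year = config$years,
                      rec = seq_len(k), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$d, grid$year, grid$rec), ]
  if (k == 1) {
    grid$person_weight <- config$n_patients_per_drug_year
  } else {
    g <- stats::rgamma(nrow(grid), shape = 1)
    tot <- stats::ave(g, grid$d, grid$year, FUN = sum)
    grid$person_weight <- config$n_patients_per_drug_year * g / tot
  }
  name <- canon[grid$d]
  code <- codes[grid$d]
  if (config$name_noise) {
    noisy <- grid$rec %% 2 == 0
    tokens <- c("500 mg tablets", "10 mg", "ophthalmic solution",
                "25 mg chewable tablets", "100 mg capsules")
    name[noisy] <- paste(name[noisy],
                         tokens[sample.int(length(tokens), sum(noisy),
                                           replace = TRUE)])
    code[stats::runif(nrow(grid)) < 0.4] <- NA_character_
  }
  tibble::tibble(raw_name = name, product_code = code,
                 year = as.integer(grid$year),
                 person_weight = grid$person_weight)
}

#' Simulate an expert grade table with controlled agreement
#'
#' Given a model grading (one grade set per preferred term), emits an
#' expert table in which configured fractions of terms are constructed to be
#' subset (expert grades covered by the model's), overlapping
#' (shared and unshared grades), or disjoint from the model grades.
#' Counts per state follow a deterministic largest-remainder allocation of
#' `n * fractions` before the seeded shuffle, so exact fractions at round
#' numbers give exact counts.
#'
#' @param model_grading Tibble with columns `pt_id` and `grades`
#'   (list-column of grade labels).
#' @param fractions Named numeric `(subset, overlap, disjoint)`, summing to
#'   at most 1; terms left over are omitted from the expert table.
#' @param seed Integer seed.
#' @return Tibble with columns `pt_id`, `grades` (list-column), `state`
#'   (the planted relation, for ground truth).
#' @export
simulate_expert_grades <- function(model_grading,
                                   fractions = c(subset = 0.5,
                                                 overlap = 0.3,
                                                 disjoint = 0.2),
                                   seed = 1L) {
  stopifnot(all(c("pt_id", "grades") %in% names(model_grading)))
  fractions <- fractions[c("subset", "overlap", "disjoint")]
  if (anyNA(fractions) || any(fractions < 0) || sum(fractions) > 1 + 1e-9) {
    stop("fractions must be named (subset, overlap, disjoint), ",
         "non-negative, and sum to at most 1", call. = FALSE)
  }
  n <- nrow(model_grading)
  raw <- n * fractions
  counts <- floor(raw)
  left <- round(n * sum(fractions)) - sum(counts)
  if (left > 0) {
    add <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[add] <- counts[add] + 1
  }

  withr::local_seed(as.integer(seed))
  ord <- sample.int(n)
  all_grades <- grade_levels()
  model_sets <- model_grading$grades

  # overlap/disjoint need a non-empty complement; serve them first from
  # eligible terms, subset takes anything
  compl_ok <- vapply(model_sets, function(g) {
    length(setdiff(all_grades, g)) > 0
  }, logical(1))
  pool <- ord
  take <- function(k, eligible) {
    hit <- pool[eligible[pool]][seq_len(k)]
    if (anyNA(hit)) {
      stop("cannot allocate requested overlap/disjoint fractions: too few ",
           "terms with fewer than 5 model grades", call. = FALSE)
    }
    pool <<- setdiff(pool, hit)
    hit
  }
  idx_overlap <- take(counts[["overlap"]], compl_ok)
  idx_disjoint <- take(counts[["disjoint"]], compl_ok)
  idx_subset <- pool[seq_len(counts[["subset"]])]

  make_set <- function(i, state) {
    model <- model_sets[[i]]
    compl <- setdiff(all_grades, model)
    switch(state,
      subset = sample(model, sample.int(length(model), 1)),
      overlap = c(sample(model, 1), sample(compl, 1)),
      disjoint = sample(compl, sample.int(min(2, length(compl)), 1))
    )
  }
  picked <- c(idx_subset, idx_overlap, idx_disjoint)
  states <- rep(c("subset", "overlap", "disjoint"),
                times = c(length(idx_subset), length(idx_overlap),
                          length(idx_disjoint)))
  out <- tibble::tibble(
    pt_id = model_grading$pt_id[picked],
    grades = purrr::map2(picked, states, make_set),
    state = states
  )
  out[order(match(out$pt_id, model_grading$pt_id)), ]
}

#' Simulate a drug-to-target map, optionally with a planted association
#'
#' Each drug receives 1..`max_targets_per_drug` targets drawn from a pool.
#' A planted target can be enriched among a chosen set of carrier drugs at
#' a configured odds ratio: non-carriers get the planted target with
#' probability `base_prob`, carriers with the probability whose odds are
#' `or * base_prob / (1 - base_prob)`.
#'
#' @param drug_ids Character vector of drugs to map.
#' @param n_targets Size of the target pool (`T001`...).
#' @param max_targets_per_drug Upper bound on targets per drug; `0` gives an
#'   empty map.
#' @param planted Optional list with elements `target_id`, `carrier_drugs`,
#'   `or` (> 0), `base_prob`.
#' @param seed Integer seed.
#' @return Tibble with columns `drug_id`, `target_id`.
#' @export
simulate_target_map <- function(drug_ids, n_targets = 20,
                                max_targets_per_drug = 3,
                                planted = NULL, seed = 1L) {
  if (max_targets_per_drug == 0 || length(drug_ids) == 0) {
    return(tibble::tibble(drug_id = character(), target_id = character()))
  }
  withr::local_seed(as.integer(seed))
  pool <- sprintf("T%03d", seq_len(n_targets))
  if (!is.null(planted)) {
    if (is.null(planted$or) || planted$or <= 0) {
      stop("planted odds ratio must be > 0", call. = FALSE)
    }
    pool <- setdiff(pool, planted$target_id)
  }
  base <- purrr::map_dfr(drug_ids, function(d) {
    k <- sample.int(max_targets_per_drug, 1)
    tibble::tibble(drug_id = d,
                   target_id = sample(pool, min(k, length(pool))))
  })
  if (!is.null(planted)) {
    p0 <- planted$base_prob %||% 0.2
    odds1 <- planted$or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    carrier <- drug_ids %in% planted$carrier_drugs
    p <- ifelse(carrier, p1, p0)
    has <- stats::runif(length(drug_ids)) < p
    base <- dplyr::bind_rows(base, tibble::tibble(
      drug_id = drug_ids[has], target_id = planted$target_id))
  }
  dplyr::distinct(base)
}
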