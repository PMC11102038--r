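test_that("report counts follow incidence x reporting-rate thinning", {
  base <- function(rate, seed = 7) {
    sim_config(n_drugs = 1, n_adrs = 1, n_patients_per_drug_year = 10000,
               years = 2012L, incidence_matrix = matrix(0.01, 1, 1),
               outcome_profile = c(1, 0, 0, 0, 0),
               reporting_rate_serious = rate, reporting_rate_other = rate,
               excluded_soc_fraction = 0, seed = seed)
  }
  # full reporting: expect ~ Binomial(10000, 0.01) = 100 +/- 3 SD
  full <- simulate_ade_reports(base(1))
  expect_lt(abs(n_reports(full$reports) - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  # 6% reporting thins the count to ~6
  thin <- simulate_ade_reports(base(0.06))
  expect_lt(abs(n_reports(thin$reports) - 6), 3 * sqrt(10000 * 6e-4))
})

test_that("zero incidence produces zero reports and degenerate configs signal emptiness", {
  cfg <- sim_config(n_drugs = 2, n_adrs = 2,
                    incidence_matrix = matrix(0, 2, 2), seed = 3)
  out <- simulate_ade_reports(cfg)
  expect_equal(n_reports(out$reports), 0)
  # ground truth still emitted for every pair
  expect_equal(nrow(out$truth$true_incidence), 4)

  empty_cfg <- sim_config(n_drugs = 0, n_adrs = 0, years = integer(0))
  expect_message(out2 <- simulate_ade_reports(empty_cfg), "degenerate")
  expect_equal(n_reports(out2$reports), 0)
})

test_that("identical seeds reproduce identical outputs, different seeds differ", {
  cfg <- sim_config(n_drugs = 3, n_adrs = 4,
                    n_patients_per_drug_year = 3000, seed = 21)
  a <- simulate_ade_reports(cfg)
  b <- simulate_ade_reports(cfg)
  expect_identical(a$reports, b$reports)
  expect_identical(simulate_prescriptions(cfg), simulate_prescriptions(cfg))

  cfg2 <- sim_config(n_drugs = 3, n_adrs = 4,
                     n_patients_per_drug_year = 3000, seed = 22)
  expect_false(identical(simulate_ade_reports(cfg2)$reports, a$reports))

  # byte-identical CSV on re-run
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_prescriptions_csv(simulate_prescriptions(cfg), f1)
  write_prescriptions_csv(simulate_prescriptions(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reporting thinning converges to the configured rate per severity stratum", {
  cfg <- sim_config(n_drugs = 2, n_adrs = 3,
                    n_patients_per_drug_year = 50000,
                    years = 2012:2015,
                    incidence_matrix = matrix(0.005, 2, 3),
                    outcome_profile = c(0.3, 0.2, 0.2, 0.15, 0.15),
                    seed = 13)
  out <- simulate_ade_reports(cfg)
  adrs <- out$reports$adrs
  serious_reported <- sum(adrs$outcome %in% c("O4", "O5"))
  other_reported <- sum(adrs$outcome %in% c("O1", "O2", "O3"))
  tall <- out$truth$event_tallies
  # expected events by stratum from the profile: 30% serious, 70% other
  total_events <- sum(tall$n_events)
  exp_serious <- total_events * 0.3 * cfg$reporting_rate_serious
  exp_other <- total_events * 0.7 * cfg$reporting_rate_other
  expect_lt(abs(serious_reported - exp_serious), 3 * sqrt(exp_serious))
  expect_lt(abs(other_reported - exp_other), 3 * sqrt(exp_other))
  # ground truth covers every simulated pair (no orphan keys)
  expect_true(all(paste(tall$drug_id, tall$adr_id) %in%
                    paste(out$truth$true_incidence$drug_id,
                          out$truth$true_incidence$adr_id)))
})

test_that("prescription weights sum to the annual volume per drug-year", {
  cfg1 <- sim_config(n_drugs = 1, n_adrs = 1,
                     n_patients_per_drug_year = 12000, years = 2012:2013,
                     name_noise = FALSE, prescription_records_per_year = 1,
                     seed = 2)
  rx <- simulate_prescriptions(cfg1)
  sums <- tapply(rx$person_weight, rx$year, sum)
  expect_equal(as.numeric(sums), c(12000, 12000))

  cfgk <- sim_config(n_drugs = 2, n_adrs = 1,
                     n_patients_per_drug_year = 12000, years = 2012L,
                     prescription_records_per_year = 5, seed = 2)
  rxk <- simulate_prescriptions(cfgk)
  by_drug <- tapply(rxk$person_weight, sub(" .*", "", rxk$raw_name), sum)
  expect_equal(as.numeric(by_drug), c(12000, 12000), tolerance = 1e-9)
})

test_that("expert-grade generator hits exact state fractions and extremes", {
  model <- mk_model_grading(n = 100, seed = 5)
  expert <- simulate_expert_grades(model, seed = 1)
  expect_equal(
    as.integer(table(expert$state)[c("subset", "overlap", "disjoint")]),
    c(50L, 30L, 20L))
  # planted relations are genuine: recheck with consistency_state()
  states <- purrr::map2_chr(
    model$grades[match(expert$pt_id, model$pt_id)], expert$grades,
    consistency_state)
  remap <- c(subset = "consistent", overlap = "partially_consistent",
             disjoint = "inconsistent")
  expect_equal(states, unname(remap[expert$state]))

  all_subset <- simulate_expert_grades(model, c(subset = 1, overlap = 0,
                                                disjoint = 0), seed = 2)
  expect_true(all(all_subset$state == "subset"))
  expect_error(simulate_expert_grades(model, c(subset = 0.9, overlap = 0.3,
                                               disjoint = 0)),
               "sum to at most 1")
})

test_that("target map planting recovers the configured odds ratio", {
  drugs <- sprintf("D%03d", 1:200)
  carriers <- drugs[1:100]

  # null plant: estimate ~ 1
  null_map <- simulate_target_map(drugs, planted = list(
    target_id = "TX", carrier_drugs = carriers, or = 1, base_prob = 0.3),
    seed = 4)
  has <- drugs %in% null_map$drug_id[null_map$target_id == "TX"]
  carr <- drugs %in% carriers
  null_or <- ror(sum(carr & has), sum(carr & !has), sum(!carr & has),
                 sum(!carr & !has))
  expect_true(null_or$ci_low < 1 && null_or$ci_high > 1)

  # OR = 5 plant: drug-level 95% CI covers 5 in >= 90% of 100 seeds
  covered <- vapply(1:100, function(s) {
    m <- simulate_target_map(drugs, planted = list(
      target_id = "TX", carrier_drugs = carriers, or = 5,
      base_prob = 0.2), seed = s)
    has <- drugs %in% m$drug_id[m$target_id == "TX"]
    est <- ror(sum(carr & has), sum(carr & !has), sum(!carr & has),
               sum(!carr & !has))
    est$ci_low <= 5 && est$ci_high >= 5
  }, logical(1))
  expect_gte(mean(covered), 0.9)

  expect_equal(nrow(simulate_target_map(drugs, max_targets_per_drug = 0)), 0)
  expect_error(simulate_target_map(drugs, planted = list(
    target_id = "TX", carrier_drugs = carriers, or = 0)), "must be > 0")
})
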