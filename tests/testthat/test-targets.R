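scored_pairs_fixture <- function() {
  # 3 drugs x 2 ADRs, fully crossed, one fatal-grade ADR
  tidyr::expand_grid(drug_id = c("D1", "D2", "D3"),
                     adr_id = c("A1", "A2")) |>
    dplyr::mutate(severity_grade = ifelse(adr_id == "A2", "death", "mild"),
                  frequency = ifelse(adr_id == "A2", 1e-5, 5e-3))
}

test_that("entries cross drugs with targets and drop singletons in one pass", {
  pairs <- scored_pairs_fixture()
  tm <- tidyr::expand_grid(drug_id = c("D1", "D2", "D3"),
                           target_id = c("T1", "T2"))
  entries <- build_target_entries(pairs, tm)
  expect_equal(nrow(entries), 12)  # 3 drugs x 2 ADRs x 2 targets
  expect_true(all(table(entries$target_id) == 6))

  # an ADR tied to a single target is excluded...
  tm_single <- tibble::tibble(drug_id = c("D1", "D2", "D3"),
                              target_id = "T1")
  expect_equal(nrow(build_target_entries(pairs, tm_single)), 0)

  # ...and exclusion counts come from the pre-exclusion entry set
  pairs3 <- dplyr::bind_rows(
    scored_pairs_fixture(),
    tibble::tibble(drug_id = "D4", adr_id = "A3",
                   severity_grade = "mild", frequency = 1e-4))
  tm3 <- dplyr::bind_rows(tm, tibble::tibble(drug_id = "D4",
                                             target_id = "T3"))
  entries3 <- build_target_entries(pairs3, tm3)
  # A3 has one target (T3) and T3 one ADR -> both singleton, removed
  expect_false(any(entries3$adr_id == "A3"))
  expect_false(any(entries3$target_id == "T3"))
  expect_equal(nrow(entries3), 12)

  expect_equal(nrow(build_target_entries(
    pairs, tibble::tibble(drug_id = character(),
                          target_id = character()))), 0)
})

test_that("target odds ratios match the hand-built contingency and the enumeration oracle", {
  # (a, b, c, d) = (8, 2, 4, 86): OR = 8*86 / (2*4) = 86
  entries <- dplyr::bind_rows(
    tidyr::expand_grid(i = 1:8,
                       tibble::tibble(adr_id = "A", target_id = "T")),
    tidyr::expand_grid(i = 1:2,
                       tibble::tibble(adr_id = "other", target_id = "T")),
    tidyr::expand_grid(i = 1:4,
                       tibble::tibble(adr_id = "A", target_id = "other")),
    tidyr::expand_grid(i = 1:86,
                       tibble::tibble(adr_id = "other", target_id = "other"))
  ) |>
    dplyr::mutate(drug_id = sprintf("D%03d", dplyr::row_number()),
                  grade = "mild", frequency = 1e-4)
  res <- target_or(entries, target_id = "T", adr_id = "A")
  expect_equal(c(res$a, res$b, res$c, res$d), c(8, 2, 4, 86))
  expect_equal(res$or, 86)

  # naive double-loop oracle over the same entries
  a <- sum(entries$adr_id == "A" & entries$target_id == "T")
  b <- sum(entries$adr_id != "A" & entries$target_id == "T")
  cc <- sum(entries$adr_id == "A" & entries$target_id != "T")
  d <- sum(entries$adr_id != "A" & entries$target_id != "T")
  expect_equal(res$or, (a * d) / (b * cc))
  # cell conservation
  expect_equal(res$a + res$b + res$c + res$d, nrow(entries))
})

test_that("independence gives OR near 1 and the null calibration is ~5%", {
  withr::local_seed(33)
  # balanced independent assignment: OR ~ 1
  ent <- tidyr::expand_grid(adr_id = sprintf("A%d", 1:10),
                            target_id = sprintf("T%d", 1:10)) |>
    dplyr::mutate(drug_id = sprintf("D%d", dplyr::row_number()),
                  grade = "mild", frequency = 1e-4)
  res <- target_or(ent, target_id = "T1", adr_id = "A1")
  expect_false(res$significant)

  # two-sided 95% CI excludes 1 in ~5% of independent-null tables
  n_sim <- 1000
  N <- 600
  cells <- stats::rmultinom(n_sim, N, c(0.06, 0.14, 0.24, 0.56))
  res2 <- adrquant:::woolf_or(cells[1, ], cells[2, ], cells[3, ],
                              cells[4, ], alternative = "two.sided")
  sig <- res2$significant
  expect_gt(mean(sig), 0.03)
  expect_lt(mean(sig), 0.07)
})

test_that("zone assignment is total, exclusive and threshold-driven", {
  expect_equal(zone_assign(5, 1e-4), 1L)
  expect_equal(zone_assign(5, 0.01), 2L)
  expect_equal(zone_assign(0.5, 1e-4), 3L)
  expect_equal(zone_assign(0.5, 0.01), 4L)
  # boundary values are "high" (>= threshold)
  expect_equal(zone_assign(2, 1e-3), 2L)
  zones <- zone_assign(c(0.1, 10, 3, 1), c(1e-5, 1e-2, 1e-4, 0.5))
  expect_false(any(is.na(zones)))
  expect_error(zone_assign(1, 1, or_threshold = 0), "positive")
})

test_that("fatal-risk screening ranks enriched targets and handles empty groups", {
  pairs <- scored_pairs_fixture()
  tm <- dplyr::bind_rows(
    tidyr::expand_grid(drug_id = c("D1", "D2", "D3"),
                       target_id = c("T1", "T2")),
    tibble::tibble(drug_id = c("D1", "D2"), target_id = "TRISK"))
  entries <- build_target_entries(pairs, tm)
  risky <- fatal_risk_targets(entries, or_threshold = 0)
  expect_true(all(diff(risky$or) <= 0))
  expect_true(all(c("or", "ci_low", "ci_high", "drugs") %in% names(risky)))

  # no fatal grades -> empty with a notice
  mild_only <- dplyr::mutate(entries, grade = "mild")
  expect_message(out <- fatal_risk_targets(mild_only), "no entries")
  expect_equal(nrow(out), 0)

  # infinite threshold -> empty
  expect_equal(nrow(fatal_risk_targets(entries, or_threshold = Inf)), 0)
})

test_that("a planted fatal-enriched target is recovered by the screen", {
  withr::local_seed(44)
  drugs <- sprintf("D%03d", 1:60)
  # drugs 1..20 carry a fatal ADR; TRISK planted among them at high odds
  pairs <- dplyr::bind_rows(
    tibble::tibble(drug_id = drugs[1:20], adr_id = "FATAL",
                   severity_grade = "death", frequency = 1e-5),
    tibble::tibble(drug_id = drugs, adr_id = "MILD1",
                   severity_grade = "mild", frequency = 1e-3),
    tibble::tibble(drug_id = drugs, adr_id = "MILD2",
                   severity_grade = "moderate", frequency = 1e-3))
  tm <- simulate_target_map(drugs, n_targets = 10,
                            max_targets_per_drug = 2,
                            planted = list(target_id = "TRISK",
                                           carrier_drugs = drugs[1:20],
                                           or = 25, base_prob = 0.1),
                            seed = 7)
  entries <- build_target_entries(pairs, tm)
  risky <- fatal_risk_targets(entries, or_threshold = 2)
  expect_true("TRISK" %in% risky$target_id)
})
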