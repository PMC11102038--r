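test_that("qualification drops unreliable and unrelated reports", {
  x <- qualification_fixture()
  q <- qualify_reports(x)
  expect_setequal(q$reports$report_id, c("q01", "q02", "q03", "q04"))
  att <- attr(q, "attrition")
  expect_equal(att$removed[att$rule == "nonprofessional_reporter"], 3L)
  expect_equal(att$removed[att$rule == "no_adr_outside_excluded_socs"], 2L)
  expect_equal(att$removed[att$rule == "multi_ingredient_or_biologic_drug"],
               1L)
})

test_that("qualification is the identity on clean input, empty on empty, idempotent", {
  clean <- bind_reports(mk_report("a", "aspirin", "Headache"),
                        mk_report("b", "ibuprofen", "Nausea"))
  q <- qualify_reports(clean)
  expect_equal(q$reports, clean$reports)
  expect_equal(q$adrs, clean$adrs)

  expect_equal(n_reports(qualify_reports(empty_ade_reports())), 0)

  x <- qualification_fixture()
  once <- qualify_reports(x)
  twice <- qualify_reports(once)
  expect_equal(twice$reports, once$reports)
  expect_equal(twice$adrs, once$adrs)
})

test_that("a report is kept when at least one ADR survives SOC exclusion", {
  x <- bind_reports(mk_report("m1", "aspirin", c("Headache", "Device leak"),
                              soc = c("nervous system disorders",
                                      "product issues")))
  q <- qualify_reports(x)
  expect_equal(n_reports(q), 1)
  expect_equal(q$adrs$raw_term, "Headache")

  # unknown (missing) SOC labels warn but the mention is retained
  y <- bind_reports(mk_report("m2", "aspirin", "Headache", soc = NA))
  expect_warning(qy <- qualify_reports(y), "unknown SOC")
  expect_equal(nrow(qy$adrs), 1)
})

test_that("drug resolution follows the product-code, exact, cleaned-name route order", {
  dict <- toy_dictionary()
  x <- bind_reports(
    mk_report("n1", "Aspirin 81 mg tablets", "Headache"),   # route 3
    mk_report("n2", "ACETYLSALICYLIC ACID", "Headache"),    # route 2
    mk_report("n3", "mystery compound", "Headache"),        # unresolved
    mk_report("n4", "not the name", "Headache")             # route 1
  )
  x$drugs$product_code[x$drugs$report_id == "n4"] <- "NDC-2"
  nx <- normalize_drugs(x, dict)
  got <- nx$drugs[match(c("n1", "n2", "n3", "n4"), nx$drugs$report_id), ]
  expect_equal(got$drug_id, c("DB1", "DB1", NA, "DB2"))
  expect_equal(got$resolution_route,
               c("cleaned", "exact", NA, "product_code"))
  expect_equal(got$unresolved_reason[3], "no_match")
  # unresolved mention retained for audit, not dropped
  expect_true("n3" %in% nx$reports$report_id)
})

test_that("ambiguous cleaned-name matches are flagged, and normalization is stable", {
  dict <- drug_dictionary(synonyms = tibble::tibble(
    drug_id = c("DB1", "DB2"), synonym = c("combi", "combi")))
  x <- bind_reports(mk_report("a1", "Combi 500 mg", "Headache"))
  nx <- normalize_drugs(x, dict)
  expect_true(is.na(nx$drugs$drug_id))
  expect_equal(nx$drugs$unresolved_reason, "ambiguous_cleaned_match")

  # re-application does not change anything
  x2 <- normalize_drugs(normalize_drugs(qualification_fixture(),
                                        toy_dictionary()),
                        toy_dictionary())
  x3 <- normalize_drugs(qualification_fixture(), toy_dictionary())
  expect_equal(x2$drugs$drug_id, x3$drugs$drug_id)
})

test_that("ADR terms resolve case-insensitively through synonyms", {
  x <- bind_reports(
    mk_report("t1", "aspirin", "Head ache"),
    mk_report("t2", "aspirin", "HEADACHE"),
    mk_report("t3", "aspirin", "imaginary syndrome"))
  nx <- normalize_adrs(x, toy_ontology())
  expect_equal(nx$adrs$pt_id, c("PT1", "PT1", NA))
  expect_equal(nx$adrs$unresolved_reason[3], "no_match")
})

test_that("pair table reproduces the hand-counted contingency example", {
  x <- bind_reports(
    mk_report("p1", "aspirin", "Headache"),
    mk_report("p2", "aspirin", "Headache"),
    mk_report("p3", "aspirin", "Nausea"),
    mk_report("p4", "ibuprofen", "Headache"))
  x <- normalize_adrs(normalize_drugs(x, toy_dictionary()), toy_ontology())
  pt <- build_pair_table(x)
  d1a1 <- pt[pt$drug_id == "DB1" & pt$adr_id == "PT1", ]
  expect_equal(c(d1a1$a, d1a1$b, d1a1$c, d1a1$d), c(2, 1, 1, 0))

  # a single-report collection gives a=1, b=c=d=0
  solo <- normalize_adrs(normalize_drugs(
    bind_reports(mk_report("s", "aspirin", "Headache")),
    toy_dictionary()), toy_ontology())
  spt <- build_pair_table(solo)
  expect_equal(c(spt$a, spt$b, spt$c, spt$d), c(1, 0, 0, 0))
})

test_that("a multi-ADR report contributes to each of its pairs once", {
  x <- bind_reports(
    mk_report("m", "aspirin", c("Headache", "Nausea"),
              outcome = c("O1", "O5"),
              soc = c("nervous system disorders",
                      "gastrointestinal disorders")))
  x <- normalize_adrs(normalize_drugs(x, toy_dictionary()), toy_ontology())
  pt <- build_pair_table(x)
  expect_equal(nrow(pt), 2)
  expect_equal(pt$a, c(1, 1))
  # outcome tallies follow the per-ADR codes
  expect_equal(pt$o1[pt$adr_id == "PT1"], 1)
  expect_equal(pt$o5[pt$adr_id == "PT2"], 1)
})

test_that("contingency cells match the naive enumeration oracle and conserve totals", {
  x <- random_fixture(n = 60, seed = 11)
  x <- normalize_adrs(normalize_drugs(x, toy_dictionary()), toy_ontology())
  pt <- build_pair_table(x)
  oracle <- naive_pair_oracle(x)
  expect_equal(pt[c("drug_id", "adr_id", "a", "b", "c", "d")],
               oracle, ignore_attr = TRUE)
  expect_true(all(pt$a + pt$b + pt$c + pt$d == n_reports(x)))
  # missing outcomes count in a but not in the outcome tallies
  expect_true(all(pt$o1 + pt$o2 + pt$o3 + pt$o4 + pt$o5 <= pt$n_reports))
})

test_that("support filtering uses pre-filter totals with inclusive thresholds", {
  # drug DB1 in 30 reports, DB2 in 20; threshold 26 removes all DB2 pairs
  parts <- c(
    lapply(1:30, function(i) mk_report(sprintf("a%02d", i), "aspirin",
                                       "Headache")),
    lapply(1:20, function(i) mk_report(sprintf("b%02d", i), "ibuprofen",
                                       "Nausea")))
  x <- do.call(bind_reports, parts)
  x <- normalize_adrs(normalize_drugs(x, toy_dictionary()), toy_ontology())
  pt <- build_pair_table(x)
  kept <- filter_by_support(pt, qualification_rules())
  expect_equal(unique(kept$drug_id), "DB1")
  expect_equal(attr(kept, "attrition")$removed, 1L)

  # zero thresholds are the identity
  all_kept <- filter_by_support(pt, qualification_rules(
    min_adr_reports = 0, min_drug_reports = 0, min_pair_reports = 0))
  expect_equal(nrow(all_kept), nrow(pt))

  # a pair with exactly 2 reports at threshold 2 is retained
  two <- do.call(bind_reports, lapply(1:2, function(i) {
    mk_report(sprintf("t%d", i), "aspirin", "Headache")
  }))
  two <- normalize_adrs(normalize_drugs(two, toy_dictionary()),
                        toy_ontology())
  pt2 <- build_pair_table(two)
  kept2 <- filter_by_support(pt2, qualification_rules(min_drug_reports = 2))
  expect_equal(kept2$n_reports, 2L)
})
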