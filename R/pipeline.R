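#' Pipeline configuration
#'
#' Bundles every stage's parameters. The stage order is fixed by the
#' model's dependencies: severity grading must precede frequency
#' estimation because the underreporting rate is keyed to the assigned
#' grade.
#'
#' @param sim A [sim_config()] describing the simulated inputs.
#' @param rules A [qualification_rules()] object.
#' @param severity A [severity_params()] object.
#' @param scope Outcome-conditioning scope (see [outcome_distribution()]).
#' @param yr Estimation-window length in years for frequency.
#' @param urr_serious,urr_other Underreporting rates by grade group.
#' @param or_threshold,freq_threshold Mechanism-zone thresholds (see
#'   [zone_assign()]).
#' @param fatal_or_threshold Fatal-risk screen threshold.
#' @param expert_fractions Named fractions for the simulated expert table
#'   (see [simulate_expert_grades()]); `NULL` skips the evaluation stage.
#' @param target_map_spec List of arguments for [simulate_target_map()]
#'   (`n_targets`, `max_targets_per_drug`, optional `planted`); `NULL`
#'   skips the association stage.
#' @param out_dir Output directory for artifacts; `NULL` writes nothing.
#' @param seed Pipeline seed; overrides `sim$seed` and seeds the expert
#'   and target generators.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            rules = qualification_rules(),
                            severity = severity_params(),
                            scope = "per_pair",
                            yr = 8,
                            urr_serious = 0.77,
                            urr_other = 0.94,
                            or_threshold = 2,
                            freq_threshold = 1e-3,
                            fatal_or_threshold = 2,
                            expert_fractions = c(subset = 0.5,
                                                 overlap = 0.3,
                                                 disjoint = 0.2),
                            target_map_spec = list(n_targets = 20,
                                                   max_targets_per_drug = 3),
                            out_dir = NULL,
                            seed = NULL) {
  stopifnot(inherits(sim, "sim_config"),
            inherits(rules, "qualification_rules"),
            inherits(severity, "severity_params"))
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, rules = rules, severity = severity,
                 scope = scope, yr = yr,
                 urr_serious = urr_serious, urr_other = urr_other,
                 or_threshold = or_threshold,
                 freq_threshold = freq_threshold,
                 fatal_or_threshold = fatal_or_threshold,
                 expert_fractions = expert_fractions,
                 target_map_spec = target_map_spec,
                 out_dir = out_dir, seed = sim$seed),
            class = "pipeline_config")
}

pipeline_error <- function(stage, parent) {
  stop(rlang::error_cnd(class = "adrquant_pipeline_error",
                        stage = stage,
                        message = sprintf("pipeline stage '%s' failed: %s",
                                          stage,
                                          conditionMessage(parent))))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) pipeline_error(stage, e))
}

#' Run the full characterization pipeline
#'
#' Executes simulate -> qualify -> normalize -> pair counting -> support
#' filter -> disproportionality -> severity grading -> frequency ->
#' evaluation -> target association on a simulated scenario, collecting
#' per-stage attrition in a run manifest. Re-running with the same config
#' reproduces identical outputs. When `config$out_dir` is set, artifacts
#' are written there: `pair_table.tsv`, `grade_boundaries.json`,
#' `aap.tsv`, `evaluation.json`, `target_entries.tsv`,
#' `fatal_risk_targets.json`, `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a result bundle: `pairs` (fully annotated pair
#'   table), `boundaries`, `aap`, `evaluation` (or `NULL` when skipped),
#'   `entries`, `fatal_targets`, `truth`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package = "adrquant",
                   version = as.character(utils::packageVersion("adrquant")),
                   schema_version = adrquant_schema_version,
                   seed = config$seed,
                   config_hash = rlang::hash(unclass(config)),
                   stages = list())
  tally <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  sim <- run_stage("simulate", {
    out <- simulate_ade_reports(config$sim)
    out$prescriptions <- simulate_prescriptions(config$sim)
    out
  })
  tally("simulate", n_reports = n_reports(sim$reports),
        n_prescription_records = nrow(sim$prescriptions))

  qualified <- run_stage("qualify", qualify_reports(sim$reports,
                                                    config$rules))
  tally("qualify", n_in = n_reports(sim$reports),
        n_out = n_reports(qualified),
        attrition = attr(qualified, "attrition"))

  qualified <- run_stage("normalize", {
    x <- normalize_drugs(qualified, sim$dictionary)
    normalize_adrs(x, sim$ontology)
  })

  pairs <- run_stage("pair_table", build_pair_table(qualified))
  tally("pair_table", n_pairs = nrow(pairs))

  supported <- run_stage("support_filter",
                         filter_by_support(pairs, config$rules))
  tally("support_filter", n_in = nrow(pairs), n_out = nrow(supported),
        attrition = attr(supported, "attrition"))

  significant <- run_stage("disproportionality", {
    significance_filter(add_ror(supported))
  })
  tally("disproportionality", n_in = nrow(supported),
        n_out = nrow(significant),
        attrition = attr(significant, "attrition"))
  if (nrow(significant) == 0) {
    pipeline_error("disproportionality",
                   simpleError("no pairs survive the significance filter"))
  }

  scored <- run_stage("severity", {
    suppressMessages(score_pairs(significant, config$severity,
                                 config$scope))
  })
  boundaries <- grade_boundaries(config$severity)
  tally("severity", n_scored = sum(!is.na(scored$severity_score)),
        n_unscorable = sum(is.na(scored$severity_score)))

  aap <- run_stage("frequency", {
    direct <- compute_aap(sim$prescriptions, sim$dictionary,
                          period = config$sim$years)
    infer_aap_by_atc(direct, sim$dictionary)
  })
  scored <- run_stage("frequency",
                      add_frequency(scored, aap, yr = config$yr,
                                    urr_serious = config$urr_serious,
                                    urr_other = config$urr_other))
  tally("frequency",
        n_direct = sum(aap$source == "direct"),
        n_atc_inferred = sum(aap$source == "atc_inferred"),
        n_unavailable = sum(aap$source == "unavailable"),
        n_pairs_without_frequency = sum(is.na(scored$frequency)))

  evaluation <- NULL
  if (!is.null(config$expert_fractions)) {
    evaluation <- run_stage("evaluate", {
      model <- model_grade_sets(scored)
      expert <- simulate_expert_grades(model, config$expert_fractions,
                                       seed = config$seed + 2L)
      evaluate_grades(model, expert[c("pt_id", "grades")])
    })
    tally("evaluate", n_mutual = evaluation$n_mutual,
          summary = evaluation$summary)
  } else {
    tally("evaluate", skipped = "no expert table configured")
    message("evaluation stage skipped: no expert table configured")
  }

  entries <- NULL
  fatal_targets <- NULL
  if (!is.null(config$target_map_spec)) {
    assoc <- run_stage("associate", {
      tm <- simulate_target_map(
        drug_ids = unique(scored$drug_id),
        n_targets = config$target_map_spec$n_targets %||% 20,
        max_targets_per_drug =
          config$target_map_spec$max_targets_per_drug %||% 3,
        planted = config$target_map_spec$planted,
        seed = config$seed + 3L)
      entries <- build_target_entries(scored, tm)
      fatal <- withCallingHandlers(
        fatal_risk_targets(entries, config$fatal_or_threshold),
        message = function(m) invokeRestart("muffleMessage"))
      list(entries = entries, fatal = fatal)
    })
    entries <- assoc$entries
    fatal_targets <- assoc$fatal
    tally("associate", n_entries = nrow(entries),
          n_fatal_risk_targets = nrow(fatal_targets))
  } else {
    tally("associate", skipped = "no target map configured")
  }

  bundle <- list(pairs = scored, boundaries = boundaries, aap = aap,
                 evaluation = evaluation, entries = entries,
                 fatal_targets = fatal_targets, truth = sim$truth,
                 manifest = manifest)
  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(bundle, config$out_dir)
  }
  invisible(bundle)
}

write_pipeline_artifacts <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(bundle$pairs, p("pair_table.tsv"))
  jsonlite::write_json(
    list(schema_version = adrquant_schema_version,
         grades = bundle$boundaries$grades,
         edges = bundle$boundaries$edges),
    p("grade_boundaries.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(bundle$aap, p("aap.tsv"))
  if (!is.null(bundle$evaluation)) {
    jsonlite::write_json(
      list(schema_version = adrquant_schema_version,
           n_mutual = bundle$evaluation$n_mutual,
           summary = bundle$evaluation$summary),
      p("evaluation.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$entries)) {
    readr::write_tsv(bundle$entries, p("target_entries.tsv"))
    ft <- bundle$fatal_targets
    jsonlite::write_json(
      list(schema_version = adrquant_schema_version,
           targets = ft),
      p("fatal_risk_targets.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML document onto [pipeline_config()]: top-level keys `seed`,
#' `out_dir`, `scope`, `yr`, `urr_serious`, `urr_other`, `or_threshold`,
#' `freq_threshold`, `fatal_or_threshold`, plus nested blocks `sim`
#' (fields of [sim_config()]), `rules` (fields of
#' [qualification_rules()]), `severity` (`penalty`, `weight`),
#' `expert_fractions` and `target_map` (`n_targets`,
#' `max_targets_per_drug`). Omitted keys take the package defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's seed.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  rules <- do.call(qualification_rules, y$rules %||% list())
  sev <- do.call(severity_params, y$severity %||% list())
  ef <- y$expert_fractions
  if (!is.null(ef)) ef <- unlist(ef)
  pipeline_config(
    sim = sim, rules = rules, severity = sev,
    scope = y$scope %||% "per_pair",
    yr = y$yr %||% 8,
    urr_serious = y$urr_serious %||% 0.77,
    urr_other = y$urr_other %||% 0.94,
    or_threshold = y$or_threshold %||% 2,
    freq_threshold = y$freq_threshold %||% 1e-3,
    fatal_or_threshold = y$fatal_or_threshold %||% 2,
    expert_fractions = if (is.null(y$expert_fractions) &&
                             !isTRUE(y$skip_evaluation)) {
      c(subset = 0.5, overlap = 0.3, disjoint = 0.2)
    } else if (isTRUE(y$skip_evaluation)) NULL else ef,
    target_map_spec = if (isTRUE(y$skip_association)) NULL else
      (y$target_map %||% list(n_targets = 20, max_targets_per_drug = 3)),
    out_dir = y$out_dir,
    seed = seed %||% y$seed
  )
}
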