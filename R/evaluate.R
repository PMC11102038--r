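#' Preferred terms shared by two grade tables
#'
#' The evaluation is restricted to the mutual preferred terms present in
#' both the model grading and the expert table; unmatched counts on both
#' sides are attached as attributes `n_model_only` / `n_expert_only`.
#'
#' @param model_grading,expert_table Tibbles keyed by `pt_id`.
#' @return Character vector of shared PT ids.
#' @export
mutual_terms <- function(model_grading, expert_table) {
  shared <- intersect(model_grading$pt_id, expert_table$pt_id)
  structure(shared,
            n_model_only = length(setdiff(model_grading$pt_id, shared)),
            n_expert_only = length(setdiff(expert_table$pt_id, shared)))
}

#' Consistency state of a model grade set against an expert grade set
#'
#' Because an ADR may carry different grades under different drug
#' therapies, both systems assign grade *sets* per preferred term. The
#' comparison is a trichotomy: `consistent` when the expert grades are
#' fully matched or covered by the model grades (expert subset of model),
#' `partially_consistent` when the sets overlap without coverage, and
#' `inconsistent` when they are mutually exclusive.
#'
#' @param model_grades,expert_grades Non-empty character vectors of grade
#'   labels from [grade_levels()].
#' @return One of `"consistent"`, `"partially_consistent"`,
#'   `"inconsistent"`.
#' @export
consistency_state <- function(model_grades, expert_grades) {
  if (length(model_grades) == 0 || length(expert_grades) == 0) {
    stop("grade sets must be non-empty", call. = FALSE)
  }
  bad <- setdiff(c(model_grades, expert_grades), grade_levels())
  if (length(bad) > 0) {
    stop("unknown grade label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (all(expert_grades %in% model_grades)) return("consistent")
  if (length(intersect(model_grades, expert_grades)) > 0) {
    return("partially_consistent")
  }
  "inconsistent"
}

#' Model grade sets per preferred term
#'
#' The model's grade set for a PT is the union of severity grades over all
#' its retained (scored) drug-ADR pairs.
#'
#' @param pairs A scored pair table with `adr_id` and `severity_grade`.
#' @return Tibble with columns `pt_id`, `grades` (list-column).
#' @export
model_grade_sets <- function(pairs) {
  stopifnot(all(c("adr_id", "severity_grade") %in% names(pairs)))
  pairs |>
    dplyr::filter(!is.na(.data$severity_grade)) |>
    dplyr::group_by(pt_id = .data$adr_id) |>
    dplyr::summarise(grades = list(unique(.data$severity_grade)),
                     .groups = "drop")
}

#' Evaluate a model grading against an expert grade table
#'
#' Classifies every mutual preferred term into the consistency trichotomy
#' and summarizes counts and percentages (2 decimal places). Strict set
#' equality is additionally reported (`identical` column) for transparency:
#' a `consistent` term may cover the expert grades with extra model grades.
#'
#' @param model_grading Tibble with `pt_id`, `grades` (list-column), e.g.
#'   from [model_grade_sets()].
#' @param expert_table Tibble with `pt_id`, `grades` (list-column).
#' @return List with `summary` (state, n, pct), `detail` (per-PT tibble)
#'   and `n_mutual`, `n_model_only`, `n_expert_only`.
#' @export
evaluate_grades <- function(model_grading, expert_table) {
  shared <- mutual_terms(model_grading, expert_table)
  states <- c("consistent", "partially_consistent", "inconsistent")
  if (length(shared) == 0) {
    message("no mutual preferred terms; empty evaluation")
    return(list(
      summary = tibble::tibble(state = states, n = 0L, pct = NA_real_),
      detail = tibble::tibble(pt_id = character(), model_grades = list(),
                              expert_grades = list(), state = character(),
                              identical = logical()),
      n_mutual = 0L,
      n_model_only = attr(shared, "n_model_only"),
      n_expert_only = attr(shared, "n_expert_only")))
  }
  mg <- model_grading$grades[match(shared, model_grading$pt_id)]
  eg <- expert_table$grades[match(shared, expert_table$pt_id)]
  detail <- tibble::tibble(
    pt_id = as.character(shared),
    model_grades = mg,
    expert_grades = eg,
    state = purrr::map2_chr(mg, eg, consistency_state),
    identical = purrr::map2_lgl(mg, eg, ~ setequal(.x, .y))
  )
  counts <- table(factor(detail$state, levels = states))
  summary <- tibble::tibble(
    state = states,
    n = as.integer(counts),
    pct = round(100 * as.integer(counts) / length(shared), 2)
  )
  list(summary = summary, detail = detail, n_mutual = length(shared),
       n_model_only = attr(shared, "n_model_only"),
       n_expert_only = attr(shared, "n_expert_only"))
}
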