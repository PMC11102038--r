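#' Severity model parameters
#'
#' The penalized model scores treatment outcomes in a reciprocal manner:
#' the mildest end point ("recovered") receives the largest penalty and the
#' fatal end point the smallest, `Penalty = (5, 4, 3, 2, 1)` for O1..O5,
#' while an emphasis weight `w = (1, 2, 3, 4, 5)` amplifies severe
#' outcomes. The per-outcome base score is
#' `w_k / log2(penalty_k + 1)`, which with the defaults equals
#' `1/log2 6, 2/log2 5, 3/log2 4, 4/log2 3, 5/log2 2` - strictly
#' increasing, the property the grade boundaries rely on.
#'
#' @param penalty,weight Strictly positive numeric vectors of length 5
#'   (indexed by outcome O1..O5).
#' @return An object of class `severity_params`.
#' @export
severity_params <- function(penalty = c(5, 4, 3, 2, 1), weight = 1:5) {
  stopifnot(length(penalty) == 5, length(weight) == 5)
  if (any(penalty <= 0) || any(weight <= 0)) {
    stop("penalty and weight must be strictly positive", call. = FALSE)
  }
  structure(list(penalty = as.numeric(penalty),
                 weight = as.numeric(weight)),
            class = "severity_params")
}

# per-outcome base scores (the sigma-free pure-outcome scores)
base_scores <- function(params) {
  params$weight / log2(params$penalty + 1)
}

#' Sigmoid association-strength factor
#'
#' Maps the reporting odds ratio onto `(0.5, 1)` via
#' `sigma = 1 / (1 + exp(-log2(ROR)))`: exactly 0.5 at `ROR = 1` and
#' approaching 1 as `ROR -> Inf`. Upstream significance filtering
#' guarantees `ROR > 1`, so the factor in practice modulates the severity
#' score between half and the full outcome base score.
#'
#' @param ror Positive reporting odds ratio (vectorized).
#' @return Numeric vector of association factors.
#' @examples
#' association_factor(c(1, 2, 1e6))
#' @export
association_factor <- function(ror) {
  if (any(!is.na(ror) & ror <= 0)) {
    stop("association_factor() is defined for positive odds ratios only",
         call. = FALSE)
  }
  1 / (1 + exp(-log2(ror)))
}

#' Outcome distributions for scoring
#'
#' Converts the per-pair outcome tallies `o1`..`o5` into conditional
#' outcome probabilities. With `scope = "per_pair"` each pair is normalized
#' over its own outcome-bearing reports; with `scope = "per_adr"` the
#' tallies are pooled over all drugs sharing the ADR before normalizing, so
#' every pair of an ADR shares one distribution. Pairs with zero
#' outcome-bearing reports get `NA` probabilities and are excluded from
#' scoring with reason `"no_outcome_reports"`.
#'
#' @param pairs A pair table with columns `o1`..`o5` (and `adr_id` for the
#'   pooled scope).
#' @param scope `"per_pair"` (default) or `"per_adr"`.
#' @return `pairs` with probability columns `p1`..`p5` and `n_outcomes`
#'   added.
#' @export
outcome_distribution <- function(pairs, scope = c("per_pair", "per_adr")) {
  scope <- match.arg(scope)
  ocols <- paste0("o", 1:5)
  stopifnot(all(ocols %in% names(pairs)))
  counts <- as.matrix(pairs[ocols])
  if (scope == "per_adr") {
    stopifnot("adr_id" %in% names(pairs))
    pooled <- rowsum(counts, pairs$adr_id)
    counts <- pooled[match(pairs$adr_id, rownames(pooled)), , drop = FALSE]
  }
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, NA_real_)
  colnames(p) <- paste0("p", 1:5)
  dplyr::bind_cols(pairs, tibble::as_tibble(p),
                   tibble::tibble(n_outcomes = as.integer(tot)))
}

#' Penalized outcome-weighted severity score
#'
#' `score = sigma * sum_k(weight_k * p_k / log2(penalty_k + 1))`, where
#' `p` is the conditional outcome distribution and `sigma` the sigmoid
#' association factor. With default parameters the score lies in
#' `[0, 5]`; the pure-outcome extremes at `sigma = 1` are the grade
#' boundaries.
#'
#' @param p Probability 5-vector, or an `n x 5` matrix of distributions
#'   (rows may be `NA` for unscorable pairs).
#' @param sigma Association factor(s), recycled against the rows of `p`.
#' @param params A [severity_params()] object.
#' @return Numeric score vector.
#' @examples
#' severity_score(c(0, 0, 0, 0, 1), sigma = 1)  # 5, the maximum
#' @export
severity_score <- function(p, sigma = 1, params = severity_params()) {
  stopifnot(inherits(params, "severity_params"))
  if (is.null(dim(p))) {
    if (length(p) != 5) stop("p must have 5 outcome probabilities",
                             call. = FALSE)
    p <- matrix(p, nrow = 1)
  }
  if (ncol(p) != 5) stop("p must have 5 columns", call. = FALSE)
  bad <- rowSums(is.na(p)) == 0 &
    (abs(rowSums(p) - 1) > 1e-6 | apply(p < 0, 1, any))
  if (any(bad)) {
    stop("each outcome distribution must be non-negative and sum to 1",
         call. = FALSE)
  }
  as.numeric(sigma * (p %*% base_scores(params)))
}

#' Theoretical grade boundaries from pure-outcome extremes
#'
#' The five severity grades partition the score axis at the scores of the
#' extreme cases in which a single treatment outcome occurs
#' (`P(O_k) = 1`) with the association factor at its supremum 1:
#' `edges = (0, w_1/log2(p_1+1), ..., w_5/log2(p_5+1))`. With default
#' parameters (to 3 decimals): 0, 0.387, 0.861, 1.500, 2.524, 5.000.
#' Parameter sets whose pure-outcome scores are not strictly increasing in
#' outcome order are rejected - the grades would be ill-ordered.
#'
#' @param params A [severity_params()] object.
#' @return An object of class `grade_boundaries`: list with `edges`
#'   (6 ascending reals) and `grades` (the 5 labels).
#' @export
grade_boundaries <- function(params = severity_params()) {
  base <- base_scores(params)
  if (any(diff(base) <= 0)) {
    stop("pure-outcome scores must increase strictly with outcome ",
         "severity; adjust penalty/weight", call. = FALSE)
  }
  structure(list(edges = c(0, base), grades = grade_levels()),
            class = "grade_boundaries")
}

#' @export
print.grade_boundaries <- function(x, ...) {
  cat("<grade_boundaries>\n")
  for (g in seq_along(x$grades)) {
    cat(sprintf("  %-16s (%.3f, %.3f]\n", x$grades[g], x$edges[g],
                x$edges[g + 1]))
  }
  invisible(x)
}

#' Assign a severity grade to a score
#'
#' Grade intervals are lower-open/upper-closed, so each pure-outcome
#' extreme score lands in its own grade; a score of 0 is mild. Scores and
#' edges are compared at 3-decimal resolution (`digits = 3`), matching the
#' printed precision of the boundary table, so e.g. 0.387 grades as mild.
#'
#' @param score Numeric score(s) in `[0, max edge]`; `NA` passes through.
#' @param boundaries A [grade_boundaries()] object.
#' @param digits Decimal resolution at which scores and edges are compared.
#' @return Character vector of grade labels.
#' @export
assign_grade <- function(score, boundaries = grade_boundaries(),
                         digits = 3) {
  stopifnot(inherits(boundaries, "grade_boundaries"))
  edges <- round(boundaries$edges, digits)
  s <- round(score, digits)
  out_of_range <- !is.na(s) & (s < edges[1] | s > edges[6])
  if (any(out_of_range)) {
    stop("score outside [", edges[1], ", ", edges[6], "]", call. = FALSE)
  }
  idx <- findInterval(s, edges, left.open = TRUE)
  idx <- pmax(idx, 1L)  # score 0 -> mild
  out <- boundaries$grades[idx]
  out[is.na(s)] <- NA_character_
  out
}

#' Score and grade a pair table
#'
#' Convenience wrapper chaining [outcome_distribution()],
#' [association_factor()] on the pair RORs, [severity_score()] and
#' [assign_grade()]. Pairs without outcome-bearing reports are retained
#' with `NA` score/grade and `excluded_reason = "no_outcome_reports"`.
#'
#' @param pairs A pair table with `o1`..`o5` and `ror` columns.
#' @param params A [severity_params()] object.
#' @param scope Outcome-conditioning scope, see [outcome_distribution()].
#' @return `pairs` with columns `p1`..`p5`, `n_outcomes`, `sigma`,
#'   `severity_score`, `severity_grade`, `excluded_reason` added.
#' @export
score_pairs <- function(pairs, params = severity_params(),
                        scope = c("per_pair", "per_adr")) {
  stopifnot("ror" %in% names(pairs))
  scored <- outcome_distribution(pairs, scope)
  scored$sigma <- association_factor(scored$ror)
  p <- as.matrix(scored[paste0("p", 1:5)])
  scored$severity_score <- severity_score(p, scored$sigma, params)
  scored$severity_grade <- assign_grade(scored$severity_score,
                                        grade_boundaries(params))
  scored$excluded_reason <- ifelse(scored$n_outcomes == 0,
                                   "no_outcome_reports", NA_character_)
  n_excl <- sum(scored$n_outcomes == 0)
  if (n_excl > 0) {
    message(n_excl, " pair(s) lack outcome-bearing reports and were not scored")
  }
  scored
}
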