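# Woolf log-normal machinery shared by the ROR and the target-OR screens.
woolf_or <- function(a, b, c, d, conf_level = 0.95, zero_correction = TRUE,
                     alternative = c("greater", "two.sided"),
                     alpha = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(all(c(a, b, c, d) >= 0))
  any_zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_correction) {
    # Haldane-Anscombe: add 0.5 to every cell of tables with a zero cell
    corr <- ifelse(any_zero, 0.5, 0)
    a <- a + corr; b <- b + corr; c <- c + corr; d <- d + corr
  }
  undef <- b * c == 0
  or <- ifelse(undef, NA_real_, (a * d) / (b * c))
  if (any(undef)) {
    warning("odds ratio undefined for ", sum(undef),
            " table(s) with an empty margin (zero correction off)",
            call. = FALSE)
  }
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  log_or <- log(or)
  ci_low <- exp(log_or - z * se)
  ci_high <- exp(log_or + z * se)
  significant <- if (alternative == "greater") {
    # one-sided test of H1: OR > 1 at level alpha
    !is.na(or) & or > 1 & log_or / se > stats::qnorm(1 - alpha)
  } else {
    # two-sided: the conf_level CI excludes 1
    !is.na(or) & (ci_low > 1 | ci_high < 1)
  }
  tibble::tibble(or = or, ci_low = ci_low, ci_high = ci_high,
                 significant = significant)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' For a report-level 2x2 contingency table `(a, b, c, d)` the reporting
#' odds ratio is `ROR = (a * d) / (b * c)`, with the log-scale normal
#' (Woolf) interval `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' With `zero_correction` on (the default), 0.5 is added to every cell of a
#' table containing a zero. An ROR above 1 flags the drug as a risk factor
#' for the ADR; the significance flag tests the one-sided hypothesis
#' `ROR > 1` at `P < alpha` (equivalently, the lower bound of the
#' `1 - 2*alpha` interval exceeds 1), while `ci_low`/`ci_high` report the
#' `conf_level` interval.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized): `a` drug
#'   with ADR, `b` drug without ADR, `c` ADR without drug, `d` neither.
#' @param zero_correction Add 0.5 to all cells of tables with a zero cell?
#'   With the correction off, tables with `b * c = 0` return `NA` with a
#'   warning rather than an infinite estimate.
#' @param conf_level Confidence level of the reported interval.
#' @param alpha One-sided significance level of the filter.
#' @return Tibble with columns `ror`, `ci_low`, `ci_high`, `significant`.
#' @examples
#' ror(10, 20, 30, 240)   # point estimate 4.0
#' @export
ror <- function(a, b, c, d, zero_correction = TRUE, conf_level = 0.95,
                alpha = 0.05) {
  res <- woolf_or(a, b, c, d, conf_level = conf_level,
                  zero_correction = zero_correction,
                  alternative = "greater", alpha = alpha)
  dplyr::rename(res, ror = "or")
}

#' @rdname ror
#' @param pairs A pair table with contingency columns `a`, `b`, `c`, `d`.
#' @param ... Passed to [ror()].
#' @export
add_ror <- function(pairs, ...) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(pairs)))
  dplyr::bind_cols(pairs, ror(pairs$a, pairs$b, pairs$c, pairs$d, ...))
}

#' Keep only significantly disproportional pairs
#'
#' Retains pairs flagged significant by [ror()] (one-sided `ROR > 1` at
#' `P < .05`). The attrition count is attached as the `attrition`
#' attribute.
#'
#' @param pairs A pair table carrying a `significant` column (see
#'   [add_ror()]).
#' @return The retained pairs.
#' @export
significance_filter <- function(pairs) {
  stopifnot("significant" %in% names(pairs))
  keep <- pairs$significant %in% TRUE
  out <- pairs[keep, , drop = FALSE]
  attr(out, "attrition") <- tibble::tibble(
    rule = "not_significant", removed = as.integer(sum(!keep)))
  out
}
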