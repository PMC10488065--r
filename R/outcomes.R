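#' Normality-gated choice of two-sample test
#'
#' Shapiro-Wilk in each group at `alpha_normality`; the t-test is chosen
#' only when both groups pass, otherwise the rank-sum (Mann-Whitney U)
#' test. Groups with fewer than 3 observations (or constant values, for
#' which the normality test is undefined) force the rank-sum branch.
#'
#' @param values_a,values_b numeric vectors.
#' @param alpha_normality significance level of the normality gate
#'   (default 0.05).
#' @return `"t-test"` or `"rank-sum"`.
#' @export
choose_test <- function(values_a, values_b, alpha_normality = 0.05) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    warning("fewer than 3 observations in a group; forcing rank-sum test")
    return("rank-sum")
  }
  normal <- vapply(list(values_a, values_b), function(v) {
    if (length(unique(v)) < 3 || length(v) > 5000) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha_normality
  }, logical(1))
  if (all(normal)) "t-test" else "rank-sum"
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration for small untied samples, otherwise the normal
#' approximation with continuity and tie corrections (mid-ranks for ties),
#' as implemented in [stats::wilcox.test()]. Identical pooled values give
#' p = 1.
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  if (length(unique(c(values_a, values_b))) == 1) return(1)
  p <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, correct = TRUE)$p.value)
  if (is.nan(p)) 1 else min(1, p)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of tables at least as extreme as the
#' observed one (probabilities not exceeding the observed table's). An
#' empty margin gives p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
exact_count_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

# exact or chi-square p for an RxC contingency table; exact first (larger
# workspace), deterministic chi-square fallback if the network algorithm
# gives up on a large table
categorical_test <- function(table) {
  if (all(dim(table) == 2L)) return(exact_count_test(table))
  tryCatch(
    stats::fisher.test(table, workspace = 2e7)$p.value,
    error = function(e) {
      warning("Fisher exact test infeasible for this table (",
              conditionMessage(e), "); falling back to chi-square")
      suppressWarnings(stats::chisq.test(table)$p.value)
    })
}

#' Classify acute kidney injury from a creatinine trajectory
#'
#' AKI is positive when serum creatinine rises by strictly more than
#' `delta_mgdl` above baseline within `delta_window_h` hours, or reaches
#' at least `ratio` times baseline within `ratio_window_h` hours (or until
#' the last available value, whichever ends first). The delta criterion is
#' checked first.
#'
#' @param baseline preoperative creatinine, mg/dL (> 0).
#' @param series data.frame with columns `hours` (>= 0, from surgery end)
#'   and `creatinine` (mg/dL), or an encoded string as stored in cohort
#'   tables.
#' @param delta_mgdl strict rise threshold within the short window
#'   (default 0.3 mg/dL).
#' @param delta_window_h short window (default 48 h).
#' @param ratio fold-rise threshold, at-or-above (default 1.5).
#' @param ratio_window_h long window (default 168 h = 7 days).
#' @return list of class `aki_outcome`: `aki` (logical),
#'   `criterion_met` (`"delta48h"`, `"ratio7d"` or `"none"`),
#'   `baseline_creatinine`, `max_postop_creatinine`, `unevaluable`
#'   (TRUE for an empty series).
#' @export
classify_aki <- function(baseline, series, delta_mgdl = 0.3,
                         delta_window_h = 48, ratio = 1.5,
                         ratio_window_h = 168) {
  stopifnot(is.numeric(baseline), baseline > 0)
  if (is.character(series)) series <- decode_creatinine_series(series)
  stopifnot(all(c("hours", "creatinine") %in% names(series)))
  if (nrow(series) == 0) {
    return(structure(list(aki = FALSE, criterion_met = "none",
                          baseline_creatinine = baseline,
                          max_postop_creatinine = NA_real_,
                          unevaluable = TRUE), class = "aki_outcome"))
  }
  stopifnot(all(series$hours >= 0), all(series$creatinine > 0))
  # comparisons carry a tiny tolerance so that values exactly at a
  # clinical boundary (e.g. a rise of exactly 0.30 mg/dL, or exactly
  # 1.5-fold) are classified by the stated rule rather than by
  # floating-point representation error
  eps <- 1e-9
  delta_hit <- any(series$hours <= delta_window_h &
                     series$creatinine - baseline > delta_mgdl + eps)
  ratio_hit <- any(series$hours <= ratio_window_h &
                     series$creatinine >= ratio * baseline - eps)
  criterion <- if (delta_hit) "delta48h" else if (ratio_hit) "ratio7d"
  else "none"
  structure(list(aki = criterion != "none", criterion_met = criterion,
                 baseline_creatinine = baseline,
                 max_postop_creatinine = max(series$creatinine),
                 unevaluable = FALSE), class = "aki_outcome")
}

#' @export
print.aki_outcome <- function(x, ...) {
  cat(sprintf("<aki_outcome: %s (%s), baseline %.2f, max postop %s mg/dL>\n",
              if (x$aki) "AKI" else "no AKI", x$criterion_met,
              x$baseline_creatinine,
              ifelse(is.na(x$max_postop_creatinine), "NA",
                     sprintf("%.2f", x$max_postop_creatinine))))
  invisible(x)
}

#' Format a count with its percentage
#'
#' Renders `"131 (23.2)"` style cells; percentages computed on unrounded
#' counts and printed to one decimal.
#'
#' @param n count.
#' @param total denominator.
#' @return character scalar.
#' @export
fmt_count_pct <- function(n, total) {
  sprintf("%d (%.1f)", n, 100 * n / total)
}

# "median (Q1, Q3)" with type-7 quartiles, 3 significant digits
fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sprintf("%s (%s, %s)", signif(q[2], 3), signif(q[1], 3), signif(q[3], 3))
}

fmt_mean_sd <- function(x) {
  sprintf("%s (%s)", signif(mean(x), 3), signif(stats::sd(x), 3))
}

#' Group-comparison table
#'
#' One row per variable, comparing the two arms of a cohort table:
#' continuous variables are summarized as median (IQR, type-7 quartiles)
#' or mean (SD) according to the Shapiro-Wilk normality gate and compared
#' with the matching rank-sum or t test; binary and categorical variables
#' are summarized as n (%) and compared with the Fisher exact test.
#' A standardized-mean-difference column uses the continuous or binary
#' formula (level maximum for multi-level categoricals). No
#' multiple-testing adjustment is applied; all tests are two-sided.
#'
#' @param cohort cohort data.frame containing a `group` column plus the
#'   variables.
#' @param variables character vector of column names to compare.
#' @param matched_ids optional character vector of patient ids restricting
#'   the table to a matched subset (requires a `patient_id` column).
#' @param group_col name of the grouping column (two levels).
#' @param group_a level reported as the first summary column (default
#'   `"non-HPI"` if present).
#' @return data.frame of class `comparison_table` with columns `variable`,
#'   `summary_a`, `summary_b`, `test_used`, `p_value`, `smd`.
#' @export
build_comparison_table <- function(cohort, variables,
                                   matched_ids = NULL,
                                   group_col = "group",
                                   group_a = NULL) {
  stopifnot(group_col %in% names(cohort))
  if (!is.null(matched_ids)) {
    stopifnot("patient_id" %in% names(cohort))
    cohort <- cohort[cohort$patient_id %in% matched_ids, , drop = FALSE]
  }
  g <- as.character(cohort[[group_col]])
  lv <- sort(unique(g))
  if (length(lv) != 2)
    stop("grouping column must have exactly two levels", call. = FALSE)
  if (is.null(group_a)) group_a <- if ("non-HPI" %in% lv) "non-HPI" else lv[1]
  group_b <- setdiff(lv, group_a)
  in_a <- g == group_a

  rows <- lapply(variables, function(nm) {
    col <- cohort[[nm]]
    if (is.character(col) || is.factor(col)) {
      col <- as.character(col)
      tab <- table(factor(col), factor(g, levels = c(group_a, group_b)))
      lv_smd <- vapply(rownames(tab), function(l) {
        smd_binary(mean(col[in_a] == l), mean(col[!in_a] == l))
      }, numeric(1))
      data.frame(
        variable = nm,
        summary_a = paste(sprintf("%s %s", rownames(tab),
                                  fmt_count_pct(tab[, 1], sum(in_a))),
                          collapse = "; "),
        summary_b = paste(sprintf("%s %s", rownames(tab),
                                  fmt_count_pct(tab[, 2], sum(!in_a))),
                          collapse = "; "),
        test_used = "exact-count",
        p_value = categorical_test(tab),
        smd = lv_smd[[which.max(abs(lv_smd))]],
        stringsAsFactors = FALSE)
    } else if (all(col %in% 0:1)) {
      n_a <- sum(col[in_a]); n_b <- sum(col[!in_a])
      tab <- matrix(c(n_a, sum(in_a) - n_a, n_b, sum(!in_a) - n_b), 2)
      data.frame(
        variable = nm,
        summary_a = fmt_count_pct(n_a, sum(in_a)),
        summary_b = fmt_count_pct(n_b, sum(!in_a)),
        test_used = "exact-count",
        p_value = exact_count_test(tab),
        smd = smd_binary(n_a / sum(in_a), n_b / sum(!in_a)),
        stringsAsFactors = FALSE)
    } else {
      a <- col[in_a]; b <- col[!in_a]
      test <- suppressWarnings(choose_test(a, b))
      if (test == "t-test") {
        p <- stats::t.test(a, b)$p.value
        sa <- fmt_mean_sd(a); sb <- fmt_mean_sd(b)
      } else {
        p <- rank_sum_test(a, b)
        sa <- fmt_median_iqr(a); sb <- fmt_median_iqr(b)
      }
      data.frame(variable = nm, summary_a = sa, summary_b = sb,
                 test_used = test, p_value = p,
                 smd = smd_continuous(a, b), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(group_a, group_b)
  class(out) <- c("comparison_table", class(out))
  out
}

#' @export
print.comparison_table <- function(x, digits = 3, ...) {
  g <- attr(x, "groups")
  cat(sprintf("Group comparison: %s vs %s\n", g[1], g[2]))
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, digits)
  df$smd <- round(df$smd, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' AKI outcomes for a whole cohort
#'
#' @param cohort cohort data.frame with `patient_id`, `preop_creatinine`
#'   and the encoded `postop_creatinine_series` column.
#' @param ... passed to [classify_aki()].
#' @return data.frame with one row per patient: `patient_id`, `aki` (0/1),
#'   `criterion_met`, `max_postop_creatinine`.
#' @export
classify_aki_cohort <- function(cohort, ...) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    res <- classify_aki(cohort$preop_creatinine[i],
                        cohort$postop_creatinine_series[i], ...)
    data.frame(patient_id = cohort$patient_id[i],
               aki = as.integer(res$aki),
               criterion_met = res$criterion_met,
               max_postop_creatinine = res$max_postop_creatinine,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
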