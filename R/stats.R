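# Group comparisons used throughout the study: descriptive summaries,
# two-sample Student's t, Wilcoxon rank-sum, and one-way ANOVA. Thin wrappers
# over the standard R tests that normalize inputs, handle the degenerate
# zero-variance cases explicitly, and return a common result shape.

.comparison_result <- function(test_name, group_labels, statistic, p_value,
                               n_per_group, note = NA_character_) {
  tibble::tibble(test_name = test_name,
                 groups = paste(group_labels, collapse = " vs "),
                 statistic = statistic, p_value = p_value,
                 n = paste(n_per_group, collapse = ","), note = note)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sample t by default (the classical Student form);
#' Welch's unequal-variance version via `var_equal = FALSE`. Two-sided.
#'
#' @param group_a,group_b Numeric samples (n >= 2 each).
#' @param var_equal Pool the variances (default TRUE).
#' @param labels Group labels for the result row.
#' @return A one-row comparison tibble: `test_name`, `groups`, `statistic`
#'   (t), `p_value`, `n`.
#' @export
students_t <- function(group_a, group_b, var_equal = TRUE,
                       labels = c("A", "B")) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  nm <- if (var_equal) "Student t (pooled)" else "Welch t"
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(.comparison_result(nm, labels, 0, 1,
                                c(length(group_a), length(group_b)),
                                "zero variance in both groups"))
    }
    return(.comparison_result(nm, labels, Inf * sign(mean(group_a) - mean(group_b)),
                              0, c(length(group_a), length(group_b)),
                              "zero variance, unequal means"))
  }
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  .comparison_result(nm, labels, unname(ht$statistic), ht$p.value,
                     c(length(group_a), length(group_b)))
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties; exact two-sided p-value for tie-free samples with
#' combined n <= `exact_max`, Normal approximation with tie and continuity
#' correction otherwise.
#'
#' @param group_a,group_b Numeric samples (n >= 1 each).
#' @param exact_max Largest combined sample size for the exact null
#'   distribution.
#' @param labels Group labels for the result row.
#' @return A one-row comparison tibble (statistic is the Mann-Whitney W of
#'   group A).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact_max = 20,
                              labels = c("A", "B")) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  n <- length(group_a) + length(group_b)
  if (length(unique(c(group_a, group_b))) == 1) {
    return(.comparison_result("Wilcoxon rank-sum", labels,
                              length(group_a) * length(group_b) / 2, 1,
                              c(length(group_a), length(group_b)),
                              "all values identical"))
  }
  ties <- any(duplicated(c(group_a, group_b)))
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = !ties && n <= exact_max,
                correct = TRUE)
  )
  .comparison_result("Wilcoxon rank-sum", labels, unname(ht$statistic),
                     ht$p.value, c(length(group_a), length(group_b)))
}

#' One-way ANOVA
#'
#' Classical fixed-effects F test (`F = MS_between / MS_within`). With every
#' within-group variance zero and group means unequal, F is infinite and p is
#' reported as 0 with a note.
#'
#' @param groups List of >= 2 numeric samples, each n >= 2.
#' @param labels Optional group labels.
#' @return A one-row comparison tibble (statistic is F).
#' @export
one_way_anova <- function(groups, labels = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  if (is.null(labels)) labels <- paste0("G", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  within_var <- vapply(groups, var, numeric(1))
  means <- vapply(groups, mean, numeric(1))
  if (all(within_var == 0)) {
    if (diff(range(means)) == 0) {
      return(.comparison_result("one-way ANOVA", labels, 0, 1, ns,
                                "all groups identical"))
    }
    return(.comparison_result("one-way ANOVA", labels, Inf, 0, ns,
                              "zero within-group variance"))
  }
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), ns))
  ht <- oneway.test(vals ~ g, var.equal = TRUE)
  .comparison_result("one-way ANOVA", labels, unname(ht$statistic),
                     ht$p.value, ns)
}

#' Descriptive summary (n, mean, sample sd)
#'
#' @param sample Numeric vector (n >= 1).
#' @param label Optional label.
#' @return A tibble: `label`, `n`, `mean`, `sd` (n - 1 denominator; 0 for a
#'   single value).
#' @export
describe <- function(sample, label = "sample") {
  stopifnot(length(sample) >= 1)
  tibble::tibble(label = label, n = length(sample), mean = mean(sample),
                 sd = if (length(sample) > 1) sd(sample) else 0)
}
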