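#' Unpaired two-sample t-test
#'
#' Two-sided comparison of two independent groups at alpha = 0.05, the
#' standard two-group design for sham vs. blast comparisons. The default is
#' the Student (pooled-variance) test; Welch's unequal-variance form is
#' available via `variant`. No multiple-testing correction is applied:
#' each metric/marker is tested on its own, which the report output notes.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @param metric Name of the compared quantity, carried into the result.
#' @param groups Length-2 character vector of group labels.
#'
#' @return An object of class `group_comparison`: a list with the metric
#'   name, group means, SEMs and sizes, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, and `significant` (p < 0.05).
#' @export
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
unpaired_t_test <- function(a, b, variant = c("student", "welch"),
                            metric = "metric", groups = c("a", "b")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("'", metric, "': each group needs >= 2 finite values")
  if (stats::var(a) + stats::var(b) == 0 && mean(a) == mean(b)) {
    # identical degenerate samples: no evidence of a difference
    tt <- list(statistic = c(t = 0),
               parameter = c(df = length(a) + length(b) - 2), p.value = 1)
  } else if (stats::var(a) + stats::var(b) == 0) {
    stop("'", metric, "': zero variance in both groups, t-test undefined")
  } else {
    tt <- stats::t.test(a, b, var.equal = variant == "student")
  }
  structure(list(
    metric = metric,
    group_labels = groups,
    means = c(mean(a), mean(b)),
    sems = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b))),
    n = c(length(a), length(b)),
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < 0.05,
    variant = variant), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: %s %.4g +/- %.3g (n=%d) vs %s %.4g +/- %.3g (n=%d)\n  t(%.4g) = %.4g, p = %.4g%s  [%s t-test; no multiplicity correction]\n",
    x$metric, x$group_labels[1L], x$means[1L], x$sems[1L], x$n[1L],
    x$group_labels[2L], x$means[2L], x$sems[2L], x$n[2L],
    x$degrees_of_freedom, x$t_statistic, x$p_value,
    if (x$significant) " *" else "", x$variant))
  invisible(x)
}

#' Convert a group comparison to a tibble row
#'
#' @param comparison A `group_comparison` from [unpaired_t_test()].
#' @return A one-row tibble.
#' @export
comparison_row <- function(comparison) {
  stopifnot(inherits(comparison, "group_comparison"))
  x <- comparison
  tibble::tibble(
    metric = x$metric,
    group_a = x$group_labels[1L], group_b = x$group_labels[2L],
    mean_a = x$means[1L], sem_a = x$sems[1L], n_a = x$n[1L],
    mean_b = x$means[2L], sem_b = x$sems[2L], n_b = x$n[2L],
    t_statistic = x$t_statistic,
    degrees_of_freedom = x$degrees_of_freedom,
    p_value = x$p_value, significant = x$significant)
}

#' Group summary as mean +/- SEM
#'
#' Per-group mean and standard error of the mean (SD / sqrt(n)), the form
#' in which bar-graph results are reported. Groups of size 1 get SEM 0 and
#' are flagged by their `n`.
#'
#' @param values Numeric vector.
#' @param group Grouping vector of the same length.
#'
#' @return A tibble with `group`, `n`, `mean`, `sem`.
#' @export
#' @examples
#' group_summary(c(2, 4, 6, 1, 3), rep(c("sham", "blast"), c(3, 2)))
group_summary <- function(values, group) {
  stopifnot(is.numeric(values), length(values) == length(group),
            length(values) >= 1L)
  levels <- unique(group)
  rows <- lapply(levels, function(g) {
    v <- values[group == g & is.finite(values)]
    tibble::tibble(group = g, n = length(v), mean = mean(v),
                   sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  })
  do.call(rbind, rows)
}

#' Compare every metric in a tidy table between two groups
#'
#' @param data Tidy data frame with columns `subject_id`, `group`,
#'   `metric`, `value`.
#' @param variant t-test variant; see [unpaired_t_test()].
#'
#' @return A tibble with one [comparison_row()] per metric.
#' @export
compare_groups <- function(data, variant = c("student", "welch")) {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "group", "metric", "value") %in% names(data)))
  variant <- match.arg(variant)
  groups <- unique(data$group)
  if (length(groups) != 2L)
    stop("expected exactly 2 groups, got ", length(groups))
  rows <- lapply(unique(data$metric), function(m) {
    d <- data[data$metric == m, ]
    comparison_row(unpaired_t_test(
      d$value[d$group == groups[1L]], d$value[d$group == groups[2L]],
      variant = variant, metric = m, groups = groups))
  })
  do.call(rbind, rows)
}
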