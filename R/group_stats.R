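## Hierarchical statistics: per-animal averaging, normality-gated test
## selection (t / Mann-Whitney for two groups, ANOVA+Tukey / Kruskal-Wallis
## for more), cumulative frequencies, and mean +/- s.e.m. summaries.

#' Average cell-level values per animal
#'
#' Group comparisons use the animal, not the cell, as the unit of analysis:
#' cell values are averaged per (animal, group) before testing.
#'
#' @param table A [measurement_table()] (or data.frame with `value`,
#'   `animal_id`, `group_label`).
#' @return `data.frame(animal_id, group_label, value, n_cells)`, one row per
#'   animal.
#' @export
animal_means <- function(table) {
  if (nrow(table) == 0) stop("empty measurement table")
  agg <- aggregate(value ~ animal_id + group_label, data = as.data.frame(table),
                   FUN = mean)
  n <- aggregate(value ~ animal_id + group_label, data = as.data.frame(table),
                 FUN = length)
  agg$n_cells <- n$value
  agg[order(agg$group_label, agg$animal_id), c("animal_id", "group_label",
                                               "value", "n_cells")]
}

## Shapiro-Wilk p-value per group; NA when the test is undefined
## (n < 3 or zero within-group variance).
.shapiro_by_group <- function(values, groups) {
  vapply(split(values, groups), function(v) {
    if (length(v) < 3 || length(unique(v)) == 1) return(NA_real_)
    shapiro.test(v)$p.value
  }, numeric(1))
}

#' Compare groups on per-animal means
#'
#' Implements the normality-gated test-selection logic: Shapiro-Wilk per
#' group at `alpha`; with two groups, both normal -> two-tailed two-sample
#' Student's t-test (equal variances by default), otherwise Mann-Whitney U;
#' with more than two groups, all normal -> one-way ANOVA with Tukey's range
#' post hoc, otherwise Kruskal-Wallis.  Groups whose normality cannot be
#' assessed (fewer than 3 animals, or constant values) fail the gate and the
#' non-parametric branch is taken.  If every group is constant the report is
#' returned with statistic 0, p = 1 and `degenerate = TRUE`.
#'
#' @param per_animal Output of [animal_means()] (columns `value`,
#'   `group_label`), with >= 2 groups and >= 2 animals per group.
#' @param alpha Significance level for the normality gate and the report.
#' @param var_equal Use the equal-variance Student's t-test (default); set
#'   `FALSE` for Welch.
#' @return A `test_report`: list with `test`, `branch`
#'   (`"parametric"`/`"nonparametric"`), `statistic`, `p_value`,
#'   `normality_p`, `posthoc` (Tukey table or `NULL`), `alpha`,
#'   `degenerate`, `n_per_group`.
#' @export
compare_groups <- function(per_animal, alpha = 0.05, var_equal = TRUE) {
  d <- as.data.frame(per_animal)
  stopifnot(all(c("value", "group_label") %in% names(d)))
  d$group_label <- factor(d$group_label)
  ng <- nlevels(d$group_label)
  if (ng < 2) stop("need at least 2 groups")
  sizes <- table(d$group_label)
  if (any(sizes < 2)) stop("every group needs at least 2 animals")
  sw <- .shapiro_by_group(d$value, d$group_label)

  degenerate <- all(tapply(d$value, d$group_label,
                           function(v) length(unique(v)) == 1))
  if (degenerate) {
    rep <- list(test = if (ng == 2) "Student t" else "one-way ANOVA",
                branch = "parametric", statistic = 0, p_value = 1,
                normality_p = sw, posthoc = NULL, alpha = alpha,
                degenerate = TRUE, n_per_group = as.vector(sizes))
    class(rep) <- "test_report"
    return(rep)
  }

  normal <- !anyNA(sw) && all(sw >= alpha)
  posthoc <- NULL
  if (ng == 2) {
    g <- split(d$value, d$group_label)
    if (normal) {
      ht <- t.test(g[[1]], g[[2]], var.equal = var_equal)
      test <- if (var_equal) "Student t" else "Welch t"
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- suppressWarnings(wilcox.test(g[[1]], g[[2]]))
      test <- "Mann-Whitney U"
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    if (normal) {
      fit <- aov(value ~ group_label, data = d)
      s <- summary(fit)[[1]]
      stat <- s$`F value`[1]; p <- s$`Pr(>F)`[1]
      test <- "one-way ANOVA"
      tk <- TukeyHSD(fit)$group_label
      posthoc <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL)
    } else {
      ht <- kruskal.test(value ~ group_label, data = d)
      stat <- unname(ht$statistic); p <- ht$p.value
      test <- "Kruskal-Wallis"
    }
  }
  rep <- list(test = test,
              branch = if (normal) "parametric" else "nonparametric",
              statistic = stat, p_value = p, normality_p = sw,
              posthoc = posthoc, alpha = alpha, degenerate = FALSE,
              n_per_group = as.vector(sizes))
  class(rep) <- "test_report"
  rep
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s (%s branch): statistic = %.4g, p = %.4g%s\n",
              x$test, x$branch, x$statistic, x$p_value,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  if (!is.null(x$posthoc)) {
    cat("Tukey post hoc:\n"); print(x$posthoc)
  }
  invisible(x)
}

#' Cumulative frequency table
#'
#' Empirical cumulative distribution over the cell-level values: sorted
#' unique values with the cumulative fraction of observations `<=` each
#' value; the final fraction is 1.
#'
#' @param values Numeric vector (>= 1 value).
#' @return `data.frame(value, cum_fraction)`.
#' @export
ecdf_table <- function(values) {
  if (length(values) == 0) stop("empty input")
  v <- sort(unique(values))
  cf <- cumsum(as.numeric(table(factor(values, levels = v)))) / length(values)
  data.frame(value = v, cum_fraction = cf)
}

#' Mean and standard error per group
#'
#' @param per_animal Output of [animal_means()] (columns `value`,
#'   `group_label`).
#' @return `data.frame(group_label, n, mean, sem)`; `sem = sd/sqrt(n)`,
#'   `NA` when `n < 2`.
#' @export
sem_summary <- function(per_animal) {
  d <- as.data.frame(per_animal)
  g <- split(d$value, d$group_label)
  data.frame(group_label = names(g),
             n = vapply(g, length, integer(1)),
             mean = vapply(g, mean, numeric(1)),
             sem = vapply(g, function(v)
               if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v)),
               numeric(1)),
             row.names = NULL)
}
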