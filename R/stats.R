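# Group-comparison statistics: the normality-gated two-group test and
# ANOVA + Tukey for more than two groups, with a full decision trail.

normality_gate <- function(x, alpha) {
  n <- length(x)
  if (stats::sd(x) == 0) {
    # a constant sample carries no distributional evidence; treat as
    # non-normal so the rank test (which handles ties) is used
    return(list(test = "none (zero variance)", p = 0, normal = FALSE))
  }
  if (n <= 50) {
    ht <- stats::shapiro.test(x)
    list(test = "shapiro-wilk", p = ht$p.value, normal = ht$p.value >= alpha)
  } else {
    ht <- nortest::lillie.test(x)
    list(test = "lilliefors-ks", p = ht$p.value, normal = ht$p.value >= alpha)
  }
}

#' Two-group comparison with the normality-gated decision path
#'
#' Tests each group for normality (Shapiro-Wilk for n <= 50, Lilliefors
#' Kolmogorov-Smirnov for larger samples) at `alpha_normality`; when both
#' groups pass, an unpaired two-sided Student's t-test is used (Welch
#' correction available via `welch`), otherwise a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test. The full decision trail is recorded.
#'
#' @param x,y Numeric samples, each of length >= 3.
#' @param labels Character vector of two group labels.
#' @param alpha_normality Normality-gate significance level (default 0.05).
#' @param welch Use the Welch t-test instead of Student's (default `FALSE`).
#' @param measure Optional measure name carried into the result.
#' @return A `bs_comparison` list: `test_used`, `statistic`, `p_value`,
#'   `normality` (per-group test and p), group `means`, `sems`, `n`.
#' @export
compare_two_groups <- function(x, y, labels = c("x", "y"),
                               alpha_normality = 0.05, welch = FALSE,
                               measure = NULL) {
  if (length(x) < 3L || length(y) < 3L) {
    stop_validation("each group needs at least 3 observations")
  }
  if (any(!is.finite(c(x, y)))) stop_validation("samples must be finite")
  nx <- normality_gate(x, alpha_normality)
  ny <- normality_gate(y, alpha_normality)
  if (nx$normal && ny$normal) {
    ht <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
    test_used <- if (welch) "welch t" else "student t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                         correct = TRUE))
    test_used <- "mann-whitney"
  }
  structure(list(
    measure = measure, groups = labels, test_used = test_used,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    normality = list(tests = c(nx$test, ny$test), p = c(nx$p, ny$p),
                     alpha = alpha_normality,
                     normal = c(nx$normal, ny$normal)),
    means = c(mean(x), mean(y)), sems = c(sem(x), sem(y)),
    n = c(length(x), length(y))
  ), class = "bs_comparison")
}

#' @export
print.bs_comparison <- function(x, ...) {
  cat(sprintf("<bs_comparison>%s %s vs %s: %s, statistic %.4g, p = %.4g\n",
              if (!is.null(x$measure)) paste0(" [", x$measure, "]") else "",
              x$groups[1], x$groups[2], x$test_used, x$statistic, x$p_value))
  cat(sprintf("  means +/- SEM: %.4g +/- %.4g (n=%d) vs %.4g +/- %.4g (n=%d)\n",
              x$means[1], x$sems[1], x$n[1], x$means[2], x$sems[2], x$n[2]))
  invisible(x)
}

#' Multi-group comparison: ANOVA with Tukey's multiple comparisons
#'
#' One-way ANOVA over >= 3 groups, or two-way ANOVA over a full factorial
#' design, followed by Tukey's HSD pairwise comparisons (family-wise error
#' 0.05).
#'
#' @param values Numeric response vector.
#' @param group Group labels (one-way) or the first factor (two-way).
#' @param design `"one_way"` or `"two_way"`.
#' @param factor_b Second factor for the two-way design.
#' @param measure Optional measure name.
#' @return A `bs_anova` list: `design`, `anova` (F and p per term), `tukey`
#'   (data.frame of pairwise comparisons with adjusted p), group `means`,
#'   `sems`, `n`.
#' @export
compare_many_groups <- function(values, group, design = c("one_way", "two_way"),
                                factor_b = NULL, measure = NULL) {
  design <- match.arg(design)
  if (any(!is.finite(values))) stop_validation("values must be finite")
  group <- factor(group)
  if (design == "one_way") {
    if (nlevels(group) < 3L) {
      stop_validation("one-way design needs at least 3 groups")
    }
    if (any(table(group) < 2L)) {
      stop_validation("each group needs at least 2 observations")
    }
    fit <- stats::aov(values ~ group)
    tk <- stats::TukeyHSD(fit)$group
    tukey_term <- "group"
  } else {
    if (is.null(factor_b)) stop_validation("two-way design needs factor_b")
    fb <- factor(factor_b)
    tab <- table(group, fb)
    if (any(tab == 0L)) {
      stop_validation("two-way design must have every factor cell filled")
    }
    if (any(tab < 2L)) {
      stop_validation("each factor cell needs at least 2 observations")
    }
    fit <- stats::aov(values ~ group * fb)
    tk <- stats::TukeyHSD(fit)$`group:fb`
    tukey_term <- "group:fb"
  }
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  keep <- terms != "Residuals"
  anova_tbl <- data.frame(term = terms[keep],
                          df = an$Df[keep],
                          F = an$`F value`[keep],
                          p = an$`Pr(>F)`[keep], row.names = NULL)
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL)
  cell <- if (design == "one_way") group else interaction(group, factor_b, sep = ":")
  structure(list(
    measure = measure, design = design, term = tukey_term,
    anova = anova_tbl, tukey = tukey,
    means = tapply(values, cell, mean),
    sems = tapply(values, cell, sem),
    n = as.integer(table(cell))
  ), class = "bs_anova")
}

#' @export
print.bs_anova <- function(x, ...) {
  cat(sprintf("<bs_anova>%s %s design\n",
              if (!is.null(x$measure)) paste0(" [", x$measure, "]") else "",
              x$design))
  print(x$anova)
  cat("Tukey HSD:\n")
  print(x$tukey)
  invisible(x)
}

#' Per-measure comparison tables for a cohort
#'
#' For each requested measure in a long table
#' (`subject_id`, `group_label`, `measure`, `value`), runs the appropriate
#' comparison: [compare_two_groups()] for 2 groups, [compare_many_groups()]
#' (one-way) for >= 3 groups, descriptive statistics only for a single
#' group. Measures absent from the table are listed as absent, not fatal.
#'
#' @param measures Long-format data.frame with `subject_id`, `group_label`,
#'   `measure`, `value` columns.
#' @param which Measures to tabulate; default all present.
#' @param alpha_normality Normality-gate level for two-group comparisons.
#' @return A `figure_table` list: per-measure results plus a `summary`
#'   data.frame (measure, status, test, statistic, p_value).
#' @export
figure_table <- function(measures, which = NULL, alpha_normality = 0.05) {
  need <- c("subject_id", "group_label", "measure", "value")
  if (!is.data.frame(measures) || !all(need %in% names(measures))) {
    stop_validation("measures must have columns %s", paste(need, collapse = ", "))
  }
  if (is.null(which)) which <- unique(measures$measure)
  results <- list()
  rows <- list()
  for (m in which) {
    sub <- measures[measures$measure == m & is.finite(measures$value), ]
    groups <- unique(sub$group_label)
    if (nrow(sub) == 0L) {
      results[[m]] <- list(status = "absent")
      rows[[m]] <- data.frame(measure = m, status = "absent", test = NA,
                              statistic = NA_real_, p_value = NA_real_)
      next
    }
    if (length(groups) == 1L) {
      vals <- sub$value
      results[[m]] <- list(status = "descriptive", group = groups,
                           mean = mean(vals), sem = sem(vals), n = length(vals))
      rows[[m]] <- data.frame(measure = m, status = "descriptive", test = NA,
                              statistic = NA_real_, p_value = NA_real_)
    } else if (length(groups) == 2L) {
      cmp <- compare_two_groups(sub$value[sub$group_label == groups[1]],
                                sub$value[sub$group_label == groups[2]],
                                labels = groups,
                                alpha_normality = alpha_normality,
                                measure = m)
      results[[m]] <- cmp
      rows[[m]] <- data.frame(measure = m, status = "two_group",
                              test = cmp$test_used, statistic = cmp$statistic,
                              p_value = cmp$p_value)
    } else {
      cmp <- compare_many_groups(sub$value, sub$group_label,
                                 design = "one_way", measure = m)
      results[[m]] <- cmp
      rows[[m]] <- data.frame(measure = m, status = "anova",
                              test = "one-way anova + tukey",
                              statistic = cmp$anova$F[1],
                              p_value = cmp$anova$p[1])
    }
  }
  structure(list(results = results, summary = do.call(rbind, c(rows, list(
    make.row.names = FALSE)))), class = "figure_table")
}

#' @export
print.figure_table <- function(x, ...) {
  cat("<figure_table>\n")
  print(x$summary)
  invisible(x)
}
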