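# The normality-gated two-group decision path and ANOVA + Tukey.

test_that("identical samples yield p = 1 on the rank-test path", {
  set.seed(20)
  x <- rexp(30)                       # skewed, so the gate picks Mann-Whitney
  cmp <- compare_two_groups(x, x)
  expect_equal(cmp$test_used, "mann-whitney")
  expect_equal(cmp$p_value, 1)
})

test_that("well-separated normal samples take the t-test path", {
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20, 3)
  cmp <- compare_two_groups(x, y)
  expect_equal(cmp$test_used, "student t")
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$normality$tests, c("shapiro-wilk", "shapiro-wilk"))
  expect_true(all(cmp$normality$p >= 0.05))
  # decision path is deterministic: same data, same result
  cmp2 <- compare_two_groups(x, y)
  expect_identical(cmp$p_value, cmp2$p_value)
  expect_identical(cmp$test_used, cmp2$test_used)
  # reported SEMs are SD/sqrt(n) exactly
  expect_equal(cmp$sems, c(sd(x) / sqrt(20), sd(y) / sqrt(20)))
  expect_error(compare_two_groups(c(1, 2), y), "at least 3")
})

test_that("skewed samples are routed to Mann-Whitney in most seeds", {
  chosen <- vapply(1:100, function(s) {
    set.seed(s)
    compare_two_groups(rexp(30), rexp(30))$test_used
  }, character(1))
  expect_gte(sum(chosen == "mann-whitney"), 90)
})

test_that("large samples use the Lilliefors gate", {
  set.seed(21)
  cmp <- compare_two_groups(rnorm(80), rnorm(80, 0.1))
  expect_equal(cmp$normality$tests, c("lilliefors-ks", "lilliefors-ks"))
})

test_that("one-way ANOVA and Tukey match a hand computation", {
  g1 <- c(6, 8, 4, 5, 3, 4)
  g2 <- c(8, 12, 9, 11, 6, 8)
  g3 <- c(13, 9, 11, 8, 7, 12)
  values <- c(g1, g2, g3)
  group <- rep(c("a", "b", "c"), each = 6)
  res <- compare_many_groups(values, group, design = "one_way")
  # sums of squares from first principles
  gm <- mean(values)
  means <- c(mean(g1), mean(g2), mean(g3))
  ssb <- 6 * sum((means - gm)^2)
  ssw <- sum((g1 - means[1])^2) + sum((g2 - means[2])^2) +
    sum((g3 - means[3])^2)
  f_hand <- (ssb / 2) / (ssw / 15)
  p_hand <- pf(f_hand, 2, 15, lower.tail = FALSE)
  expect_equal(res$anova$F[1], f_hand, tolerance = 1e-4)
  expect_equal(res$anova$p[1], p_hand, tolerance = 1e-4)
  # Tukey adjusted p from the studentized range distribution
  msw <- ssw / 15
  q12 <- abs(means[1] - means[2]) / sqrt(msw / 6)
  p12_hand <- ptukey(q12, nmeans = 3, df = 15, lower.tail = FALSE)
  got <- res$tukey$p_adj[res$tukey$comparison == "b-a"]
  expect_equal(got, p12_hand, tolerance = 1e-4)
})

test_that("Tukey adjusted p never undercuts the unadjusted pairwise p", {
  for (seed in 1:10) {
    set.seed(seed)
    values <- rnorm(24, mean = rep(c(0, 0.5, 1, 0.2), each = 6))
    group <- rep(letters[1:4], each = 6)
    res <- compare_many_groups(values, group)
    raw <- pairwise.t.test(values, group, p.adjust.method = "none",
                           pool.sd = TRUE)$p.value
    for (k in seq_len(nrow(res$tukey))) {
      pair <- strsplit(res$tukey$comparison[k], "-")[[1]]
      p_raw <- raw[max(pair), min(pair)]
      expect_gte(res$tukey$p_adj[k] + 1e-12, p_raw)
    }
  }
})

test_that("a 5-SD shifted group is flagged by every Tukey pairwise test", {
  set.seed(30)
  values <- c(rnorm(18), rnorm(6, 5))
  group <- rep(c("a", "b", "c", "shifted"), each = 6)
  res <- compare_many_groups(values, group)
  hit <- grepl("shifted", res$tukey$comparison)
  expect_true(all(res$tukey$p_adj[hit] < 0.01))
})

test_that("two-way ANOVA requires a full factorial and reports Tukey cells", {
  set.seed(31)
  a <- rep(c("young", "aged"), each = 8)
  b <- rep(rep(c("veh", "drug"), each = 4), 2)
  y <- rnorm(16) + (a == "aged") * 2
  res <- compare_many_groups(y, a, design = "two_way", factor_b = b)
  expect_setequal(res$anova$term, c("group", "fb", "group:fb"))
  expect_equal(nrow(res$tukey), choose(4, 2))
  # missing cell is refused
  expect_error(compare_many_groups(y[-(1:4)], a[-(1:4)], design = "two_way",
                                   factor_b = b[-(1:4)]),
               "cell")
})

test_that("figure_table dispatches by group count and flags absences", {
  set.seed(32)
  long <- rbind(
    data.frame(subject_id = sprintf("y%d", 1:6), group_label = "young",
               measure = "bsr_percent", value = rnorm(6, 20, 3)),
    data.frame(subject_id = sprintf("a%d", 1:6), group_label = "aged",
               measure = "bsr_percent", value = rnorm(6, 60, 3)),
    data.frame(subject_id = sprintf("y%d", 1:6), group_label = "young",
               measure = "solo", value = rnorm(6)))
  ft <- figure_table(long, which = c("bsr_percent", "solo", "not_measured"))
  expect_equal(ft$summary$status,
               c("two_group", "descriptive", "absent"))
  expect_lt(ft$results$bsr_percent$p_value, 0.01)
  expect_equal(ft$results$solo$n, 6)
})
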