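grouped <- function(values, labels) tibble::tibble(value = values,
                                                   label = labels)

test_that("normality gate routes Gaussian and heavy-tailed samples correctly", {
  routes <- vapply(1:200, function(s) {
    set.seed(s)
    d <- grouped(rnorm(90), rep(c("a", "b", "c"), each = 30))
    normality_gate(d)$route
  }, character(1))
  expect_gt(mean(routes == "parametric"), 0.80) # ~(1 - alpha)^3 = 0.857
  routes_ln <- vapply(1:100, function(s) {
    set.seed(s)
    d <- grouped(exp(rnorm(90, sd = 1.5)), rep(c("a", "b", "c"), each = 30))
    normality_gate(d)$route
  }, character(1))
  expect_gt(mean(routes_ln == "nonparametric"), 0.95)
  # degenerate group
  d <- grouped(c(1, 1, 1, rnorm(10)), rep(c("a", "b"), c(3, 10)))
  expect_warning(g <- normality_gate(d), "nonparametric")
  expect_equal(g$route, "nonparametric")
  expect_equal(g$status, "degenerate group")
})

test_that("global test holds its size and has power under separation", {
  pvals <- vapply(1:1000, function(s) {
    set.seed(s)
    d <- grouped(rnorm(30), rep(c("a", "b", "c"), each = 10))
    global_group_test(d, route = "nonparametric")$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.005)
  # power at a 1.5 sd shift with the clinical group sizes
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    d <- grouped(c(rnorm(21), rnorm(39, 1.5), rnorm(42, 3)),
                 rep(c("a", "b", "c"), c(21, 39, 42)))
    global_group_test(d, route = "nonparametric")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  # all-tied input: p = 1 convention
  expect_equal(global_group_test(grouped(rep(2, 30), rep(c("a", "b", "c"), 10)),
                                 route = "nonparametric")$p_value,
               1)
  # two groups reduce to the rank-sum test
  d2 <- grouped(c(1, 3, 5, 2, 4, 6), rep(c("a", "b"), each = 3))
  kw <- global_group_test(d2, route = "nonparametric")
  expect_lt(abs(kw$p_value -
                  wilcox.test(c(1, 3, 5), c(2, 4, 6))$p.value), 0.2)
})

test_that("pairwise Mann-Whitney matches exact enumeration and Bonferroni holds", {
  # {1,2,3} vs {4,5,6}: U = 0; exact two-sided p = 2/choose(6,3) = 0.1
  d <- grouped(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  pw <- pairwise_mwu_bonferroni(d)
  expect_equal(pw$u, 0)
  expect_equal(pw$p_raw, 2 / choose(6, 3))
  # identical groups: adjusted p ~ 1
  set.seed(1)
  v <- rnorm(60)
  d3 <- grouped(rep(v[1:20], 3), rep(c("a", "b", "c"), each = 20))
  pw3 <- pairwise_mwu_bonferroni(d3)
  expect_true(all(pw3$p_adj > 0.99))
  # Bonferroni never decreases a p-value and caps at 1
  set.seed(2)
  d4 <- grouped(rnorm(60), rep(c("a", "b", "c"), each = 20))
  pw4 <- pairwise_mwu_bonferroni(d4)
  expect_true(all(pw4$p_adj >= pw4$p_raw))
  expect_true(all(pw4$p_adj <= 1))
  expect_equal(nrow(pw4), 3L)
})

test_that("family-wise error stays below alpha under the all-null design", {
  fw <- vapply(1:1000, function(s) {
    set.seed(s + 4000)
    d <- grouped(rnorm(102), rep(c("a", "b", "c"), c(21, 39, 42)))
    any(pairwise_mwu_bonferroni(d)$p_adj < 0.05)
  }, logical(1))
  expect_lte(mean(fw), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("youden index is exact arithmetic with range validation", {
  expect_equal(youden_index(0.832, 0.903), 0.735)
  expect_equal(youden_index(1, 1), 1)
  expect_equal(youden_index(0.733, 0.812), 0.545)
  expect_error(youden_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("perfectly separated scores give AUC 1 with degenerate CI", {
  rb <- bootstrap_roc(c(1, 2, 3, 10, 11, 12),
                      rep(c(FALSE, TRUE), each = 3), b = 200, seed = 1)
  expect_equal(rb$auc, 1)
  expect_equal(unname(rb$auc_ci), c(1, 1))
  expect_equal(rb$youden, 1)
})

test_that("mean bootstrap AUC matches the binormal closed form across d", {
  for (d in c(0.5, 1, 1.81, 2.56)) {
    set.seed(round(100 * d))
    scores <- c(rnorm(60), rnorm(42, mean = d))
    labels <- rep(c(FALSE, TRUE), c(60, 42))
    rb <- bootstrap_roc(scores, labels, b = 1000, seed = 7)
    theory <- pnorm(d / sqrt(2))
    # 2 Monte-Carlo SEs of the empirical AUC at these sample sizes
    se <- sqrt(theory * (1 - theory) / min(60, 42))
    expect_lt(abs(rb$auc - theory), 2 * se + 0.02)
  }
})

test_that("null scores give an AUC interval covering 0.5", {
  set.seed(11)
  rb <- bootstrap_roc(rnorm(200), rep(c(FALSE, TRUE), 100), b = 500,
                      seed = 3)
  expect_lt(rb$auc_ci[1], 0.5)
  expect_gt(rb$auc_ci[2], 0.5)
})

test_that("the mean curve is monotone and consistent with per-iteration AUCs", {
  set.seed(12)
  rb <- bootstrap_roc(c(rnorm(50), rnorm(50, 1)),
                      rep(c(FALSE, TRUE), each = 50), b = 500, seed = 5)
  expect_true(all(diff(rb$mean_tpr) >= -1e-12))
  trap <- sum(diff(rb$fpr_grid) *
                (head(rb$mean_tpr, -1) + tail(rb$mean_tpr, -1)) / 2)
  expect_lt(abs(trap - rb$auc), 0.01)
  # determinism contract given the seed
  set.seed(12)
  sc <- c(rnorm(50), rnorm(50, 1))
  a <- bootstrap_roc(sc, rep(c(FALSE, TRUE), each = 50), b = 200, seed = 9)
  b <- bootstrap_roc(sc, rep(c(FALSE, TRUE), each = 50), b = 200, seed = 9)
  expect_identical(glance(a), glance(b))
})

test_that("the bootstrap AUC agrees with an independent ROC implementation", {
  set.seed(13)
  sc <- c(rnorm(40), rnorm(40, 1.2))
  lb <- rep(c(FALSE, TRUE), each = 40)
  ours <- bootstrap_roc(sc, lb, b = 1, seed = 1)$auc_full
  theirs <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lb, sc))))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("full-data cutoff maximizes J with ties toward specificity", {
  # separated toy scores: any threshold in (2, 3] is optimal; midpoint 2.5
  cut <- full_data_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(cut$threshold, 2.5)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
  # brute-force oracle on overlapping samples
  set.seed(14)
  sc <- round(c(rnorm(30), rnorm(30, 1)), 1)
  lb <- rep(c(FALSE, TRUE), each = 30)
  cut2 <- full_data_cutoff(sc, lb)
  js <- vapply(sort(unique(sc)), function(th) {
    sum(lb & sc >= th) / 30 + sum(!lb & sc < th) / 30 - 1
  }, numeric(1))
  expect_equal(cut2$j, max(js))
  # label flip leaves J invariant (orientation reversal)
  cut3 <- full_data_cutoff(-sc, !lb)
  expect_equal(cut3$j, cut2$j)
  # all-equal scores
  expect_equal(full_data_cutoff(rep(1, 6), rep(c(TRUE, FALSE), 3))$status,
               "all scores equal")
})

test_that("compare_groups gates pairwise testing on the global test", {
  co <- simulate_cohort_params(cohort_spec(seed = 6L))
  cg <- compare_groups(co, c("SAI", "AmpMaxInd"))
  expect_setequal(cg$global$parameter, c("SAI", "AmpMaxInd"))
  # the no-effect parameter is (almost surely) not carried to pairwise tests
  expect_true("SAI" %in% cg$pairwise$parameter)
  expect_equal(nrow(cg$pairwise[cg$pairwise$parameter == "SAI", ]), 3L)
})
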