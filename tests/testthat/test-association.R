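test_that("the published contingency tables and Fisher p-values come out of the catalog", {
  cat3 <- gabr_functional_catalog()
  t_del <- build_contingency(cat3, polyphen_category == "damaging",
                             reduced_current)
  expect_equal(unclass(t_del), matrix(c(9L, 1L, 9L, 13L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(round(fisher_exact_2x2(t_del), 4), 0.0189)
  t_dom <- build_contingency(cat3, domain %in% c("NT", "TM"), reduced_current)
  expect_equal(unclass(t_dom), matrix(c(14L, 3L, 4L, 11L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(round(fisher_exact_2x2(t_dom), 4), 0.0036)
  t_gat <- build_contingency(cat3, domain %in% c("NT", "TM"), gating_defect)
  expect_equal(unclass(t_gat), matrix(c(12L, 5L, 3L, 12L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(round(fisher_exact_2x2(t_gat), 4), 0.0060)
})

test_that("Fisher p matches stats::fisher.test and a no-association table gives 1", {
  expect_equal(fisher_exact_2x2(contingency_2x2(1, 1, 1, 1)), 1.0)
  set.seed(99)
  for (i in 1:30) {
    m <- matrix(rpois(4, 6), 2)
    if (sum(m) == 0) next
    expect_equal(fisher_exact_2x2(m), fisher.test(m)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(contingency_2x2(0, 0, 0, 0)),
               class = "gabrisk_bad_table")
})

test_that("Fisher p is invariant under simultaneous row/column transposition", {
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rpois(4, 5) + c(1, 0, 0, 0), 2)
    expect_equal(fisher_exact_2x2(m), fisher_exact_2x2(m[2:1, 2:1]))
    expect_equal(fisher_exact_2x2(m), fisher_exact_2x2(t(m)))
  }
})

test_that("empty predicates and records are rejected cleanly", {
  expect_error(build_contingency(gabr_functional_catalog(),
                                 humdiv_score, reduced_current),
               class = "gabrisk_bad_input")
  tab0 <- build_contingency(empty_cat <- gabr_functional_catalog()[0, ],
                            reduced_current, gating_defect)
  expect_equal(sum(tab0), 0)
  expect_error(fisher_exact_2x2(tab0), class = "gabrisk_bad_table")
})

test_that("group comparisons flag large shifts and only those", {
  set.seed(21)
  wt <- rnorm(20)
  groups <- list(shifted = rnorm(20, mean = 5), unshifted = rnorm(20))
  cmp <- compare_to_wt(wt, groups, test = "anova_dunnett")
  expect_true(cmp$significant[cmp$group == "shifted"])
  expect_false(cmp$significant[cmp$group == "unshifted"])
  # permutation oracle for the large effect
  pooled <- c(wt, groups$shifted)
  obs <- mean(groups$shifted) - mean(wt)
  perm <- replicate(500, {
    idx <- sample(40, 20)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  expect_lt(mean(abs(perm) >= abs(obs)), 0.01)
  cmp_t <- compare_to_wt(wt, groups, test = "t")
  expect_true(cmp_t$significant[cmp_t$group == "shifted"])
  expect_false(cmp_t$significant[cmp_t$group == "unshifted"])
})

test_that("identical groups give p-values near 1 and no flags", {
  vals <- rep(c(1, 2, 3, 4, 5), 3)
  cmp <- compare_to_wt(vals, list(a = vals, b = vals))
  expect_true(all(cmp$p_value > 0.999))
  expect_false(any(cmp$significant))
})

test_that("Dunnett adjusted p-values dominate the unadjusted two-sample p", {
  set.seed(7)
  wt <- rnorm(15)
  groups <- lapply(1:4, function(i) rnorm(15, mean = i / 4))
  names(groups) <- paste0("g", 1:4)
  cmp <- compare_to_wt(wt, groups, test = "anova_dunnett")
  unadj <- 2 * pt(-abs(cmp$statistic), df = cmp$df)
  expect_true(all(cmp$p_value >= unadj - 1e-12))
})

test_that("Dunnett machinery agrees with the multivariate-t reference", {
  skip_if_not_installed("mvtnorm")
  k <- 5; n <- 12; df <- (k + 1) * n - (k + 1)
  q <- dunnett_critical(0.05, rep(n, k), n, df)
  corr <- matrix(0.5, k, k); diag(corr) <- 1
  set.seed(1)
  p_ref <- mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                         df = df, corr = corr)
  expect_equal(as.numeric(p_ref), 0.95, tolerance = 2e-3)
  expect_equal(dunnett_prob(q, rep(n, k), n, df), 0.95, tolerance = 1e-5)
})

test_that("classification reproduces published calls from summary statistics", {
  # density comparisons (variant - wt) with their significance, plus the
  # gating ratio computed from the summary kinetics
  comp <- tibble::tibble(
    group = c("a1T441M", "b3V200I", "a1D9E"),
    p_value = c(1e-6, 0.01, 0.6),
    diff = c(411.7 - 871.4, 645.7 - 873.6, 725.7 - 871.4))
  ratios <- c(
    gating_impairment_ratio(1.574, 1.063, 51.31, 83.78)$ratio, # 2.42
    gating_impairment_ratio(1.624, 1.067, 120.0, 82.96)$ratio, # ~1.05
    gating_impairment_ratio(1.295, 1.063, 100.6, 83.78)$ratio) # ~1.01
  calls <- classify_variant(comp, ratios)
  expect_equal(calls$reduced_current, c(TRUE, TRUE, FALSE))
  expect_equal(calls$gating_defect, c(TRUE, FALSE, FALSE))
  # wild type against itself: never flagged
  self <- classify_variant(tibble::tibble(p_value = 1, diff = 0),
                           gating_impairment_ratio(1, 1, 1, 1))
  expect_false(self$reduced_current)
  expect_false(self$gating_defect)
  expect_error(classify_variant(tibble::tibble(x = 1), 1),
               class = "gabrisk_bad_input")
})
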