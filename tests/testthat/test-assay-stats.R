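test_that("doubling time reproduces the two-point formula", {
  expect_equal(doubling_time(c(3, 7.5), c(0.1, 0.8)), 1.5)
  expect_equal(doubling_time(c(4, 5.5), c(0.1, 0.2)), 1.5)
  # invariant to scaling all OD values
  expect_equal(doubling_time(c(3, 7.5), 50 * c(0.1, 0.8)), 1.5)
  expect_error(doubling_time(c(3, 7.5), c(0.1, -1)), "positive")
  expect_error(doubling_time(c(3, 4), c(0.1, 0.2), window = c(5, 7)),
               "window")
  expect_warning(out <- doubling_time(c(3, 7.5), c(0.8, 0.1)), "no growth")
  expect_true(is.na(out))
})

test_that("the multi-point fit reduces to the printed formula on two points", {
  set.seed(31)
  for (i in 1:25) {
    t1 <- runif(1, 3, 5)
    t2 <- runif(1, t1 + 0.5, 7.5)
    od <- sort(runif(2, 0.05, 1.5))
    lm_based <- doubling_time(c(t1, t2), od)
    printed <- (t2 - t1) * log(2) / log(od[2] / od[1])
    expect_equal(lm_based, printed)
  }
})

test_that("delta delta Ct gives exact powers of two", {
  tab <- data.frame(strain = rep(c("WT", "mut2x", "mut025"), each = 2),
                    replicate = rep(1:2, 3),
                    ct_target = c(20, 20, 19, 19, 22, 22),
                    ct_reference = rep(15, 6))
  out <- delta_delta_ct(tab)
  ps <- out$per_strain
  expect_equal(ps$rel_expr[ps$strain == "WT"], 1)
  expect_equal(ps$rel_expr[ps$strain == "mut2x"], 2)     # ddCt = -1
  expect_equal(ps$rel_expr[ps$strain == "mut025"], 0.25) # ddCt = +2
  # all-equal table gives 1 everywhere
  tab$ct_target <- 20
  expect_true(all(delta_delta_ct(tab)$per_strain$rel_expr == 1))
  # invariant to adding a constant to every Ct
  tab2 <- tab
  tab2$ct_target <- tab2$ct_target + 3.3
  tab2$ct_reference <- tab2$ct_reference + 3.3
  expect_equal(delta_delta_ct(tab2)$per_strain$rel_expr,
               delta_delta_ct(tab)$per_strain$rel_expr)
  tab$ct_reference[1] <- NA
  expect_error(delta_delta_ct(tab), "non-finite")
  expect_error(delta_delta_ct(data.frame(strain = "x", replicate = 1,
                                         ct_target = 1, ct_reference = 1),
                              baseline_strain = "WT"), "baseline")
})

test_that("normalizations divide by totals and by the WT mean", {
  expect_equal(normalize_to_total(100, 100), 1)
  expect_equal(normalize_to_total(c(a = 30, b = 60), c(a = 10, b = 20)),
               c(a = 3, b = 3))
  expect_error(normalize_to_total(c(lane1 = 5), c(lane1 = 0)), "lane1")
  vals <- c(2, 30)
  strains <- c("WT", "mut")
  out <- normalize_to_wt(vals, strains)
  expect_equal(out[2], 15)
  expect_equal(out[1], 1)
  # permutation invariance
  out_p <- normalize_to_wt(rev(vals), rev(strains))
  expect_equal(rev(out_p), out)
  expect_error(normalize_to_wt(1:3, c("a", "a", "b"), wt_strain = "WT"),
               "WT")
})

test_that("Welch t and ANOVA + Tukey handle the canonical cases", {
  x <- c(1, 2, 3, 4)
  two <- welch_t(x, x)
  expect_equal(two$statistic, 0)
  expect_equal(two$p_value, 1)
  expect_error(welch_t(c(1, 1), x, names = c("flat", "ok")), "flat")
  expect_error(welch_t(1, x, names = c("tiny", "ok")), "tiny")
  set.seed(8)
  res <- anova_tukey(list(a = rnorm(8), b = rnorm(8), c = rnorm(8, 4)))
  expect_equal(nrow(res$tukey), 3)
  expect_lt(res$tukey$p_adj[res$tukey$comparison == "c-a"], 0.01)
  expect_gt(res$tukey$p_adj[res$tukey$comparison == "b-a"], 0.05)
})
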