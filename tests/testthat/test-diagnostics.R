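# Decision engine, Dunn's test, equation-variant comparisons, summaries.

mk_distinct <- function(p13, p15, alpha = 0.05) {
  tibble::tibble(
    isotope = c("d13c", "d15n"),
    statistic = c(NA_real_, NA_real_),
    p_value = c(p13, p15),
    distinct = c(p13 < alpha, p15 < alpha),
    alpha_level = alpha,
    n_littoral = 10L, n_pelagic = 10L, exact = FALSE
  )
}

test_that("distinct baselines, few violations, equal lambdas -> raw LCU + tp2", {
  dx <- mk_distinct(0.001, 0.002)
  vs <- boundary_violation_stats(c(rep(0.5, 49), 1.2)) # 2% outside
  rec <- recommend_equations(dx, vs, lambdas_equal = TRUE)
  expect_equal(rec$ru_method, "lcu")
  expect_equal(rec$tp_method, "tp2")
  expect_equal(rec$alpha_source, "lcu")
  expect_length(rec$rationale, 3)
})

test_that("non-distinct d13C baselines -> one-source TP with pooled baseline", {
  dx <- mk_distinct(0.4, 0.001)
  vs <- boundary_violation_stats(c(0.2, 0.8))
  rec <- recommend_equations(dx, vs, lambdas_equal = TRUE)
  expect_equal(rec$ru_method, "not_applicable")
  expect_equal(rec$tp_method, "tp1_lbp")
  expect_equal(rec$alpha_source, "none")
})

test_that("heavy violations and unequal lambdas -> LCU_R + absolute-lambda TP", {
  dx <- mk_distinct(0.001, 0.002)
  vs <- boundary_violation_stats(c(rep(1.3, 4), rep(0.5, 6))) # 40% outside
  rec <- recommend_equations(dx, vs, lambdas_equal = FALSE)
  expect_equal(rec$ru_method, "lcu_r")
  expect_equal(rec$tp_method, "tp2_abs")
  expect_equal(rec$alpha_source, "lcu_r")
})

test_that("the recommendation is pure and its rationale traces the rules", {
  dx <- mk_distinct(0.001, 0.3) # d15N not distinct: caution logged
  vs <- boundary_violation_stats(c(0.2, 1.4, 0.5, 0.6))
  r1 <- recommend_equations(dx, vs, lambdas_equal = FALSE)
  r2 <- recommend_equations(dx, vs, lambdas_equal = FALSE)
  expect_identical(r1, r2)
  expect_true(any(grepl("Caution", r1$rationale)))
  expect_true(any(grepl("25.0%", r1$rationale))) # inputs recorded in trace
})

test_that("Dunn's test reproduces the hand oracle and Bonferroni inflates p", {
  pw <- dunn_test(1:6, rep(c("a", "b", "c"), each = 2))
  z_ac <- abs(pw$z[pw$group_a == "a" & pw$group_b == "c"])
  expect_equal(z_ac, 2.138, tolerance = 1e-2)
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-15))
  expect_true(all(pw$p_adjusted <= 1))
  expect_equal(nrow(pw), 3) # all unordered pairs
})

test_that("identical variant values give omnibus p = 1 and no flagged pairs", {
  rec <- tibble::tibble(
    specimen_id = as.character(1:5),
    lcu = rep(0.5, 5), lcu_adj = rep(0.5, 5), lcu_r = rep(0.5, 5)
  )
  cmp <- compare_equation_variants(rec, family = "lcu")
  expect_equal(cmp$omnibus$p_value, 1, tolerance = 1e-9)
  expect_equal(cmp$omnibus$statistic, 0)
  expect_false(any(cmp$pairwise$significant))
})

test_that("variant comparison reproduces the Kruskal-Wallis/Dunn oracles", {
  rec <- tibble::tibble(
    specimen_id = as.character(1:2),
    lcu = c(1, 2), lcu_adj = c(3, 4), lcu_r = c(5, 6)
  )
  cmp <- compare_equation_variants(rec, family = "lcu")
  expect_equal(cmp$omnibus$statistic, 4.571, tolerance = 1e-3)
  pair <- cmp$pairwise
  z13 <- abs(pair$z[pair$variant_a == "lcu" & pair$variant_b == "lcu_r"])
  expect_equal(z13, 2.138, tolerance = 1e-2)
  # omnibus is invariant to relabeling of variants
  rec2 <- rec
  names(rec2)[2:4] <- c("lcu_r", "lcu", "lcu_adj")
  cmp2 <- compare_equation_variants(rec2, family = "lcu")
  expect_equal(cmp2$omnibus$statistic, cmp$omnibus$statistic)
  expect_error(
    compare_equation_variants(rec[1, ], family = "lcu"),
    class = "lcutools_error"
  )
})

test_that("a 3.4 permil baseline gap flags the two one-source TPs apart", {
  set.seed(31)
  em <- em_default(d15n_littoral = 7.4, d15n_pelagic = 4) # gap = delta_n
  cons <- consumer_tbl(
    d13c = rnorm(50, -24, 0.5),
    d15n = rnorm(50, 12, 0.3)
  )
  rec <- compute_metric_suite(cons, em)
  cmp <- compare_equation_variants(rec, family = "tp")
  pair <- cmp$pairwise
  hit <- pair[pair$variant_a == "tp1_lb" & pair$variant_b == "tp1_p" |
    pair$variant_a == "tp1_p" & pair$variant_b == "tp1_lb", ]
  expect_true(hit$significant) # construction forces a 1.0 TP shift
})

test_that("paired alternative runs and agrees on the obvious construction", {
  set.seed(32)
  rec <- tibble::tibble(
    specimen_id = as.character(1:20),
    lcu = runif(20), lcu_adj = runif(20) + 2, lcu_r = runif(20)
  )
  cmp <- compare_equation_variants(rec, family = "lcu", paired = TRUE)
  expect_equal(cmp$omnibus$method, "friedman")
  pair <- cmp$pairwise
  expect_true(pair$significant[pair$variant_a == "lcu" &
    pair$variant_b == "lcu_adj"])
})

test_that("summarize_metrics computes group statistics and outside percent", {
  rec <- tibble::tibble(
    specimen_id = c("a", "b"), species = "fish",
    lcu = c(0.4, 0.8), lcu_adj = c(0.4, 0.8), lcu_r = c(0, 1)
  )
  sm <- summarize_metrics(rec, by = "species")
  lcu_row <- sm[sm$metric == "lcu", ]
  expect_equal(lcu_row$mean, 0.6)
  expect_equal(lcu_row$sd, 0.2828, tolerance = 1e-3)
  expect_equal(lcu_row$min, 0.4)
  expect_equal(lcu_row$pct_outside, 0)
  # single record: mean equals the record and SD is 0
  sm1 <- summarize_metrics(rec[1, ], by = "species")
  expect_equal(sm1$sd, rep(0, nrow(sm1)))
  expect_equal(sm1$mean[sm1$metric == "lcu"], 0.4)
  # cohort constructed entirely above 1
  rec_out <- tibble::tibble(
    specimen_id = as.character(1:4), species = "x",
    lcu = c(1.1, 1.5, 2, 1.2)
  )
  sm_out <- summarize_metrics(rec_out, by = "species")
  expect_equal(sm_out$pct_outside[sm_out$metric == "lcu"], 100)
})

test_that("group-mean LCU in summaries matches LCU of the group-mean d13C", {
  set.seed(33)
  em <- em_default()
  cons <- consumer_tbl(d13c = rnorm(30, -23, 2), d15n = rnorm(30, 11, 1))
  rec <- compute_metric_suite(cons, em)
  rec$species <- "fish"
  sm <- summarize_metrics(rec, by = "species")
  expect_equal(
    sm$mean[sm$metric == "lcu"],
    compute_lcu(mean(cons$d13c), em),
    tolerance = 1e-12
  )
})
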