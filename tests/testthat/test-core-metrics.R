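# Mixing-model and trophic-position equations against hand-computed values.

test_that("LCU solves the two-endmember mixing model, unclipped", {
  em <- em_default()
  expect_equal(compute_lcu(em$d13c_littoral, em), 1.0)
  expect_equal(compute_lcu(em$d13c_pelagic, em), 0.0)
  expect_equal(compute_lcu(-24, em), 0.5)
  expect_equal(compute_lcu(-18, em), 1.25) # outside [0,1], returned raw
  expect_error(
    compute_lcu(-24, endmember_set(-25, -25, 6, 4)),
    class = "lcutools_degenerate_endmembers"
  )
})

test_that("clipping forces LCU into [0,1] and rescaling spans the range", {
  expect_equal(clip_lcu(c(1.3, -0.2, 0.6)), c(1, 0, 0.6))
  expect_equal(rescale_lcu(c(0.2, 0.6, 1.0)), c(0, 0.5, 1))
  expect_equal(rescale_lcu(c(-0.4, 1.6)), c(0, 1))
  v <- c(0.13, 0.92, 0.4, -0.3, 1.7)
  r <- rescale_lcu(v)
  expect_equal(r[which.min(v)], 0)
  expect_equal(r[which.max(v)], 1)
  expect_error(rescale_lcu(0.5), class = "lcutools_error")
  expect_error(rescale_lcu(c(0.4, 0.4)), class = "lcutools_degenerate_range")
})

test_that("forward mixing model hits the endmembers at alpha 0 and 1", {
  em <- em_default()
  expect_equal(mix_d13c(1, em), em$d13c_littoral)
  expect_equal(mix_d13c(0, em), em$d13c_pelagic)
  expect_equal(mix_d13c(0.5, em), -24)
})

test_that("one-source TP follows the baseline-corrected d15N ladder", {
  expect_equal(tp_one_source(5.2, 5.2, lambda = 2), 2)
  expect_equal(tp_one_source(5.2 + 3.4, 5.2, lambda = 2, delta_n = 3.4), 3)
  expect_equal(tp_one_source(12, 5.2, lambda = 2, delta_n = 3.4), 4)
  expect_error(tp_one_source(12, 5.2, delta_n = 0), class = "lcutools_error")
  expect_error(tp_one_source(12, 5.2, delta_n = -1), class = "lcutools_error")
})

test_that("two-source TP mixes the d15N baselines by alpha", {
  em <- em_default()
  expect_equal(
    tp_two_source(10, 1, em),
    tp_one_source(10, em$d15n_littoral)
  )
  expect_equal(
    tp_two_source(10, 0, em),
    tp_one_source(10, em$d15n_pelagic)
  )
  expect_equal(tp_two_source(10, 0.5, em), 3.4706, tolerance = 1e-4)
})

test_that("absolute-lambda TP weights the baseline trophic positions", {
  em <- em_default(lambda_littoral = 2.25, lambda_pelagic = 2.0)
  expect_equal(tp_two_source_abs(10, 0.4, em), 3.6294, tolerance = 1e-4)
  expect_equal(
    tp_two_source_abs(10, 1, em),
    em$lambda_littoral + (10 - em$d15n_littoral) / 3.4
  )
  # equal lambdas reduce to the plain two-source equation
  em_eq <- em_default(lambda_littoral = 2, lambda_pelagic = 2)
  for (a in c(-0.3, 0, 0.42, 1, 1.6)) {
    expect_equal(tp_two_source_abs(10, a, em_eq), tp_two_source(10, a, em_eq))
  }
})

test_that("pooled baseline averages specimens (or habitat means) as asked", {
  bl <- tibble::tibble(
    role = c("littoral_baseline", "pelagic_baseline"),
    d15n = c(6, 4)
  )
  expect_equal(pooled_baseline(bl), 5)
  same <- tibble::tibble(
    role = rep(c("littoral_baseline", "pelagic_baseline"), 3),
    d15n = rep(7.3, 6)
  )
  expect_equal(pooled_baseline(same), 7.3)
  expect_error(pooled_baseline(same[0, ]), class = "lcutools_error")
  expect_error(
    pooled_baseline(bl[bl$role == "littoral_baseline", ]),
    class = "lcutools_error"
  )
  # unbalanced counts: specimen pooling weights by n, habitat means do not
  unbal <- tibble::tibble(
    role = c(rep("littoral_baseline", 3), "pelagic_baseline"),
    d15n = c(6, 6, 6, 4)
  )
  expect_equal(pooled_baseline(unbal, "specimens"), 5.5)
  expect_equal(pooled_baseline(unbal, "habitat_means"), 5)
})

test_that("metric suite cascades identities at the littoral endmember", {
  em <- em_default(lambda_littoral = 2.25, lambda_pelagic = 2.0)
  one <- tibble::tibble(
    specimen_id = "x", d13c = em$d13c_littoral, d15n = em$d15n_littoral
  )
  rec <- compute_metric_suite(one, em)
  expect_equal(rec$lcu, 1)
  expect_equal(rec$tp1_lb, 2) # lambda_default
  expect_equal(rec$tp2, rec$tp1_lb)
  expect_equal(rec$tp2abs, em$lambda_littoral) # consumer at baseline
  expect_true(is.na(rec$lcu_r)) # undefined for a single consumer
})

test_that("metric suite recovers alpha exactly for forward-model cohorts", {
  em <- em_default(lambda_littoral = 2.25, lambda_pelagic = 2.0)
  alpha <- c(-0.2, 0, 0.25, 0.5, 0.8, 1, 1.2)
  cons <- tibble::tibble(
    specimen_id = as.character(seq_along(alpha)),
    d13c = mix_d13c(alpha, em),
    d15n = tp_two_source(0, alpha, em) * 0 + 10 # fixed d15n
  )
  rec <- compute_metric_suite(cons, em)
  expect_equal(rec$lcu, alpha, tolerance = 1e-12)
  # all nine TP columns present and finite
  tp_cols <- c(
    "tp1_lb", "tp1_p", "tp1_lbp", "tp2", "tp2_adj", "tp2_r",
    "tp2abs", "tp2abs_adj", "tp2abs_r"
  )
  expect_true(all(tp_cols %in% names(rec)))
  expect_true(all(is.finite(as.matrix(rec[, tp_cols]))))
  # algebraic identity linking the absolute-lambda and plain variants
  lam <- 2
  shift <- rec$lcu * (em$lambda_littoral - lam) +
    (1 - rec$lcu) * (em$lambda_pelagic - lam)
  expect_equal(rec$tp2abs - rec$tp2, shift, tolerance = 1e-12)
})

test_that("boundary violation accounting treats the bounds as inside", {
  v <- boundary_violation_stats(c(0.1, 0.5, 0.9))
  expect_equal(v$pct_outside, 0)
  expect_false(v$exceeds_threshold)
  v2 <- boundary_violation_stats(c(1.2, -0.1, 0.5, 0.7), threshold = 0.05)
  expect_equal(v2$n_above_1, 1)
  expect_equal(v2$n_below_0, 1)
  expect_equal(v2$pct_outside, 50)
  expect_true(v2$exceeds_threshold)
  v3 <- boundary_violation_stats(c(0, 1))
  expect_equal(v3$pct_outside, 0)
  expect_error(boundary_violation_stats(numeric(0)), class = "lcutools_error")
})

test_that("endmember and config constructors validate their inputs", {
  expect_error(endmember_set(NA, -28, 6, 4), class = "lcutools_error")
  expect_error(endmember_set(-20, -28, 6, 4, lambda_littoral = 0.5),
    class = "lcutools_error"
  )
  expect_error(metric_config(delta_n = -1), class = "lcutools_error")
  expect_error(metric_config(violation_threshold = 1.5),
    class = "lcutools_error"
  )
})
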