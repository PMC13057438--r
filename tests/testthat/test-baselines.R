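# Endmember construction, habitat-distinctness tests, grouping screens and
# policy-driven endmember resolution.

test_that("aggregate_endmembers takes per-habitat means and records counts", {
  bl <- tibble::tibble(
    specimen_id = as.character(1:3),
    species = c("mayfly", "mayfly", "mussel"),
    role = c("littoral_baseline", "littoral_baseline", "pelagic_baseline"),
    tissue = "whole", season = "all", stratum = "main",
    d13c = c(-20, -22, -28), d15n = c(6, 7, 4)
  )
  em <- aggregate_endmembers(bl, lambdas = c(littoral = 2.25, pelagic = 2))
  expect_equal(em$d13c_littoral, -21)
  expect_equal(em$d15n_littoral, 6.5)
  expect_equal(em$d13c_pelagic, -28)
  expect_equal(em$n_littoral, 2L)
  expect_equal(em$n_pelagic, 1L)
  expect_equal(em$lambda_littoral, 2.25)
  # permutation invariance
  em2 <- aggregate_endmembers(bl[c(3, 1, 2), ],
    lambdas = c(littoral = 2.25, pelagic = 2)
  )
  expect_equal(unclass(em2), unclass(em))
  # missing habitat in scope errors, naming the habitat
  expect_error(
    aggregate_endmembers(bl[1:2, ]),
    regexp = "pelagic", class = "lcutools_error"
  )
})

test_that("distinctness test matches exact enumeration on tiny groups", {
  lit <- tibble::tibble(d13c = c(1, 2), d15n = c(1, 2))
  pel <- tibble::tibble(d13c = c(3, 4), d15n = c(3, 4))
  rep <- test_habitat_distinctness(lit, pel)
  expect_equal(rep$p_value, c(1 / 3, 1 / 3), tolerance = 1e-12)
  expect_true(all(rep$exact))
  expect_false(any(rep$distinct))
})

test_that("identical baseline groups are maximally indistinct (p = 1)", {
  x <- tibble::tibble(d13c = c(-20, -21, -22), d15n = c(5, 6, 7))
  rep <- test_habitat_distinctness(x, x)
  expect_equal(rep$p_value, c(1, 1), tolerance = 1e-6)
  expect_false(any(rep$distinct))
})

test_that("well-separated baselines are flagged distinct", {
  set.seed(21)
  lit <- tibble::tibble(d13c = rnorm(20, -20, 0.3), d15n = rnorm(20, 6, 0.3))
  pel <- tibble::tibble(d13c = rnorm(20, -24, 0.3), d15n = rnorm(20, 4, 0.3))
  rep <- test_habitat_distinctness(lit, pel)
  expect_true(all(rep$distinct))
  # symmetry under swapping the groups
  rep_sw <- test_habitat_distinctness(pel, lit)
  expect_equal(rep$p_value, rep_sw$p_value, tolerance = 1e-12)
  expect_error(
    test_habitat_distinctness(lit[1, , drop = FALSE], pel),
    class = "lcutools_error"
  )
})

test_that("exact and approximate rank-sum branches agree on tie-free data", {
  set.seed(22)
  for (i in 1:30) {
    a <- rnorm(8, 0, 1)
    b <- rnorm(8, runif(1, 0, 1.5), 1)
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
    p_approx <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(p_exact - p_approx), 0.05)
  }
})

test_that("grouping screen reproduces the Kruskal-Wallis hand oracle", {
  samples <- tibble::tibble(
    specimen_id = as.character(1:6), species = "fish", role = "consumer",
    tissue = "muscle", season = "all",
    stratum = rep(c("a", "b", "c"), each = 2),
    d13c = c(1, 2, 3, 4, 5, 6), d15n = c(1, 2, 3, 4, 5, 6)
  )
  rep <- screen_grouping_factors(samples, "stratum")
  expect_equal(nrow(rep), 2) # one row per isotope
  expect_equal(rep$statistic, c(4.571, 4.571), tolerance = 1e-3)
  expect_equal(rep$method, rep("kruskal_dunn", 2))
  pw <- rep$pairwise[[1]]
  z_ac <- pw$z[pw$group_a == "a" & pw$group_b == "c" |
    pw$group_a == "c" & pw$group_b == "a"]
  expect_equal(abs(z_ac), 2.138, tolerance = 1e-2)
})

test_that("two identical levels yield p = 1 and insufficient levels error", {
  samples <- tibble::tibble(
    specimen_id = as.character(1:6), species = "fish", role = "consumer",
    tissue = "muscle", season = rep(c("May", "August"), each = 3),
    stratum = "main",
    d13c = rep(c(-20, -21, -22), 2), d15n = rep(c(5, 6, 7), 2)
  )
  rep <- screen_grouping_factors(samples, "season")
  expect_equal(rep$method, rep("wilcoxon", 2))
  expect_equal(rep$p_value, c(1, 1), tolerance = 1e-6)
  expect_error(
    screen_grouping_factors(samples[samples$season == "May", ], "season"),
    class = "lcutools_error"
  )
})

test_that("season screen splits by tissue when several tissues are present", {
  set.seed(24)
  mk <- function(tissue, shift) {
    tibble::tibble(
      specimen_id = paste0(tissue, 1:20), species = "lake_trout",
      role = "consumer", tissue = tissue,
      season = rep(c("May", "August"), each = 10), stratum = "main",
      d13c = rnorm(20, -24, 0.2) + rep(c(0, shift), each = 10),
      d15n = rnorm(20, 10, 0.2) + rep(c(0, shift), each = 10)
    )
  }
  samples <- dplyr::bind_rows(mk("muscle", 0), mk("liver", 2))
  rep <- screen_grouping_factors(samples, "season")
  expect_true("tissue" %in% names(rep))
  liver <- rep[rep$tissue == "liver", ]
  muscle <- rep[rep$tissue == "muscle", ]
  expect_true(all(liver$significant))
  expect_false(any(muscle$significant))
})

test_that("endmember resolution follows the stratum and tissue policy", {
  bl <- dplyr::bind_rows(
    baseline_tbl(5, season = "May", seed = 1),
    baseline_tbl(5,
      d13c = c(littoral = -19, pelagic = -27), season = "August", seed = 2
    )
  )
  pol <- grouping_policy(stratum_matching = FALSE)
  emt <- build_endmember_table(bl, pol, c(littoral = 2.25, pelagic = 2))
  # pooled + one per season
  expect_setequal(emt$season, c("all", "May", "August"))
  liver_fish <- list(stratum = "main", season = "May", tissue = "liver")
  muscle_fish <- list(stratum = "main", season = "May", tissue = "muscle")
  em_liver <- resolve_endmembers(liver_fish, emt, pol)
  em_muscle <- resolve_endmembers(muscle_fish, emt, pol)
  expect_equal(em_liver$season, "May")
  expect_equal(em_muscle$season, "all")
  # a consumer from an unknown stratum errors, listing available scopes
  pol2 <- grouping_policy(stratum_matching = TRUE)
  emt2 <- build_endmember_table(bl, pol2, c(littoral = 2.25, pelagic = 2))
  expect_error(
    resolve_endmembers(
      list(stratum = "nowhere", season = "May", tissue = "muscle"),
      emt2, pol2
    ),
    regexp = "Available scopes", class = "lcutools_error"
  )
})

test_that("grouping policy validates its season rules", {
  expect_error(grouping_policy(season_matching = c(muscle = "sometimes")),
    class = "lcutools_error"
  )
  pol <- grouping_policy()
  expect_true(pol$stratum_matching)
  expect_equal(unname(pol$season_matching[["liver"]]), "match_season")
})
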