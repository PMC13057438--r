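# Nonparametric helpers shared by the baseline screens and the
# equation-comparison reports. Wilcoxon and Kruskal-Wallis come from stats;
# Dunn's post hoc test is implemented here on pooled mid-ranks.

#' Dunn's post hoc test
#'
#' Pairwise z-tests on pooled mid-ranks, the standard follow-up to a
#' significant Kruskal-Wallis omnibus. For groups i and j,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))` with the
#' tie correction `T = sum(t^3 - t) / (12 (N - 1))` over tie groups of size
#' t. P-values are two-sided normal tails, adjusted for multiple comparisons
#' (Bonferroni by default).
#'
#' @param x Numeric vector of observations.
#' @param g Grouping vector (coerced to factor), same length as `x`.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @param alpha_level Significance level for the `significant` flag.
#' @return A tibble with one row per unordered group pair: `group_a`,
#'   `group_b`, `z`, `p_value`, `p_adjusted`, `significant`.
#' @examples
#' dunn_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
#' @export
dunn_test <- function(x, g, p_adjust = "bonferroni", alpha_level = 0.05) {
  g <- factor(g)
  if (nlevels(g) < 2) {
    abort("Dunn's test needs at least two groups.", class = "lcutools_error")
  }
  keep <- is.finite(x)
  x <- x[keep]
  g <- droplevels(g[keep])
  n <- length(x)
  r <- rank(x) # mid-ranks
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  var_core <- n * (n + 1) / 12 - tie_term
  rbar <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    se2 <- var_core * (1 / sizes[[a]] + 1 / sizes[[b]])
    if (se2 <= 0) {
      # every observation tied: no evidence of any difference
      z[k] <- 0
      p_raw[k] <- 1
    } else {
      z[k] <- (rbar[[a]] - rbar[[b]]) / sqrt(se2)
      p_raw[k] <- 2 * pnorm(-abs(z[k]))
    }
  }
  p_adj <- pmin(p.adjust(p_raw, method = p_adjust), 1)
  tibble::tibble(
    group_a = pairs[1, ],
    group_b = pairs[2, ],
    z = z,
    p_value = p_raw,
    p_adjusted = p_adj,
    significant = p_adj < alpha_level
  )
}

# Two-sided Wilcoxon rank-sum with the branch rule used throughout the
# package: exact enumeration when both groups have <= 8 tie-free
# observations, tie-corrected normal approximation (with continuity
# correction) otherwise. Returns list(statistic, p_value, exact).
rank_sum_test <- function(a, b) {
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !anyDuplicated(c(a, b))
  res <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  p <- res$p.value
  if (is.nan(p)) p <- 1 # identical constant groups: approximation degenerates
  list(statistic = unname(res$statistic), p_value = min(p, 1), exact = exact)
}

# Kruskal-Wallis that tolerates an all-tied input (stats::kruskal.test
# returns NaN there because the tie correction divides by zero); identical
# values across groups carry no evidence, so statistic 0 / p 1.
kruskal_omnibus <- function(x, g) {
  g <- factor(g)
  if (diff(range(x)) == 0) {
    return(list(statistic = 0, df = nlevels(g) - 1, p_value = 1))
  }
  res <- kruskal.test(x, g)
  list(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value
  )
}

#' Advisory distribution screens
#'
#' Shapiro-Wilk normality and Levene variance-homogeneity checks, run per
#' group. These are diagnostics only: they log a recommendation and the
#' pipeline proceeds nonparametrically regardless, which is why every
#' downstream comparison uses rank tests.
#'
#' @param x Numeric observations.
#' @param g Grouping vector.
#' @return A tibble with one row per test (`shapiro_wilk` per group,
#'   `levene` overall): `test`, `group`, `statistic`, `p_value`, `pass`.
#' @export
assumption_screens <- function(x, g) {
  g <- factor(g)
  rows <- lapply(levels(g), function(lev) {
    xi <- x[g == lev]
    if (length(xi) < 3 || diff(range(xi)) == 0) {
      return(tibble::tibble(
        test = "shapiro_wilk", group = lev,
        statistic = NA_real_, p_value = NA_real_, pass = NA
      ))
    }
    sw <- shapiro.test(xi)
    tibble::tibble(
      test = "shapiro_wilk", group = lev,
      statistic = unname(sw$statistic), p_value = sw$p.value,
      pass = sw$p.value >= 0.05
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nlevels(g) >= 2 && requireNamespace("car", quietly = TRUE)) {
    lv <- car::leveneTest(x, g)
    out <- dplyr::bind_rows(out, tibble::tibble(
      test = "levene", group = "all",
      statistic = lv[1, "F value"], p_value = lv[1, "Pr(>F)"],
      pass = lv[1, "Pr(>F)"] >= 0.05
    ))
  }
  out
}
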