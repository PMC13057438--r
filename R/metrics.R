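# Core mixing-model and trophic-position equations.
#
# All isotope values are per-mil: d13c vs VPDB, d15n vs atmospheric N2.
# No unit conversion is performed anywhere in the package.

#' Littoral and pelagic baseline endmembers
#'
#' Bundles the mean isotope values of the two habitat baselines together with
#' their assumed trophic positions (lambda) and the scope (stratum, season)
#' the set applies to. The littoral/benthic endmember anchors nearshore carbon
#' (typically enriched in 13C); the pelagic endmember anchors open-water
#' carbon.
#'
#' @param d13c_littoral,d13c_pelagic Mean baseline d13C per habitat (per mil).
#' @param d15n_littoral,d15n_pelagic Mean baseline d15N per habitat (per mil).
#' @param lambda_littoral,lambda_pelagic Assumed trophic position of each
#'   baseline taxon (dimensionless, >= 1). Strict primary consumers sit at 2;
#'   omnivorous macroinvertebrates somewhat higher (e.g. mayfly 2.25,
#'   oligochaete 2.5).
#' @param n_littoral,n_pelagic Number of baseline specimens behind each mean.
#' @param stratum,season Labels recording the scope this set was built for
#'   (`"all"` means pooled).
#'
#' @return An object of class `endmember_set`.
#' @examples
#' endmember_set(-20, -28, 6, 4, lambda_littoral = 2.25)
#' @export
endmember_set <- function(d13c_littoral, d13c_pelagic,
                          d15n_littoral, d15n_pelagic,
                          lambda_littoral = 2, lambda_pelagic = 2,
                          n_littoral = 1L, n_pelagic = 1L,
                          stratum = "all", season = "all") {
  means <- c(d13c_littoral, d13c_pelagic, d15n_littoral, d15n_pelagic)
  if (!all(is.finite(means))) {
    abort("All endmember means must be finite.", class = "lcutools_error")
  }
  if (lambda_littoral < 1 || lambda_pelagic < 1) {
    abort("Baseline lambda values must be >= 1.", class = "lcutools_error")
  }
  if (n_littoral < 1 || n_pelagic < 1) {
    abort("Endmember sample counts must be >= 1.", class = "lcutools_error")
  }
  structure(
    list(
      d13c_littoral = as.numeric(d13c_littoral),
      d13c_pelagic = as.numeric(d13c_pelagic),
      d15n_littoral = as.numeric(d15n_littoral),
      d15n_pelagic = as.numeric(d15n_pelagic),
      lambda_littoral = as.numeric(lambda_littoral),
      lambda_pelagic = as.numeric(lambda_pelagic),
      n_littoral = as.integer(n_littoral),
      n_pelagic = as.integer(n_pelagic),
      stratum = as.character(stratum),
      season = as.character(season)
    ),
    class = "endmember_set"
  )
}

#' @export
print.endmember_set <- function(x, ...) {
  cat("<endmember_set>  scope: stratum =", x$stratum, "| season =", x$season, "\n")
  cat(sprintf(
    "  littoral: d13C %+.2f  d15N %+.2f  lambda %.2f  (n = %d)\n",
    x$d13c_littoral, x$d15n_littoral, x$lambda_littoral, x$n_littoral
  ))
  cat(sprintf(
    "  pelagic:  d13C %+.2f  d15N %+.2f  lambda %.2f  (n = %d)\n",
    x$d13c_pelagic, x$d15n_pelagic, x$lambda_pelagic, x$n_pelagic
  ))
  invisible(x)
}

#' Configuration of the metric suite
#'
#' @param delta_n Diet-tissue discrimination factor for d15N, i.e. per-mil
#'   enrichment per trophic step. Default 3.4.
#' @param lambda_default Assumed trophic position applied to all baselines in
#'   the one-source and plain two-source TP equations. Default 2.
#' @param violation_threshold Fraction of a population allowed outside the
#'   `[0, 1]` LCU bounds before the range-rescaled scaling is recommended.
#'   Default 0.05.
#' @param rescale_scope Whether the LCU_R min/max is taken over the whole
#'   analysis group (`"per_system"`, default) or within each stratum
#'   (`"per_stratum"`).
#' @param pooling How the combined-baseline d15N used by the pooled one-source
#'   TP is formed: mean over all individual baseline specimens
#'   (`"specimens"`, default) or mean of the two habitat means
#'   (`"habitat_means"`).
#'
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(delta_n = 3.4, lambda_default = 2,
                          violation_threshold = 0.05,
                          rescale_scope = c("per_system", "per_stratum"),
                          pooling = c("specimens", "habitat_means")) {
  if (!is.numeric(delta_n) || delta_n <= 0) {
    abort("`delta_n` must be a positive number.", class = "lcutools_error")
  }
  if (violation_threshold <= 0 || violation_threshold >= 1) {
    abort("`violation_threshold` must lie strictly between 0 and 1.",
      class = "lcutools_error"
    )
  }
  structure(
    list(
      delta_n = delta_n,
      lambda_default = lambda_default,
      violation_threshold = violation_threshold,
      rescale_scope = match.arg(rescale_scope),
      pooling = match.arg(pooling)
    ),
    class = "metric_config"
  )
}

#' Littoral carbon use (two-endmember mixing model)
#'
#' Solves the two-source d13C mixing model for the proportion of a consumer's
#' carbon derived from the littoral/benthic food-web base:
#' `LCU = (d13C_consumer - d13C_P) / (d13C_LB - d13C_P)`.
#' Values near 1 indicate littoral reliance, near 0 pelagic reliance. The raw
#' value is returned unclipped: it falls outside `[0, 1]` whenever the
#' baselines do not bracket the consumer.
#'
#' @param d13c_consumer Numeric vector of consumer d13C values (per mil).
#' @param endmembers An [endmember_set()].
#' @return Numeric vector of dimensionless LCU values, unbounded.
#' @seealso [clip_lcu()], [rescale_lcu()], [mix_d13c()]
#' @examples
#' em <- endmember_set(-20, -28, 6, 4)
#' compute_lcu(c(-24, -18), em) # 0.5, 1.25
#' @export
compute_lcu <- function(d13c_consumer, endmembers) {
  stopifnot(inherits(endmembers, "endmember_set"))
  spread <- endmembers$d13c_littoral - endmembers$d13c_pelagic
  if (spread == 0) {
    abort(
      paste(
        "Littoral and pelagic baseline d13C means are equal: the mixing",
        "model is degenerate. This signals a one-source system; use a",
        "one-source trophic position with a pooled baseline instead."
      ),
      class = c("lcutools_degenerate_endmembers", "lcutools_error")
    )
  }
  (d13c_consumer - endmembers$d13c_pelagic) / spread
}

#' Clip littoral carbon use to the unit interval
#'
#' The adjusted scaling (LCU_adj): values above 1 are set to 1 and values
#' below 0 to 0. Clipping removes out-of-bound variation at the cost of
#' piling mass on the extremes.
#'
#' @param lcu Numeric vector of raw LCU values.
#' @return Values clipped into `[0, 1]`.
#' @export
clip_lcu <- function(lcu) {
  if (!all(is.finite(lcu))) {
    abort("`lcu` must be finite.", class = "lcutools_error")
  }
  pmin(pmax(lcu, 0), 1)
}

#' Rescale littoral carbon use to the observed system range
#'
#' The relative scaling (LCU_R): each value is mapped to
#' `(x - min) / (max - min)` using the minimum and maximum raw LCU observed
#' across all organisms in the analysis group. The consumer with the lowest
#' d13C maps to 0 and the highest to 1, preserving relative variability when
#' the sampled baselines do not span the consumers.
#'
#' @param lcu_values Numeric vector of raw LCU values (length >= 2).
#' @return Numeric vector in `[0, 1]`, same order as the input.
#' @export
rescale_lcu <- function(lcu_values) {
  if (length(lcu_values) < 2) {
    abort("Range rescaling needs at least two values.", class = "lcutools_error")
  }
  rng <- range(lcu_values)
  if (rng[1] == rng[2]) {
    abort("All LCU values are equal: range rescaling is undefined.",
      class = c("lcutools_degenerate_range", "lcutools_error")
    )
  }
  (lcu_values - rng[1]) / (rng[2] - rng[1])
}

#' Forward two-source mixing model for d13C
#'
#' The inverse of [compute_lcu()]: predicts a consumer's d13C from its
#' littoral carbon proportion, `alpha * d13C_LB + (1 - alpha) * d13C_P`.
#' `alpha` is deliberately not restricted to `[0, 1]` so out-of-bound mixtures
#' round-trip exactly.
#'
#' @param alpha Numeric vector of littoral carbon proportions.
#' @inheritParams compute_lcu
#' @return Predicted consumer d13C (per mil).
#' @export
mix_d13c <- function(alpha, endmembers) {
  stopifnot(inherits(endmembers, "endmember_set"))
  alpha * endmembers$d13c_littoral + (1 - alpha) * endmembers$d13c_pelagic
}

#' One-source trophic position
#'
#' `TP1 = lambda + (d15N_consumer - d15N_base) / delta_n`, where `lambda` is
#' the assumed trophic position of the baseline organisms and `delta_n` the
#' per-step d15N enrichment.
#'
#' @param d15n_consumer Numeric vector of consumer d15N (per mil).
#' @param d15n_base Baseline d15N (per mil).
#' @param lambda Assumed trophic position of the baseline. Default 2.
#' @param delta_n Diet-tissue discrimination factor (per mil per trophic
#'   step, > 0). Default 3.4.
#' @return Numeric vector of trophic positions.
#' @export
tp_one_source <- function(d15n_consumer, d15n_base, lambda = 2, delta_n = 3.4) {
  check_delta_n(delta_n)
  lambda + (d15n_consumer - d15n_base) / delta_n
}

#' Two-source trophic position
#'
#' `TP2 = lambda + (d15N_consumer - (alpha * d15N_LB + (1 - alpha) * d15N_P))
#' / delta_n`. The carbon-source proportion `alpha` is one of the LCU
#' scalings; out-of-bound values are accepted unmodified so that the raw-LCU
#' variant propagates exactly as observed.
#'
#' @inheritParams tp_one_source
#' @param alpha Littoral carbon proportion(s) plugged into the d15N baseline
#'   mixture (LCU, LCU_adj or LCU_R).
#' @param endmembers An [endmember_set()] supplying the two d15N baselines.
#' @return Numeric vector of trophic positions.
#' @export
tp_two_source <- function(d15n_consumer, alpha, endmembers, lambda = 2,
                          delta_n = 3.4) {
  stopifnot(inherits(endmembers, "endmember_set"))
  check_delta_n(delta_n)
  base <- alpha * endmembers$d15n_littoral + (1 - alpha) * endmembers$d15n_pelagic
  lambda + (d15n_consumer - base) / delta_n
}

#' Two-source trophic position with absolute lambda
#'
#' Extends the two-source equation to baselines that occupy different assumed
#' trophic positions: the single lambda is replaced by the alpha-weighted
#' mixture `lambda_LB * alpha + lambda_P * (1 - alpha)` carried by the
#' endmember set.
#'
#' @inheritParams tp_two_source
#' @return Numeric vector of trophic positions.
#' @export
tp_two_source_abs <- function(d15n_consumer, alpha, endmembers, delta_n = 3.4) {
  stopifnot(inherits(endmembers, "endmember_set"))
  check_delta_n(delta_n)
  lambda_abs <- alpha * endmembers$lambda_littoral +
    (1 - alpha) * endmembers$lambda_pelagic
  base <- alpha * endmembers$d15n_littoral + (1 - alpha) * endmembers$d15n_pelagic
  lambda_abs + (d15n_consumer - base) / delta_n
}

check_delta_n <- function(delta_n) {
  if (!is.numeric(delta_n) || length(delta_n) != 1 || !is.finite(delta_n) ||
    delta_n <= 0) {
    abort("`delta_n` must be a single positive number.",
      class = "lcutools_error"
    )
  }
  invisible(delta_n)
}

#' Pooled baseline d15N
#'
#' The combined baseline feeding the pooled one-source TP variant: the mean
#' d15N over all individual littoral and pelagic baseline specimens
#' (`method = "specimens"`, default), or the unweighted mean of the two
#' habitat means (`method = "habitat_means"`).
#'
#' @param baseline_samples A data frame of baseline measurements with columns
#'   `role` (one of `littoral_baseline`, `pelagic_baseline`) and `d15n`.
#' @param method Pooling rule, see above.
#' @return A single pooled d15N value (per mil).
#' @export
pooled_baseline <- function(baseline_samples,
                            method = c("specimens", "habitat_means")) {
  method <- match.arg(method)
  if (is.null(baseline_samples) || nrow(baseline_samples) == 0) {
    abort("No baseline specimens supplied for pooling.",
      class = "lcutools_error"
    )
  }
  lit <- baseline_samples$d15n[baseline_samples$role == "littoral_baseline"]
  pel <- baseline_samples$d15n[baseline_samples$role == "pelagic_baseline"]
  if (length(lit) == 0 || length(pel) == 0) {
    missing <- if (length(lit) == 0) "littoral_baseline" else "pelagic_baseline"
    abort(paste0("Pooling requires both habitats; missing: ", missing, "."),
      class = "lcutools_error"
    )
  }
  if (method == "specimens") mean(c(lit, pel)) else (mean(lit) + mean(pel)) / 2
}

#' Compute the full LCU and trophic-position suite
#'
#' For every consumer, computes raw LCU, the clipped (LCU_adj) and
#' range-rescaled (LCU_R) scalings, and the nine trophic-position variants:
#' three one-source TPs (littoral-only, pelagic-only, pooled baseline), three
#' two-source TPs with alpha set to each LCU scaling, and three absolute-
#' lambda two-source TPs with the same three alphas. LCU_R is rescaled over
#' all consumers passed in, i.e. the analysis group defines the observed
#' range.
#'
#' @param consumers Data frame with columns `specimen_id`, `d13c`, `d15n`.
#' @param endmembers An [endmember_set()].
#' @param baseline_samples Individual baseline measurements used for the
#'   pooled one-source variant; if `NULL`, the pooled baseline falls back to
#'   the mean of the two endmember means.
#' @param config A [metric_config()].
#' @return A tibble with one row per consumer and columns `specimen_id`,
#'   `lcu`, `lcu_adj`, `lcu_r`, `tp1_lb`, `tp1_p`, `tp1_lbp`, `tp2`,
#'   `tp2_adj`, `tp2_r`, `tp2abs`, `tp2abs_adj`, `tp2abs_r`.
#' @examples
#' em <- endmember_set(-20, -28, 6, 4, lambda_littoral = 2.25)
#' fish <- tibble::tibble(
#'   specimen_id = c("a", "b", "c"),
#'   d13c = c(-26, -23, -19), d15n = c(10, 12, 11)
#' )
#' compute_metric_suite(fish, em)
#' @export
compute_metric_suite <- function(consumers, endmembers,
                                 baseline_samples = NULL,
                                 config = metric_config()) {
  stopifnot(inherits(endmembers, "endmember_set"), inherits(config, "metric_config"))
  if (is.null(consumers) || nrow(consumers) == 0) {
    abort("`consumers` must contain at least one row.", class = "lcutools_error")
  }
  lcu <- compute_lcu(consumers$d13c, endmembers)
  lcu_adj <- clip_lcu(lcu)
  lcu_r <- if (length(lcu) >= 2) {
    rescale_lcu(lcu) # degenerate-range errors propagate
  } else {
    rep(NA_real_, length(lcu))
  }
  pooled <- if (!is.null(baseline_samples)) {
    pooled_baseline(baseline_samples, method = config$pooling)
  } else {
    (endmembers$d15n_littoral + endmembers$d15n_pelagic) / 2
  }
  metric_records(
    consumers$specimen_id, consumers$d15n, lcu, lcu_adj, lcu_r,
    endmembers, pooled, config
  )
}

# Shared vectorised assembly of one MetricRecord row per consumer.
metric_records <- function(specimen_id, d15n, lcu, lcu_adj, lcu_r,
                           endmembers, pooled_d15n, config) {
  l0 <- config$lambda_default
  dn <- config$delta_n
  tp2_for <- function(a) tp_two_source(d15n, a, endmembers, lambda = l0, delta_n = dn)
  tp2abs_for <- function(a) tp_two_source_abs(d15n, a, endmembers, delta_n = dn)
  tibble::tibble(
    specimen_id = specimen_id,
    lcu = lcu,
    lcu_adj = lcu_adj,
    lcu_r = lcu_r,
    tp1_lb = tp_one_source(d15n, endmembers$d15n_littoral, l0, dn),
    tp1_p = tp_one_source(d15n, endmembers$d15n_pelagic, l0, dn),
    tp1_lbp = tp_one_source(d15n, pooled_d15n, l0, dn),
    tp2 = tp2_for(lcu),
    tp2_adj = tp2_for(lcu_adj),
    tp2_r = tp2_for(lcu_r),
    tp2abs = tp2abs_for(lcu),
    tp2abs_adj = tp2abs_for(lcu_adj),
    tp2abs_r = tp2abs_for(lcu_r)
  )
}

#' Out-of-bounds accounting for raw LCU
#'
#' Counts population members whose raw LCU lies strictly above 1 or strictly
#' below 0 (values exactly on the bounds count as inside) and flags the
#' population when the outside fraction exceeds the threshold, the trigger
#' for preferring the range-rescaled scaling.
#'
#' @param lcu_values Numeric vector of raw LCU values (non-empty).
#' @param threshold Fraction above which the flag is raised. Default 0.05.
#' @return A list of class `violation_summary` with `n_total`, `n_above_1`,
#'   `n_below_0`, `pct_outside` (0-100 scale) and `exceeds_threshold`.
#' @export
boundary_violation_stats <- function(lcu_values, threshold = 0.05) {
  if (length(lcu_values) == 0) {
    abort("`lcu_values` must be non-empty.", class = "lcutools_error")
  }
  n_above <- sum(lcu_values > 1)
  n_below <- sum(lcu_values < 0)
  frac <- (n_above + n_below) / length(lcu_values)
  structure(
    list(
      n_total = length(lcu_values),
      n_above_1 = n_above,
      n_below_0 = n_below,
      pct_outside = 100 * frac,
      exceeds_threshold = frac > threshold,
      threshold = threshold
    ),
    class = "violation_summary"
  )
}

#' @export
print.violation_summary <- function(x, ...) {
  cat(sprintf(
    "<violation_summary> n = %d | >1: %d | <0: %d | outside: %.1f%% | flag: %s\n",
    x$n_total, x$n_above_1, x$n_below_0, x$pct_outside,
    if (x$exceeds_threshold) "exceeds threshold" else "within threshold"
  ))
  invisible(x)
}
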