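# Decision engine and equation-comparison reports.

.lcu_variants <- c("lcu", "lcu_adj", "lcu_r")
.tp_variants <- c(
  "tp1_lb", "tp1_p", "tp1_lbp",
  "tp2", "tp2_adj", "tp2_r",
  "tp2abs", "tp2abs_adj", "tp2abs_r"
)

#' Recommend a resource-use scaling and trophic-position equation
#'
#' Walks the decision chain that maps baseline diagnostics to an equation
#' pair:
#' 1. If the littoral and pelagic baselines are not distinct in d13C, the
#'    mixing model is unsupported: resource use is not applicable and the
#'    one-source TP with all baselines pooled is recommended.
#' 2. Otherwise, if more than the threshold fraction of raw LCU values fall
#'    outside `[0, 1]`, the range-rescaled scaling (LCU_R) is recommended as
#'    the resource-use metric and as the alpha feeding the two-source TP;
#'    within the threshold the raw LCU serves both roles.
#' 3. Equal assumed baseline trophic positions select the plain two-source
#'    TP; unequal lambdas select the absolute-lambda variant.
#' Non-distinct d15N baselines alongside distinct d13C do not change the
#' path but are recorded as a caution in the rationale.
#'
#' @param distinctness Output of [test_habitat_distinctness()].
#' @param violations A `violation_summary` from [boundary_violation_stats()].
#' @param lambdas_equal Are the two baselines assumed to occupy the same
#'   trophic position?
#' @return A list of class `ru_recommendation`: `ru_method` (`"lcu"`,
#'   `"lcu_r"` or `"not_applicable"`), `tp_method`, `alpha_source`, and a
#'   `rationale` character vector tracing every rule fired with its inputs.
#' @examples
#' bl_l <- tibble::tibble(d13c = c(-20, -20.5, -19.5), d15n = c(6, 6.2, 5.8))
#' bl_p <- tibble::tibble(d13c = c(-28, -28.5, -27.5), d15n = c(4, 4.2, 3.8))
#' dx <- test_habitat_distinctness(bl_l, bl_p)
#' vs <- boundary_violation_stats(c(0.2, 0.5, 1.1, 0.7))
#' recommend_equations(dx, vs, lambdas_equal = TRUE)
#' @export
recommend_equations <- function(distinctness, violations, lambdas_equal) {
  stopifnot(inherits(violations, "violation_summary"))
  d13 <- distinctness[distinctness$isotope == "d13c", ]
  d15 <- distinctness[distinctness$isotope == "d15n", ]
  rationale <- character(0)
  note <- function(msg) rationale <<- c(rationale, msg)

  if (!d13$distinct) {
    note(sprintf(
      "Baselines not distinct in d13C (p = %.4f >= %.2f): mixing model unsupported; pool all baselines.",
      d13$p_value, d13$alpha_level
    ))
    note("One-source TP with pooled baseline (tp1_lbp) recommended; no alpha needed.")
    rec <- list(
      ru_method = "not_applicable", tp_method = "tp1_lbp",
      alpha_source = "none", rationale = rationale
    )
    return(structure(rec, class = "ru_recommendation"))
  }

  note(sprintf(
    "Baselines distinct in d13C (p = %.4f < %.2f): two-source mixing model supported.",
    d13$p_value, d13$alpha_level
  ))
  if (nrow(d15) == 1 && !d15$distinct) {
    note(sprintf(
      "Caution: baselines not distinct in d15N (p = %.4f); two-source path retained.",
      d15$p_value
    ))
  }
  if (violations$exceeds_threshold) {
    note(sprintf(
      "%.1f%% of raw LCU outside [0, 1] (> %.0f%% threshold): use range-rescaled LCU_R.",
      violations$pct_outside, 100 * violations$threshold
    ))
    ru <- "lcu_r"
  } else {
    note(sprintf(
      "%.1f%% of raw LCU outside [0, 1] (<= %.0f%% threshold): raw LCU acceptable.",
      violations$pct_outside, 100 * violations$threshold
    ))
    ru <- "lcu"
  }
  if (isTRUE(lambdas_equal)) {
    note("Assumed baseline trophic positions equal: two-source TP (tp2).")
    tp <- "tp2"
  } else {
    note("Assumed baseline trophic positions differ: absolute-lambda two-source TP (tp2_abs).")
    tp <- "tp2_abs"
  }
  structure(
    list(ru_method = ru, tp_method = tp, alpha_source = ru, rationale = rationale),
    class = "ru_recommendation"
  )
}

#' @export
print.ru_recommendation <- function(x, ...) {
  cat("<ru_recommendation>\n")
  cat("  resource use:", x$ru_method, "| TP equation:", x$tp_method,
    "| alpha source:", x$alpha_source, "\n"
  )
  cat("  rationale:\n")
  for (r in x$rationale) cat("   -", r, "\n")
  invisible(x)
}

#' Compare LCU or TP equation variants
#'
#' Tests whether the scalings/equations yield different value distributions
#' for one species: a Kruskal-Wallis omnibus treating each variant's
#' per-individual values as a group, followed by Dunn's pairwise z-tests
#' with Bonferroni adjustment. Values from the same individuals are treated
#' as independent groups by design (the convention of the comparison being
#' replicated); set `paired = TRUE` for a Friedman omnibus with paired
#' signed-rank follow-ups instead.
#'
#' @param records Metric records from [compute_metric_suite()] (optionally
#'   carrying a `species` column).
#' @param species Optional species code to filter `records` by.
#' @param family `"lcu"` (3 variants) or `"tp"` (9 variants).
#' @param alpha_level Significance level for flags. Default 0.05.
#' @param paired Use the paired alternative? Default `FALSE`.
#' @return A list of class `equation_comparison`: `species`, `family`,
#'   `omnibus` (statistic, df, p_value, method) and `pairwise` (tibble over
#'   all unordered variant pairs).
#' @export
compare_equation_variants <- function(records, species = NULL,
                                      family = c("lcu", "tp"),
                                      alpha_level = 0.05, paired = FALSE) {
  family <- match.arg(family)
  if (!is.null(species) && "species" %in% names(records)) {
    records <- records[records$species == species, , drop = FALSE]
  }
  variants <- if (family == "lcu") .lcu_variants else .tp_variants
  variants <- intersect(variants, names(records))
  long <- tidyr::pivot_longer(
    records[, c("specimen_id", variants)],
    dplyr::all_of(variants),
    names_to = "variant", values_to = "value"
  )
  long <- long[is.finite(long$value), , drop = FALSE]
  counts <- table(long$variant)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("Need >= 2 variants with >= 2 finite values each.",
      class = "lcutools_error"
    )
  }
  if (paired) {
    wide <- tidyr::pivot_wider(long,
      names_from = "variant", values_from = "value"
    )
    mat <- as.matrix(wide[stats::complete.cases(wide[, variants]), variants])
    fr <- stats::friedman.test(mat)
    omnibus <- list(
      statistic = unname(fr$statistic), df = unname(fr$parameter),
      p_value = fr$p.value, method = "friedman"
    )
    pairs <- utils::combn(variants, 2)
    pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]
      b <- pairs[2, k]
      res <- suppressWarnings(
        wilcox.test(mat[, a], mat[, b], paired = TRUE, exact = FALSE)
      )
      p <- if (is.nan(res$p.value)) 1 else res$p.value
      tibble::tibble(
        variant_a = a, variant_b = b, z = NA_real_, p_value = p
      )
    })
    pw$p_adjusted <- pmin(p.adjust(pw$p_value, "bonferroni"), 1)
    pw$significant <- pw$p_adjusted < alpha_level
  } else {
    omni <- kruskal_omnibus(long$value, long$variant)
    omnibus <- c(omni, method = "kruskal_wallis")
    pw <- dunn_test(long$value, long$variant,
      p_adjust = "bonferroni", alpha_level = alpha_level
    )
    names(pw)[names(pw) == "group_a"] <- "variant_a"
    names(pw)[names(pw) == "group_b"] <- "variant_b"
  }
  structure(
    list(
      species = species %||% NA_character_, family = family,
      omnibus = omnibus, pairwise = pw
    ),
    class = "equation_comparison"
  )
}

#' @export
print.equation_comparison <- function(x, ...) {
  cat(sprintf(
    "<equation_comparison> %s variants%s: %s statistic = %.3f, p = %.4g\n",
    x$family,
    if (is.na(x$species)) "" else paste0(" (", x$species, ")"),
    x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value
  ))
  sig <- x$pairwise[x$pairwise$significant, , drop = FALSE]
  cat("  significant pairs:", nrow(sig), "of", nrow(x$pairwise), "\n")
  invisible(x)
}

#' Summary table of LCU and TP variants
#'
#' Per-group mean, SD, min and max for every metric column present, plus the
#' percentage of individuals whose raw LCU lies outside `[0, 1]` (reported
#' on the `lcu` rows).
#'
#' @param records Metric records, optionally joined with grouping metadata.
#' @param by Character vector of grouping columns present in `records`
#'   (e.g. `c("species", "stratum")`). Empty for one overall group.
#' @return A tibble with one row per group x metric: grouping columns,
#'   `metric`, `n`, `mean`, `sd`, `min`, `max`, `pct_outside` (`NA` except
#'   for `metric == "lcu"`).
#' @export
summarize_metrics <- function(records, by = character(0)) {
  if (nrow(records) == 0) {
    abort("`records` must be non-empty.", class = "lcutools_error")
  }
  metrics <- intersect(c(.lcu_variants, .tp_variants), names(records))
  long <- tidyr::pivot_longer(
    records[, c(by, "specimen_id", metrics)],
    dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(by, "metric")))),
    n = sum(is.finite(.data$value)),
    mean = mean(.data$value[is.finite(.data$value)]),
    sd = sd(.data$value[is.finite(.data$value)]),
    min = suppressWarnings(min(.data$value[is.finite(.data$value)])),
    max = suppressWarnings(max(.data$value[is.finite(.data$value)])),
    pct_outside = if (.data$metric[1] == "lcu") {
      100 * mean(.data$value > 1 | .data$value < 0, na.rm = TRUE)
    } else {
      NA_real_
    },
    .groups = "drop"
  )
  out$sd[out$n == 1] <- 0 # single-record groups: no dispersion, not NA
  out$metric <- factor(out$metric, levels = metrics)
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(by, "metric"))))
}

#' Mean +/- SD isotope biplot
#'
#' d13C-d15N biplot of group means with SD error bars, colored by species
#' and shaped by tissue: the standard at-a-glance view of where consumers
#' sit relative to the baseline endmembers.
#'
#' @param measurements Measurement data frame (consumers and baselines).
#' @return A ggplot object.
#' @export
plot_isotope_biplot <- function(measurements) {
  sm <- dplyr::summarise(
    dplyr::group_by(measurements, .data$species, .data$tissue, .data$role),
    d13c_mean = mean(.data$d13c), d13c_sd = sd(.data$d13c),
    d15n_mean = mean(.data$d15n), d15n_sd = sd(.data$d15n),
    .groups = "drop"
  )
  sm$d13c_sd[is.na(sm$d13c_sd)] <- 0
  sm$d15n_sd[is.na(sm$d15n_sd)] <- 0
  ggplot2::ggplot(sm, ggplot2::aes(
    x = .data$d13c_mean, y = .data$d15n_mean,
    colour = .data$species, shape = .data$tissue
  )) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$d15n_mean - .data$d15n_sd,
      ymax = .data$d15n_mean + .data$d15n_sd
    ), width = 0.1) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$d13c_mean - .data$d13c_sd,
      xmax = .data$d13c_mean + .data$d13c_sd
    ), height = 0.05) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = expression(delta^13 * C ~ ("‰")),
      y = expression(delta^15 * N ~ ("‰"))
    ) +
    ggplot2::theme_minimal()
}
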