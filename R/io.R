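# Data ingestion, validation, configuration and the end-to-end pipeline.

#' Read a long-format isotope CSV
#'
#' One row per analyzed specimen. Required columns (case-insensitive):
#' `specimen_id`, `species`, `role`, `tissue`, `season`, `stratum`, `d13c`,
#' `d15n`. The delimiter is auto-detected among comma and tab. Rows whose
#' isotope values do not parse as numbers are dropped and counted, never
#' imputed.
#'
#' @param path Path to the file.
#' @param col_map Optional named character vector mapping standard column
#'   names to the file's column names, e.g.
#'   `c(d13c = "delta13C", stratum = "basin")`.
#' @return An `isotope_dataset`: a list with `measurements` (tibble) and
#'   `provenance` (`path`, `n_read`, `n_dropped`, `n_retained`).
#' @export
read_dataset <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "lcutools_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) {
    abort(paste0("Empty file: ", path), class = "lcutools_error")
  }
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >
    lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(raw) <- tolower(names(raw))
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- tolower(col_map[[std]])
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- std
    }
  }
  missing <- setdiff(.measurement_cols, names(raw))
  if (length(missing) > 0) {
    abort(
      paste0(
        "Missing required column(s): ", paste(missing, collapse = ", "), "."
      ),
      class = "lcutools_error"
    )
  }
  raw <- raw[, .measurement_cols]
  raw$d13c <- suppressWarnings(as.numeric(raw$d13c))
  raw$d15n <- suppressWarnings(as.numeric(raw$d15n))
  ok <- is.finite(raw$d13c) & is.finite(raw$d15n)
  n_read <- nrow(raw)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(paste0(
      "Dropped ", n_dropped, " row(s) with unparseable/missing isotope values."
    ))
  }
  dat <- raw[ok, , drop = FALSE]
  dat$role <- tolower(dat$role)
  validate_measurements(dat)
  structure(
    list(
      measurements = tibble::as_tibble(dat),
      provenance = list(
        path = path, n_read = n_read,
        n_dropped = n_dropped, n_retained = nrow(dat)
      )
    ),
    class = "isotope_dataset"
  )
}

#' Validate a measurement table
#'
#' Checks the schema and roles, enforces finite isotope values, warns (never
#' errors) on isotopically implausible values (d13C outside `[-50, 0]` or
#' d15N outside `[-10, 30]` per mil) and on duplicated specimen ids.
#'
#' @param measurements A measurement data frame.
#' @return The input, invisibly.
#' @export
validate_measurements <- function(measurements) {
  missing <- setdiff(.measurement_cols, names(measurements))
  if (length(missing) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing, collapse = ", "), "."),
      class = "lcutools_error"
    )
  }
  bad_role <- setdiff(unique(measurements$role), .roles)
  if (length(bad_role) > 0) {
    abort(
      paste0(
        "Unknown role(s): ", paste(bad_role, collapse = ", "),
        ". Expected: ", paste(.roles, collapse = ", "), "."
      ),
      class = "lcutools_error"
    )
  }
  if (!all(is.finite(measurements$d13c)) || !all(is.finite(measurements$d15n))) {
    abort("Isotope values must be finite.", class = "lcutools_error")
  }
  n_implaus <- sum(measurements$d13c < -50 | measurements$d13c > 0 |
    measurements$d15n < -10 | measurements$d15n > 30)
  if (n_implaus > 0) {
    warn(paste0(
      n_implaus, " specimen(s) have isotopically implausible values ",
      "(d13C outside [-50, 0] or d15N outside [-10, 30] per mil)."
    ))
  }
  if (anyDuplicated(measurements$specimen_id)) {
    warn("Duplicated specimen_id values present.")
  }
  invisible(measurements)
}

#' Pipeline run configuration
#'
#' @param metric A [metric_config()].
#' @param policy A [grouping_policy()].
#' @param lambdas Named vector of assumed baseline trophic positions used
#'   when aggregating endmembers.
#' @param alpha_level Significance level for all screens and flags.
#' @param paired_comparison Use the paired variant-comparison alternative?
#' @param out_dir Output directory (`NULL` = no files written).
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(metric = metric_config(), policy = grouping_policy(),
                       lambdas = c(littoral = 2, pelagic = 2),
                       alpha_level = 0.05, paired_comparison = FALSE,
                       out_dir = NULL, seed = 1L) {
  structure(
    list(
      metric = metric, policy = policy, lambdas = lambdas,
      alpha_level = alpha_level, paired_comparison = isTRUE(paired_comparison),
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Write / read a run configuration (YAML)
#'
#' The on-disk form round-trips: reading a written config yields an equal
#' `run_config`.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- list(
    metric = unclass(config$metric),
    policy = list(
      stratum_matching = config$policy$stratum_matching,
      season_matching = as.list(config$policy$season_matching)
    ),
    lambdas = as.list(config$lambdas),
    alpha_level = config$alpha_level,
    paired_comparison = config$paired_comparison,
    out_dir = config$out_dir,
    seed = config$seed
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  run_config(
    metric = metric_config(
      delta_n = lst$metric$delta_n,
      lambda_default = lst$metric$lambda_default,
      violation_threshold = lst$metric$violation_threshold,
      rescale_scope = lst$metric$rescale_scope,
      pooling = lst$metric$pooling
    ),
    policy = grouping_policy(
      stratum_matching = lst$policy$stratum_matching,
      season_matching = unlist(lst$policy$season_matching)
    ),
    lambdas = unlist(lst$lambdas),
    alpha_level = lst$alpha_level,
    paired_comparison = isTRUE(lst$paired_comparison),
    out_dir = lst$out_dir,
    seed = lst$seed
  )
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    lcutools_error = function(e) {
      abort(paste0("[", stage, "] ", conditionMessage(e)),
        class = c("lcutools_stage_error", "lcutools_error")
      )
    }
  )
}

#' Per-consumer metric records under a matching policy
#'
#' The policy-aware counterpart of [compute_metric_suite()]: resolves each
#' consumer's endmember scope (stratum, and season for fast-turnover
#' tissues), computes raw LCU against the scope endmembers, range-rescales
#' within the configured scope, and assembles the nine TP variants with the
#' scope's pooled baseline.
#'
#' @param measurements Long-format measurement table (consumers and
#'   baselines).
#' @param policy A [grouping_policy()].
#' @param config A [metric_config()].
#' @param lambdas Named vector of assumed baseline trophic positions.
#' @return A tibble of metric records carrying `species`, `stratum`,
#'   `season`, `tissue` alongside the LCU scalings and nine TP variants.
#' @export
compute_records <- function(measurements, policy = grouping_policy(),
                            config = metric_config(),
                            lambdas = c(littoral = 2, pelagic = 2)) {
  validate_measurements(measurements)
  consumers <- measurements[measurements$role == "consumer", , drop = FALSE]
  baselines <- measurements[measurements$role != "consumer", , drop = FALSE]
  if (nrow(consumers) == 0) {
    abort("No consumer rows in the dataset.", class = "lcutools_error")
  }
  if (nrow(baselines) == 0) {
    abort("No baseline rows in the dataset.", class = "lcutools_error")
  }
  emt <- build_endmember_table(baselines, policy, lambdas)
  rule <- unname(policy$season_matching[consumers$tissue])
  rule[is.na(rule)] <- "pool_seasons"
  consumers$.scope_stratum <- if (policy$stratum_matching) {
    as.character(consumers$stratum)
  } else {
    "all"
  }
  consumers$.scope_season <- ifelse(
    rule == "match_season", as.character(consumers$season), "all"
  )
  # raw LCU per scope
  consumers$lcu <- NA_real_
  scopes <- unique(consumers[, c(".scope_stratum", ".scope_season")])
  scope_em <- list()
  for (k in seq_len(nrow(scopes))) {
    key <- paste(scopes$.scope_stratum[k], scopes$.scope_season[k], sep = "\r")
    hit <- which(emt$stratum == scopes$.scope_stratum[k] &
      emt$season == scopes$.scope_season[k])
    if (length(hit) == 0) {
      avail <- paste0("(", emt$stratum, ", ", emt$season, ")", collapse = ", ")
      abort(paste0(
        "No endmember set for scope (", scopes$.scope_stratum[k], ", ",
        scopes$.scope_season[k], "). Available scopes: ", avail, "."
      ), class = "lcutools_error")
    }
    em <- emt$endmembers[[hit[1]]]
    scope_em[[key]] <- em
    idx <- consumers$.scope_stratum == scopes$.scope_stratum[k] &
      consumers$.scope_season == scopes$.scope_season[k]
    consumers$lcu[idx] <- compute_lcu(consumers$d13c[idx], em)
  }
  # range rescaling within the configured scope
  consumers$lcu_r <- NA_real_
  rs_group <- if (config$rescale_scope == "per_stratum") {
    consumers$.scope_stratum
  } else {
    rep("system", nrow(consumers))
  }
  for (grp in unique(rs_group)) {
    idx <- rs_group == grp
    if (sum(idx) >= 2) {
      consumers$lcu_r[idx] <- rescale_lcu(consumers$lcu[idx])
    }
  }
  consumers$lcu_adj <- clip_lcu(consumers$lcu)
  # assemble records per scope (TP equations need scope endmembers)
  recs <- list()
  for (k in seq_len(nrow(scopes))) {
    key <- paste(scopes$.scope_stratum[k], scopes$.scope_season[k], sep = "\r")
    em <- scope_em[[key]]
    idx <- consumers$.scope_stratum == scopes$.scope_stratum[k] &
      consumers$.scope_season == scopes$.scope_season[k]
    sub <- consumers[idx, , drop = FALSE]
    bl <- baselines
    if (scopes$.scope_stratum[k] != "all") {
      bl <- bl[bl$stratum == scopes$.scope_stratum[k], , drop = FALSE]
    }
    if (scopes$.scope_season[k] != "all") {
      bl <- bl[bl$season == scopes$.scope_season[k], , drop = FALSE]
    }
    pooled <- pooled_baseline(bl, method = config$pooling)
    rec <- metric_records(
      sub$specimen_id, sub$d15n, sub$lcu, sub$lcu_adj, sub$lcu_r,
      em, pooled, config
    )
    rec <- dplyr::bind_cols(
      sub[, c("species", "stratum", "season", "tissue")], rec
    )
    recs[[k]] <- rec
  }
  out <- dplyr::bind_rows(recs)
  out <- out[match(consumers$specimen_id, out$specimen_id), , drop = FALSE]
  dplyr::relocate(tibble::as_tibble(out), "specimen_id")
}

#' Run the full analysis pipeline
#'
#' End-to-end order: habitat-distinctness tests of the baselines first, then
#' advisory grouping screens (stratum/season/tissue where multiple levels
#' exist), then endmember construction and the per-consumer metric suite,
#' then boundary-violation accounting, the equation recommendation, summary
#' tables, and the equation-variant comparisons. When `config$out_dir` is
#' set, all tables are written as CSV (4 decimal places), the recommendation
#' as JSON, plus a manifest recording the configuration hash and seed;
#' outputs are deterministic given (input, config, seed).
#'
#' @param dataset An `isotope_dataset` from [read_dataset()] or a plain
#'   measurement data frame.
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `endmember_table`, `records`,
#'   `distinctness` (overall and per stratum), `screens`, `violations` (per
#'   species x stratum), `recommendation`, `summary`, `comparisons`,
#'   `manifest`.
#' @export
run_pipeline <- function(dataset, config = run_config()) {
  measurements <- if (inherits(dataset, "isotope_dataset")) {
    dataset$measurements
  } else {
    tibble::as_tibble(dataset)
  }
  with_stage("validate", validate_measurements(measurements))
  consumers <- measurements[measurements$role == "consumer", , drop = FALSE]
  baselines <- measurements[measurements$role != "consumer", , drop = FALSE]
  if (nrow(baselines) == 0) {
    abort("[baseline_builder] No baseline rows in the dataset.",
      class = c("lcutools_stage_error", "lcutools_error")
    )
  }

  # 1. habitat distinctness, overall and per stratum
  lit <- baselines[baselines$role == "littoral_baseline", , drop = FALSE]
  pel <- baselines[baselines$role == "pelagic_baseline", , drop = FALSE]
  distinct_all <- with_stage(
    "baseline_builder",
    test_habitat_distinctness(lit, pel, config$alpha_level)
  )
  distinct_all$stratum <- "all"
  dx <- list(distinct_all)
  strata <- unique(as.character(baselines$stratum))
  if (config$policy$stratum_matching && length(strata) > 1) {
    for (st in strata) {
      d <- tryCatch(
        test_habitat_distinctness(
          lit[lit$stratum == st, , drop = FALSE],
          pel[pel$stratum == st, , drop = FALSE],
          config$alpha_level
        ),
        lcutools_error = function(e) NULL
      )
      if (!is.null(d)) {
        d$stratum <- st
        dx[[length(dx) + 1]] <- d
      }
    }
  }
  distinctness <- dplyr::bind_rows(dx)

  # 2. advisory grouping screens
  screens <- list()
  for (fct in c("stratum", "season", "tissue")) {
    if (length(unique(measurements[[fct]])) > 1) {
      screens[[fct]] <- tryCatch(
        screen_grouping_factors(measurements, fct, config$alpha_level),
        lcutools_error = function(e) NULL
      )
    }
  }

  # 3. endmembers + metric suite
  emt <- with_stage(
    "baseline_builder",
    build_endmember_table(baselines, config$policy, config$lambdas)
  )
  records <- with_stage(
    "core_metrics",
    compute_records(measurements, config$policy, config$metric, config$lambdas)
  )

  # 4. violation accounting per population (species x stratum)
  pop_group <- if (length(strata) > 1) c("species", "stratum") else "species"
  violations <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(pop_group))),
    n_total = dplyr::n(),
    n_above_1 = sum(.data$lcu > 1),
    n_below_0 = sum(.data$lcu < 0),
    pct_outside = 100 * (.data$n_above_1 + .data$n_below_0) / .data$n_total,
    exceeds_threshold = (.data$n_above_1 + .data$n_below_0) / .data$n_total >
      config$metric$violation_threshold,
    .groups = "drop"
  )
  overall_violation <- boundary_violation_stats(
    records$lcu, config$metric$violation_threshold
  )

  # 5. recommendation from system-wide diagnostics
  lambdas_equal <- config$lambdas[["littoral"]] == config$lambdas[["pelagic"]]
  recommendation <- recommend_equations(
    distinct_all, overall_violation, lambdas_equal
  )

  # 6. summaries
  by_cols <- "species"
  for (fct in c("stratum", "season", "tissue")) {
    if (length(unique(records[[fct]])) > 1) by_cols <- c(by_cols, fct)
  }
  summary_tbl <- summarize_metrics(records, by = by_cols)

  # 7. per-species equation comparisons
  comparisons <- list()
  for (sp in unique(records$species)) {
    for (fam in c("lcu", "tp")) {
      cmp <- tryCatch(
        compare_equation_variants(records, sp, fam,
          alpha_level = config$alpha_level,
          paired = config$paired_comparison
        ),
        lcutools_error = function(e) NULL
      )
      if (!is.null(cmp)) comparisons[[paste(sp, fam, sep = ".")]] <- cmp
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lcutools")),
    config_hash = rlang::hash(unclass_config(config)),
    seed = config$seed,
    n_measurements = nrow(measurements),
    n_consumers = nrow(consumers),
    n_baselines = nrow(baselines)
  )

  result <- structure(
    list(
      endmember_table = emt, records = records, distinctness = distinctness,
      screens = screens, violations = violations,
      overall_violation = overall_violation,
      recommendation = recommendation, summary = summary_tbl,
      comparisons = comparisons, manifest = manifest
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_result(result, config$out_dir)
  }
  result
}

unclass_config <- function(config) {
  rapply(unclass(config), identity, how = "replace")
}

round4 <- function(df) {
  df[] <- lapply(df, function(x) if (is.numeric(x)) round(x, 4) else x)
  df
}

#' Write pipeline outputs to a directory
#'
#' @param result A `pipeline_result`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emt <- result$endmember_table
  em_flat <- dplyr::bind_rows(lapply(emt$endmembers, function(e) {
    tibble::as_tibble(unclass(e))
  }))
  readr::write_csv(round4(em_flat), file.path(out_dir, "endmembers.csv"))
  readr::write_csv(round4(result$records), file.path(out_dir, "metric_records.csv"))
  readr::write_csv(round4(result$distinctness), file.path(out_dir, "distinctness.csv"))
  readr::write_csv(round4(result$violations), file.path(out_dir, "violations.csv"))
  readr::write_csv(round4(result$summary), file.path(out_dir, "summary.csv"))
  if (length(result$comparisons) > 0) {
    cmp_rows <- purrr::map_dfr(names(result$comparisons), function(nm) {
      cmp <- result$comparisons[[nm]]
      pw <- cmp$pairwise
      pw$species <- cmp$species
      pw$family <- cmp$family
      pw$omnibus_statistic <- cmp$omnibus$statistic
      pw$omnibus_p <- cmp$omnibus$p_value
      pw
    })
    readr::write_csv(round4(cmp_rows), file.path(out_dir, "comparisons.csv"))
  }
  rec <- result$recommendation
  jsonlite::write_json(
    list(
      ru_method = rec$ru_method, tp_method = rec$tp_method,
      alpha_source = rec$alpha_source, rationale = rec$rationale
    ),
    file.path(out_dir, "recommendation.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  consumers:", x$manifest$n_consumers,
    "| baselines:", x$manifest$n_baselines, "\n"
  )
  cat(sprintf(
    "  raw LCU outside [0,1]: %.1f%%\n", x$overall_violation$pct_outside
  ))
  cat("  recommendation:", x$recommendation$ru_method, "/",
    x$recommendation$tp_method, "\n"
  )
  invisible(x)
}

#' Write a measurement table (and optional truth table) as CSV
#'
#' Companion to [generate_system()] for the `simulate` CLI command.
#'
#' @param system Output of [generate_system()].
#' @param path CSV path for the measurements.
#' @param truth_path Optional CSV path for the ground truth.
#' @return `path`, invisibly.
#' @export
write_system_csv <- function(system, path, truth_path = NULL) {
  readr::write_csv(system$measurements, path)
  if (!is.null(truth_path)) readr::write_csv(system$truth, truth_path)
  invisible(path)
}
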