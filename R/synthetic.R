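# Synthetic lake food-web generator. Consumers are built by running the
# two-endmember mixing model forward (d13C) and inverting the two-source TP
# equation (d15N), so every emitted specimen carries a known alpha and TP
# that the estimators can be checked against.

#' Specification of one simulated consumer species
#'
#' @param species Species code.
#' @param n Individuals per (stratum, season) combination.
#' @param alpha_range Range `[lo, hi]` of true littoral carbon proportions;
#'   values outside `[0, 1]` are allowed and emulate consumers whose d13C
#'   exceeds the baseline span.
#' @param trophic_level True trophic position of the species.
#' @param tissues Tissues sampled from each individual; all tissues of an
#'   individual share its alpha and TP.
#' @param alpha_dist `"uniform"` draws alpha uniformly over the range;
#'   `"grid"` spaces the n individuals evenly from lo to hi inclusive
#'   (useful when exact range endpoints are needed).
#' @param tp_jitter_sd SD of individual jitter added to `trophic_level`.
#' @return A list of class `species_spec`.
#' @export
species_spec <- function(species, n, alpha_range = c(0, 1), trophic_level = 3.5,
                         tissues = "muscle",
                         alpha_dist = c("uniform", "grid"),
                         tp_jitter_sd = 0) {
  if (alpha_range[1] > alpha_range[2]) {
    abort("`alpha_range` must satisfy lo <= hi.", class = "lcutools_error")
  }
  structure(
    list(
      species = species, n = as.integer(n), alpha_range = alpha_range,
      trophic_level = trophic_level, tissues = tissues,
      alpha_dist = match.arg(alpha_dist), tp_jitter_sd = tp_jitter_sd
    ),
    class = "species_spec"
  )
}

#' Specification of a simulated lake system
#'
#' Defines the study conditions: baseline endmember distributions, assumed
#' baseline trophic positions, spatial (basin) offsets applied to everything
#' in a stratum, seasonal offsets applied to baselines and fast-turnover
#' liver tissue only, tissue offsets, the consumer species, and the noise
#' model (independent Gaussian per isotope; the default 0.2 per mil matches
#' typical mass-spectrometer precision).
#'
#' @param baseline_d13c,baseline_d15n Named vectors `c(littoral = , pelagic
#'   = )` of baseline means (per mil). Littoral d13C must exceed pelagic
#'   d13C, the premise of the littoral-pelagic mixing model.
#' @param baseline_sd Named vector `c(d13c = , d15n = )` of baseline SDs.
#' @param lambda Named vector of assumed baseline trophic positions.
#' @param baseline_species Named vector of baseline taxon labels.
#' @param n_baseline Baseline specimens per habitat per (stratum, season).
#' @param basin_offsets Named list `stratum -> c(d13c = , d15n = )`; applied
#'   to baselines and consumers of that stratum. `NULL` for one stratum.
#' @param season_offsets Named list `season -> c(d13c = , d15n = )`; applied
#'   to baselines and liver only. `NULL` for one season.
#' @param tissue_offsets Named list `tissue -> c(d13c = , d15n = )` of
#'   consumer tissue shifts relative to muscle.
#' @param species List of [species_spec()] objects.
#' @param delta_n Trophic discrimination used to generate d15N.
#' @param noise_sd Gaussian measurement/ecological noise SD (per mil),
#'   independent across isotopes.
#' @param seed Integer RNG seed; generation is reproducible under it.
#' @return A list of class `system_spec`.
#' @export
system_spec <- function(baseline_d13c = c(littoral = -20, pelagic = -28),
                        baseline_d15n = c(littoral = 6, pelagic = 4),
                        baseline_sd = c(d13c = 0.5, d15n = 0.5),
                        lambda = c(littoral = 2, pelagic = 2),
                        baseline_species = c(
                          littoral = "mayfly",
                          pelagic = "mussel"
                        ),
                        n_baseline = 15,
                        basin_offsets = NULL,
                        season_offsets = NULL,
                        tissue_offsets = list(
                          muscle = c(d13c = 0, d15n = 0),
                          fin = c(d13c = 0, d15n = 0),
                          liver = c(d13c = -1, d15n = -0.5)
                        ),
                        species = list(species_spec("generic", 20)),
                        delta_n = 3.4, noise_sd = 0.2, seed = 1) {
  if (baseline_d13c[["littoral"]] <= baseline_d13c[["pelagic"]]) {
    abort("Littoral baseline d13C must exceed pelagic baseline d13C.",
      class = "lcutools_error"
    )
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "lcutools_error")
  }
  stopifnot(all(vapply(species, inherits, logical(1), "species_spec")))
  structure(
    list(
      baseline_d13c = baseline_d13c, baseline_d15n = baseline_d15n,
      baseline_sd = baseline_sd, lambda = lambda,
      baseline_species = baseline_species, n_baseline = as.integer(n_baseline),
      basin_offsets = basin_offsets, season_offsets = season_offsets,
      tissue_offsets = tissue_offsets, species = species,
      delta_n = delta_n, noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "system_spec"
  )
}

offset_of <- function(offsets, key, iso) {
  if (is.null(offsets) || !key %in% names(offsets)) {
    return(0)
  }
  v <- offsets[[key]]
  if (iso %in% names(v)) v[[iso]] else 0
}

#' Generate a synthetic lake system
#'
#' Draws baseline specimens from their (offset-shifted) normal
#' distributions, then builds each consumer from its true alpha and trophic
#' position: d13C from the forward mixing model against the scope's expected
#' endmember means, d15N from the alpha-weighted baseline mixture plus
#' `(TP - lambda_weighted) * delta_n`, with tissue offsets, liver-only
#' season offsets, and independent Gaussian noise on both isotopes.
#'
#' @param spec A [system_spec()].
#' @param seed Optional RNG seed overriding `spec$seed`.
#' @return A list with two tibbles: `measurements` (long-format isotope
#'   data, consumers plus baselines) and `truth` (`specimen_id`,
#'   `true_alpha`, `true_tp` and generating scope, one row per
#'   measurement-row of a consumer).
#' @examples
#' sys <- generate_system(scenario_presets()$simple)
#' head(sys$measurements)
#' @export
generate_system <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "system_spec"))
  set.seed(seed %||% spec$seed)
  strata <- names(spec$basin_offsets) %||% "main"
  seasons <- names(spec$season_offsets) %||% "all"
  meas <- list()
  truth <- list()
  for (st in strata) {
    bo13 <- offset_of(spec$basin_offsets, st, "d13c")
    bo15 <- offset_of(spec$basin_offsets, st, "d15n")
    for (se in seasons) {
      so13 <- offset_of(spec$season_offsets, se, "d13c")
      so15 <- offset_of(spec$season_offsets, se, "d15n")
      # baselines: both habitats shifted by basin and season
      for (hab in c("littoral", "pelagic")) {
        n <- spec$n_baseline
        meas[[length(meas) + 1]] <- tibble::tibble(
          specimen_id = sprintf("bl_%s_%s_%s_%03d", hab, st, se, seq_len(n)),
          species = spec$baseline_species[[hab]],
          role = paste0(hab, "_baseline"),
          tissue = "whole", season = se, stratum = st,
          d13c = rnorm(n, spec$baseline_d13c[[hab]] + bo13 + so13,
            spec$baseline_sd[["d13c"]]
          ),
          d15n = rnorm(n, spec$baseline_d15n[[hab]] + bo15 + so15,
            spec$baseline_sd[["d15n"]]
          )
        )
      }
      # consumers: expected endmember means of this stratum (annual mean,
      # i.e. no season shift; liver adds it below)
      mu13 <- spec$baseline_d13c + bo13
      mu15 <- spec$baseline_d15n + bo15
      for (sp in spec$species) {
        n <- sp$n
        alpha <- if (sp$alpha_dist == "grid" && n > 1) {
          seq(sp$alpha_range[1], sp$alpha_range[2], length.out = n)
        } else {
          runif(n, sp$alpha_range[1], sp$alpha_range[2])
        }
        tp <- sp$trophic_level + rnorm(n, 0, sp$tp_jitter_sd)
        lambda_w <- alpha * spec$lambda[["littoral"]] +
          (1 - alpha) * spec$lambda[["pelagic"]]
        for (tis in sp$tissues) {
          to13 <- offset_of(spec$tissue_offsets, tis, "d13c")
          to15 <- offset_of(spec$tissue_offsets, tis, "d15n")
          liver_so13 <- if (tis == "liver") so13 else 0
          liver_so15 <- if (tis == "liver") so15 else 0
          d13c <- alpha * mu13[["littoral"]] + (1 - alpha) * mu13[["pelagic"]] +
            to13 + liver_so13 + rnorm(n, 0, spec$noise_sd)
          base15 <- alpha * mu15[["littoral"]] + (1 - alpha) * mu15[["pelagic"]] +
            liver_so15
          d15n <- base15 + (tp - lambda_w) * spec$delta_n + to15 +
            rnorm(n, 0, spec$noise_sd)
          ids <- sprintf("%s_%s_%s_%03d_%s", sp$species, st, se, seq_len(n), tis)
          meas[[length(meas) + 1]] <- tibble::tibble(
            specimen_id = ids, species = sp$species, role = "consumer",
            tissue = tis, season = se, stratum = st, d13c = d13c, d15n = d15n
          )
          truth[[length(truth) + 1]] <- tibble::tibble(
            specimen_id = ids, species = sp$species,
            true_alpha = alpha, true_tp = tp,
            stratum = st, season = se, tissue = tis
          )
        }
      }
    }
  }
  list(
    measurements = dplyr::bind_rows(meas),
    truth = dplyr::bind_rows(truth)
  )
}

#' Case-study-shaped scenario presets
#'
#' Three ready-made [system_spec()]s mirroring the structures commonly met
#' in lake isotope studies:
#' * `simple`: one stratum, one season, muscle only; mayfly/unionid
#'   baselines (lambda 2.25 / 2.0); species alphas jointly spanning 0-1.
#' * `spatial`: three basins with 2 per-mil basin offsets (far exceeding the
#'   0.5 per-mil baseline SD); oligochaete/dreissenid baselines (lambda
#'   2.5 / 2.0); several species with alpha ranges extending above 1, so raw
#'   LCU spills outside its bounds.
#' * `temporal_tissue`: two seasons and three tissues per fish; seasonal
#'   baseline shift expressed in liver but not muscle/fin; liver offset
#'   -1.0 / -0.5 per mil vs muscle.
#'
#' @return A named list of `system_spec` objects.
#' @export
scenario_presets <- function() {
  list(
    simple = system_spec(
      baseline_d13c = c(littoral = -20, pelagic = -28),
      baseline_d15n = c(littoral = 6, pelagic = 4),
      baseline_sd = c(d13c = 0.5, d15n = 0.4),
      lambda = c(littoral = 2.25, pelagic = 2),
      baseline_species = c(littoral = "mayfly", pelagic = "unionid_mussel"),
      n_baseline = 30,
      species = list(
        species_spec("lake_trout", 20, c(0.0, 0.4), 4.2),
        species_spec("walleye", 20, c(0.2, 0.8), 4.0),
        species_spec("yellow_perch", 20, c(0.3, 0.9), 3.3),
        species_spec("smallmouth_bass", 20, c(0.6, 1.0), 3.6)
      ),
      noise_sd = 0.2, seed = 101
    ),
    spatial = system_spec(
      baseline_d13c = c(littoral = -21, pelagic = -27),
      baseline_d15n = c(littoral = 8, pelagic = 9),
      baseline_sd = c(d13c = 0.5, d15n = 0.5),
      lambda = c(littoral = 2.5, pelagic = 2),
      baseline_species = c(
        littoral = "oligochaete",
        pelagic = "dreissenid_mussel"
      ),
      n_baseline = 30,
      basin_offsets = list(
        west = c(d13c = -2, d15n = -1.5),
        central = c(d13c = 0, d15n = 0),
        east = c(d13c = 2, d15n = 1.5)
      ),
      species = list(
        species_spec("smallmouth_bass", 15, c(0.8, 1.4), 3.6),
        species_spec("walleye", 15, c(0.1, 0.7), 4.2),
        species_spec("yellow_perch", 15, c(0.4, 1.1), 3.4),
        species_spec("white_sucker", 15, c(0.5, 1.0), 3.0)
      ),
      noise_sd = 0.2, seed = 202
    ),
    temporal_tissue = system_spec(
      baseline_d13c = c(littoral = -22, pelagic = -30),
      baseline_d15n = c(littoral = 5, pelagic = 3.5),
      baseline_sd = c(d13c = 0.5, d15n = 0.4),
      lambda = c(littoral = 2.25, pelagic = 2),
      baseline_species = c(littoral = "mayfly", pelagic = "unionid_mussel"),
      n_baseline = 15,
      season_offsets = list(
        May = c(d13c = 0, d15n = 0),
        August = c(d13c = 1, d15n = 0.8)
      ),
      species = list(
        species_spec("lake_trout", 30, c(0.1, 0.5), 4.1,
          tissues = c("muscle", "fin", "liver")
        ),
        species_spec("smallmouth_bass", 30, c(0.5, 1.1), 3.6,
          tissues = c("muscle", "fin", "liver")
        ),
        species_spec("white_sucker", 30, c(0.4, 0.9), 3.0,
          tissues = c("muscle", "fin", "liver")
        )
      ),
      noise_sd = 0.2, seed = 303
    )
  )
}

#' Parameter-recovery report
#'
#' Compares the estimated metrics against the generator's ground truth:
#' per species and estimator, `bias = mean(estimate - truth)` and RMSE,
#' with the alpha estimators (the three LCU scalings) scored against
#' `true_alpha` and the nine TP variants against `true_tp`. Also reports
#' the fraction of raw LCU outside `[0, 1]` per species.
#'
#' @param measurements,truth The two tibbles from [generate_system()].
#' @param endmembers Optional single [endmember_set()] applied to all
#'   consumers; if `NULL`, endmembers are aggregated from the generated
#'   baselines under `policy`.
#' @param config A [metric_config()].
#' @param policy A [grouping_policy()] used when endmembers are built from
#'   the data.
#' @param lambdas Baseline trophic positions for endmember aggregation.
#' @return A tibble: `species`, `estimator`, `target` (`"alpha"`/`"tp"`),
#'   `n`, `bias`, `rmse`, `pct_outside` (raw-LCU rows only).
#' @export
recovery_report <- function(measurements, truth, endmembers = NULL,
                            config = metric_config(),
                            policy = grouping_policy(),
                            lambdas = c(littoral = 2, pelagic = 2)) {
  consumers <- measurements[measurements$role == "consumer", , drop = FALSE]
  if (!setequal(consumers$specimen_id, truth$specimen_id)) {
    abort("Consumer specimen ids do not match the truth table.",
      class = "lcutools_error"
    )
  }
  if (!is.null(endmembers)) {
    baselines <- measurements[measurements$role != "consumer", , drop = FALSE]
    records <- compute_metric_suite(consumers, endmembers, baselines, config)
    records$species <- consumers$species[match(
      records$specimen_id, consumers$specimen_id
    )]
  } else {
    records <- compute_records(measurements, policy, config, lambdas)
  }
  joined <- dplyr::inner_join(records, truth[, c(
    "specimen_id", "true_alpha", "true_tp"
  )], by = "specimen_id")
  score <- function(est, target_col, target_lbl) {
    err <- joined[[est]] - joined[[target_col]]
    dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(species = joined$species, err = err, raw = joined$lcu),
        .data$species
      ),
      estimator = est, target = target_lbl,
      n = sum(is.finite(.data$err)),
      bias = mean(.data$err[is.finite(.data$err)]),
      rmse = sqrt(mean(.data$err[is.finite(.data$err)]^2)),
      pct_outside = if (est == "lcu") {
        100 * mean(.data$raw > 1 | .data$raw < 0)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  }
  out <- dplyr::bind_rows(
    lapply(.lcu_variants, score, target_col = "true_alpha", target_lbl = "alpha"),
    lapply(.tp_variants, score, target_col = "true_tp", target_lbl = "tp")
  )
  dplyr::arrange(out, .data$species, .data$target, .data$estimator)
}
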