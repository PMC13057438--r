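# Building endmember sets from raw baseline measurements, and the screens
# that decide how consumers are matched to baselines across strata, seasons
# and tissues.

#' Aggregate baseline specimens into an endmember set
#'
#' Takes arithmetic means of d13C and d15N per habitat over the baseline
#' specimens falling inside the requested scope, records counts, and attaches
#' the assumed trophic position of each habitat's baseline taxon.
#'
#' @param baseline_samples Data frame of measurements with columns `role`
#'   (`littoral_baseline` / `pelagic_baseline`), `d13c`, `d15n` and
#'   optionally `stratum`, `season`.
#' @param stratum,season Scope filters; `NULL` pools across the factor.
#' @param lambdas Named numeric vector `c(littoral = , pelagic = )` of
#'   assumed baseline trophic positions.
#' @return An [endmember_set()] whose scope labels record the filters
#'   applied (`"all"` where pooled).
#' @examples
#' bl <- tibble::tibble(
#'   role = c("littoral_baseline", "littoral_baseline", "pelagic_baseline"),
#'   d13c = c(-20, -22, -28), d15n = c(6, 6.5, 4)
#' )
#' aggregate_endmembers(bl, lambdas = c(littoral = 2.25, pelagic = 2))
#' @export
aggregate_endmembers <- function(baseline_samples, stratum = NULL,
                                 season = NULL,
                                 lambdas = c(littoral = 2, pelagic = 2)) {
  stopifnot(all(c("littoral", "pelagic") %in% names(lambdas)))
  dat <- baseline_samples
  if (!is.null(stratum)) dat <- dat[dat$stratum == stratum, , drop = FALSE]
  if (!is.null(season)) dat <- dat[dat$season == season, , drop = FALSE]
  lit <- dat[dat$role == "littoral_baseline", , drop = FALSE]
  pel <- dat[dat$role == "pelagic_baseline", , drop = FALSE]
  scope_txt <- paste0(
    "stratum = ", stratum %||% "all", ", season = ", season %||% "all"
  )
  if (nrow(lit) == 0 || nrow(pel) == 0) {
    missing <- if (nrow(lit) == 0) "littoral" else "pelagic"
    abort(
      paste0("No ", missing, " baseline specimens in scope (", scope_txt, ")."),
      class = "lcutools_error"
    )
  }
  endmember_set(
    d13c_littoral = mean(lit$d13c), d13c_pelagic = mean(pel$d13c),
    d15n_littoral = mean(lit$d15n), d15n_pelagic = mean(pel$d15n),
    lambda_littoral = lambdas[["littoral"]],
    lambda_pelagic = lambdas[["pelagic"]],
    n_littoral = nrow(lit), n_pelagic = nrow(pel),
    stratum = stratum %||% "all", season = season %||% "all"
  )
}

#' Test whether the two habitat baselines are isotopically distinct
#'
#' Two-sided Wilcoxon rank-sum tests of littoral vs pelagic baseline values,
#' run separately for d13C and d15N. Distinct baselines justify the
#' two-source mixing model; indistinct d13C baselines signal a one-source
#' system. Exact enumeration is used when both groups have at most 8 tie-free
#' values; otherwise the tie-corrected normal approximation.
#'
#' @param littoral,pelagic Data frames of baseline measurements with columns
#'   `d13c` and `d15n` (at least 2 rows each).
#' @param alpha_level Significance level for the `distinct` flag. Default
#'   0.05.
#' @return A tibble with one row per isotope: `isotope`, `statistic`,
#'   `p_value`, `distinct`, `alpha_level`, `n_littoral`, `n_pelagic`,
#'   `exact`.
#' @export
test_habitat_distinctness <- function(littoral, pelagic, alpha_level = 0.05) {
  if (nrow(littoral) < 2 || nrow(pelagic) < 2) {
    abort("Need at least 2 baseline specimens per habitat.",
      class = "lcutools_error"
    )
  }
  one <- function(iso) {
    res <- rank_sum_test(littoral[[iso]], pelagic[[iso]])
    tibble::tibble(
      isotope = iso,
      statistic = res$statistic,
      p_value = res$p_value,
      distinct = res$p_value < alpha_level,
      alpha_level = alpha_level,
      n_littoral = nrow(littoral),
      n_pelagic = nrow(pelagic),
      exact = res$exact
    )
  }
  dplyr::bind_rows(one("d13c"), one("d15n"))
}

#' Screen a grouping factor for isotopic structure
#'
#' Decides whether a candidate grouping factor (stratum/basin, season,
#' tissue) structures the isotope data of each species and therefore should
#' drive baseline matching. With more than two levels: Kruskal-Wallis per
#' isotope followed by Dunn's pairwise tests with Bonferroni adjustment.
#' With exactly two levels: Wilcoxon rank-sum. Seasons are screened within
#' species x tissue, since tissues integrate diet over different timescales.
#'
#' @param samples Data frame of measurements (columns `species`, `d13c`,
#'   `d15n`, plus the factor column, plus `tissue` when screening seasons).
#' @param factor One of `"stratum"`, `"season"`, `"tissue"`.
#' @param alpha_level Significance level. Default 0.05.
#' @return A tibble with one row per species (x tissue for the season
#'   screen) x isotope: grouping columns, `isotope`, `n_levels`, `method`,
#'   `statistic`, `p_value`, `significant`, and a `pairwise` list-column of
#'   Dunn results (`NULL` for two-level screens).
#' @export
screen_grouping_factors <- function(samples,
                                    factor = c("stratum", "season", "tissue"),
                                    alpha_level = 0.05) {
  factor <- match.arg(factor)
  by_cols <- "species"
  if (factor == "season" && "tissue" %in% names(samples) &&
    length(unique(samples$tissue)) > 1) {
    by_cols <- c("species", "tissue")
  }
  groups <- dplyr::group_split(dplyr::group_by(
    samples,
    dplyr::across(dplyr::all_of(by_cols))
  ))
  rows <- lapply(groups, function(grp) {
    lev_tab <- table(grp[[factor]])
    usable <- names(lev_tab)[lev_tab >= 2]
    if (length(usable) < 2) {
      abort(
        paste0(
          "Fewer than 2 usable levels of `", factor, "` (>= 2 obs each) for ",
          paste(unlist(grp[1, by_cols]), collapse = "/"), "."
        ),
        class = "lcutools_error"
      )
    }
    grp <- grp[grp[[factor]] %in% usable, , drop = FALSE]
    iso_rows <- lapply(c("d13c", "d15n"), function(iso) {
      x <- grp[[iso]]
      g <- factor(grp[[factor]])
      if (length(usable) == 2) {
        res <- rank_sum_test(x[g == usable[1]], x[g == usable[2]])
        out <- tibble::tibble(
          isotope = iso, n_levels = 2L, method = "wilcoxon",
          statistic = res$statistic, p_value = res$p_value,
          significant = res$p_value < alpha_level,
          pairwise = list(NULL)
        )
      } else {
        omni <- kruskal_omnibus(x, g)
        pw <- dunn_test(x, g, p_adjust = "bonferroni", alpha_level = alpha_level)
        out <- tibble::tibble(
          isotope = iso, n_levels = length(usable), method = "kruskal_dunn",
          statistic = omni$statistic, p_value = omni$p_value,
          significant = omni$p_value < alpha_level,
          pairwise = list(pw)
        )
      }
      dplyr::bind_cols(grp[1, by_cols, drop = FALSE], out)
    })
    dplyr::bind_rows(iso_rows)
  })
  dplyr::bind_rows(rows)
}

#' Baseline-matching policy
#'
#' Encodes how consumers are matched to endmember sets: whether matching is
#' restricted to the consumer's stratum (e.g. basin), and per tissue whether
#' baselines from the consumer's season are used or season-pooled baselines.
#' Fast-turnover tissues (liver) reflect recent diet and should be
#' season-matched; slow tissues (muscle, fin) integrate across seasons.
#'
#' @param stratum_matching Match consumers to same-stratum endmembers?
#'   Default `TRUE`.
#' @param season_matching Named character vector mapping each tissue to
#'   `"match_season"` or `"pool_seasons"`.
#' @return A list of class `grouping_policy`.
#' @export
grouping_policy <- function(stratum_matching = TRUE,
                            season_matching = c(
                              muscle = "pool_seasons",
                              fin = "pool_seasons",
                              liver = "match_season",
                              whole = "pool_seasons"
                            )) {
  bad <- setdiff(unique(season_matching), c("match_season", "pool_seasons"))
  if (length(bad) > 0) {
    abort(paste0(
      "Invalid season matching rule(s): ", paste(bad, collapse = ", "),
      ". Use 'match_season' or 'pool_seasons'."
    ), class = "lcutools_error")
  }
  structure(
    list(
      stratum_matching = isTRUE(stratum_matching),
      season_matching = season_matching
    ),
    class = "grouping_policy"
  )
}

#' Build the table of endmember sets a policy requires
#'
#' Aggregates baseline specimens into one endmember set per scope the policy
#' can request: each stratum (or `"all"` when stratum matching is off)
#' crossed with each observed season plus the season-pooled `"all"` set.
#'
#' @param baseline_samples Data frame of baseline measurements.
#' @param policy A [grouping_policy()].
#' @param lambdas Named vector of baseline trophic positions, as in
#'   [aggregate_endmembers()].
#' @return A tibble with columns `stratum`, `season` and a list-column
#'   `endmembers` of [endmember_set()] objects.
#' @export
build_endmember_table <- function(baseline_samples,
                                  policy = grouping_policy(),
                                  lambdas = c(littoral = 2, pelagic = 2)) {
  strata <- if (policy$stratum_matching && "stratum" %in% names(baseline_samples)) {
    unique(as.character(baseline_samples$stratum))
  } else {
    NA_character_
  }
  seasons <- if ("season" %in% names(baseline_samples)) {
    unique(as.character(baseline_samples$season))
  } else {
    character(0)
  }
  need_season <- any(policy$season_matching == "match_season") &&
    length(seasons) > 1
  season_scopes <- c(NA_character_, if (need_season) seasons)
  rows <- list()
  for (st in strata) {
    for (se in season_scopes) {
      em <- tryCatch(
        aggregate_endmembers(
          baseline_samples,
          stratum = if (is.na(st)) NULL else st,
          season = if (is.na(se)) NULL else se,
          lambdas = lambdas
        ),
        lcutools_error = function(e) NULL
      )
      if (!is.null(em)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          stratum = em$stratum, season = em$season, endmembers = list(em)
        )
      }
    }
  }
  if (length(rows) == 0) {
    abort("No scope contained both littoral and pelagic baseline specimens.",
      class = "lcutools_error"
    )
  }
  dplyr::bind_rows(rows)
}

#' Resolve the endmember set for a consumer
#'
#' Applies the matching policy: the set from the consumer's stratum when
#' stratum matching is on, and from the consumer's season when its tissue is
#' season-matched (fast turnover), otherwise the season-pooled set.
#'
#' @param consumer A one-row data frame (or list) with `stratum`, `season`,
#'   `tissue`.
#' @param endmember_table Output of [build_endmember_table()].
#' @param policy A [grouping_policy()].
#' @return The matching [endmember_set()].
#' @export
resolve_endmembers <- function(consumer, endmember_table,
                               policy = grouping_policy()) {
  want_stratum <- if (policy$stratum_matching) {
    as.character(consumer$stratum)
  } else {
    "all"
  }
  tissue <- as.character(consumer$tissue)
  rule <- policy$season_matching[tissue]
  if (is.na(rule)) rule <- "pool_seasons"
  want_season <- if (rule == "match_season") as.character(consumer$season) else "all"
  hit <- which(endmember_table$stratum == want_stratum &
    endmember_table$season == want_season)
  if (length(hit) == 0) {
    avail <- paste0(
      "(", endmember_table$stratum, ", ", endmember_table$season, ")",
      collapse = ", "
    )
    abort(paste0(
      "No endmember set for scope (", want_stratum, ", ", want_season,
      "). Available scopes: ", avail, "."
    ), class = "lcutools_error")
  }
  endmember_table$endmembers[[hit[1]]]
}
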