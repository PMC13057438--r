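# Shared fixtures, all built in code.

em_default <- function(...) {
  args <- utils::modifyList(
    list(
      d13c_littoral = -20, d13c_pelagic = -28,
      d15n_littoral = 6, d15n_pelagic = 4
    ),
    list(...)
  )
  do.call(endmember_set, args)
}

# n baseline specimens per habitat with given means/SD, one scope
baseline_tbl <- function(n = 10, d13c = c(littoral = -20, pelagic = -28),
                         d15n = c(littoral = 6, pelagic = 4), sd = 0.3,
                         stratum = "main", season = "all", seed = 42) {
  set.seed(seed)
  dplyr::bind_rows(lapply(c("littoral", "pelagic"), function(h) {
    tibble::tibble(
      specimen_id = sprintf("bl_%s_%s_%s_%02d", h, stratum, season, seq_len(n)),
      species = if (h == "littoral") "mayfly" else "mussel",
      role = paste0(h, "_baseline"),
      tissue = "whole", season = season, stratum = stratum,
      d13c = rnorm(n, d13c[[h]], sd),
      d15n = rnorm(n, d15n[[h]], sd)
    )
  }))
}

consumer_tbl <- function(d13c, d15n, species = "fish", tissue = "muscle",
                         season = "all", stratum = "main") {
  n <- length(d13c)
  tibble::tibble(
    specimen_id = sprintf("c_%s_%s_%03d", species, tissue, seq_len(n)),
    species = species, role = "consumer", tissue = tissue,
    season = season, stratum = stratum, d13c = d13c, d15n = d15n
  )
}

# noise-free preset variant with grid alphas spanning the species ranges
noise_free_simple <- function() {
  spec <- scenario_presets()$simple
  spec$noise_sd <- 0
  spec$baseline_sd <- c(d13c = 0, d15n = 0)
  spec$species <- lapply(spec$species, function(sp) {
    sp$alpha_dist <- "grid"
    sp
  })
  spec
}
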