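#' Load a pipeline configuration file
#'
#' Reads a YAML configuration carrying league structures, season labels,
#' null-test settings, and generator parameters. Every section is
#' optional; missing entries fall back to the package defaults. The
#' shipped default file is at
#' `system.file("extdata", "default_config.yaml", package = "hfamc")`.
#'
#' @param path YAML file path, or `NULL` for the shipped defaults.
#' @return a list with elements `structures` (tibble), `base_seasons`,
#'   `closed_season`, `null_spec` (an [null_spec()]), and `sim_params`
#'   (an [sim_params()]).
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "hfamc")
  }
  cfg <- yaml::read_yaml(path)

  structures <- if (!is.null(cfg$leagues)) {
    dplyr::bind_rows(lapply(cfg$leagues, function(l) {
      tibble(league = l$league,
             matchdays_per_season = as.integer(l$matchdays_per_season),
             matches_per_matchday = as.integer(l$matches_per_matchday),
             closed_door_matches = as.integer(l$closed_door_matches))
    }))
  } else {
    league_structures()
  }
  base_seasons <- cfg$baseline_seasons %||% baseline_seasons()
  closed_season <- cfg$closed_door_season %||% closed_door_season()

  ns <- cfg$null_spec %||% list()
  spec <- null_spec(
    n_draws = ns$n_draws %||% 1e6,
    seed = ns$seed,
    scheme = ns$scheme %||% "overall_stratified",
    tie_rule = ns$tie_rule %||% "inclusive_both",
    alpha = ns$alpha %||% 0.05,
    zero_denominator_share = ns$zero_denominator_share %||% 0.5,
    add_one = isTRUE(ns$add_one)
  )

  sp <- cfg$sim_params %||% list()
  pair <- function(x, default) {
    if (is.null(x)) default else c(home = x$home, away = x$away)
  }
  params <- sim_params(
    structures = structures,
    goal_rates = pair(sp$goal_rates, c(home = 1.5, away = 1.2)),
    shot_rates = pair(sp$shot_rates, c(home = 14, away = 11)),
    possession_shape = if (is.null(sp$possession_shape))
      c(alpha = 20, beta = 17) else
      c(alpha = sp$possession_shape$alpha, beta = sp$possession_shape$beta),
    foul_rates = pair(sp$foul_rates, c(home = 12, away = 13)),
    yellow_rates = pair(sp$yellow_rates, c(home = 1.8, away = 2.1)),
    red_probs = pair(sp$red_probs, c(home = 0.04, away = 0.06)),
    effect = if (is.null(sp$effect))
      c(goals = 1, shots = 1, possession = 1, fouls = 1, yellows = 1,
        reds = 1) else unlist(sp$effect),
    base_seasons = base_seasons,
    closed_season = closed_season,
    seed = sp$seed,
    null = isTRUE(sp$null_mode)
  )
  list(structures = structures, base_seasons = base_seasons,
       closed_season = closed_season, null_spec = spec,
       sim_params = params)
}
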