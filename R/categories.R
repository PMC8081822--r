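#' The seven home-team share categories
#'
#' Each category is a per-match statistic whose home-team share over a set
#' of matches measures one facet of the home-field advantage. The four
#' *offense* categories (points, goals, shots, possession) favor the home
#' side when their share exceeds 0.5; the three *referee* categories
#' (fouls, yellow cards, red cards) count sanctions against each side, so a
#' share *below* 0.5 favors the home side.
#'
#' @return A tibble with columns `category` and `direction`
#'   (`"offense"` or `"referee"`), in the canonical reporting order.
#' @export
#' @examples
#' hfa_categories()
hfa_categories <- function() {
  tibble(
    category = c("points", "goals", "shots", "possession",
                 "fouls", "yellows", "reds"),
    direction = c(rep("offense", 4L), rep("referee", 3L))
  )
}

category_names <- function() hfa_categories()$category

#' Advantage direction of a category
#'
#' @param category one of `"points"`, `"goals"`, `"shots"`, `"possession"`,
#'   `"fouls"`, `"yellows"`, `"reds"`.
#' @return `"offense"` or `"referee"`.
#' @export
category_direction <- function(category) {
  cats <- hfa_categories()
  category <- match.arg(category, cats$category)
  cats$direction[match(category, cats$category)]
}

#' League points awarded for a final score
#'
#' Standard three-point rule: the winner earns 3 points, the loser 0, and a
#' draw gives 1 point to each side. Vectorized over matches.
#'
#' @param home_goals,away_goals non-negative integer goal counts.
#' @return A tibble with integer columns `home_points` and `away_points`.
#' @export
#' @examples
#' points_from_score(2, 1)   # 3 - 0
#' points_from_score(1, 1)   # 1 - 1
points_from_score <- function(home_goals, away_goals) {
  stopifnot(length(home_goals) == length(away_goals))
  if (any(home_goals < 0) || any(away_goals < 0))
    stop("goal counts must be non-negative", call. = FALSE)
  hp <- ifelse(home_goals > away_goals, 3L,
               ifelse(home_goals < away_goals, 0L, 1L))
  ap <- ifelse(away_goals > home_goals, 3L,
               ifelse(away_goals < home_goals, 0L, 1L))
  tibble(home_points = as.integer(hp), away_points = as.integer(ap))
}

#' Per-match home and away amounts for a category
#'
#' Routes the `points` category through [points_from_score()]; `possession`
#' passes the two printed percentages through; every other category returns
#' the raw per-side counts.
#'
#' @param matches a match tibble (one row per match, canonical columns; see
#'   [read_matches()]).
#' @param category category name.
#' @return A tibble with numeric columns `home` and `away`, one row per match.
#' @export
category_amounts <- function(matches, category) {
  category <- match.arg(category, category_names())
  switch(category,
    points = {
      pts <- points_from_score(matches$home_goals, matches$away_goals)
      tibble(home = as.numeric(pts$home_points),
             away = as.numeric(pts$away_points))
    },
    goals = tibble(home = as.numeric(matches$home_goals),
                   away = as.numeric(matches$away_goals)),
    shots = tibble(home = as.numeric(matches$home_shots),
                   away = as.numeric(matches$away_shots)),
    possession = tibble(home = as.numeric(matches$home_possession),
                        away = as.numeric(matches$away_possession)),
    fouls = tibble(home = as.numeric(matches$home_fouls),
                   away = as.numeric(matches$away_fouls)),
    yellows = tibble(home = as.numeric(matches$home_yellows),
                     away = as.numeric(matches$away_yellows)),
    reds = tibble(home = as.numeric(matches$home_reds),
                  away = as.numeric(matches$away_reds))
  )
}

# home / total amount vectors for the resampling kernels
share_vectors <- function(matches, category) {
  am <- category_amounts(matches, category)
  list(home = am$home, total = am$home + am$away)
}

#' Aggregate home-team share of a category over a set of matches
#'
#' The share is the ratio of aggregate sums,
#' \eqn{\sum \mathrm{home} / \sum (\mathrm{home} + \mathrm{away})}, over
#' all matches in the set — not the mean of per-match shares. When the
#' denominator is zero (possible for rare events such as red cards in small
#' samples) the value carries an explicit undefined marker rather than a
#' silent 0; downstream resampling maps undefined shares to a configurable
#' neutral value.
#'
#' @param matches non-empty match tibble.
#' @param category category name.
#' @return An object of class `hfa_share`: a list with fields `value`
#'   (proportion, or `NA` when undefined), `defined`, `numerator`,
#'   `denominator`, and `category`.
#' @export
#' @examples
#' m <- toy_matches(6)
#' home_share(m, "points")
home_share <- function(matches, category) {
  category <- match.arg(category, category_names())
  if (is.null(nrow(matches)) || nrow(matches) == 0L)
    stop("home_share() requires a non-empty set of matches", call. = FALSE)
  v <- share_vectors(matches, category)
  num <- sum(v$home)
  den <- sum(v$total)
  structure(
    list(
      value = if (den > 0) num / den else NA_real_,
      defined = den > 0,
      numerator = num,
      denominator = den,
      category = category
    ),
    class = "hfa_share"
  )
}

#' @export
print.hfa_share <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<hfa_share> %s: %.4f (%g / %g over matches)\n",
                x$category, x$value, x$numerator, x$denominator))
  } else {
    cat(sprintf("<hfa_share> %s: undefined (zero denominator)\n",
                x$category))
  }
  invisible(x)
}
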