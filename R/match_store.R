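#' League structures and expected closed-door counts
#'
#' Defaults describe the four top European divisions over the study window:
#' Germany plays 34 matchdays of 9 matches per season (18 clubs), while
#' Spain, England, and Italy play 38 matchdays of 10 matches (20 clubs).
#' `closed_door_matches` is the number of matches each league completed
#' without spectators at the end of the 2019/2020 season.
#'
#' @param leagues subset of `c("DE", "ES", "EN", "IT")` to keep.
#' @return A tibble with columns `league`, `matchdays_per_season`,
#'   `matches_per_matchday`, `closed_door_matches`.
#' @export
#' @examples
#' league_structures()
#' league_structures("DE")
league_structures <- function(leagues = c("DE", "ES", "EN", "IT")) {
  all <- tibble(
    league = c("DE", "ES", "EN", "IT"),
    matchdays_per_season = c(34L, 38L, 38L, 38L),
    matches_per_matchday = c(9L, 10L, 10L, 10L),
    closed_door_matches = c(83L, 111L, 92L, 130L)
  )
  leagues <- match.arg(leagues, all$league, several.ok = TRUE)
  all[match(leagues, all$league), ]
}

#' Default baseline season labels
#'
#' The four full seasons preceding the closed-door period. Season labels
#' are opaque strings matched exactly; no date arithmetic is performed.
#'
#' @return character vector of four season labels.
#' @export
baseline_seasons <- function() {
  c("2015/2016", "2016/2017", "2017/2018", "2018/2019")
}

#' @rdname baseline_seasons
#' @export
closed_door_season <- function() "2019/2020"

match_columns <- function() {
  c("league", "season", "home_team", "away_team",
    "home_goals", "away_goals", "home_shots", "away_shots",
    "home_possession", "away_possession", "home_fouls", "away_fouls",
    "home_yellows", "away_yellows", "home_reds", "away_reds", "crowd")
}

count_columns <- function() {
  c("home_goals", "away_goals", "home_shots", "away_shots",
    "home_fouls", "away_fouls", "home_yellows", "away_yellows",
    "home_reds", "away_reds")
}

# Tolerance on home + away possession summing to 100: source sites print
# integer (or one-decimal) percentages, so broadcast rounding can leave the
# pair up to half a point off.
POSSESSION_SUM_TOL <- 0.5

#' Row-level structural validation of match records
#'
#' Checks every row against the match-record invariants: counts are
#' non-negative integers, possession percentages lie in \[0, 100\] and sum
#' to 100 within a tolerance of 0.5, a team never plays itself, the crowd
#' flag is one of the two recognised values, and closed-door rows carry the
#' closed-door season label.
#'
#' @param matches match tibble.
#' @param leagues recognised league codes.
#' @param closed_season season label required on closed-door rows.
#' @return A tibble of problems with columns `row`, `field`, `problem`;
#'   zero rows when everything validates.
#' @export
validate_matches <- function(matches,
                             leagues = league_structures()$league,
                             closed_season = closed_door_season()) {
  probs <- list()
  note <- function(row, field, problem) {
    probs[[length(probs) + 1L]] <<- tibble(row = row, field = field,
                                           problem = problem)
  }
  for (col in count_columns()) {
    x <- matches[[col]]
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    for (r in bad) note(r, col, "count must be a non-negative integer")
  }
  for (col in c("home_possession", "away_possession")) {
    x <- matches[[col]]
    bad <- which(is.na(x) | x < 0 | x > 100)
    for (r in bad) note(r, col, "possession must lie in [0, 100]")
  }
  psum <- matches$home_possession + matches$away_possession
  bad <- which(!is.na(psum) & abs(psum - 100) > POSSESSION_SUM_TOL)
  for (r in bad) {
    note(r, "home_possession",
         sprintf("possession sums to %.1f (must be 100 within %.1f)",
                 psum[r], POSSESSION_SUM_TOL))
  }
  bad <- which(matches$home_team == matches$away_team)
  for (r in bad) note(r, "home_team", "home and away team identical")
  bad <- which(!matches$league %in% leagues)
  for (r in bad) note(r, "league",
                      sprintf("unrecognised league '%s'", matches$league[r]))
  bad <- which(!matches$crowd %in% c("with_spectators", "closed_doors"))
  for (r in bad) note(r, "crowd",
                      "crowd must be 'with_spectators' or 'closed_doors'")
  bad <- which(matches$crowd == "closed_doors" &
                 matches$season != closed_season)
  for (r in bad) {
    note(r, "season",
         sprintf("closed-door rows must have season '%s'", closed_season))
  }
  if (length(probs) == 0L) {
    tibble(row = integer(), field = character(), problem = character())
  } else {
    out <- dplyr::bind_rows(probs)
    out[order(out$row), ]
  }
}

#' Construct a baseline / closed-door dataset from match records
#'
#' Partitions validated match rows into the two analysis periods: the
#' baseline (matches played with spectators during the baseline seasons)
#' and the closed-door test set (matches of the closed-door season played
#' without spectators). Rows from other season/crowd combinations — for
#' example closed-door-season matches that were still played in front of
#' spectators — belong to neither period and are dropped with a logged
#' count, and rows violating the record invariants are rejected with
#' row-level diagnostics.
#'
#' @param matches match tibble with the canonical columns.
#' @param base_seasons baseline season labels.
#' @param closed_season the closed-door season label.
#' @param leagues recognised league codes.
#' @param quiet suppress messages about dropped/rejected rows.
#' @return An object of class `hfa_dataset`: a list with tibbles
#'   `baseline` and `closed_doors`, plus attributes `problems` (the
#'   rejection diagnostics) and `n_dropped` (rows in neither period).
#' @export
hfa_dataset <- function(matches,
                        base_seasons = baseline_seasons(),
                        closed_season = closed_door_season(),
                        leagues = league_structures()$league,
                        quiet = FALSE) {
  missing_cols <- setdiff(match_columns(), names(matches))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  matches <- as_tibble(matches)[, match_columns()]
  probs <- validate_matches(matches, leagues = leagues,
                            closed_season = closed_season)
  if (nrow(probs) > 0L) {
    bad_rows <- unique(probs$row)
    if (!quiet) {
      message(sprintf("rejected %d invalid row(s); see attr(, 'problems')",
                      length(bad_rows)))
    }
    matches <- matches[-bad_rows, ]
  }
  is_base <- matches$crowd == "with_spectators" &
    matches$season %in% base_seasons
  is_closed <- matches$crowd == "closed_doors" &
    matches$season == closed_season
  n_dropped <- sum(!is_base & !is_closed)
  if (n_dropped > 0L && !quiet) {
    message(sprintf(
      "dropped %d row(s) outside both analysis periods (e.g. %s matches played with spectators)",
      n_dropped, closed_season))
  }
  structure(
    list(baseline = matches[is_base, ], closed_doors = matches[is_closed, ]),
    problems = probs,
    n_dropped = n_dropped,
    class = "hfa_dataset"
  )
}

#' @export
print.hfa_dataset <- function(x, ...) {
  cat(sprintf(
    "<hfa_dataset> baseline: %d matches, closed doors: %d matches\n",
    nrow(x$baseline), nrow(x$closed_doors)))
  for (lg in sort(unique(c(x$baseline$league, x$closed_doors$league)))) {
    cat(sprintf("  %s: %d baseline / %d closed-door\n", lg,
                sum(x$baseline$league == lg),
                sum(x$closed_doors$league == lg)))
  }
  invisible(x)
}

#' Read match records from CSV
#'
#' Expects a UTF-8 CSV with a header and the canonical columns (league,
#' season, teams, per-side goals/shots/possession/fouls/yellows/reds, and a
#' `crowd` flag). Rows violating the record invariants are rejected with
#' row-level diagnostics; a missing column is an error.
#'
#' @inheritParams hfa_dataset
#' @param path CSV file path.
#' @return An `hfa_dataset`; see [hfa_dataset()].
#' @export
read_matches <- function(path,
                         base_seasons = baseline_seasons(),
                         closed_season = closed_door_season(),
                         leagues = league_structures()$league,
                         quiet = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    league = readr::col_character(),
    season = readr::col_character(),
    home_team = readr::col_character(),
    away_team = readr::col_character(),
    home_possession = readr::col_double(),
    away_possession = readr::col_double(),
    crowd = readr::col_character(),
    .default = readr::col_integer()
  ))
  hfa_dataset(raw, base_seasons = base_seasons,
              closed_season = closed_season, leagues = leagues,
              quiet = quiet)
}

#' Write a dataset back to the canonical CSV schema
#'
#' @param dataset an `hfa_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(dataset, path) {
  stopifnot(inherits(dataset, "hfa_dataset"))
  readr::write_csv(dplyr::bind_rows(dataset$baseline, dataset$closed_doors),
                   path)
  invisible(path)
}

#' Check dataset sizes against the expected league structures
#'
#' Compares per-league baseline counts against
#' `matchdays_per_season * matches_per_matchday * n_seasons` and the
#' closed-door counts against `closed_door_matches`, plus overall totals.
#' A reporting operation: mismatches are flagged, never fatal. With the
#' default structures a full-fidelity dataset has 5,784 baseline and 416
#' closed-door matches (6,200 in total).
#'
#' @param dataset an `hfa_dataset`.
#' @param structures league structure tibble, see [league_structures()].
#' @param n_seasons number of baseline seasons.
#' @return A tibble with columns `scope`, `partition`, `expected`,
#'   `actual`, `ok`.
#' @export
validate_counts <- function(dataset, structures = league_structures(),
                            n_seasons = length(baseline_seasons())) {
  stopifnot(inherits(dataset, "hfa_dataset"))
  rows <- lapply(seq_len(nrow(structures)), function(i) {
    lg <- structures$league[i]
    exp_base <- structures$matchdays_per_season[i] *
      structures$matches_per_matchday[i] * n_seasons
    exp_closed <- structures$closed_door_matches[i]
    tibble(
      scope = lg,
      partition = c("baseline", "closed_doors"),
      expected = c(exp_base, exp_closed),
      actual = c(sum(dataset$baseline$league == lg),
                 sum(dataset$closed_doors$league == lg))
    )
  })
  out <- dplyr::bind_rows(rows)
  overall <- tibble(
    scope = "overall",
    partition = c("baseline", "closed_doors"),
    expected = c(sum(out$expected[out$partition == "baseline"]),
                 sum(out$expected[out$partition == "closed_doors"])),
    actual = c(nrow(dataset$baseline), nrow(dataset$closed_doors))
  )
  out <- dplyr::bind_rows(out, overall)
  out$ok <- out$expected == out$actual
  out
}

#' Small deterministic match fixture
#'
#' Builds `n` structurally valid matches with varied scores, shot counts,
#' possession splits, and card counts from simple arithmetic patterns (no
#' randomness). Used for examples, enumeration oracles, and tests.
#'
#' @param n number of matches.
#' @param league,season,crowd constants applied to every row.
#' @return a match tibble.
#' @export
#' @examples
#' toy_matches(4)
toy_matches <- function(n = 12, league = "DE", season = "2015/2016",
                        crowd = "with_spectators") {
  i <- seq_len(n)
  hp <- 44 + (i %% 5L) * 3
  tibble(
    league = league,
    season = season,
    home_team = sprintf("H%02d", i),
    away_team = sprintf("A%02d", i),
    home_goals = as.integer(i %% 4L),
    away_goals = as.integer((i + 1L) %% 3L),
    home_shots = as.integer(8L + (i %% 5L)),
    away_shots = as.integer(10L + (i %% 3L)),
    home_possession = hp,
    away_possession = 100 - hp,
    home_fouls = as.integer(9L + (i %% 6L)),
    away_fouls = as.integer(12L + (i %% 4L)),
    home_yellows = as.integer(i %% 3L),
    away_yellows = as.integer((i + 1L) %% 4L),
    home_reds = as.integer(i %% 5L == 0L),
    away_reds = as.integer(i %% 4L == 0L),
    crowd = crowd
  )
}
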