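# Hand-checkable fixtures used across the suite.

# Baseline of four matches with final scores 3-0, 1-1, 0-3, 3-0.
# Home points per match: 3, 1, 0, 3; the six size-2 subsample points
# shares are {0.8, 0.5, 1.0, 0.2, 0.8, 0.5}.
worked_baseline <- function() {
  m <- toy_matches(4)
  m$home_goals <- c(3L, 1L, 0L, 3L)
  m$away_goals <- c(0L, 1L, 3L, 0L)
  m
}

# Closed-door pair {1-1, 0-2}: home points 1 of 5 -> points share 0.2.
worked_closed <- function() {
  m <- toy_matches(2, season = "2019/2020", crowd = "closed_doors")
  m$home_goals <- c(1L, 0L)
  m$away_goals <- c(1L, 2L)
  m
}

as_dataset <- function(baseline, closed) {
  hfa_dataset(dplyr::bind_rows(baseline, closed), quiet = TRUE)
}

# Swap every home_* field with its away_* counterpart.
mirror_matches <- function(m) {
  out <- m
  for (f in c("team", "goals", "shots", "possession", "fouls",
              "yellows", "reds")) {
    h <- paste0("home_", f)
    a <- paste0("away_", f)
    out[[h]] <- m[[a]]
    out[[a]] <- m[[h]]
  }
  out
}
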