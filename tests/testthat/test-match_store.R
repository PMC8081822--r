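test_that("points follow the 3/1/0 rule and swap with the scoreline", {
  expect_equal(points_from_score(2, 1), tibble::tibble(home_points = 3L,
                                                       away_points = 0L))
  expect_equal(points_from_score(1, 1), tibble::tibble(home_points = 1L,
                                                       away_points = 1L))
  expect_equal(points_from_score(0, 0), tibble::tibble(home_points = 1L,
                                                       away_points = 1L))
  grid <- expand.grid(h = 0:4, a = 0:4)
  fwd <- points_from_score(grid$h, grid$a)
  rev <- points_from_score(grid$a, grid$h)
  expect_equal(fwd$home_points, rev$away_points)
  expect_equal(fwd$away_points, rev$home_points)
  pairs <- paste(fwd$home_points, fwd$away_points)
  expect_true(all(pairs %in% c("3 0", "0 3", "1 1")))
})

test_that("a well-formed CSV reads into a validated dataset", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- dplyr::bind_rows(toy_matches(2), worked_closed())
  readr::write_csv(rows, path)
  ds <- read_matches(path, quiet = TRUE)
  expect_s3_class(ds, "hfa_dataset")
  expect_equal(nrow(ds$baseline), 2L)
  expect_equal(nrow(ds$closed_doors), 2L)
  expect_equal(nrow(attr(ds, "problems")), 0L)
})

test_that("rows violating record invariants are rejected with diagnostics", {
  bad <- toy_matches(3)
  bad$home_possession[2] <- 55
  bad$away_possession[2] <- 46   # sums to 101, beyond the 0.5 tolerance
  bad$away_reds[3] <- -1L
  probs <- validate_matches(bad)
  expect_setequal(unique(probs$row), c(2L, 3L))
  expect_true(any(grepl("possession sums", probs$problem)))
  expect_true(any(probs$field == "away_reds"))

  ds <- suppressMessages(hfa_dataset(bad))
  expect_equal(nrow(ds$baseline), 1L)
  expect_equal(nrow(attr(ds, "problems")), 2L)
})

test_that("closed-door rows outside the closed-door season are rejected", {
  m <- toy_matches(2, season = "2018/2019", crowd = "closed_doors")
  probs <- validate_matches(m)
  expect_equal(nrow(probs), 2L)
  expect_true(all(probs$field == "season"))
})

test_that("a missing column is a schema error", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- toy_matches(2)
  m$home_fouls <- NULL
  readr::write_csv(m, path)
  expect_error(read_matches(path, quiet = TRUE), "home_fouls")
})

test_that("closed-season matches played with spectators are neither baseline nor test data", {
  rows <- dplyr::bind_rows(
    toy_matches(3),
    toy_matches(2, season = "2019/2020", crowd = "with_spectators"),
    worked_closed()
  )
  expect_message(ds <- hfa_dataset(rows), "dropped 2 row")
  expect_equal(nrow(ds$baseline), 3L)
  expect_equal(nrow(ds$closed_doors), 2L)
  expect_equal(attr(ds, "n_dropped"), 2L)
})

test_that("write_matches then read_matches is the identity on valid datasets", {
  params <- sim_params(structures = league_structures(c("DE", "ES")),
                       seed = 5)
  params$structures$closed_door_matches <- c(9L, 10L)
  params$structures$matchdays_per_season <- c(3L, 2L)
  ds <- generate_dataset(params)
  path <- withr::local_tempfile(fileext = ".csv")
  write_matches(ds, path)
  ds2 <- read_matches(path, quiet = TRUE)
  expect_equal(as.data.frame(ds2$baseline), as.data.frame(ds$baseline))
  expect_equal(as.data.frame(ds2$closed_doors),
               as.data.frame(ds$closed_doors))
})

test_that("validate_counts reports expected versus actual sizes", {
  empty <- hfa_dataset(toy_matches(0), quiet = TRUE)
  rep <- validate_counts(empty)
  expect_true(all(rep$actual == 0L))
  expect_false(any(rep$ok))
  expect_equal(rep$expected[rep$scope == "overall"], c(5784L, 416L))

  # partial dataset: actuals counted per league, mismatches flagged not fatal
  part <- as_dataset(toy_matches(5), worked_closed())
  rep2 <- validate_counts(part)
  expect_equal(rep2$actual[rep2$scope == "DE"], c(5L, 2L))
  expect_false(rep2$ok[rep2$scope == "DE"][1])
})
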