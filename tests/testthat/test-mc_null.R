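test_that("tail counting respects direction and tie rule", {
  s <- c(0.8, 0.5, 1.0, 0.2, 0.8, 0.5)  # subsample shares of the worked baseline
  expect_equal(tail_count(s, 0.2, "points"), 1L)
  expect_equal(tail_count(c(0.4, 0.5, 0.6), 0.5, "fouls",
                          "inclusive_both"), 2L)
  expect_equal(tail_count(c(0.4, 0.5, 0.6), 0.5, "fouls",
                          "paper_asymmetric"), 1L)
  expect_equal(tail_count(s, 0.1, "points"), 0L)  # empty lower tail
  # inclusive counts >= asymmetric for referee; equal without ties
  for (obs in c(0.45, 0.5, 0.55)) {
    inc <- tail_count(c(0.4, 0.5, 0.6), obs, "yellows", "inclusive_both")
    asym <- tail_count(c(0.4, 0.5, 0.6), obs, "yellows", "paper_asymmetric")
    expect_gte(inc, asym)
    if (!obs %in% c(0.4, 0.5, 0.6)) expect_equal(inc, asym)
  }
})

test_that("exact enumeration reproduces hand-computed tail probabilities", {
  base <- worked_baseline()
  # independent hand enumeration: home points 3,1,0,3; the six pair shares
  hp <- c(3, 1, 0, 3)
  tp <- c(3, 2, 3, 3)
  pairs <- combn(4, 2)
  shares <- apply(pairs, 2, function(ix) sum(hp[ix]) / sum(tp[ix]))
  expect_setequal(round(shares, 10), round(c(0.8, 0.5, 1.0, 0.2, 0.8, 0.5), 10))

  expect_equal(exact_p(base, 2, 0.2, "points"), 1 / 6)
  expect_equal(exact_p(base, 2, 0.2, "points"),
               mean(shares <= 0.2))
  # n = N: a single subsample, p is exactly 0 or 1
  full_share <- home_share(base, "points")$value
  expect_equal(exact_p(base, 4, full_share, "points"), 1)
  expect_equal(exact_p(base, 4, full_share - 0.01, "points"), 0)
  # referee category at the maximum attainable share has a non-empty tail
  mx <- max(apply(pairs, 2, function(ix)
    sum(base$home_fouls[ix]) /
      sum(base$home_fouls[ix] + base$away_fouls[ix])))
  expect_gte(exact_p(base, 2, mx, "fouls"), 1 / 6)
  expect_error(exact_p(toy_matches(30), 15, 0.5, "points", cap = 1000),
               "cap")
})

test_that("subsample draws are uniform over unordered subsets", {
  expect_error(draw_subsample(worked_baseline(), 5), "cannot draw")
  expect_equal(nrow(draw_subsample(worked_baseline(), 0)), 0L)
  set.seed(8)
  full <- draw_subsample(worked_baseline(), 4)
  expect_setequal(full$home_team, worked_baseline()$home_team)

  # identify each size-2 subset of 4 by a power-of-2 weight sum
  w <- c(1, 2, 4, 8)
  set.seed(17)
  sums <- hfamc:::mc_subsample_sums(w, w, 2L, 60000L)
  freq <- table(factor(sums$num, levels = c(3, 5, 9, 6, 10, 12))) / 60000
  se <- sqrt((1 / 6) * (5 / 6) / 60000)
  expect_true(all(abs(freq - 1 / 6) <= 4 * se))
})

test_that("Monte Carlo p matches exact enumeration on the worked example", {
  ds <- as_dataset(worked_baseline(), worked_closed())
  spec <- null_spec(n_draws = 120000, seed = 23, scheme = "overall_pooled")
  res <- empirical_p(ds, "points", "overall", spec)
  expect_equal(res$observed_share, 0.2)
  expect_equal(res$n_test, 2L)
  expect_lt(abs(res$p_hat - 1 / 6), 4 * sqrt((1 / 6) * (5 / 6) / 120000))
})

test_that("identical spec and dataset give identical results in any order", {
  ds <- generate_dataset(sim_params(structures = league_structures("DE"),
                                    seed = 3))
  spec <- null_spec(n_draws = 3000, seed = 99, scheme = "overall_pooled")
  a <- run_analysis(ds, spec)
  b <- run_analysis(ds, spec)
  expect_identical(a, b)
  # cell streams are derived from the root seed, not from call order
  cell <- empirical_p(ds, "yellows", "DE", spec)
  expect_identical(cell$extreme_count,
                   a$extreme_count[a$scope == "DE" &
                                     a$category == "yellows"])
})

test_that("p_hat is monotone in the observed share, direction-aware", {
  base <- generate_dataset(sim_params(structures = league_structures("DE"),
                                      seed = 12))$baseline
  ds_for <- function(closed) {
    structure(list(baseline = base, closed_doors = closed),
              class = "hfa_dataset")
  }
  spec <- null_spec(n_draws = 4000, seed = 61)
  # closed sets with increasing home dominance
  seeds <- c(301, 302, 303)
  effects <- c(0.5, 1.0, 2.0)
  p_points <- p_fouls <- obs_points <- obs_fouls <- numeric(3)
  for (i in 1:3) {
    pr <- sim_params(structures = league_structures("DE"),
                     effect = c(goals = effects[i], shots = 1,
                                possession = 1, fouls = effects[i],
                                yellows = 1, reds = 1),
                     seed = seeds[1])   # same stream, different effect
    cd <- generate_dataset(pr)$closed_doors
    rp <- empirical_p(ds_for(cd), "points", "DE", spec)
    rf <- empirical_p(ds_for(cd), "fouls", "DE", spec)
    p_points[i] <- rp$p_hat; obs_points[i] <- rp$observed_share
    p_fouls[i] <- rf$p_hat;  obs_fouls[i] <- rf$observed_share
  }
  expect_true(all(diff(obs_points) > 0))
  expect_true(all(diff(p_points) >= 0))   # offense: larger share, larger p
  expect_true(all(diff(obs_fouls) > 0))
  expect_true(all(diff(p_fouls) <= 0))    # referee: larger share, smaller p
})

test_that("zero-denominator subsamples map to the neutral share and are logged", {
  base <- toy_matches(6)
  base$home_reds <- c(1L, 0L, 0L, 0L, 0L, 0L)
  base$away_reds <- c(0L, 1L, 0L, 0L, 0L, 0L)
  closed <- toy_matches(2, season = "2019/2020", crowd = "closed_doors")
  closed$home_reds <- c(1L, 0L); closed$away_reds <- c(0L, 0L)
  ds <- as_dataset(base, closed)
  spec <- null_spec(n_draws = 5000, seed = 4, scheme = "overall_pooled")
  res <- empirical_p(ds, "reds", "overall", spec)
  # C(4,2)/C(6,2) = 6/15 of subsets contain no red card at all
  expect_gt(res$n_zero_denominator, 0L)
  pe <- exact_p(base, 2, res$observed_share, "reds")
  expect_lt(abs(res$p_hat - pe), 4 * sqrt(pe * (1 - pe) / 5000) + 1e-12)
})

test_that("bootstrap CI brackets the share and degenerates correctly", {
  same <- toy_matches(8)
  same$home_goals <- rep(2L, 8); same$away_goals <- rep(1L, 8)
  ci <- baseline_share_ci(same, "points", replicates = 500, seed = 2)
  expect_equal(ci$lower, ci$share)
  expect_equal(ci$upper, ci$share)

  m <- generate_dataset(sim_params(structures = league_structures("DE"),
                                   null = TRUE, seed = 6))$baseline
  ci2 <- baseline_share_ci(m, "points", replicates = 2000, seed = 7)
  expect_lte(ci2$lower, ci2$share)
  expect_gte(ci2$upper, ci2$share)
})

test_that("bootstrap CIs for a symmetric generator cover 0.5 at close to nominal rate", {
  covered <- 0L
  for (r in 1:30) {
    m <- generate_dataset(sim_params(structures = league_structures("DE"),
                                     null = TRUE, seed = 2028 + r))$baseline
    ci <- baseline_share_ci(m, "points", replicates = 1000,
                            seed = 500 + r)
    covered <- covered + (ci$lower <= 0.5 && 0.5 <= ci$upper)
  }
  # Binomial(30, 0.95): P(covered < 24) is below 1e-4
  expect_gte(covered, 24L)
})
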