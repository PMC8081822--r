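#' Configure the Monte Carlo null
#'
#' Bundles every knob of the subsampling null into one object. The full
#' design repeats the subsample draw 1,000,000 times; smaller values are
#' appropriate for exploration and simulation studies.
#'
#' @param n_draws number of Monte Carlo subsamples per cell (default 1e6).
#' @param seed root seed. Each (scope, category) cell derives its own
#'   independent stream from it, so results do not depend on the order in
#'   which cells are computed. `NULL` draws a random root.
#' @param scheme sampling scheme for the *overall* scope.
#'   `"overall_stratified"` (default) draws each league's closed-door count
#'   from that league's baseline and unions the draws, preserving the
#'   observed league mix; `"overall_pooled"` draws the total closed-door
#'   count from the pooled baseline; `"per_league"` skips the overall scope
#'   entirely.
#' @param tie_rule how subsample shares exactly equal to the observed value
#'   are counted for referee categories: `"inclusive_both"` (default;
#'   ties are extreme on both sides, conservative) or `"paper_asymmetric"`
#'   (offense inclusive, referee strict). Offense categories are always
#'   inclusive. Ties are common because shares are ratios of small-integer
#'   sums.
#' @param alpha one-sided significance level (default 0.05).
#' @param zero_denominator_share neutral share substituted when a subsample
#'   has a zero denominator (possible for red cards); default 0.5, i.e.
#'   "no advantage". Substitutions are counted and reported.
#' @param add_one if `TRUE`, report the add-one permutation estimate
#'   `(b + 1) / (m + 1)` instead of the plain `b / m`. Off by default so
#'   reported p-values are plain extreme-draw fractions.
#' @return an object of class `hfa_null_spec`.
#' @export
null_spec <- function(n_draws = 1e6, seed = NULL,
                      scheme = c("overall_stratified", "overall_pooled",
                                 "per_league"),
                      tie_rule = c("inclusive_both", "paper_asymmetric"),
                      alpha = 0.05, zero_denominator_share = 0.5,
                      add_one = FALSE) {
  scheme <- match.arg(scheme)
  tie_rule <- match.arg(tie_rule)
  n_draws <- as.double(n_draws)
  if (!is.finite(n_draws) || n_draws < 1)
    stop("n_draws must be >= 1", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  if (!(zero_denominator_share >= 0 && zero_denominator_share <= 1))
    stop("zero_denominator_share must lie in [0, 1]", call. = FALSE)
  structure(
    list(n_draws = n_draws, seed = seed, scheme = scheme,
         tie_rule = tie_rule, alpha = alpha,
         zero_denominator_share = zero_denominator_share,
         add_one = add_one),
    class = "hfa_null_spec"
  )
}

#' @export
print.hfa_null_spec <- function(x, ...) {
  cat(sprintf(
    "<hfa_null_spec> draws: %s, scheme: %s, tie rule: %s, alpha: %g, seed: %s\n",
    format(x$n_draws, big.mark = ","), x$scheme, x$tie_rule, x$alpha,
    if (is.null(x$seed)) "random" else x$seed))
  invisible(x)
}

#' Draw a uniform without-replacement subsample of matches
#'
#' Uses the current RNG stream; call `set.seed()` first for repeatability.
#'
#' @param matches match tibble.
#' @param n subsample size, at most `nrow(matches)`.
#' @return `n` distinct rows of `matches`.
#' @export
draw_subsample <- function(matches, n) {
  nb <- nrow(matches)
  if (n > nb)
    stop(sprintf("cannot draw %d matches from a baseline of %d", n, nb),
         call. = FALSE)
  if (n == 0L) return(matches[integer(), ])
  matches[sample.int(nb, n), ]
}

#' Count null draws at least as extreme as the observed share
#'
#' Offense categories look for a home disadvantage, so a draw is extreme
#' when its share is less than or equal to the observed value. Referee
#' categories look for sanctions shifting onto the home side, so a draw is
#' extreme when its share is greater than or equal to (tie rule
#' `"inclusive_both"`) or strictly greater than (`"paper_asymmetric"`) the
#' observed value.
#'
#' Equal rational shares compare equal exactly in floating point (IEEE
#' division is correctly rounded), so no tie tolerance is needed.
#'
#' @param samples numeric vector of null shares.
#' @param observed observed share (must be defined).
#' @param category category name (fixes the tail direction).
#' @param tie_rule `"inclusive_both"` or `"paper_asymmetric"`.
#' @return integer count of extreme draws.
#' @export
tail_count <- function(samples, observed, category,
                       tie_rule = c("inclusive_both", "paper_asymmetric")) {
  tie_rule <- match.arg(tie_rule)
  if (is.na(observed))
    stop("observed share must be defined", call. = FALSE)
  if (category_direction(category) == "offense") {
    sum(samples <= observed)
  } else if (tie_rule == "inclusive_both") {
    sum(samples >= observed)
  } else {
    sum(samples > observed)
  }
}

# Null subsample shares for one cell. Returns list(shares, n_zero_den).
# For the stratified overall scope, draws are per-league and the share is
# the ratio of the unioned sums, matching the aggregate-share definition.
null_shares <- function(baseline, category, n, spec,
                        strata = NULL) {
  m <- as.integer(spec$n_draws)
  if (is.null(strata)) {
    v <- share_vectors(baseline, category)
    sums <- mc_subsample_sums(v$home, v$total, as.integer(n), m)
    num <- sums$num
    den <- sums$den
  } else {
    num <- numeric(m)
    den <- numeric(m)
    for (s in strata) {
      v <- share_vectors(s$matches, category)
      sums <- mc_subsample_sums(v$home, v$total, as.integer(s$n), m)
      num <- num + sums$num
      den <- den + sums$den
    }
  }
  zero <- den <= 0
  shares <- ifelse(zero, spec$zero_denominator_share, num / den)
  list(shares = shares, n_zero_den = sum(zero))
}

observed_share_value <- function(matches, category, spec) {
  sh <- home_share(matches, category)
  if (!sh$defined) {
    message(sprintf(
      "observed %s share undefined (zero denominator); using neutral share %g",
      category, spec$zero_denominator_share))
    return(spec$zero_denominator_share)
  }
  sh$value
}

#' Empirical tail p-value for one category and scope
#'
#' Computes the observed closed-door share for the scope, draws
#' `spec$n_draws` baseline subsamples of the closed-door sample size, and
#' counts draws at least as extreme in the hypothesized direction. The
#' reported `p_hat` is the plain extreme-draw fraction, with Monte Carlo
#' standard error `sqrt(p(1-p)/m)`.
#'
#' @param dataset an `hfa_dataset`.
#' @param category category name.
#' @param scope a league code or `"overall"`.
#' @param spec an [null_spec()] configuration.
#' @return one-row tibble (a test result): `scope`, `category`,
#'   `direction`, `n_test`, `observed_share`, `n_draws`, `extreme_count`,
#'   `p_hat`, `mc_se`, `n_zero_denominator`, `significant`.
#' @export
empirical_p <- function(dataset, category, scope = "overall",
                        spec = null_spec()) {
  stopifnot(inherits(dataset, "hfa_dataset"))
  category <- match.arg(category, category_names())
  leagues <- sort(unique(c(dataset$baseline$league,
                           dataset$closed_doors$league)))
  if (scope == "overall") {
    closed <- dataset$closed_doors
  } else {
    closed <- dataset$closed_doors[dataset$closed_doors$league == scope, ]
  }
  if (nrow(closed) == 0L)
    stop(sprintf("no closed-door matches for scope '%s'", scope),
         call. = FALSE)
  n_test <- nrow(closed)
  observed <- observed_share_value(closed, category, spec)

  cell_seed <- if (is.null(spec$seed)) NULL else {
    derive_seed(spec$seed, scope_key(scope),
                match(category, category_names()))
  }
  draws <- with_seed(cell_seed, {
    if (scope != "overall") {
      base <- dataset$baseline[dataset$baseline$league == scope, ]
      if (nrow(base) < n_test)
        stop(sprintf("baseline for scope '%s' smaller than test set", scope),
             call. = FALSE)
      null_shares(base, category, n_test, spec)
    } else if (spec$scheme == "overall_pooled") {
      if (nrow(dataset$baseline) < n_test)
        stop("pooled baseline smaller than test set", call. = FALSE)
      null_shares(dataset$baseline, category, n_test, spec)
    } else {
      strata <- lapply(leagues, function(lg) {
        nl <- sum(closed$league == lg)
        bl <- dataset$baseline[dataset$baseline$league == lg, ]
        if (nrow(bl) < nl)
          stop(sprintf("baseline for league '%s' smaller than its closed-door count", lg),
               call. = FALSE)
        list(matches = bl, n = nl)
      })
      strata <- Filter(function(s) s$n > 0, strata)
      null_shares(NULL, category, n_test, spec, strata = strata)
    }
  })
  m <- as.integer(spec$n_draws)
  k <- tail_count(draws$shares, observed, category, spec$tie_rule)
  p_hat <- if (spec$add_one) (k + 1) / (m + 1) else k / m
  tibble(
    scope = scope,
    category = category,
    direction = category_direction(category),
    n_test = n_test,
    observed_share = observed,
    n_draws = m,
    extreme_count = as.integer(k),
    p_hat = p_hat,
    mc_se = sqrt(p_hat * (1 - p_hat) / m),
    n_zero_denominator = draws$n_zero_den,
    significant = p_hat < spec$alpha
  )
}

#' Exact tail probability by full subset enumeration
#'
#' Brute-force oracle for the Monte Carlo engine: enumerates every
#' unordered size-`n` subset of the baseline, computes its share, and
#' applies the same tail direction, tie rule, and zero-denominator policy
#' as [empirical_p()]. Intended for small instances; refuses when
#' `choose(N, n)` exceeds `cap`.
#'
#' @param baseline match tibble.
#' @param n subsample size (>= 1).
#' @param observed observed share to test against.
#' @param category category name.
#' @param tie_rule tie rule, as in [null_spec()].
#' @param zero_denominator_share neutral share for zero-denominator subsets.
#' @param cap enumeration cap on `choose(N, n)` (default 5e6).
#' @return the exact tail probability (a proportion).
#' @export
#' @examples
#' base <- toy_matches(6)
#' exact_p(base, 2, observed = 0.4, category = "points")
exact_p <- function(baseline, n, observed, category,
                    tie_rule = c("inclusive_both", "paper_asymmetric"),
                    zero_denominator_share = 0.5, cap = 5e6) {
  tie_rule <- match.arg(tie_rule)
  category <- match.arg(category, category_names())
  nb <- nrow(baseline)
  stopifnot(n >= 1, n <= nb)
  ncomb <- choose(nb, n)
  if (ncomb > cap) {
    stop(sprintf(
      "choose(%d, %d) = %g exceeds the enumeration cap of %g subsets",
      nb, n, ncomb, cap), call. = FALSE)
  }
  v <- share_vectors(baseline, category)
  idx <- combn(nb, n)
  num <- colSums(matrix(v$home[idx], nrow = n))
  den <- colSums(matrix(v$total[idx], nrow = n))
  shares <- ifelse(den <= 0, zero_denominator_share, num / den)
  tail_count(shares, observed, category, tie_rule) / ncomb
}

#' Percentile-bootstrap confidence interval for a baseline share
#'
#' Resamples whole matches with replacement, recomputes the aggregate
#' share on each resample, and reports percentile bounds.
#'
#' @param matches non-empty match tibble.
#' @param category category name.
#' @param replicates bootstrap replicates (default 10,000).
#' @param seed optional seed for the resampling stream.
#' @param conf confidence level (default 0.95).
#' @return an object of class `hfa_share_ci` with fields `share`, `lower`,
#'   `upper`, `method`, `replicates`, `conf`, `category`.
#' @export
baseline_share_ci <- function(matches, category, replicates = 10000,
                              seed = NULL, conf = 0.95) {
  category <- match.arg(category, category_names())
  sh <- home_share(matches, category)
  v <- share_vectors(matches, category)
  sums <- with_seed(seed,
                    boot_resample_sums(v$home, v$total,
                                       as.integer(replicates)))
  shares <- ifelse(sums$den <= 0, 0.5, sums$num / sums$den)
  qs <- quantile(shares, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 names = FALSE)
  structure(
    list(share = sh$value, lower = qs[1], upper = qs[2],
         method = "percentile_bootstrap",
         replicates = as.integer(replicates), conf = conf,
         category = category),
    class = "hfa_share_ci"
  )
}

#' @export
print.hfa_share_ci <- function(x, ...) {
  cat(sprintf(
    "<hfa_share_ci> %s share %.4f, %d%% CI [%.4f, %.4f] (%s, %d replicates)\n",
    x$category, x$share, round(100 * x$conf), x$lower, x$upper,
    x$method, x$replicates))
  invisible(x)
}

#' Run the full analysis: every category over every scope
#'
#' Applies [empirical_p()] to all seven categories over the overall scope
#' and each league individually (35 cells with the default scheme; the
#' `"per_league"` scheme omits the overall scope). Each cell runs on its
#' own seed-derived stream, so the result table is invariant to the order
#' in which cells are computed.
#'
#' @param dataset an `hfa_dataset`.
#' @param spec an [null_spec()] configuration.
#' @return tibble of test results, one row per (scope, category).
#' @export
run_analysis <- function(dataset, spec = null_spec()) {
  stopifnot(inherits(dataset, "hfa_dataset"))
  leagues <- unique(dataset$closed_doors$league)
  canonical <- league_structures()$league
  leagues <- c(intersect(canonical, leagues), setdiff(leagues, canonical))
  scopes <- if (spec$scheme == "per_league") leagues else
    c("overall", leagues)
  rows <- list()
  for (sc in scopes) {
    for (cat in category_names()) {
      rows[[length(rows) + 1L]] <- empirical_p(dataset, cat, sc, spec)
    }
  }
  dplyr::bind_rows(rows)
}
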