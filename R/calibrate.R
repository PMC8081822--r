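#' Empirical p-values over replicated synthetic datasets
#'
#' Generates `replicates` independent datasets from `params` and runs
#' [empirical_p()] for each requested category on each, all on streams
#' derived from `spec$seed`. This is the workhorse behind both null
#' calibration and power probes.
#'
#' @param params an [sim_params()] object (its own `seed` is ignored; the
#'   replicate streams come from `spec$seed`).
#' @param scope scope passed to [empirical_p()].
#' @param spec an [null_spec()]; `n_draws` here is per cell per replicate.
#' @param replicates number of replicate datasets.
#' @param categories categories to test (default all seven).
#' @return numeric matrix `replicates x length(categories)` of `p_hat`
#'   values, with categories as column names.
#' @export
replicate_pvalues <- function(params, scope = "DE", spec = null_spec(),
                              replicates = 100,
                              categories = category_names()) {
  stopifnot(inherits(params, "hfa_sim_params"))
  root <- spec$seed %||% random_root_seed()
  out <- matrix(NA_real_, nrow = replicates, ncol = length(categories),
                dimnames = list(NULL, categories))
  for (r in seq_len(replicates)) {
    gen_params <- params
    gen_params$seed <- derive_seed(root, 101L, r)
    ds <- generate_dataset(gen_params)
    spec_r <- spec
    spec_r$seed <- derive_seed(root, 202L, r)
    for (j in seq_along(categories)) {
      out[r, j] <- empirical_p(ds, categories[j], scope, spec_r)$p_hat
    }
  }
  out
}

#' Type-I error calibration of the Monte Carlo test under the null
#'
#' Under a pure-null generator the closed-door block is an independent
#' draw from the same process as the baseline, so the test should reject
#' at close to its nominal level. This runs the test on `replicates`
#' regenerated null datasets and reports the per-category rejection rate
#' at `spec$alpha` together with the binomial 99% band around the nominal
#' level. Refuses non-null parameter sets, for which rejection rates
#' confound size with power.
#'
#' @inheritParams replicate_pvalues
#' @return an object of class `hfa_calibration`: a list with `table` (a
#'   tibble of per-category rejection rates and band bounds), `pvalues`
#'   (the replicate matrix), and the run settings.
#' @export
calibrate_null <- function(params, scope = "DE", spec = null_spec(),
                           replicates = 500,
                           categories = category_names()) {
  if (!is_null_params(params))
    stop("calibrate_null() requires pure-null simulation parameters ",
         "(see sim_params(null = TRUE))", call. = FALSE)
  pmat <- replicate_pvalues(params, scope, spec, replicates, categories)
  alpha <- spec$alpha
  half_band <- 2.576 * sqrt(alpha * (1 - alpha) / replicates)
  rates <- colMeans(pmat < alpha)
  tab <- tibble(
    category = categories,
    rejection_rate = as.numeric(rates),
    alpha = alpha,
    band_lower = max(0, alpha - half_band),
    band_upper = alpha + half_band,
    within_band = rates >= max(0, alpha - half_band) &
      rates <= alpha + half_band
  )
  structure(
    list(table = tab, pvalues = pmat, replicates = replicates,
         n_draws = spec$n_draws, scope = scope, alpha = alpha),
    class = "hfa_calibration"
  )
}

#' @export
print.hfa_calibration <- function(x, ...) {
  cat(sprintf(
    "<hfa_calibration> %d null replicates, scope %s, %s draws/cell, alpha %g\n",
    x$replicates, x$scope, format(x$n_draws, big.mark = ","), x$alpha))
  cat(sprintf("  99%% binomial band: [%.4f, %.4f]\n",
              x$table$band_lower[1], x$table$band_upper[1]))
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-10s rejection rate %.4f %s\n", x$table$category[i],
                x$table$rejection_rate[i],
                if (x$table$within_band[i]) "" else "(outside band)"))
  }
  invisible(x)
}
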