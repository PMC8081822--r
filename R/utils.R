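`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state (or removes `.Random.seed` if there was none). Used
#' throughout so that seeded operations never perturb the session RNG.
#'
#' @param seed integer seed, or `NULL` to run `code` on the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic integer stream-splitting: mixes a root seed with a sequence
# of small integer keys into a new seed < 2^31. A linear-congruential mix is
# enough here; statistical quality comes from R's generator, this only has
# to keep distinct (scope, category, replicate) cells on distinct streams.
derive_seed <- function(root, ...) {
  keys <- c(...)
  s <- as.double(root %% 2147483647)
  for (k in keys) {
    s <- (s * 69069 + as.double(k) * 30103 + 1) %% 2147483629
  }
  as.integer(s) + 1L
}

# Stable small-integer key for a scope label (league code or "overall").
scope_key <- function(scope) {
  v <- utf8ToInt(scope)
  sum(v * seq_along(v)) %% 100000L
}

random_root_seed <- function() sample.int(2147483646L, 1L)
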