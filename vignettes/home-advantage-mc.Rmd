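---
title: "Change or chance: a subsampling test for the closed-door home advantage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Change or chance: a subsampling test for the closed-door home advantage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Home teams in professional soccer reliably win more than half of the
points at stake. When matches were played behind closed doors at the end
of the 2019/2020 season, several leagues appeared to lose this advantage
— but each league contributed only 83–130 such matches. Over samples
that small, share statistics fluctuate substantially even when nothing
has changed. `hfamc` implements a resampling answer: treat the four
preceding full seasons as a reservoir of "normal" matches, repeatedly
draw random subsamples of exactly the closed-door sample size, and ask
what fraction of those subsamples is at least as unfavourable to the
home side as the closed-door matches actually were. That fraction is a
one-sided empirical p-value; if it is small, the closed-door pattern is
unlikely to be an artifact of sample size.

Because the subsamples are drawn from the same pool of real matches,
confounders that travel with matches — team strength imbalances, quality
of opposition, schedule effects — are represented in the null
distribution automatically. What the design cannot do is attribute a
detected change to any specific cause (absent crowds, altered routines,
rule changes such as five substitutions); it only rules out sampling
noise.

## Statistics and hypotheses

Seven per-match statistics are aggregated into home shares
$T_c(S) = \sum_S \mathrm{home}_c / \sum_S (\mathrm{home}_c + \mathrm{away}_c)$:

| category   | direction | extreme tail | per-match amounts |
|------------|-----------|--------------|-------------------|
| points     | offense   | lower        | 3/1/0 rule from the score |
| goals      | offense   | lower        | goals scored |
| shots      | offense   | lower        | shots taken |
| possession | offense   | lower        | printed possession percentages |
| fouls      | referee   | upper        | fouls awarded against each side |
| yellows    | referee   | upper        | yellow cards |
| reds       | referee   | upper        | red cards |

The directions encode three one-sided hypotheses fixed a priori: under a
loss of home advantage the offense shares *decline* (tail counts
subsample shares $\le$ the observed value) and the sanction shares
against the home side *rise* (tail counts shares $\ge$ observed). The
tests are deliberately one-sided and uncorrected for multiplicity,
mirroring the directional design; users who need family-wise control can
feed the 35-cell result table to `p.adjust()`.

**Aggregate versus per-match shares.** "The proportion of points won by
the home teams from the total points earned" is a ratio of aggregate
sums, and that is the definition used for every category. The
alternative — averaging per-match shares — coincides for possession
(each match sums to 100) but differs slightly for count categories in
draw-heavy sets. The aggregate reading matches the points wording and
keeps every category on the same footing, including matches where a
category's total is zero.

## The Monte Carlo null

`empirical_p()` draws `n_draws` subsamples of the closed-door size `n`
from the scope's baseline, uniformly **without replacement** (a new
subsample each draw; within a draw no match repeats), computes each
subsample's share, and counts the extreme ones. Key knobs in
`null_spec()`:

* `n_draws` — 1,000,000 in the full design; simulation studies in this
  package use 2,000–20,000 per cell, which changes only the Monte Carlo
  granularity of `p_hat`, never its center. The Monte Carlo standard
  error `sqrt(p(1-p)/M)` is reported alongside every p-value.
* `scheme` — the overall scope can be sampled `overall_stratified`
  (default: draw each league's closed-door count from that league's own
  baseline and union the draws) or `overall_pooled` (draw 416 from the
  pooled 5,784). Pooling reads most literally as "from all the matches",
  but it lets the league composition of each draw drift away from the
  observed 83/111/92/130 mix; stratification holds the mix fixed, which
  is why it is the default. Both are exposed because the choice is a
  genuine modelling fork; on synthetic data the two give very similar
  p-values.
* `tie_rule` — subsample shares are ratios of small-integer sums, so
  exact ties with the observed share carry real probability mass. The
  default `inclusive_both` counts ties as extreme in both directions
  (conservative); `paper_asymmetric` reproduces the literal asymmetric
  wording (inclusive for offense, strict for referee categories). The
  package compares shares with exact floating-point equality, which is
  safe here: IEEE division is correctly rounded, so equal rational
  shares always produce bit-identical doubles.
* `alpha` — 0.05, one-sided, per cell.
* `zero_denominator_share` — a subsample can contain no red card at all,
  leaving that share undefined. Such draws are mapped to the neutral
  value 0.5 ("no advantage"), a direction-symmetric default, and their
  count is logged in `n_zero_denominator`. The same policy applies to an
  undefined *observed* share.
* `add_one` — the plain estimator `b/M` is reported by default, matching
  the convention of quoting extreme-draw counts directly; the add-one
  permutation estimate `(b+1)/(M+1)` is available but off.

**Reproducibility.** A single root seed spawns an independent RNG stream
per (scope, category) cell via a deterministic integer mix, so the
result table is bit-identical whether cells are computed in order, in
parallel batches, or one at a time, and `run_analysis()` reruns are
`identical()`. Seeded operations restore the caller's RNG state.

## The exact oracle

`exact_p()` enumerates all `choose(N, n)` unordered subsamples (capped
at 5×10⁶) with the same tail, tie, and zero-denominator semantics, which
pins the Monte Carlo engine down on small instances: on a 12-match
baseline with n = 4 (495 subsets) the engine at 100,000 draws agrees
with enumeration within four Monte Carlo standard errors for every
category and both tie rules (`oracle_comparison()`, also exposed as the
`oracle` CLI subcommand). The canonical hand example: baseline scores
{3–0, 1–1, 0–3, 3–0} and a closed-door pair with points share 0.2 give
exact p = 1/6.

## Baseline confidence intervals

The construction behind interval estimates of the baseline shares is a
percentile bootstrap over matches: resample `|B|` matches with
replacement, recompute the aggregate share, take the 2.5th/97.5th
percentiles of 10,000 replicates. It is assumption-light and respects
the ratio structure of the statistic; the method and replicate count are
recorded in the returned object. The bootstrap treats matches as the
exchangeable unit, consistent with the subsampling null.

## The synthetic league

`sim_params()`/`generate_dataset()` produce datasets with the exact
study layout: per league, `matchdays × matches-per-matchday` matches per
season over four baseline seasons (Germany 34×9, the others 38×10 —
5,784 in total) plus a closed-door block of 83/111/92/130. The
generative model is the structure the analysis itself assumes —
independent matches, exchangeable within period:

* goals, shots, fouls, yellow cards: independent Poisson per side;
* red cards: Bernoulli per side per match;
* possession: home fraction from a Beta(α, β), away = 100 − home,
  printed to one decimal.

Default non-null rates (goals 1.5/1.2, shots 14/11, possession
Beta(20, 17), fouls 12/13, yellows 1.8/2.1, red probabilities 0.04/0.06)
are plausibility values for demonstration, chosen once to resemble
top-division magnitudes; they are *invented*, and every test that
asserts numbers uses the pure-null mode or degenerate settings. Null
mode (`null = TRUE`) sets each pair to its midpoint and a symmetric
possession Beta(18.5, 18.5), making home and away exchangeable, so every
category's expected share is exactly 0.5. The closed-door `effect` knobs
multiply the *home* parameter of one category in the closed-door block
only (the possession knob scales α), giving a clean way to inject a
directional change of known size.

What the generator does **not** emulate: team-strength heterogeneity and
schedule structure (team labels are permuted each matchday with faithful
match counts but no round-robin constraint), within-season form, score
dependence between the sides (no bivariate correlation), or
between-category dependence (shots and goals are drawn independently).
Passing tests therefore demonstrate the *inference machinery* —
uniformity of subsampling, tail accounting, calibration, power,
determinism — on data with the assumed exchangeability structure; they
do not validate the exchangeability of real seasons, where team quality
and fixture effects induce dependence that the subsampling design
absorbs only to the extent that matches remain exchangeable units.

## Calibration and power

With a pure-null generator the closed-door block is an independent draw
from the same process as the baseline, so p-values should be roughly
uniform and the rejection rate at α ≈ α. Exact uniformity is not
attainable for two structural reasons, both properties of the design
rather than defects of the implementation:

1. *Finite baseline.* The null distribution is built from one realized
   baseline of N matches, while the observed block is independent of it.
   The observed-minus-baseline-mean contrast has variance
   ∝ (1/n + 1/N), but subsample shares scatter around the baseline mean
   with variance ∝ (1/n − 1/N); for n = 83, N = 1224 the mismatch
   inflates the effective z by ≈ 7%, pushing the true one-sided
   rejection rate at 0.05 to ≈ 0.06. It vanishes as N grows and is the
   price of treating a finite baseline as the reference population.
2. *Discreteness.* Count-based shares have atoms; with inclusive tie
   handling the p-value is super-uniform at atom boundaries, nudging
   rates conservatively — most visibly for red cards, with roughly eight
   cards per 83-match block.

The calibration study (`calibrate_null()`, criterion-level run: 500
regenerated null datasets, Germany scope n = 83, 10,000 draws per cell)
checks that each category's rejection rate stays within ±0.025 of 0.05,
a band wide enough to absorb both structural effects plus binomial noise
at 500 replicates. The power probe scales the closed-door home goal rate
to 0.6× null: across 100 replicates at 2,000 draws per cell the median
points and goals p-values drop far below their null medians while the
referee categories, untouched by the goal knob, stay at the nominal
rate. Replicate counts and per-cell draw sizes for these studies (500 ×
10,000 for calibration; 100 × 2,000 for the power probe; 300 × 5,000 in
the acceptance script) were chosen to keep each study's binomial
uncertainty well inside the bands it asserts while completing in
minutes on a single core.

## Data handling choices

* Rows violating structural invariants (negative counts, possession
  pair off by more than 0.5 from 100, a team playing itself, a
  closed-door row outside the closed-door season) are **rejected with
  row-level diagnostics**, never imputed: how the original analysis
  handled incomplete rows is unknowable, and silent imputation would
  contaminate shares. The possession tolerance of 0.5 accommodates
  integer broadcast rounding.
* Closed-door-season matches played *with* spectators belong to neither
  period and are dropped with a logged count; relegation/playoff rounds
  are outside the league structures and simply never match the schema.
* Season labels are opaque strings; partition membership is all the
  analysis needs.

## Limitations

* The test is a significance statement about sampling variability, not
  an effect-size estimate; report the observed shares alongside p.
* One-sided, per-cell inference: 35 cells at α = 0.05 imply false
  positives under the global null (the calibration study quantifies
  exactly this).
* The subsampling null conditions on the realized baseline; with only
  four seasons per league the mild anticonservativity described above is
  inherent.
* Synthetic defaults are not fitted to any real league; conclusions
  about real data require real data through `read_matches()`.
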