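---
title: "Models and methods behind playtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind playtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`playtrace` analyses click-level telemetry from serious-game dietary
trials in children: it encodes raw game events into seven-state play
sequences, models pooled play as a first-order Markov chain, reduces each
child's play to six interpretable measures, and links those measures to
the trial's healthy-food-choice outcomes. This vignette records the models
and every substantive design decision: what is assumed, which defaults
were chosen and why, and what the validation machinery does and does not
demonstrate.

## 1. From telemetry to sequences

A telemetry record is one click or game event: child, session (day 1 or
2), level, date, a `HH-MM-SS-mmm` clock stamp, and a free-text status.
Seven status descriptions are recognised and mapped to the alphabet
`{S, 1, 2, 3, 4, 5, E}`; matching is exact after lower-casing and
whitespace squashing, and any other status is quarantined into a rejects
report rather than silently dropped — telemetry exports are messy and a
silent drop would bias sequence lengths. Timestamps are combined with the
date column so ordering survives midnight; sorting is stable, so records
with identical stamps keep file order (the log's order is treated as
authoritative for ties).

A *play* is a contiguous episode of one level by one child. Episodes are
split at level starts and level changes; an episode that does not open
with `S`, an `E` that is not its final event, or a level resumed after
being abandoned mid-episode are structural errors — they indicate a
corrupted or misordered log, not analysable play. A play cut off by the
end of a session keeps its partial sequence and is flagged `incomplete`
rather than discarded: incomplete plays still carry valid transitions and
excluding them would selectively remove long, late-session plays. Sequence
*length* counts all symbols including `S` and `E`; *transitions* count
adjacent pairs whose states differ, so a burst of repeated bad-food shots
(`333`) contributes length but no transitions. Pattern analysis keeps only
each child's chronologically first encounter of each level, across both
sessions: first encounters reflect how a child meets a mechanic, while
replays mix in practice effects.

## 2. The pooled Markov chain

Play at any level is modeled as a discrete, time-homogeneous, first-order
Markov chain over the seven states, estimated by pooling adjacent pairs
over all sequences and row-normalising. Three numerical conventions:

* `E` is absorbing with an all-zero outgoing row — a level end terminates
  the walk, and a self-loop at `E` would be a modelling artefact.
* Nothing re-enters `S`; its column is structurally zero.
* Rows never observed leaving are reported as *undefined* (all-zero,
  listed in `$undefined_rows`) rather than smoothed to uniform: the
  estimator reports raw maximum-likelihood proportions and refuses to
  invent mass.

First-order homogeneity is an acknowledged simplification: real play
drifts as children learn across levels. The chain is a descriptive pooling
device, and a single-level chain (for example level 1 only) is available
via the pipeline's `level_filter`.

## 3. The six gameplay measures

Per child, over first-encounter plays: `level_max` (highest level
reached), `avg_seqlen` (mean sequence length), `avg_transition` (mean
state-changing pairs), the shield-kill share, and `avg_gfact` /
`avg_bfact` (good/bad food facts read per level played). Conventions that
matter:

* **Shield share smoothing.** `(sum2 + α)/(sum2 + sum4 + 2α)` with
  α = 0.5 by default. Symmetric additive smoothing keeps the share a
  legal fraction strictly inside (0, 1) for children who never killed a
  robot one way; the half-count default is the Jeffreys-style choice, and
  a child with 0 shield kills against 165 shot kills scores 0.003 —
  on the scale real cohorts exhibit. α is configurable because other
  smoothing conventions are defensible.
* **Fact-read denominators** are levels *played*, not levels with any
  read: a child who reads nothing scores 0, not `NaN`, and reading
  intensity is per opportunity.
* **Fact reads are matched to retained plays**: reads on the post-level
  screen of a replayed level are excluded along with the replay.
* **Cohort summary** uses the sample (n−1) variance and
  CV = 100·sd/mean. Published cohort tables of these measures are
  internally consistent under the sample-variance convention and not
  under the population one, which fixes the choice.

## 4. Trial statistics

* **Mann-Whitney U** (min convention) with the exact permutation null
  when both arms are small (`min(n) ≤ 10`, total ≤ 25) and tie-free,
  otherwise the tie-corrected normal approximation with continuity
  correction. Identical multisets short-circuit to p = 1 with a
  degeneracy flag.
* **Cohen's d** uses the Bessel-corrected pooled SD. Equal means return
  d = 0 even with zero pooled SD; unequal means with zero pooled SD are
  an explicit infinite-effect error.
* **Power** is the noncentral-t power of the two-sample t-test,
  ncp = d·√(n_t·n_c/(n_t+n_c)), both tails counted. Sample size defaults
  to *one-sided* testing: a directional intervention hypothesis is the
  design-stage convention this arithmetic reproduces (d = 0.5, α = .05,
  power .80 gives a total of 102). The flag is exposed because the
  two-sided analogue (128) is equally standard.
* **Cohen's κ** from the usual marginal-product chance agreement; two
  constant, identical raters are κ = 1 with a degeneracy flag rather than
  0/0.
* **Kendall τ-b** (tie-adjusted) with the exact small-sample null when
  tie-free; zero-variance margins are an error, not τ = 0.
* **Distribution choice** compares maximum-likelihood AICs of a normal
  (k = 2, ML variance) and Poisson (k = 1) fit to the marginal outcome.
* **Stepwise selection** is `step()`-style bidirectional AIC descent from
  the full model; ties keep the current (smaller) model; exactly
  collinear candidates are dropped with a warning before selection; a
  baseline-preference adjustment term can be forced in and is never
  subject to selection.
* **Robust errors**: HC1 for linear models, the classical HC0 sandwich
  for Poisson. Published analyses of this design say only "robust SE";
  both flavours are configurable and recorded in the fit object, and
  these defaults are the most common pairing in applied work.

The outcome side analyses the choice count pooled over both days (0–4),
on treatment children with complete outcomes; children missing either
day's outcome are excluded from comparisons and regressions but never
from telemetry analyses. Site exclusions are deliberately asymmetric in
the pipeline: play-pattern analyses use every site with telemetry, while
outcome analyses honour `exclude_schools` — the situation where one
site's behavioural outcomes are unusable but its telemetry is fine.

## 5. The synthetic-cohort generator

Raw telemetry from such trials is essentially never deposited, so the
package ships a generator whose defaults emulate the published study
conditions, and validation rests on parameter recovery. Defaults, and
where each comes from:

* `n_children = 104`, 1:1 allocation, three schools (0.35/0.35/0.30) —
  the trial's design.
* `base_matrix`: anchored to the three published interior transition
  probabilities (P(1→2) = .08, P(3→3) = .67, P(3→4) = .19). The
  remaining mass was set, once, so that the homogeneous chain's expected
  sequence length (≈65) and expected transitions per sequence (≈22.5)
  match the published cohort means; self-loops on the action states do
  most of that work. The matrix is illustrative, not a reconstruction.
* `levels played = 1 + NegBin(mu = 14, size = 25)`, capped at 80: mean 15
  with variance ≈22, matching the published mean and spread of levels
  played; pure Poisson is available via `levels_dispersion = Inf`.
* `dirichlet_kappa = 60`: each child's rows are
  Dirichlet(κ·base row), so κ→∞ recovers the base chain. κ = 60
  reproduces the published between-child CV of mean sequence length
  (≈45–60%).
* `shield_sdlog = 1.2`: strategy was the most variable published measure
  (CV ≈ 130%, range 0.003–0.98), far beyond what symmetric Dirichlet
  noise produces. Each child's base-row mass into the shield-kill state
  is therefore scaled by a unit-mean log-normal factor (rows
  renormalised, absorbing mass preserved), giving children who nearly
  never and nearly always kill by shield while leaving the pooled chain
  near its anchors.
* `fact_rate_good = 0.43`, `fact_rate_bad = 0.12`, `fact_shape = 1.2`:
  cohort-mean reads per level equal the published means; the gamma shape
  reproduces the published variances (≈0.18 and ≈0.02) of the per-child
  rates almost exactly. Heterogeneous reading propensity is also what
  makes fact-reading a usable regressor.
* **Outcome model**: per-day healthy choices are Binomial(2, p) with
  logit p = β₀ + β_g·AvgGFact + β_b·AvgBFact + β_base·GoodBase for
  treatment children and β₀ᶜ + β_base·GoodBase for controls. A
  binomial-logit respects the hard 0–2 daily range; near p = ½ its
  coefficients are numerically comparable to linear coefficients on the
  0–4 pooled count, so the defaults β_g = 1.1, β_b = −9.5,
  β_base = 0.9 carry the signs and rough magnitudes of the published
  regressions, and β₀ = 0.95 / β₀ᶜ = −0.97 reproduce arm means of about
  2.5 and 1.3. A separate control intercept is required because the
  game's main effect cannot be expressed through fact-reading terms the
  control arm does not have.
* `p_goodbase = 0.4` (plausible prevalence of a healthy favourite food
  at baseline), `p_missing = 0.05` (one missing outcome day per ~20
  children), identification outcomes Binomial(4, ·) per day with a small
  treatment shift — all chosen once as realistic, none anchored to a
  published number.

Reproducibility is per-child: child *i*'s draws derive from
`(seed, i)` alone, so enlarging a cohort never rewrites existing
children.

**What the generator does not emulate**: learning within and across
levels (the chain is homogeneous), session-level effects, within-child
correlation between play style and fact reading, school-level clustering,
and any demographic structure in outcomes. Passing recovery tests
therefore demonstrates that the *pipeline* is correct and well-calibrated
under the stated model — not that the model captures every feature of
real cohorts.

## 6. Validation and problem sizes

`recover_parameters()` rebuilds sequences from raw synthetic events,
recomputes measures, and refits the outcome model *on the generating
(binomial-logit) scale* with sandwich errors, comparing estimates to the
generating coefficients; the trial-style normal and Poisson fits are
attached for inspection but are not the recovery target, since their
estimands differ from the logit-scale truth by construction. The test
suite and acceptance script exercise, at sizes chosen to keep a full run
in minutes on one CPU:

* chain recovery from 2,000 simulated sequences (max cell error well
  under 0.02; a homogeneous κ = 10⁶ cohort reproduces the base matrix
  to the same tolerance);
* coefficient recovery within 3 robust SEs on a 1,000-child cohort;
* 95% robust-CI coverage of null effects over 200 cohorts of 80
  children with shortened play (coverage lands near 92–95%: the HC0
  sandwich is known to undercover slightly at small n — a deliberate
  trade-off for misspecification robustness, and the reason the
  acceptance band is 90–99%);
* exact Mann-Whitney p-values against full permutation enumeration, and
  Kendall τ-b against O(n²) pair counting with ties;
* the sign and significance of the simulated bad-fact association on
  300–500-child cohorts.

## 7. Known limitations

Beyond the generator's scope notes above: the regression layer fits 3–4
terms on trial-scale samples (n ≈ 25 treatment children in the
motivating design), where robust SEs are noisy and stepwise selection is
unstable — the package exposes both, but small-cohort results should be
read as exploratory, as in the trials that motivate the design. The
Markov layer is first-order and pooled; it will average over genuinely
heterogeneous strategies, which is exactly why the per-child measures,
not the chain, feed the outcome models.
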