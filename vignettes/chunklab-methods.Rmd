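---
title: "Detecting and analysing motor chunks in action streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing motor chunks in action streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunklab)
```

## The problem

Theories of skilled motor performance hold that practice welds commonly
co-occurring actions into *chunks*: automatized sequences that are planned
once and executed rapidly, with a characteristically slow first action and
fast subsequent actions. `chunklab` operationalises this idea for
timestamped categorical action logs — the kind of telemetry a real-time
strategy game engine records — and provides the full analysis chain:

1. **ingest** — read and validate canonical action-log CSVs, aggregate raw
   screen positions into `ScreenShift` actions, compute per-action latencies;
2. **detect** — find action n-grams (lengths 2–4) that occur more often than
   the base rates of their component actions predict;
3. **savings** — measure the time a chunked action saves relative to
   same-type non-chunked actions;
4. **diversity** — measure how far a player's sequencing departs from a
   random shuffle of their own actions;
5. **stats** — the skill-level inferential layer (additive two-way ANOVA
   with partial $\eta^2$, t-tests, correlation, family-wise corrected
   planned comparisons);
6. **simulate** — a generative simulator with planted chunks and ground
   truth, used to validate each of the stages above by parameter recovery.

## The chunk detector

Each action belongs to one of seven types (see `action_types()`). For a
game of $a$ actions, the marginal proportion of type $i$ is
$p_i = n_i / a$, computed on the full stream. The null model is a player
who picks a type at random $a$ times from these marginals.

The detection procedure, run independently for n-gram lengths 2, 3 and 4:

1. Partition the stream into non-overlapping tiles of length $n$
   (`tile_ngrams()`); a remainder shorter than $n$ is discarded.
2. Drop every tile containing an immediately adjacent repeat of
   RightClick, Train or HotkeySelect (`filter_repeat_tiles()`). These
   actions occur in long uninterrupted strings that are artifactual
   (held-down keys) or carry abnormally low latencies.
3. Split the retained tiles uniformly at random into training and test
   halves (`split_train_test()`; odd counts put the extra tile in
   training).
4. For every distinct n-gram in the training set, compute the upper-tail
   binomial p-value $P(X \ge K)$ with $X \sim \mathrm{Bin}(n_{\text{train}},
   p_{i}p_{j}\cdots)$, and nominate the five with the smallest p-values
   (`nominate_candidates()`). Because these were chosen by optimisation,
   their training p-values are optimistic and are discarded from
   inference.
5. Recount each candidate on the held-out test tiles and recompute the
   p-value with $n_{\text{test}}$ trials (`confirm_chunks()`). A test
   p-value strictly below $\alpha = 0.05$ confirms a chunk.
6. Finally, mark every sliding occurrence of every confirmed chunk in the
   full stream (`mark_chunked_actions()`). A marked action whose
   predecessor is unmarked (or that begins the game) is a *first action*;
   an uninterrupted run of chunked actions has exactly one, so nested or
   back-to-back chunks behave as one larger planned unit.

Two deliberate asymmetries deserve emphasis. Counting for the binomial
test uses *non-overlapping tiles*, because the binomial model needs
(approximately) independent trials; marking uses *sliding occurrences*,
because once a chunk is confirmed every realisation of it in the stream is
of interest. And candidates can only be n-grams actually observed in the
training half: an unseen n-gram is never nominated.

### Error control

With five candidates per length and a strict per-test $\alpha = 0.05$ on
held-out data, a game yields at most 15 chunks. The binomial null is an
approximation — tile counts in a finite stream are weakly dependent and the
marginals are estimated from the same game — so the per-candidate false
confirmation rate is checked empirically: on 1,000 simulated pure-noise
games of 2,000 actions the acceptance suite requires the rate to stay at or
below 0.05 (within three Monte-Carlo standard errors); in practice it sits
around 0.03–0.04, i.e. slightly conservative, because nominated candidates
have already absorbed the most extreme training-half noise.

## Time savings

For one annotated game, the baseline for each type is the mean latency of
its *non-chunked* actions with defined latency (`type_baselines()`);
baselines are per game, never pooled, and the game's first action (latency
undefined) never enters. A chunked action's saving is
`baseline(type) − latency`, positive when the chunked action was faster.
Game-level savings (`game_savings()`) are reported in seconds and split
exactly into the first-action and inter-action (subsequent within-chunk)
components. Chunked actions of a type with no non-chunked representative
have no defensible baseline; they are excluded rather than given a pooled
baseline (avoiding cross-type contamination) and their count is reported.

Where the classic timing comparison is wanted
(`first_vs_inter_summary()`), "inter-action latency" means the non-first
chunked actions. An alternative reading — all non-chunked actions — exists,
but the within-chunk reading is the one that isolates the chunk-internal
timing signature, and the non-chunked side is already represented by the
baselines.

`redundant_rightclick_latency()` is a detector-free probe: maximal runs of
two or more right-clicks flanked by screen shifts (a stream boundary counts
as a flank) are nearly always redundant commands, so their within-run
latencies track raw motor speed. The run's first click is excluded — its
latency reflects the preceding shift, not the repetition.

## Sequence diversity

Comparing raw unique-sequence counts across players confounds diversity
with speed (faster players emit more actions), so diversity is computed on
a fixed window: the 200 actions immediately before and the 200 immediately
at-or-after the ten-minute mark (600,000 ms; `sample_window()`). Games
unable to fill both halves are excluded and counted.

The statistic $G$ is the number of distinct sliding subsequences of
lengths 2, 3 and 4 in the 400-action sample, summed
(`unique_sequence_count()`). Its permutation baseline $\overline{S}$ is the
mean of the same statistic over 100 uniform permutations of the sample
(`permutation_baseline()`), and

$$\text{randomness} = G - \overline{S}.$$

A formal permutation percentile is useless here — real behaviour is so
structured that $G$ falls far below every permuted $S$ — so the difference
itself is the measure: near zero for random-like sequencing, strongly
negative for repetitive behaviour. Three interpretation choices are built
in and flagged:

* **Sliding windows**, not tiles, for uniqueness counting: "unique
  sequences in a sample" naturally means all subsequences, and a tiled
  count would depend on phase.
* Windows straddling the before/after join are counted; the sample is
  treated as one 400-action sequence.
* $G$ is computed on the sample (not the whole game) so that it is
  directly comparable to $\overline{S}$, which necessarily lives on the
  sample; `unique_sequence_count()` accepts any sequence if a whole-game
  variant is wanted.

## Inferential layer

Skill-level analyses model per-game summaries (`build_game_summaries()`)
with an additive two-way ANOVA, League (8 levels) plus a categorical
nuisance factor such as player species (`anova_additive()`). Cohorts are
observational and unbalanced, so the default tests are marginal
(Type-II-style): each factor adjusted for the other, which is well defined
in an additive model; a sequential option exists because ANOVA software
defaults differ. Effect sizes are partial
$\eta^2 = SS_\text{effect}/(SS_\text{effect}+SS_\text{residual})$.
Factors with a single observed level are dropped (with a message), so the
model degrades to the classical one-way ANOVA — an identity the acceptance
suite checks against the closed-form F to $10^{-9}$.

Pairwise skill-level contrasts (`planned_comparisons()`) use pooled-variance
two-sample t-tests with Holm adjustment by default (Bonferroni etc. via
`method`; Welch via `var_equal = FALSE`). Degenerate zero-variance inputs
to any test return a flagged `degenerate` row rather than infinities.

## The simulator

`simulate_game()` implements the generative story the detector assumes:
a player draws, per emission, a repertoire chunk (with probability equal to
its usage rate), an artifactual repeat burst (probability
`repeat_run_rate`), or a single action from their marginals. Emissions
never interleave. Latencies are `base × multiplier × noise` with lognormal
noise of mean one, so every mean is interpretable on the base scale.

Key defaults, chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| base latency | 1019 ms (league 1) → 234 ms (league 8), geometric interpolation | skill-graded median per-action latency |
| `first_action_multiplier` | 1.28 | slow chunk-initial planning cost |
| `within_chunk_multiplier` | 0.78 | fast within-chunk execution |
| `latency_sigma` | 0.5 | lognormal noise scale (right-skewed, positive) |
| repertoire rates | 0.04/0.03/0.02/0.01 (lengths 2,2,3,4) | ≈ 20–28 % of actions chunked |
| `repeat_run_rate`, mean length | 0.05, 4 (geometric) | RightClick/Train/Hotkey bursts |
| species | 6 levels, ±6 % latency effect | nuisance factor |

With 1.28/0.78 the net expected saving per bigram emission is
$\text{base}\times(0.22 - 0.28) \approx -0.06\,\text{base}$ — small
relative to play time, emulating a regime where first-action costs nearly
cancel within-chunk gains. `expected_game_savings()` gives the exact
analytic expectation of the savings estimator for a simulated game, which
is what the recovery tests compare against. In those experiments
`repeat_run_rate` is set to 0: repeat bursts are non-chunked but
artificially fast, so they would shift same-type baselines and the
expectation would no longer be closed-form.

What the simulator does **not** emulate: game state and strategy, opponent
interaction, non-stationarity within a game (fatigue, early-game build
orders), latency autocorrelation beyond the chunk structure, and chunk
repertoires that drift over time. Passing recovery tests therefore show
that the estimators are correct *under the stated generative model*, not
that real replay data satisfies that model.

## Numerical and degenerate-input choices

* Binomial tails come from `stats::pbinom(K - 1, n, p, lower.tail = FALSE)`
  and are cross-checked against an independent direct-summation oracle to
  $10^{-10}$ for $n \le 500$.
* Nomination ties (equal p-values) break by higher count, then
  lexicographic n-gram order — detection is fully deterministic given the
  split seed.
* Equal timestamps keep input order; on a key-action/screen-shift tie the
  key action goes first. A game's first action has latency `NA`, never 0.
* Latencies are rounded to integer milliseconds (floor 1 ms) in the
  simulator, matching the canonical format.
* I-DT fixation aggregation uses required positive thresholds with
  placeholder defaults (2.0 map units, 250 ms) that are *uncalibrated*:
  no aggregation parameters are established for this instrument class, so
  any serious use must set them.
* Randomness of the split and of permutations is always seeded; multi-game
  drivers derive per-game seeds from a master seed and the game's position,
  so cohort results are reproducible and games independent.
* Games with fewer than 4 retained tiles at some length skip that length
  with a recorded reason; fewer than 2 tiles cannot be split at all.

## Problem sizes used by the validation suite

The test and acceptance suites run entirely on simulated data at sizes
chosen to give stable Monte-Carlo estimates on a single CPU: 1,000
pure-noise games of 2,000 actions for the type-I check; 200 simulations of
1,000-action streams with a bigram planted at 30 % tile occupancy for
recovery; 50 games of ~400 s for savings recovery; 20 samples per point of
a 5-level chunk-usage sweep (100 permutations each) for diversity
monotonicity. Tolerances follow the statistic: exact identities at machine
precision, oracle agreements at $10^{-10}$–$10^{-9}$, Monte-Carlo
quantities at three standard errors.

## Known limitations

* The binomial null treats tiles as independent and the marginals as
  known; both are approximations whose practical effect (mild conservatism)
  is quantified only under the simulator's model.
* Chunks longer than four actions are not detected directly; they are
  handled only through the first-action logic on contiguous chunked runs.
* The repeat-drop rule removes *tiles*, not actions: repeated-type actions
  still count toward marginals and can appear inside marked occurrences.
* Diversity requires games long enough to supply 400 actions around the
  mark; short games are excluded, which can correlate with skill.
* `read_game_summaries()` lets the inferential layer run on externally
  produced per-game tables, but column semantics must be mapped by the
  caller; no schema inference is attempted.
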