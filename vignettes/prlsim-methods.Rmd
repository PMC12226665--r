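---
title: "Simulating feedback sensitivity and its sedation confound in the rodent PRL task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating feedback sensitivity and its sedation confound in the rodent PRL task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlsim)
```

## The task model

`prlsim` implements the standard rodent probabilistic reversal learning (PRL)
protocol as a deterministic-contract state machine. A session
(`prl_config()`) consists of 200 trials of at most 22 s each (2 s lever
extension delay, 10 s response window, 5 s outcome period, 5 s inter-trial
interval). The two levers have no fixed identity at session start: the lever
the animal presses first becomes the *correct* lever. A press on the correct
lever is rewarded with probability 0.8, on the incorrect lever with
probability 0.2, so a non-reward on the correct lever is *misleading negative
feedback* (NF) and a non-reward on the incorrect lever is *actual NF*. After
8 consecutive presses on the correct lever — counted regardless of reward
outcome — the contingencies reverse. Failure to press within the response
window is an omission.

Decisions the protocol leaves open, resolved here once and used everywhere:

* **Omissions and the reversal counter.** An omission is not a press, so it
  neither increments nor resets the consecutive-correct counter. Resetting on
  omission would make a heavily omitting animal reversal-free for a trivial
  bookkeeping reason rather than a behavioral one.
* **When a reversal takes effect.** At the start of the trial after the
  criterion press; a within-trial swap is ill-defined.
* **Endogenous assignment timing.** The first-press rule applies whenever the
  first press occurs, even after a long run of opening omissions, and is not
  re-applied after reversals (levers simply swap).
* **Latency.** Measured from lever extension to press. Simulated agents draw
  latency from a log-normal distribution (median `latency_location`, log-sd
  `latency_scale`); draws beyond the response window are recorded as
  omissions, which couples slowness to omission counts the way a response
  deadline does in the apparatus.
* **Randomness.** One RNG per session, split into streams drawn up front —
  reward draws first, then agent draws — so agent stochasticity never
  perturbs the contingency stream. Identical (config, agent, seed) gives
  byte-identical logs.

## The agent family

The generative policy (`wsls_agent()`) is probabilistic win-stay/lose-shift
(WSLS) with a drowsiness gate. WSLS was chosen over a delta-rule (Q-learning)
agent because its parameters map one-to-one onto the task's readouts — stay
probability after a win, shift probability after a loss — which keeps every
analytic limit checkable by hand (a Q-learning agent can be added without
touching the scoring or statistics layers, and is deliberately not part of
the validated surface).

Per trial the agent is either *drowsy* or *awake*. Drowsy trials produce an
omission or a perseverative press on the previously pressed lever,
irrespective of feedback; awake trials apply the WSLS rule to the most recent
press. `p_omit` and `p_persev` are the marginal rates of the two drowsy acts
(sequential gates, omission first). The gate follows a two-state Markov chain
(`drowsy_persistence`), so drowsiness arrives in multi-trial bouts; with
persistence 0 the gate is independent across trials. Bout structure matters:
an animal that camps on one lever through a drowsy bout sails through the
reversal criterion while on the rich lever, then keeps pressing the now-poor
lever until the bout ends — which is what depresses completed reversals and
both lose-shift ratios. Independent per-trial perseveration cannot reproduce
the reversal deficit: short perseverative runs actually *help* reach the
criterion and the animal escapes the poor lever within a few trials.

Perseveration is modeled as repeat-previous-side — pre-empting feedback —
rather than as a reduction of loss sensitivity. The distinction is the whole
point of the drowsiness confound: the policy's feedback parameters
(`p_stay_after_win`, `p_shift_after_loss`) stay untouched while the scored
lose-shift ratios fall.

## Scoring

`classify_feedback()` emits one event per press, classed `true-PF`,
`misleading-PF`, `misleading-NF` or `actual-NF` by lever role and outcome.
Stay/shift is scored against the next press. Two censoring rules are
provided:

* `strict` (default): an event whose immediately following trial is an
  omission is excluded from numerator and denominator, as is the last press
  of a session. This follows the convention that the win-stay ratio is
  computed only over presses actually followed by a press, applied
  symmetrically to the lose-shift ratios for consistency.
* `lookahead`: the relation is taken to the next press anywhere later in the
  session; only presses with no successor are censored.

Ratios with a zero denominator are `NA`, and missing values propagate to the
statistics layer, which performs complete-case deletion per outcome and
reports the n actually used.

The six per-session readouts (`summarize_session()`) are the probabilistic
and actual lose-shift ratios, the pooled win-stay ratio (stays after any
rewarded press over non-censored rewarded presses, both levers jointly — a
single pooled ratio, not a per-lever average), completed reversals, the
median press latency over press trials, and the omission count. The training
criterion (`check_training_criteria()`) is at least 3 reversals in each of 3
consecutive sessions with strictly less than 15% omissions per session.

## The statistical battery

`analyze_outcomes()` routes each readout to one of two branches, mirroring
standard practice for these measures:

* ratio outcomes → one-way repeated-measures ANOVA (subject as block; dose
  with k − 1 and (k − 1)(n − 1) df — (3, 117) at n = 40), Mauchly's test on
  the orthonormal within-subject contrast covariance, Greenhouse–Geisser
  corrected p reported alongside the uncorrected one, and Sidak-adjusted
  pairwise contrasts using the pooled within-subject error term
  (t = Δmean / √(2·MS~err~/n) on df~err~; `p_adj = 1 − (1 − p)^m`);
* count/latency outcomes → Friedman test with mid-rank tie correction
  (an all-tied matrix returns chi-square 0 with a warning rather than an
  error), followed by Dunn's post hoc
  (Z = Δmean-rank / √(k(k + 1)/(6n)), Bonferroni over the requested pairs;
  a Sidak variant is available).

Defaults resolved where conventions differ: the comparison family is all
`m = k(k−1)/2` pairs (6 at k = 4) — reporting any dose-vs-dose contrast
implies the full family; the post hoc error term is pooled (a per-pair
paired-t variant sits behind `error = "perpair"`); normality is checked with
a Lilliefors-type KS statistic whose p-value comes from Monte-Carlo
simulation of the estimated-parameter null, since parameters are estimated
from the data. Routing is fixed by outcome type by default; `routing =
"auto"` lets the normality check decide at α = 0.05.

The Latin-square generator tiles the standard 4 × 4 crossover square (each
dose once per subject, balanced over test positions) over the cohort;
`randomize = TRUE` shuffles rows and relabels symbols while preserving the
defining balance.

## The pinned demonstration scenario

`fig1_pattern()` ships the cohort scenario used throughout the tests: 40
subjects × 4 dose conditions (vehicle, 5, 10, 40 mg/kg) in the Latin-square
crossover, 200-trial sessions. Parameter choices, made once at design time:

| parameter | vehicle / 5 | 10 | 40 mg/kg | rationale |
|---|---|---|---|---|
| `p_stay_after_win` | 0.99 | 0.99 | 0.99 | trained rats rarely leave a winning lever |
| `p_shift_after_loss` | 0.75 | 0.75 | 0.75 | untouched by dose: the confound spares feedback sensitivity |
| `p_omit` | 0.02 | 0.02 | 0.40 | a strongly sedating dose omits heavily |
| `p_persev` | 0.05 | 0.05 | 0.65 | sedated animals stay near the last-pressed lever |
| `latency_location` (s) | 1.2 | 0.85 | 3.0 | the middle dose mildly speeds pressing; the high dose slows it |
| `latency_scale` | 0.40 | 0.40 | 0.55 | slower animals are also more variable |
| `drowsy_persistence` | 0.94 | 0.94 | 0.94 | structural bout length (~15–30 trials), identical at every dose |

Only `p_omit`, `p_persev` and the latency parameters differ between vehicle
and the high dose. Between-subject heterogeneity is a multiplicative
log-normal factor on the probability parameters and the latency median
(sd 0.06, constant within subject; probabilities clipped to [0, 1]), plus an
independent session-level factor of the same form (sd 0.10) representing
day-to-day behavioral state. Session-level variability is essential realism:
repeated operant testing shows within-subject, between-day variance well
above binomial sampling noise, and without it every within-subject contrast
in a 200-trial session would be implausibly precise. The subject-level sd
sits below the session-level sd because trait differences in a trained,
criterion-matched cohort are modest compared with day-to-day state.

Under this scenario the scored cohort shows the sedation signature: both
lose-shift ratios drop sharply at 40 mg/kg, reversals fall from ~9 to ~3–4,
omissions rise from ~3 to ~70–80 of 200 trials, median latency roughly
doubles, while `p_shift_after_loss` never changed — a *reduced
NF-sensitivity* reading that would be wrong.

### What the generator does and does not emulate

It emulates: the crossover design and its balance, endogenous lever
assignment, the omission/perseveration/latency signature of sedation with
bout structure, subject and day-to-day heterogeneity, and undefined ratios in
heavily omitting sessions. It does not emulate: learning or satiation within
and across sessions, carry-over between crossover periods, position-of-
testing effects, reward-magnitude sensitivity, or any pharmacokinetics —
dose labels are nothing but parameter sets. Passing tests therefore show the
*scoring and inference machinery* behaves correctly and that the confound
mechanism is sufficient to produce the qualitative pattern; they are not
evidence about any real compound.

### A structural note on the win-stay ratio

Previous-side perseveration can only add stays after wins, so the drowsy
condition's win-stay ratio carries a small upward excess of roughly
w·(1 − p_stay), where w is the drowsy share of scored rewarded presses. With
the scenario above this is ≈ 0.01–0.015, about 1.4 pooled standard errors at
n = 40 — usually, but not always, non-significant after Sidak adjustment.
The excess cannot be removed without either making win-stay degenerate
(p_stay = 1 with no jitter) or switching to a perseveration model that
spares wins, which would amount to building reduced loss sensitivity in by
hand — the very confusion the package exists to demonstrate. Analyses of
single simulated cohorts should expect an occasional nominally significant
win-stay contrast of this origin.

## Numerical and implementation choices

* Reward draws are pre-drawn per trial from the session seed; the
  consecutive-correct counter and lever swap follow the step contract
  exactly (the vectorized session loop is tested against a trial-by-trial
  replay through `step_trial()`).
* Mauchly's W uses the standard chi-square approximation; for k = 2
  sphericity is trivially 1. Greenhouse–Geisser ε comes from the eigenvalues
  of the contrast covariance.
* The Friedman statistic uses mid-ranks with the classical tie-correction
  denominator; exhaustive permutation enumeration is used as the oracle at
  small n in the tests.
* Monte-Carlo p-values use (r + 1)/(B + 1) with B configurable (400 by
  default in the battery; the seed is exposed so reports are reproducible).
* Exports are plain UTF-8 CSV/TSV with "." decimals; trial indices are
  0-based internally and 1-based in files; missing latencies are empty
  fields. Reports exclude timestamps so re-analysis is byte-stable.
* Test and demonstration problem sizes: 1000-session oracle equivalence,
  100-cohort robustness sweeps, 2000-replicate null calibrations — sizes
  chosen to keep Monte-Carlo intervals tight while the whole suite runs in a
  few minutes on one core.

## Known limitations

* The WSLS policy is blind to the hidden lever role (as it must be), so its
  probabilistic and actual lose-shift ratios coincide in expectation at
  baseline; empirically trained rats often respond more to actual than to
  misleading NF. A belief-tracking agent would be needed for that asymmetry.
* Drowsy-parameter magnitudes are design choices, not measurements —
  sedation severity was never quantified in the motivating setting, so only
  the direction and pattern of effects are anchored.
* The external-deposit ingester matches column synonyms case-insensitively
  and validates strictly, but it has been exercised only against
  synthetically shaped tables.
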