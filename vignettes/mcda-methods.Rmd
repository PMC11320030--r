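---
title: "Weighted-sum MCDA with satisfice screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-sum MCDA with satisfice screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocmcda)
```

## The decision model

`pocmcda` implements a quantitative multi-criteria decision analysis (MCDA)
of the kind used in health technology assessment to prioritise candidate
technologies — here, clinical "use cases" for point-of-care (POC) testing in
ambulance services — for entry into a platform trial. The model is a plain
weighted sum. A stakeholder panel scores each option $o$ against each
criterion $c$ on that criterion's ordinal rating scale; votes are averaged
into a mean rating $s_{o,c}$; each criterion carries a weight $w_c$; and the
option's score is

$$T_o = \sum_c w_c \, s_{o,c}.$$

Options are ranked by descending $T_o$ and the top $k$ (default 3) are
selected. Three modelling choices deserve emphasis:

* **Weights are elicited means, used raw.** $w_c$ is the arithmetic mean of
  stakeholders' 0–10 importance scores for the criterion, kept at full
  precision and *not* normalised to sum to one. Totals therefore live on the
  elicitation scale (a 4-criterion exercise with 0–4 rating scales can reach
  $4 \times 10 \times 4 = 160$); only the ordering of totals is
  interpretable, not their absolute magnitude.
* **Satisfice ("deal-breaker") rules act on the unrounded mean.** A rule
  names a contiguous tail of the rating scale — e.g. levels $\{0,1,2\}$ of a
  0–4 evidence scale, or level $\{4\}$ of a harm-direction scale — and is
  reduced to a threshold comparison: a low tail is met when
  $s_{o,c} \le \max(\text{tail})$, a high tail when
  $s_{o,c} \ge \min(\text{tail})$. Comparing the mean rather than its
  rounded category matters at the boundary: a mean of 1.69 trips a
  "levels 0–2" rule while 2.15 does not, although both round to category 2.
  Sets that are not a single tail (interior blocks, both ends, gaps) are
  rejected at configuration time as ambiguous rather than guessed at.
* **A satisfice hit flags, it does not delete.** An option meeting a rule
  during scoring is marked ineligible for selection but is still scored,
  totalled and ranked, so the panel sees the full picture. Pre-scoring
  exclusions — options a panel strikes out by explicit decision before votes
  are cast — are configuration input (an id list), not something the engine
  infers: such decisions encode deliberation that printed summaries do not
  determine.

## Pipeline stages and their contracts

The stages mirror how such exercises are actually run: importance survey →
weights (`assign_weights()`); named exclusions (`apply_exclusions()`); vote
aggregation into the scoring matrix (`build_matrix()`); ranking and top-$k$
selection (`rank_options()`); robustness analysis (`jackknife_ranks()`,
`perturb_weights()`). `run_pipeline()` composes them, writes every table plus
a digest-bearing manifest, and aborts with the stage name on any validation
failure.

Participation may vary cell by cell (workshop tools allow abstention), so
each cell records its own vote count $n_{o,c}$ and means are taken over the
votes present. A cell with *no* votes is an error at scoring time — an
absent consensus cannot silently enter a weighted sum.

All arithmetic is double precision throughout; rounding is display-only,
half-up at `rounding_dp` (default 2) decimals, applied only when reports are
rendered. Ranking ties are broken by input (configuration) order, kept
stable, and annotated in the output rather than hidden.

## Verifying a published matrix

`score_from_means()` accepts per-cell means directly, because published
matrices print means, not votes — and no integer vote set reproduces a
rounded printed mean exactly. `verify_printed_matrix()` then checks whether
each printed final score is *reconcilable* with printed weight × printed
mean: a printed mean $m$ rounded to $d$ decimals stands for any value in
$m \pm \tfrac{1}{2}10^{-d}$, so the final must lie in
$[w(m-h)-h,\; w(m+h)+h]$ with $h = \tfrac{1}{2}10^{-d}$. The bundled worked
example (`ems_poc_criteria()`, `ems_poc_printed_matrix()`) shows why this
mode exists: one criterion's printed final scores imply a multiplier near
9.59 although the printed weighting is 7.20 — an irreconcilable row that the
verifier flags on all five of its cells while confirming the other fifteen.
The engine always computes $w_c \, s_{o,c}$ faithfully; it never copies a
printed inconsistency forward.

## The synthetic stakeholder panel

Because the human surveys behind such an exercise cannot be re-run, the
package ships a generator with known latent structure (`panel_model()`).
Every cell has a latent consensus $\mu_{o,c}$ on the scale's real interval
and dispersion $\sigma_{o,c}$; every criterion has a latent importance
$\mu_{w,c} \in [0,10]$; each stakeholder answers each question independently
with probability `participation`. A response is drawn as
$\mathcal{N}(\mu, \sigma)$, clamped to the scale interval, then rounded to
the nearest scale code (halves toward the higher code; scales with skipped
codes snap to the nearest *available* code).

Defaults reflect a realistic exercise of this kind: 14 stakeholders per
voting panel, participation 1 for workshops and 0.54 for surveys of a
28-member stakeholder pool (≈15 respondents), vote dispersion 0.75 on a
5-level scale, importance dispersion 1.5 on the 0–10 scale. Seeds are
mandatory arguments — there is no hidden RNG state — and fixed seeds give
bit-identical tables.

The clamp-then-round model is the simplest with a consensus-plus-dispersion
reading, and it is deliberately imperfect near scale edges: for $\mu$ close
to the maximum, clamping can only pull responses down, so the expected
response sits *below* $\mu$ (for $\mu_w = 8.8$, $\sigma = 1.5$ on 0–10 the
bias is ≈ −0.18). `recovery_experiment()` reports this bias rather than
hiding it, and the test suite checks recovered means against the model's
analytic expectation (normal mass between scale midpoints), which coincides
with $\mu$ only in the interior. What the generator does *not* model:
inter-stakeholder correlation, anchoring, deliberation effects, or any
relationship between a stakeholder's importance scores and their votes.
Passing recovery tests therefore demonstrates correctness of the
aggregation arithmetic under an idealised panel, not fidelity to human
workshop behaviour.

## Robustness analysis

Two procedures quantify rank stability, an analysis the weighted-sum method
invites even when a one-off exercise does not perform it:

* **Leave-one-out jackknife** (`jackknife_ranks()`): re-score once per
  stakeholder removed; report every rank change. A removal that empties a
  cell flags that replicate incomplete instead of dropping it silently.
* **Weight perturbation** (`perturb_weights()`): multiply each $w_c$ by an
  independent log-normal factor with unit median and log-scale
  `noise_scale`, re-rank, and report per-option rank frequencies, top-$k$
  retention per option, and how often the baseline top-$k$ set survives
  intact. Multiplicative noise is used because it preserves non-negativity
  and perturbs *relative* importance — the thing elicitation uncertainty
  acts on; `noise_scale = 0.1` (≈10% weight jitter) and 10000 replicates are
  conservative defaults chosen here, not elicited quantities.

One symmetry subtlety: two options with *identical* mean profiles have
identical totals under every shared weight draw, so the stable tie rule
ranks the first-listed one first in 100% of replicates — by design, ties are
deterministic and annotated. The meaningful symmetric benchmark, used in the
tests, is a pair of options with *mirrored* profiles under equal baseline
weights, where exchangeability of the weight factors makes each option's
first-place probability exactly one half.

## Numerical and testing choices

* Oracle tests recompute small matrices (panels up to 4 stakeholders × 3
  options × 3 criteria) with independent nested-loop arithmetic at
  tolerance $10^{-12}$; property suites run ≈1000 random panels for
  monotonicity (raising a vote never hurts that option) and permutation
  invariance of record order.
* Recovery experiments use 1000-stakeholder panels at $\sigma = 0.5$ with
  interior consensus values, where the analytic rounding bias is below
  0.01 and three Monte-Carlo standard errors is a sharp criterion. These
  problem sizes keep the full suite under a minute while leaving the
  statistical assertions well-powered.
* Degenerate inputs are defined behaviour: zero dispersion reproduces the
  consensus exactly; zero participation yields an empty (valid) table; zero
  noise reproduces the baseline ranking in every replicate; a zero weight
  removes a criterion's influence without removing its satisfice rule.

## Limitations

The package evaluates the *arithmetic* of a weighted-sum MCDA. It does not
model why a panel chose its criteria, scales or exclusions; it treats the
scored option set as configuration because panel decisions (e.g. which
screened-out options re-enter scoring) are not always mechanically derivable
from the printed record. Weighted sums assume preferential independence
between criteria and linear value in the mean rating; neither assumption is
tested here. The ordinal scales are averaged as if interval-scaled — the
standard practice in this kind of exercise, inherited deliberately.
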