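---
title: "Methods: error analysis of continuous motor sequence tapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: error analysis of continuous motor sequence tapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapslip)
```

## The task and its atomic records

tapslip analyzes self-paced, feedback-free motor sequence tapping: a
participant repeatedly taps a short key sequence (default 4–1–3–2–4 on a
four-key pad, so the sequence length is k = 5) in performance blocks that
end after a fixed number of keypresses (default 60, i.e. 12 repetitions),
separated by rest (default 15 s). The raw record is a timestamped keypress
log; everything else — trials, errors, periods, slowing, BOLD regressors —
is derived from it.

## Segmentation: greedy earliest-match tiling

`parse_block()` scans each block left to right: a window of k keys equal to
the target sequence becomes a correct trial and the cursor jumps past it;
any other key joins the current non-trial run. Maximal runs flanked by
correct trials on both sides are errors; leading and trailing runs are
labeled residual rather than silently dropped, so the emitted spans always
partition the block (an auditable invariant tested on random streams).
Because the scan checks every cursor position, an error run can never
contain a full sequence match. Since all matches have equal length, the
earliest-match rule is also a maximum-cardinality tiling — the test suite
checks this against an independent dynamic-programming oracle by full
enumeration with a short sequence and on random 60-key streams.

`annotate_error()` classifies each error by the longest prefix of its keys
that matches a prefix of the sequence: if the whole error is such a prefix
it is an *incomplete sequence* (up to k − 2 correct keys) or a *missing one
key* error (exactly k − 1); otherwise the first wrong key sits at ordinal
p + 1, which can never exceed k (a brute-force sweep over all single
substitutions, insertions and omissions confirms this). Restart attempts
count occurrences of the first sequence transition (4 → 1) among the
error's consecutive keys, plus the bridge into the following correct trial
when the key codes make that possible.

One structural observation worth recording: for a sequence whose last code
equals its first (as 4–1–3–2–4), a "missing one key" pattern — the four-key
prefix followed directly by a restart — retiles under greedy earliest-match
into a full correct trial that borrows the restart's first key, so the
category is unreachable from this parser for this sequence. The annotation
type exists and is exercised with alternative sequences; the synthetic
generator gives it zero default weight and refuses to schedule it for
sequences where it cannot survive parsing.

### Error duration

The duration filter below needs a duration definition, and a single extra
key has zero intra-error time. tapslip therefore measures an error from
the last key of the preceding correct trial to the first key of the
following one (spanning the onset and offset transitions), which is what
makes a 0.5-s minimum meaningful for 1-key errors. A strict
first-to-last-key alternative is available via
`parse_session(duration_mode = "strict")`.

## Isolated errors, positions, and matched controls

Eligibility (`select_errors()`, thresholds in `selection_config()`): an
error must be immediately preceded and followed by at least 3 correct
trials (the last error of a block needs only 2 followers when they run to
the very end of the block), must last longer than 500 ms, and may comprise
at most 20 keys. The 20-key bound is *inclusive* here: the source
material states the exclusion both as "more than 20 keys" and "less than
20 keys" in different places; we adopt the former and expose the threshold.
Each eligible error and its neighbors form a 7-trial (or end-of-block
6-trial) period.

The within-block position of a trial whose first key has 1-based index i is
`ROUND((i − 1)/k) + 1`, with ROUND half-away-from-zero. Under the
default layout and rules, exhaustively enumerating every single-error
60-key block shows eligible positions span exactly 4..10 — the test suite
and the acceptance script both recompute this.

Controls (`enumerate_controls()`): every run of ≥ 7 consecutive correct
trials contributes a candidate window at each alignment, plus a 6-trial
window when it closes the block; a candidate's position is determined by
its 4th trial. `match_positions()` draws, per error, one same-position
candidate uniformly at random over the lexicographically ordered
candidates, without reuse of a control center within a set; errors without
a positional match are excluded with a recorded reason, so eligible errors
always reconcile as matched + excluded. Candidate windows may overlap each
other — only center-trial reuse is forbidden, because matching is by the
4th trial, not by full-window disjointness. Whether one errorless window
may serve several errors was genuinely open; forbidding center reuse keeps
the two conditions independent across pairs. `second_matched_set()`
repeats the draw excluding the first set's centers and drops errors (from
both sets) that cannot be matched twice, so the two sets cover the same
errors and are disjoint at the center level.

Timekeeping is an explicit convention: behavior is in ms, imaging in
seconds, and the conversion happens exactly once, in
`write_events_table()`. Keypress onsets are session-relative (the log
format does not say whether a recording is block- or session-relative, so
the package standardizes on the latter, with block onsets carried
separately).

## Block-normalized slowing

Speed is the transition duration between consecutive keypresses. Each
block's reference is the mean of the within-trial transitions of all its
correct trials (between-trial gaps excluded); slowing of a duration d is
`100 (d − ref)/ref` %, so 0 % is block-typical speed, the measure is
scale-free, and a block without correct trials contributes nothing (absent,
never zero — the same convention applies to phases with no constituent
transitions, e.g. a 1-key error has no within-error transitions).

`error_phase_profile()` resolves an error into the onset transition, the
within-error transitions strictly before and strictly after the first
wrong key, and the offset transition into the next correct trial.
`period_profile()` evaluates the five central roles of each matched period
(PreE2, PreE1, the center, PostE1, PostE2) — trial-level speed uses only
the four within-sequence transitions; the error center uses its onset,
within and offset transitions — and aggregates within subject first
(errors weighted equally, i.e. per-error means averaged), then across
subjects, the two-stage summary-statistics convention used throughout.

Group inference (`group_tests()`): two-tailed one-sample and paired t
tests via `stats::t.test`, and a one-way repeated-measures ANOVA with
Greenhouse–Geisser correction. The GG epsilon is Box's estimator from the
sample covariance of conditions projected on an orthonormal contrast
basis; it equals 1 exactly for 2-level designs. Huynh–Feldt is
deliberately not offered. Zero-variance input yields an absent p with a
diagnostic rather than a fabricated statistic.

## The mixed block/event-related GLM

`build_design()` builds regressors at microtime resolution (TR/16 by
default), convolves with a canonical double-gamma HRF, and samples at scan
onsets. Conventions that matter:

* **HRF**: difference of gamma densities, response delay 6 s, undershoot
  delay 16 s, unit dispersions, amplitude ratio 6, 32-s support,
  normalized to unit peak by the *analytic* peak height so the scale is
  independent of the sampling step. The source names no kernel; these are
  the field-standard parameters, exposed in `hrf_spec()`.
* **Sticks** are unit impulses at the nearest microtime bin, so a stick
  column is exactly a superposition of shifted sampled kernels (tested to
  1e−10 against direct superposition).
* **Epochs** (the per-block boxcar, and events under the
  `actual_duration` policy) enter with per-bin fractional overlap and a
  half-bin shift, making the discrete convolution a midpoint rule for the
  continuous integral. Without that shift the left-Riemann edge bias
  (order dt/2 of the sustained amplitude) leaks into edge-locked
  regressors, most visibly the GO stick that sits on the block onset.
* **High-pass**: DCT columns below the 1/128-s cutoff enter as nuisance
  regressors rather than pre-filtering — the same projection, but the
  degrees-of-freedom bookkeeping stays explicit.
* Motion parameters are appended unconvolved; the intercept is last; the
  microtime onset is the stated onset with no slice-reference shift (the
  within-TR alignment was unspecified; we time-lock to the volume onset).

`generate_model_suite()` implements the separate-models scheme: adjacent
trials share variance after HRF smearing, and a joint fit would remove it,
so each trial role is estimated in its own model — one model per trial
ordinal of errorless blocks (12 under the default layout) plus five role
models (PreE2, PreE1, E, PostE1, PostE2), each carrying the role's events
and the corresponding position-matched control events. Two supplementary
variants are options, not defaults: error onsets shifted to the first
wrong key (`onset_policy = "first_wrong_key"`, falling back to the trial
onset for errors without a wrong key), and `actual_duration` event
modeling. When every error's first key is its first wrong key the two
onset policies produce identical designs (tested).

A consequence worth stating plainly: separate models yield *marginal*
estimates, so a role's beta absorbs correlated signal from unmodeled
neighboring trials. The recovery tests therefore check region-wise sign
patterns (a series with an instantaneous error response shows a positive
error contrast; a series with delayed negative post-error amplitude shows
negative PostE1/PostE2 contrasts) rather than pretending the scheme
separates adjacent amplitudes within one series.

`fit_prewhitened()` estimates the AR(1)-plus-white-noise model in two
passes: OLS, then the lag-1 autocorrelation of residuals pooled over all
series of the run, then AR(1) whitening (first sample scaled by
sqrt(1 − phi²)) and a refit. The raw residual autocorrelation is corrected
for its projection bias (under white noise its expectation is
−tr(SH)/(n − p) for the lag-shift S and hat matrix H — far from negligible
with a bank of smooth DCT columns). This is a deliberate, documented
substitute for full restricted-maximum-likelihood iteration: the model
class is identical and the estimator is calibrated in the tests (phi
recovered within 0.05 at phi = 0.3 and at 0; residual lag-1 correlation
driven below 0.1; null contrasts rejected at the nominal 5 % rate).

Contrasts: `t_contrast()` for univariate combinations against the
whitened design; `matched_contrast()` compares error against
position-matched control either as pooled condition regressors (+1/−1,
default) or per-pair beta series averaging pairwise differences — the
trial-by-trial wording of the source is ambiguous between the two, so both
exist and agree on balanced noiseless designs. `sphere_roi_values()`
averages a map over voxels whose centers fall within the sphere radius
(inclusive; 6 mm default, 4 mm conventionally for basal ganglia and
thalamus) in the volume's own mm frame — no atlas registration.
`second_level()` runs one-sample t tests per ROI with Bonferroni over the
family (25 ROIs at alpha 0.05 give the 0.002 threshold), and
`second_level_phase()` the GG-corrected repeated-measures F over the five
roles. Cluster-level random-field correction is out of scope; uncorrected
voxel thresholds plus ROI Bonferroni are the provided inference modes.

## What the generators emulate — and what they do not

`gen_behavior()` emulates: blocks ending after exactly the configured
number of presses; log-normal inter-press intervals (positive,
right-skewed; no distribution is stated in the source, and the scale is
mean-parameterized so a multiplier m multiplies the expected duration by
exactly m); per-block speed multipliers (default a mild practice speed-up
from 1.08 to 0.94); errors scheduled by rate (default 0.03 per trial,
giving roughly 4–5 raw errors over a 14-block session, of which a few
survive the eligibility rules, comparable to the reported per-subject
yield) or by explicit (block, trial, type) schedule; and phase-specific
slowing multipliers — defaults 1.35 at the error onset, 1.5 within, 2.0 at
the offset, 1.06 for the first post-error trial, 1.3 at block initiation,
1.0 before the error, chosen once to mirror the reported ordering of
effects (offset ≫ within > onset ≫ post-error ≈ small; pre-error ≈ none).
Error key patterns are constructed so the greedy parse provably recovers
the planned labels (wrong-key errors end in repeats of the wrong key;
incomplete sequences are bare prefixes), which is what makes the
truth-label round-trip an exact test rather than a statistical one.
Scheduled errors must sit at trial ≥ 2 and at least `min_gap` (default 4)
trials apart; adjacent planned errors would merge into one run and
invalidate the truth, so such schedules are rejected.

`gen_bold()` synthesizes the noiseless signal in continuous time from the
closed-form HRF — sticks as shifted kernels, epochs via the kernel's
analytic integral — so generator and fitter share no discretization basis;
drift is a sinusoid (period 300 s by default), deliberately not the DCT
the fitter uses; noise is AR(1) with the stated marginal SD. True
amplitudes per regressor and a per-series spatial profile are carried in
the returned truth object, which is sufficient to score any stage without
re-running the generator.

What the generators do **not** emulate: learning curves across sessions,
motion and physiological noise structure, spatially correlated BOLD
fields, biophysical (balloon-type) dynamics, and any dependence of error
probability on speed (no built-in speed–accuracy coupling). Passing
recovery tests therefore demonstrate that the estimators are correct and
calibrated for data with the assumed structure — not that real recordings
satisfy those assumptions.

## Problem sizes and numerical choices

The test suite's simulation scales are the package's own choices: full
tiling-oracle enumeration uses a k = 2 sequence over small alphabets
(dense in overlapping matches, which stresses the tiling argument far more
per stream than a sparse k = 5 alphabet-4 stream does) plus 1000 random
60-key streams with the study sequence; matched-set invariants run on 500
random sessions across two files; AR(1) calibration uses 200 replicates of
n = 400 scans sharing one design matrix; null calibrations use 10,000
series fitted in a single vectorized pass; behavioral recovery uses 40
synthetic subjects; the end-to-end sign-pattern property uses 100 seeded
runs of 20 subjects with 6-block sessions. Degenerate inputs follow one
rule: absent, with a reason, never silently zero — blocks without correct
trials, phases without transitions, spheres covering no voxel center,
zero-variance group tests.

## Known limitations

* The eligibility rule for a block-final error requires its following
  correct run to reach the block's final trial; a trailing residual key
  disqualifies it. The source's "at the very end of the block" is not
  more precise than this.
* Marginal (separate-model) role estimates are intentionally not
  deconvolved; adjacent-role cross-talk is a property of the method, and
  interpretation should rest on shape and latency, not on single-role
  amplitudes.
* The pooled AR(1) coefficient is shared across all series of a run;
  spatially varying autocorrelation is not modeled.
* NIfTI support reads 4D volumes into a scans-by-voxel matrix via RNifti
  when that package is available; the TSV time-by-series path is the
  primary interface.
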