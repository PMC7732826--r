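# tapslip

Behavioral and fMRI analysis of movement errors committed during
continuous, self-paced motor sequence tapping.

## The problem

A participant taps a memorized key sequence (4–1–3–2–4 on a four-key pad)
repeatedly and as fast as possible, with no external feedback, in blocks
of 60 keypresses separated by rest. Occasional errors interrupt the
stereotyped stream. Detecting those errors in the keypress log, deciding
which are clean enough to analyze, building matched error-free baselines,
and quantifying how performance and brain activity change before, during
and after each error is a surprisingly structured pipeline — and every
step has rules that are easy to get subtly wrong. tapslip implements that
pipeline as tested, reusable R functions, for researchers analyzing
self-guided sequence-production experiments (behavior only, or behavior
plus BOLD time series).

## What it computes

**Segmentation.** A greedy earliest-match scan tiles each block with
correct trials (five consecutive keys equal to the sequence); maximal
leftover runs between correct trials are errors, annotated with the first
wrong key ordinal (never beyond 5), error type, restart attempts and
duration. Leading/trailing runs are kept as residuals so spans always
partition the block.

**Isolated errors and matched controls.** An error is eligible if flanked
by ≥ 3 correct trials (≥ 2 if it ends the block), lasts > 0.5 s and has
≤ 20 keys. Its within-block position is

    position = ROUND((i − 1) / k) + 1

for first-key index *i* and sequence length *k*; eligible positions span
exactly 4–10 in a 60-key block. Each error period is matched
pseudo-randomly to an error-free 7-trial window at the same position, and
a second, disjoint matched set supports specificity checks.

**Slowing.** Transition durations are normalized per block:
`100 (d − ref)/ref` %, where `ref` is the mean within-trial transition of
the block's correct trials. Profiles resolve the error onset,
within-error (before/after the first wrong key) and offset phases, and
the PreE2…PostE2 trial course, with one-sample/paired t tests and
repeated-measures ANOVA (Greenhouse–Geisser) at the group level.

**GLM.** A mixed block/event-related design — per-block boxcars for
sustained activity, zero-duration sticks for trial-locked transients, a
GO-cue stick, DCT high-pass (128 s), motion nuisance — convolved with a
canonical double-gamma HRF, fitted with AR(1)+white-noise prewhitening.
Adjacent trials are estimated in separate models (12 errorless-trial
models + 5 error-role models per subject); error-vs-matched-control
contrasts, sphere-ROI extraction and second-level statistics (one-sample
t, Bonferroni over the ROI family — 25 ROIs give p < 0.002) complete the
stack.

**Synthetic data.** `gen_behavior()` and `gen_bold()` produce keypress
sessions and BOLD series with the statistical structure the analysis
assumes — log-normal inter-press intervals, per-block drift, typed errors
with phase-specific slowing; HRF responses, AR(1) noise, sinusoidal drift
— carrying exact ground truth for recovery testing.

## Worked example

```r
library(tapslip)

fx <- make_fixture("one-error-block")        # one 60-key block, one error
trials <- parse_session(fx$keypresses, fx$seq)
trials[trials$kind == "error",
       c("block", "trial", "error_type", "first_wrong_ordinal",
         "n_keys", "error_duration_ms")]
#>   block trial error_type first_wrong_ordinal n_keys error_duration_ms
#> 6     1     6  wrong_key                   3      4          2759.209

sel <- select_errors(trials)
sel$periods
#>   subject block center_trial first_trial last_trial n_trials position
#> 1   sub01     1            6           3          9        7        6

round(error_phase_profile(sel$periods[1, ], trials, fx$keypresses), 1)
#>   onset within_pre within_post offset
#> 1  44.9       54.8          NA  187.7
```

The fixture's scheduled error at trial 6 is recovered as a wrong-key error
whose third key broke the sequence, with two correct keys before it; it
forms a 7-trial period at within-block position 6. Its transitions ran
44.9 % (onset) and 54.8 % (before the wrong key) slower than the block's
typical speed, and the restart transition 187.7 % slower; `within_post` is
absent (`NA`, not zero) because no key followed the wrong key. The
end-to-end driver is `run_pipeline()` (see `?run_pipeline`;
`inst/scripts/tapslip-pipeline.R` wraps it for the shell), and the methods
vignette (`vignettes/tapslip-methods.Rmd`) documents the model and every
numerical convention.

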