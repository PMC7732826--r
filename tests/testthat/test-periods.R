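s5 <- sequence_spec()

# a session with one 2-key error at trial `slot` of a 60-key block,
# transition times chosen to pass the duration filter
session_one_error <- function(slot = 6L, iv = 300) {
  keys <- c(rep(s5$codes, slot - 1L), c(4, 2), rep(s5$codes, 12L - slot))
  keys <- keys[seq_len(min(60L, length(keys)))]
  parse_session(kp_from(keys, seq_along(keys) * iv), s5)
}

test_that("within-block position follows the rounding formula", {
  expect_equal(within_block_position(1, 5), 1L)
  expect_equal(within_block_position(16, 5), 4L)
  expect_equal(within_block_position(48, 5), 10L)
  # direct evaluation against the formula over a range
  i <- 1:200
  expect_equal(within_block_position(i, 5),
               as.integer(floor((i - 1) / 5 + 0.5) + 1))
  # half-away-from-zero rounding for even k
  expect_equal(within_block_position(2, 2), 2L)  # (2-1)/2 = 0.5 -> 1
})

test_that("error eligibility rules admit and reject as specified", {
  tr <- session_one_error(6L)
  sel <- select_errors(tr, selection_config())
  expect_equal(nrow(sel$periods), 1L)
  expect_equal(sel$periods$position, 6L)
  expect_equal(sel$periods$n_trials, 7L)
  expect_equal(sel$periods$first_trial, 3L)
  expect_equal(sel$periods$last_trial, 9L)

  # same block but too-fast transitions: duration filter rejects
  tr_fast <- session_one_error(6L, iv = 100)  # duration 3 x 100 = 300 ms
  sel <- select_errors(tr_fast, selection_config())
  expect_equal(nrow(sel$periods), 0L)
  expect_match(sel$excluded$reason, "duration")

  # two errors separated by 2 correct trials: both isolation-ineligible
  keys <- c(rep(s5$codes, 3), c(2), rep(s5$codes, 2), c(2), rep(s5$codes, 5))
  keys <- keys[1:52]
  tr2 <- parse_session(kp_from(keys, seq_along(keys) * 300), s5)
  sel2 <- select_errors(tr2, selection_config())
  expect_equal(nrow(sel2$periods), 0L)
  expect_equal(nrow(sel2$excluded), 2L)

  # last error of the block followed by exactly two correct trials that
  # end the block is admitted with a 6-trial period
  keys <- c(rep(s5$codes, 9), rep(3, 5), rep(s5$codes, 2))
  tr3 <- parse_session(kp_from(keys, seq_along(keys) * 300), s5)
  sel3 <- select_errors(tr3, selection_config())
  expect_equal(nrow(sel3$periods), 1L)
  expect_equal(sel3$periods$n_trials, 6L)
  expect_equal(sel3$periods$position, 10L)

  # errors longer than max_keys are rejected
  keys <- c(rep(s5$codes, 4), rep(3, 21), rep(s5$codes, 3))
  tr4 <- parse_session(kp_from(keys, seq_along(keys) * 300), s5)
  sel4 <- select_errors(tr4, selection_config())
  expect_equal(nrow(sel4$periods), 0L)
  expect_match(sel4$excluded$reason, "too many keys")
})

test_that("exhaustive single-error enumeration spans positions 4..10", {
  cfg <- selection_config()
  positions <- integer(0)
  for (a in 0:11) {
    for (b in 0:11) {
      L <- 60L - 5L * (a + b)
      if (L < 1L || L > 25L) next
      keys <- c(rep(s5$codes, a), rep(2L, L), rep(s5$codes, b))
      tr <- parse_session(kp_from(keys, seq_along(keys) * 300), s5)
      if (!any(tr$kind == "error")) next
      sel <- select_errors(tr, cfg)
      positions <- c(positions, sel$periods$position)
    }
  }
  expect_equal(sort(unique(positions)), 4:10)
})

test_that("control window enumeration matches exhaustive expectations", {
  # errorless block of 12 correct trials: 7-trial windows centered at
  # positions 4..9 plus the end-of-block 6-trial window at position 10
  tr <- parse_session(kp_from(rep(s5$codes, 12), (1:60) * 250), s5)
  ctl <- enumerate_controls(tr)
  expect_equal(sort(ctl$position), c(4:9, 10))
  expect_equal(ctl$n_trials[ctl$position == 10], 6L)
  expect_true(all(ctl$n_trials[ctl$position < 10] == 7L))

  # no candidate window spans an error
  tr_err <- session_one_error(6L)
  ctl_err <- enumerate_controls(tr_err)
  er_trial <- tr_err$trial[tr_err$kind == "error"]
  expect_true(all(ctl_err$first_trial > er_trial |
                  ctl_err$last_trial < er_trial))

  # a block of exactly 6 correct trials only yields the end window
  tr6 <- parse_session(kp_from(rep(s5$codes, 6), (1:30) * 250), s5)
  ctl6 <- enumerate_controls(tr6)
  expect_equal(nrow(ctl6), 1L)
  expect_equal(ctl6$n_trials, 6L)
})

test_that("position matching pairs, excludes and reproduces deterministically", {
  # two-block session: one error block, one errorless block of controls
  keys1 <- c(rep(s5$codes, 5), c(4, 2), rep(s5$codes, 6))
  kp <- rbind(kp_from(keys1, seq_along(keys1) * 300, block = 1L),
              kp_from(rep(s5$codes, 12), 40000 + (1:60) * 300, block = 2L))
  tr <- parse_session(kp, s5)
  sel <- select_errors(tr, selection_config())
  ctl <- enumerate_controls(tr)
  m1 <- match_positions(sel$periods, ctl, seed = 5)
  expect_equal(nrow(m1$pairs), nrow(sel$periods))
  expect_true(all(m1$pairs$position == sel$periods$position))
  # determinism: same seed, identical pairs
  m2 <- match_positions(sel$periods, ctl, seed = 5)
  expect_identical(m1$pairs, m2$pairs)

  # an error whose position has no control is excluded with reason
  ctl_wrong <- ctl[ctl$position != sel$periods$position[1], , drop = FALSE]
  m3 <- match_positions(sel$periods, ctl_wrong, seed = 5)
  expect_equal(nrow(m3$pairs), 0L)
  expect_equal(m3$excluded$reason, "no positional match")
})

test_that("matched sets have equal counts and pairwise-equal positions on
           random sessions, and set 2 is disjoint from set 1", {
  spec <- behavior_gen_spec(n_subjects = 1L,
                            layout = block_layout(5L, 60L),
                            error_rate = 0.06, seed = 1L)
  bad <- 0L
  for (r in 1:200) {
    sim <- gen_behavior(spec, seed = 1000L + r)
    tr <- parse_session(sim$keypresses, s5)
    sel <- select_errors(tr, selection_config())
    ctl <- enumerate_controls(tr)
    m <- match_positions(sel$periods, ctl, seed = r)
    expect_true(all(m$pairs$position ==
      sel$periods$position[match(paste(m$pairs$error_block,
                                       m$pairs$error_center),
                                 paste(sel$periods$block,
                                       sel$periods$center_trial))]))
    # exclusion accounting: eligible = matched + excluded
    expect_equal(nrow(sel$periods), nrow(m$pairs) + nrow(m$excluded))
    # no control center reused within the set
    cc <- paste(m$pairs$subject, m$pairs$control_block,
                m$pairs$control_center)
    expect_equal(anyDuplicated(cc), 0L)
    sets <- second_matched_set(m, ctl, seed2 = 2000L + r)
    expect_equal(nrow(sets$set1$pairs), nrow(sets$set2$pairs))
    c1 <- paste(sets$set1$pairs$subject, sets$set1$pairs$control_block,
                sets$set1$pairs$control_center)
    c2 <- paste(sets$set2$pairs$subject, sets$set2$pairs$control_block,
                sets$set2$pairs$control_center)
    expect_length(intersect(c1, c2), 0)
  }
})

test_that("second matched set reuses the only remaining control or drops
           the error from both sets", {
  keys1 <- c(rep(s5$codes, 5), c(4, 2), rep(s5$codes, 6))
  kp <- rbind(kp_from(keys1, seq_along(keys1) * 300, block = 1L),
              kp_from(rep(s5$codes, 12), 40000 + (1:60) * 300, block = 2L),
              kp_from(rep(s5$codes, 12), 80000 + (1:60) * 300, block = 3L))
  tr <- parse_session(kp, s5)
  sel <- select_errors(tr, selection_config())
  ctl <- enumerate_controls(tr)
  pos <- sel$periods$position[1]
  ctl_pos <- ctl[ctl$position == pos, , drop = FALSE]

  # two distinct controls at the position: set 2 must take the other one
  if (nrow(ctl_pos) >= 2L) {
    m <- match_positions(sel$periods, ctl_pos, seed = 1)
    sets <- second_matched_set(m, ctl_pos, seed2 = 2)
    expect_equal(nrow(sets$set2$pairs), 1L)
    expect_false(identical(sets$set1$pairs$control_center,
                           sets$set2$pairs$control_center) &&
                 identical(sets$set1$pairs$control_block,
                           sets$set2$pairs$control_block))
  }

  # exactly one control: the error is dropped from both sets
  m1 <- match_positions(sel$periods, ctl_pos[1, , drop = FALSE], seed = 1)
  sets1 <- second_matched_set(m1, ctl_pos[1, , drop = FALSE], seed2 = 2)
  expect_equal(nrow(sets1$set1$pairs), 0L)
  expect_equal(nrow(sets1$set2$pairs), 0L)

  # no errors at all: two empty sets
  m0 <- match_positions(sel$periods[0, ], ctl, seed = 1)
  sets0 <- second_matched_set(m0, ctl, seed2 = 2)
  expect_equal(nrow(sets0$set1$pairs), 0L)
  expect_equal(nrow(sets0$set2$pairs), 0L)
})
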