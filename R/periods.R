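#' Within-block position of a trial
#'
#' `position = ROUND((i - 1) / k) + 1`, where `i` is the 1-based within-block
#' index of the trial's first key and `k` the sequence length; ROUND is
#' nearest-integer with halves away from zero (never triggered for odd
#' `(i-1)` remainders with k = 5).
#'
#' @param i 1-based first-key index (vectorized).
#' @param k sequence length.
#' @return integer position(s), 1-based.
#' @examples
#' within_block_position(1, 5)   # 1
#' within_block_position(16, 5)  # 4, the minimum eligible error position
#' within_block_position(48, 5)  # 10
#' @export
within_block_position <- function(i, k) {
  stopifnot(all(i >= 1), k >= 2)
  as.integer(round_half_away((i - 1) / k) + 1)
}

#' Select eligible isolated errors and build their periods
#'
#' An error is eligible when at least `min_pre` correct trials immediately
#' precede it and at least `min_post` immediately follow it -- or it is the
#' last error of its block, followed by at least `min_post_if_last` correct
#' trials that run to the very end of the block -- and its duration exceeds
#' `min_duration` ms and its length is at most `max_keys`.  Each eligible
#' error yields a period of its `min_pre` preceding correct trials, itself,
#' and `min_post` (or `min_post_if_last`) following correct trials; the
#' period's position is the within-block position of the error's first key.
#' Exclusions are reported with reasons, never silently.
#'
#' @param trials trials data.frame from [parse_session()].
#' @param cfg a [selection_config()].
#' @param k sequence length used for positions (default 5).
#' @return list with `periods` (data.frame: `subject`, `block`,
#'   `center_trial`, `first_trial`, `last_trial`, `n_trials`, `position`)
#'   and `excluded` (data.frame: `subject`, `block`, `trial`, `reason`).
#' @export
select_errors <- function(trials, cfg = selection_config(), k = 5L) {
  per <- list()
  exc <- list()
  for (blk in split_blocks(trials)) {
    n <- nrow(blk)
    err_idx <- which(blk$kind == "error")
    for (j in err_idx) {
      pre <- 0L
      while (j - pre - 1L >= 1L && blk$kind[j - pre - 1L] == "correct")
        pre <- pre + 1L
      post <- 0L
      while (j + post + 1L <= n && blk$kind[j + post + 1L] == "correct")
        post <- post + 1L
      is_last_error <- !any(err_idx > j)
      ends_block <- (j + post) == n
      reasons <- character(0)
      ok_post <- post >= cfg$min_post ||
        (is_last_error && ends_block && post >= cfg$min_post_if_last)
      if (pre < cfg$min_pre)
        reasons <- c(reasons, "insufficient preceding correct trials")
      if (!ok_post)
        reasons <- c(reasons, "insufficient following correct trials")
      if (!is.na(blk$error_duration_ms[j]) &&
          blk$error_duration_ms[j] <= cfg$min_duration)
        reasons <- c(reasons, "duration at or below minimum")
      if (blk$n_keys[j] > cfg$max_keys)
        reasons <- c(reasons, "too many keys")
      if (length(reasons)) {
        exc[[length(exc) + 1L]] <- data.frame(
          subject = blk$subject[1], block = blk$block[1], trial = blk$trial[j],
          reason = paste(reasons, collapse = "; "), stringsAsFactors = FALSE)
      } else {
        n_post <- min(post, cfg$min_post)
        per[[length(per) + 1L]] <- data.frame(
          subject = blk$subject[1], block = blk$block[1],
          center_trial = blk$trial[j],
          first_trial = blk$trial[j] - cfg$min_pre,
          last_trial = blk$trial[j] + n_post,
          n_trials = cfg$min_pre + 1L + n_post,
          position = within_block_position(blk$first_key[j], k),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_p <- data.frame(subject = character(0), block = integer(0),
                        center_trial = integer(0), first_trial = integer(0),
                        last_trial = integer(0), n_trials = integer(0),
                        position = integer(0), stringsAsFactors = FALSE)
  empty_e <- data.frame(subject = character(0), block = integer(0),
                        trial = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  list(periods = if (length(per)) do.call(rbind, per) else empty_p,
       excluded = if (length(exc)) do.call(rbind, exc) else empty_e)
}

#' Enumerate candidate error-free control periods
#'
#' Every run of at least `width` (default 7) consecutive correct trials
#' yields one candidate window at each admissible alignment; a
#' `width - 1`-trial window is additionally admitted when its last trial is
#' the final trial of the block (the end-of-block rule).  A candidate's
#' position is the within-block position of its 4th trial's first key (the
#' would-be matched sequence).
#'
#' @param trials trials data.frame from [parse_session()].
#' @param k sequence length used for positions (default 5).
#' @param width full window width in trials (default 7).
#' @return data.frame of candidates: `subject`, `block`, `first_trial`,
#'   `last_trial`, `center_trial`, `n_trials`, `position`.
#' @export
enumerate_controls <- function(trials, k = 5L, width = 7L) {
  out <- list()
  center_off <- 3L  # the 4th trial of the window
  for (blk in split_blocks(trials)) {
    n <- nrow(blk)
    r <- rle(blk$kind == "correct")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      rs <- starts[ri]; re <- ends[ri]; L <- re - rs + 1L
      if (L >= width) {
        for (s in rs:(re - width + 1L)) {
          ctr <- s + center_off
          out[[length(out) + 1L]] <- data.frame(
            subject = blk$subject[1], block = blk$block[1],
            first_trial = blk$trial[s], last_trial = blk$trial[s + width - 1L],
            center_trial = blk$trial[ctr], n_trials = width,
            position = within_block_position(blk$first_key[ctr], k),
            stringsAsFactors = FALSE)
        }
      }
      if (L >= width - 1L && re == n) {
        s <- re - (width - 1L) + 1L
        ctr <- s + center_off
        out[[length(out) + 1L]] <- data.frame(
          subject = blk$subject[1], block = blk$block[1],
          first_trial = blk$trial[s], last_trial = blk$trial[re],
          center_trial = blk$trial[ctr], n_trials = width - 1L,
          position = within_block_position(blk$first_key[ctr], k),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(subject = character(0), block = integer(0),
                      first_trial = integer(0), last_trial = integer(0),
                      center_trial = integer(0), n_trials = integer(0),
                      position = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pseudo-randomly match error periods to error-free periods by position
#'
#' For each eligible error (processed per subject in block/trial order) the
#' candidates are all control periods of the same subject at the same
#' within-block position whose center trial is not already used within the
#' set; one is drawn uniformly at random over the lexicographically ordered
#' candidates.  Errors without any available control are excluded with
#' reason.  Identical inputs and seed give identical output.
#'
#' @param errors `periods` data.frame from [select_errors()].
#' @param controls candidates from [enumerate_controls()].
#' @param seed integer RNG seed.
#' @param set_id set label stored with the pairs (default 1).
#' @return An object of class `matched_pairs`: list with `pairs` (one row
#'   per error/control pair, positions pairwise equal), `excluded`
#'   (errors with reasons) and `seed`.
#' @export
match_positions <- function(errors, controls, seed, set_id = 1L) {
  errors <- errors[order(errors$subject, errors$block, errors$center_trial), ,
                   drop = FALSE]
  controls <- controls[order(controls$subject, controls$block,
                             controls$center_trial), , drop = FALSE]
  pairs <- list()
  excluded <- list()
  with_seed(seed, {
    for (sj in unique(errors$subject)) {
      es <- errors[errors$subject == sj, , drop = FALSE]
      cs <- controls[controls$subject == sj, , drop = FALSE]
      used <- character(0)  # control center ids already consumed
      for (i in seq_len(nrow(es))) {
        cid <- paste(cs$block, cs$center_trial)
        ok <- cs$position == es$position[i] & !(cid %in% used)
        idx <- which(ok)
        if (!length(idx)) {
          excluded[[length(excluded) + 1L]] <- data.frame(
            subject = sj, block = es$block[i], trial = es$center_trial[i],
            reason = "no positional match", stringsAsFactors = FALSE)
          next
        }
        pick <- idx[if (length(idx) == 1L) 1L else sample.int(length(idx), 1L)]
        used <- c(used, cid[pick])
        pairs[[length(pairs) + 1L]] <- data.frame(
          subject = sj, position = es$position[i],
          error_block = es$block[i], error_center = es$center_trial[i],
          error_first = es$first_trial[i], error_last = es$last_trial[i],
          error_n_trials = es$n_trials[i],
          control_block = cs$block[pick],
          control_center = cs$center_trial[pick],
          control_first = cs$first_trial[pick],
          control_last = cs$last_trial[pick],
          control_n_trials = cs$n_trials[pick],
          set = as.integer(set_id), stringsAsFactors = FALSE)
      }
    }
  })
  empty_pair <- data.frame(
    subject = character(0), position = integer(0), error_block = integer(0),
    error_center = integer(0), error_first = integer(0),
    error_last = integer(0), error_n_trials = integer(0),
    control_block = integer(0), control_center = integer(0),
    control_first = integer(0), control_last = integer(0),
    control_n_trials = integer(0), set = integer(0), stringsAsFactors = FALSE)
  structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pair,
    excluded = if (length(excluded)) do.call(rbind, excluded)
      else data.frame(subject = character(0), block = integer(0),
                      trial = integer(0), reason = character(0),
                      stringsAsFactors = FALSE),
    seed = seed), class = "matched_pairs")
}

#' Build a second, disjoint position-matched control set
#'
#' Re-runs the matching for the errors of `set1`, excluding every control
#' center trial already used by `set1`.  Errors without a distinct match
#' are dropped from both sets, so the two sets cover the same errors and
#' are disjoint at the control-center-trial level.
#'
#' @param set1 a `matched_pairs` object.
#' @param controls candidates from [enumerate_controls()].
#' @param seed2 integer RNG seed for the second draw.
#' @return list with elements `set1` (pruned) and `set2`, both
#'   `matched_pairs`.
#' @export
second_matched_set <- function(set1, controls, seed2) {
  p1 <- set1$pairs
  if (nrow(p1)) {
    used <- paste(p1$subject, p1$control_block, p1$control_center)
    cid <- paste(controls$subject, controls$block, controls$center_trial)
    controls2 <- controls[!(cid %in% used), , drop = FALSE]
    errors <- data.frame(subject = p1$subject, block = p1$error_block,
                         center_trial = p1$error_center,
                         first_trial = p1$error_first,
                         last_trial = p1$error_last,
                         n_trials = p1$error_n_trials,
                         position = p1$position, stringsAsFactors = FALSE)
  } else {
    controls2 <- controls
    errors <- data.frame(subject = character(0), block = integer(0),
                         center_trial = integer(0), first_trial = integer(0),
                         last_trial = integer(0), n_trials = integer(0),
                         position = integer(0), stringsAsFactors = FALSE)
  }
  set2 <- match_positions(errors, controls2, seed2, set_id = 2L)
  if (nrow(set2$excluded)) {
    drop <- paste(set2$excluded$subject, set2$excluded$block,
                  set2$excluded$trial)
    keep <- !(paste(p1$subject, p1$error_block, p1$error_center) %in% drop)
    set1$pairs <- p1[keep, , drop = FALSE]
  }
  list(set1 = set1, set2 = set2)
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat("matched_pairs: ", nrow(x$pairs), " pair(s), ",
      nrow(x$excluded), " excluded, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
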