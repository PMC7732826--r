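#' Segment one block's keypress stream into trials
#'
#' Greedy earliest-match tiling: scanning left to right, a window of `k`
#' keys equal to the target sequence is emitted as a correct trial and the
#' cursor advances by `k`; otherwise the key joins the current non-trial run
#' and the cursor advances by one.  Maximal non-trial runs flanked by
#' correct trials on both sides become errors; leading/trailing runs are
#' labeled residual (never silently dropped).  The emitted spans partition
#' the block, and an error run can never contain a full sequence match (the
#' greedy scan would have claimed it).
#'
#' @param keys integer vector, the block's key codes in press order.
#' @param seq a [sequence_spec()].
#' @return data.frame with columns `kind` (`correct`/`error`/`residual`),
#'   `first_key`, `last_key` (1-based inclusive within-block key indices)
#'   and `trial` (1-based ordinal).
#' @examples
#' s <- sequence_spec()
#' parse_block(rep(s$codes, 12), s)          # 12 correct trials
#' parse_block(c(4,1,3,2,4, 4,1,2, 4,1,3,2,4), s)
#' @export
parse_block <- function(keys, seq) {
  stopifnot(inherits(seq, "sequence_spec"))
  keys <- as.integer(keys)
  if (!length(keys)) stop("keys must be non-empty")
  codes <- seq$codes
  k <- seq$k
  n <- length(keys)
  kind <- character(0)
  first <- integer(0)
  last <- integer(0)
  run_start <- NA_integer_
  i <- 1L
  while (i <= n) {
    if (i + k - 1L <= n && all(keys[i:(i + k - 1L)] == codes)) {
      if (!is.na(run_start)) {
        kind <- c(kind, "run"); first <- c(first, run_start)
        last <- c(last, i - 1L); run_start <- NA_integer_
      }
      kind <- c(kind, "correct"); first <- c(first, i)
      last <- c(last, i + k - 1L)
      i <- i + k
    } else {
      if (is.na(run_start)) run_start <- i
      i <- i + 1L
    }
  }
  if (!is.na(run_start)) {
    kind <- c(kind, "run"); first <- c(first, run_start); last <- c(last, n)
  }
  # a run is an error only when flanked by correct trials on both sides
  m <- length(kind)
  if (m) {
    is_corr <- kind == "correct"
    before <- c(FALSE, cumsum(is_corr)[-m] > 0)
    after <- rev(c(FALSE, cumsum(rev(is_corr))[-m] > 0))
    kind[kind == "run"] <- ifelse(before[kind == "run"] & after[kind == "run"],
                                  "error", "residual")
  }
  data.frame(kind = kind, first_key = first, last_key = last,
             trial = seq_len(m), stringsAsFactors = FALSE)
}

#' Annotate an error run
#'
#' Classifies an error by its first wrong key.  The longest prefix of the
#' error's keys matching a prefix of the sequence has length `p`; if the
#' whole error is such a prefix, the error is an `incomplete_sequence`
#' (`p <= k - 2` correct keys) or `missing_one_key` (`p = k - 1`), with the
#' first wrong ordinal absent.  Otherwise it is a `wrong_key` error with
#' `first_wrong_ordinal = p + 1`.  Restart attempts count occurrences of the
#' first sequence transition (`codes[1] -> codes[2]`) among consecutive
#' error keys, plus one when the error's last key is `codes[1]` and the
#' following correct trial begins with `codes[2]`.
#'
#' @param error_keys integer vector of the error's key codes.
#' @param seq a [sequence_spec()].
#' @param timestamps onset times (ms) of the error keys, or `NULL`.
#' @param t_prev onset (ms) of the last key of the preceding correct trial.
#' @param t_next onset (ms) of the first key of the following correct trial.
#' @param next_key first key code of the following correct trial (defaults
#'   to `codes[1]`, which the greedy parse guarantees).
#' @param duration_mode `"transition"` (default): duration spans the onset
#'   and offset transitions, `t_next - t_prev`; `"strict"`: time between the
#'   error's own first and last keys.
#' @return list with `error_type`, `first_wrong_ordinal`, `n_before`,
#'   `n_after`, `length_keys`, `duration`, `n_restart_attempts`.
#' @export
annotate_error <- function(error_keys, seq, timestamps = NULL,
                           t_prev = NULL, t_next = NULL,
                           next_key = seq$codes[1],
                           duration_mode = c("transition", "strict")) {
  stopifnot(inherits(seq, "sequence_spec"))
  duration_mode <- match.arg(duration_mode)
  error_keys <- as.integer(error_keys)
  len <- length(error_keys)
  if (!len) stop("error_keys must be non-empty")
  codes <- seq$codes
  k <- seq$k
  m <- min(len, k)
  p <- 0L
  while (p < m && error_keys[p + 1L] == codes[p + 1L]) p <- p + 1L
  if (p == k)
    stop("error run contains a full sequence match; invalid segmentation")
  if (p == len) {
    error_type <- if (p == k - 1L) "missing_one_key" else "incomplete_sequence"
    fwo <- NA_integer_
    n_before <- NA_integer_
    n_after <- NA_integer_
  } else {
    error_type <- "wrong_key"
    fwo <- p + 1L
    n_before <- p
    n_after <- len - p - 1L
  }
  restarts <- 0L
  if (len >= 2L)
    restarts <- sum(error_keys[-len] == codes[1] & error_keys[-1] == codes[2])
  if (error_keys[len] == codes[1] && next_key == codes[2])
    restarts <- restarts + 1L
  duration <- NA_real_
  if (duration_mode == "transition") {
    if (!is.null(t_prev) && !is.null(t_next)) {
      if (!is.null(timestamps) &&
          (t_prev >= timestamps[1] || t_next <= timestamps[len]))
        stop("t_prev/t_next must bracket the error's own timestamps")
      duration <- t_next - t_prev
    }
  } else if (!is.null(timestamps)) {
    duration <- timestamps[len] - timestamps[1]
  }
  list(error_type = error_type, first_wrong_ordinal = fwo,
       n_before = n_before, n_after = n_after, length_keys = len,
       duration = duration, n_restart_attempts = as.integer(restarts))
}

#' Transition durations of one trial
#'
#' Within-trial transitions are successive differences of the trial's key
#' onsets (`k - 1` values for a correct trial); the onset transition leads
#' into the trial's first key from the preceding key, the offset transition
#' leaves its last key into the following key.  Missing flanking keys give
#' `NA`, never zero.
#'
#' @param onsets numeric vector of all key onsets (ms) of the block.
#' @param first_key,last_key 1-based inclusive key span of the trial.
#' @return list with `within` (numeric vector), `onset` and `offset` (ms,
#'   `NA` when absent).
#' @export
transition_times <- function(onsets, first_key, last_key) {
  n <- length(onsets)
  stopifnot(first_key >= 1L, last_key <= n, first_key <= last_key)
  within <- if (last_key > first_key) diff(onsets[first_key:last_key])
            else numeric(0)
  onset <- if (first_key > 1L) onsets[first_key] - onsets[first_key - 1L]
           else NA_real_
  offset <- if (last_key < n) onsets[last_key + 1L] - onsets[last_key]
            else NA_real_
  list(within = within, onset = onset, offset = offset)
}

#' Parse and annotate a whole session
#'
#' Runs [parse_block()] on every (subject, block) keypress stream and
#' annotates each error with [annotate_error()] and its trial times.
#'
#' @param keypresses keypress data.frame (`subject`, `block`, `key`,
#'   `onset_ms`), e.g. from [read_keypress_log()] or [gen_behavior()].
#' @param seq a [sequence_spec()].
#' @param duration_mode passed to [annotate_error()].
#' @return A trials data.frame, one row per trial, with columns `subject`,
#'   `block`, `trial`, `kind`, `first_key`, `last_key`, `n_keys`,
#'   `onset_ms`, `offset_ms`, `error_type`, `first_wrong_ordinal`,
#'   `n_before`, `n_after`, `n_restart_attempts`, `error_duration_ms`.
#' @export
parse_session <- function(keypresses, seq,
                          duration_mode = c("transition", "strict")) {
  duration_mode <- match.arg(duration_mode)
  validate_keypresses(keypresses, seq$alphabet)
  out <- lapply(split_blocks(keypresses), function(kp) {
    kp <- kp[order(kp$onset_ms), , drop = FALSE]
    tr <- parse_block(kp$key, seq)
    n <- nrow(tr)
    tr$subject <- kp$subject[1]
    tr$block <- kp$block[1]
    tr$n_keys <- tr$last_key - tr$first_key + 1L
    tr$onset_ms <- kp$onset_ms[tr$first_key]
    tr$offset_ms <- kp$onset_ms[tr$last_key]
    tr$error_type <- NA_character_
    tr$first_wrong_ordinal <- NA_integer_
    tr$n_before <- NA_integer_
    tr$n_after <- NA_integer_
    tr$n_restart_attempts <- NA_integer_
    tr$error_duration_ms <- NA_real_
    for (i in which(tr$kind == "error")) {
      span <- tr$first_key[i]:tr$last_key[i]
      ann <- annotate_error(
        kp$key[span], seq,
        timestamps = kp$onset_ms[span],
        t_prev = kp$onset_ms[tr$first_key[i] - 1L],
        t_next = kp$onset_ms[tr$last_key[i] + 1L],
        next_key = kp$key[tr$last_key[i] + 1L],
        duration_mode = duration_mode)
      tr$error_type[i] <- ann$error_type
      tr$first_wrong_ordinal[i] <- ann$first_wrong_ordinal
      tr$n_before[i] <- ann$n_before
      tr$n_after[i] <- ann$n_after
      tr$n_restart_attempts[i] <- ann$n_restart_attempts
      tr$error_duration_ms[i] <- if (duration_mode == "transition")
        ann$duration
      else tr$offset_ms[i] - tr$onset_ms[i]
    }
    tr
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("subject", "block", "trial", "kind", "first_key", "last_key",
          "n_keys", "onset_ms", "offset_ms", "error_type",
          "first_wrong_ordinal", "n_before", "n_after",
          "n_restart_attempts", "error_duration_ms")]
}
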