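#' Block reference speed
#'
#' Mean of all within-trial transitions of all correct trials of the block
#' (between-trial transitions excluded).  Absent (`NA`) when the block has
#' no correct trial; downstream slowing values for that block are then
#' absent too.
#'
#' @param trials_block trials data.frame rows of one block.
#' @param onsets key onsets (ms) of that block, in press order.
#' @return mean within-sequence transition duration in ms, or `NA`.
#' @export
block_reference <- function(trials_block, onsets) {
  ci <- which(trials_block$kind == "correct")
  if (!length(ci)) return(NA_real_)
  tt <- unlist(lapply(ci, function(i)
    diff(onsets[trials_block$first_key[i]:trials_block$last_key[i]])))
  mean(tt)
}

#' Magnitude of slowing
#'
#' Relative deviation of a transition duration from the block reference, in
#' percent: `100 * (duration - reference) / reference`.  Zero means
#' block-typical speed; the measure is scale-free (rescaling all of a
#' block's durations by a constant leaves it unchanged).
#'
#' @param duration transition duration(s), ms.
#' @param reference block reference, ms (from [block_reference()]).
#' @return percent slowing; `NA` when the reference is absent.
#' @export
slowing <- function(duration, reference) {
  if (is.null(reference) || length(reference) != 1L || is.na(reference))
    return(rep(NA_real_, length(duration)))
  if (reference <= 0) stop("reference must be positive")
  100 * (duration - reference) / reference
}

# internal: per-block context (onsets vector + reference) for one subject
block_context <- function(trials, keypresses) {
  ctx <- lapply(split_blocks(keypresses), function(kp) {
    kp <- kp[order(kp$onset_ms), , drop = FALSE]
    tb <- trials[trials$subject == kp$subject[1] &
                 trials$block == kp$block[1], , drop = FALSE]
    list(subject = kp$subject[1], block = kp$block[1],
         onsets = kp$onset_ms, trials = tb,
         reference = block_reference(tb, kp$onset_ms))
  })
  names(ctx) <- vapply(ctx, function(b) paste(b$subject, b$block), "")
  ctx
}

# internal: trial-level slowing for one trial row
#  correct trial -> mean slowing of its k-1 within transitions
#  error trial   -> mean slowing over onset, within, and offset transitions
trial_slowing <- function(ctx_block, trial_row) {
  ref <- ctx_block$reference
  if (is.na(ref)) return(NA_real_)
  tt <- transition_times(ctx_block$onsets, trial_row$first_key,
                         trial_row$last_key)
  if (trial_row$kind == "error") {
    d <- c(tt$onset, tt$within, tt$offset)
    d <- d[!is.na(d)]
  } else {
    d <- tt$within
  }
  if (!length(d)) return(NA_real_)
  mean(slowing(d, ref))
}

#' Phase-resolved slowing profile of one error period
#'
#' Decomposes an error into its onset transition (into the first error
#' key), within-error transitions strictly before and strictly after the
#' first wrong key, and the offset transition (from the last error key into
#' the next correct trial).  Phases with no constituent transitions are
#' absent (`NA`), not zero -- e.g. a one-key error has only onset and
#' offset.
#'
#' @param period one row of the `periods` data.frame from [select_errors()].
#' @param trials trials data.frame of the session.
#' @param keypresses keypress data.frame of the session.
#' @return one-row data.frame with `onset`, `within_pre`, `within_post`,
#'   `offset` (percent slowing).
#' @export
error_phase_profile <- function(period, trials, keypresses) {
  kp <- keypresses[keypresses$subject == period$subject &
                   keypresses$block == period$block, , drop = FALSE]
  kp <- kp[order(kp$onset_ms), , drop = FALSE]
  tb <- trials[trials$subject == period$subject &
               trials$block == period$block, , drop = FALSE]
  ref <- block_reference(tb, kp$onset_ms)
  er <- tb[tb$trial == period$center_trial, , drop = FALSE]
  if (nrow(er) != 1L || er$kind != "error")
    stop("period center is not an error trial")
  tt <- transition_times(kp$onset_ms, er$first_key, er$last_key)
  fwo <- er$first_wrong_ordinal
  nw <- length(tt$within)  # transitions among the error's own keys
  if (is.na(fwo)) {
    # incomplete/missing: all error keys precede the (absent) wrong key
    pre_idx <- seq_len(nw)
    post_idx <- integer(0)
  } else {
    # within transition j joins keys j and j+1; it precedes the first
    # wrong key when j + 1 < fwo, follows it when j > fwo
    pre_idx <- which(seq_len(nw) + 1L < fwo)
    post_idx <- which(seq_len(nw) > fwo)
  }
  phase_mean <- function(d) if (length(d) && any(!is.na(d)))
    mean(slowing(d[!is.na(d)], ref)) else NA_real_
  data.frame(
    onset = phase_mean(tt$onset),
    within_pre = phase_mean(tt$within[pre_idx]),
    within_post = phase_mean(tt$within[post_idx]),
    offset = phase_mean(tt$offset))
}

#' Per-subject slowing profiles over matched periods
#'
#' For every matched pair, computes trial-level slowing at the five central
#' roles of the period (PreE2, PreE1, the center, PostE1, PostE2) for both
#' the error period and its position-matched control, plus the error phase
#' decomposition; then averages within subject (errors weighted equally).
#' Subjects with no pairs are dropped with a message.
#'
#' @param pairs a `matched_pairs` object from [match_positions()].
#' @param trials trials data.frame of the session.
#' @param keypresses keypress data.frame of the session.
#' @return list with `trial_profile` (columns `subject`, `condition`
#'   (`error`/`control`), `role` (`PreE2`,`PreE1`,`E`,`PostE1`,`PostE2`),
#'   `slowing`, `n_periods`) and `phase_profile` (columns `subject`,
#'   `phase`, `slowing`).
#' @export
period_profile <- function(pairs, trials, keypresses) {
  p <- pairs$pairs
  if (!nrow(p)) stop("no matched pairs")
  ctx <- block_context(trials, keypresses)
  roles <- c("PreE2", "PreE1", "E", "PostE1", "PostE2")
  offs <- -2:2
  rows <- list()
  ph <- list()
  for (i in seq_len(nrow(p))) {
    for (cond in c("error", "control")) {
      blk <- if (cond == "error") p$error_block[i] else p$control_block[i]
      ctr <- if (cond == "error") p$error_center[i] else p$control_center[i]
      cb <- ctx[[paste(p$subject[i], blk)]]
      for (r in seq_along(roles)) {
        trow <- cb$trials[cb$trials$trial == ctr + offs[r], , drop = FALSE]
        val <- if (nrow(trow) == 1L) trial_slowing(cb, trow) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          subject = p$subject[i], pair = i, condition = cond,
          role = roles[r], slowing = val, stringsAsFactors = FALSE)
      }
    }
    ctr_kind <- trials$kind[trials$subject == p$subject[i] &
                            trials$block == p$error_block[i] &
                            trials$trial == p$error_center[i]]
    if (identical(ctr_kind, "error")) {
      per <- data.frame(subject = p$subject[i], block = p$error_block[i],
                        center_trial = p$error_center[i],
                        stringsAsFactors = FALSE)
      prof <- error_phase_profile(per, trials, keypresses)
      ph[[length(ph) + 1L]] <- cbind(subject = p$subject[i], pair = i, prof,
                                     stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(slowing ~ subject + condition + role, data = long,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  np <- stats::aggregate(pair ~ subject, data = long,
                         FUN = function(x) length(unique(x)))
  names(np)[2] <- "n_periods"
  trial_profile <- merge(agg, np, by = "subject")
  trial_profile$slowing[is.nan(trial_profile$slowing)] <- NA_real_
  trial_profile$role <- factor(trial_profile$role, levels = roles)
  trial_profile <- trial_profile[order(trial_profile$subject,
                                       trial_profile$condition,
                                       trial_profile$role), , drop = FALSE]
  rownames(trial_profile) <- NULL
  if (!length(ph))
    return(list(trial_profile = trial_profile,
                phase_profile = data.frame(subject = character(0),
                                           phase = character(0),
                                           slowing = numeric(0),
                                           stringsAsFactors = FALSE)))
  phw <- do.call(rbind, ph)
  phase_long <- stats::reshape(
    phw, direction = "long",
    varying = c("onset", "within_pre", "within_post", "offset"),
    v.names = "slowing", timevar = "phase",
    times = c("onset", "within_pre", "within_post", "offset"))
  phase_profile <- stats::aggregate(
    slowing ~ subject + phase, data = phase_long, FUN = mean,
    na.rm = TRUE, na.action = NULL)
  phase_profile$slowing[is.nan(phase_profile$slowing)] <- NA_real_
  list(trial_profile = trial_profile, phase_profile = phase_profile)
}

#' Block-initiation slowing
#'
#' Trial-level slowing of the first correct trial of each block, relative
#' to the block reference; used to compare post-error slowing against the
#' cost of (re)initiating the task.  Blocks without a correct trial are
#' absent.
#'
#' @param trials trials data.frame of the session.
#' @param keypresses keypress data.frame of the session.
#' @return data.frame `subject`, `block`, `slowing` (percent).
#' @export
block_initiation_slowing <- function(trials, keypresses) {
  ctx <- block_context(trials, keypresses)
  out <- lapply(ctx, function(cb) {
    first_corr <- which(cb$trials$kind == "correct")[1]
    val <- if (is.na(first_corr)) NA_real_
      else trial_slowing(cb, cb$trials[first_corr, , drop = FALSE])
    data.frame(subject = cb$subject, block = cb$block, slowing = val,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Greenhouse-Geisser epsilon
#'
#' Box's sphericity correction factor estimated from the sample covariance
#' of the conditions: with `V = C' S C` for an orthonormal contrast basis
#' `C`, `epsilon = tr(V)^2 / ((k - 1) * tr(V^2))`.  Equals 1 exactly for
#' two-level designs (always spherical).
#'
#' @param Y numeric matrix, subjects x conditions.
#' @return epsilon in `(1/(k-1), 1]`.
#' @export
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  if (k < 2L) stop("need at least two conditions")
  S <- stats::cov(Y)
  C <- qr.Q(qr(stats::contr.helmert(k)))
  V <- crossprod(C, S %*% C)
  sum(diag(V))^2 / ((k - 1) * sum(V * V))
}

#' Group-level tests
#'
#' Two-stage summary statistics: values are per-subject summaries
#' (aggregated within subject first), tested across subjects.  Provides a
#' two-tailed one-sample t test against `mu`, a paired t test, and a
#' one-way repeated-measures ANOVA with Greenhouse-Geisser-corrected
#' degrees of freedom.  Zero-variance inputs give an absent p with a
#' diagnostic.
#'
#' @param values numeric vector (one-sample), or matrix subjects x
#'   conditions (paired with 2 columns, repeated-measures otherwise).
#' @param type `"one_sample"`, `"paired"` or `"rm_anova"`.
#' @param mu null value for the one-sample test (default 0).
#' @return one-row data.frame (`GroupStat`): `test`, `statistic`, `df1`,
#'   `df2`, `p`, `epsilon`, `correction`, `direction`, `note`.
#' @export
group_tests <- function(values, type = c("one_sample", "paired", "rm_anova"),
                        mu = 0) {
  type <- match.arg(type)
  stat_row <- function(test, statistic, df1, df2 = NA_real_, p = NA_real_,
                       epsilon = NA_real_, correction = "none",
                       direction = NA_character_, note = NA_character_)
    data.frame(test = test, statistic = statistic, df1 = df1, df2 = df2,
               p = p, epsilon = epsilon, correction = correction,
               direction = direction, note = note, stringsAsFactors = FALSE)
  if (type == "one_sample") {
    x <- values[!is.na(values)]
    n <- length(x)
    if (n < 2L) stop("need at least 2 subjects")
    if (stats::sd(x) == 0) {
      tval <- if (mean(x) == mu) 0 else Inf * sign(mean(x) - mu)
      return(stat_row("one_sample_t", tval, n - 1,
                      p = if (tval == 0) 1 else NA_real_,
                      direction = c("-", "0", "+")[sign(mean(x) - mu) + 2],
                      note = "zero variance"))
    }
    tt <- stats::t.test(x, mu = mu)
    return(stat_row("one_sample_t", unname(tt$statistic),
                    unname(tt$parameter), p = tt$p.value,
                    direction = c("-", "0", "+")[sign(mean(x) - mu) + 2]))
  }
  if (type == "paired") {
    stopifnot(is.matrix(values) || is.data.frame(values))
    values <- as.matrix(values)
    if (ncol(values) != 2L) stop("paired test needs exactly 2 columns")
    d <- values[, 1] - values[, 2]
    res <- group_tests(d, "one_sample", mu = 0)
    res$test <- "paired_t"
    return(res)
  }
  Y <- as.matrix(values)
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L) stop("need at least 2 subjects")
  subj <- rowMeans(Y); cond <- colMeans(Y); grand <- mean(Y)
  ss_cond <- n * sum((cond - grand)^2)
  resid <- Y - outer(subj, rep(1, k)) - outer(rep(1, n), cond) + grand
  ss_err <- sum(resid^2)
  if (ss_err == 0)
    return(stat_row("rm_anova_F", NA_real_, k - 1, (k - 1) * (n - 1),
                    note = "zero error variance"))
  Fv <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  eps <- gg_epsilon(Y)
  df1 <- eps * (k - 1); df2 <- eps * (k - 1) * (n - 1)
  stat_row("rm_anova_F", Fv, df1, df2,
           p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
           epsilon = eps, correction = "Greenhouse-Geisser")
}
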