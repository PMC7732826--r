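#' Behavior generator specification
#'
#' Emulates continuous self-paced sequence tapping: blocks end after exactly
#' `keys_per_block` presses, inter-press intervals are log-normal
#' (positivity and right skew) with a mean-parameterized scale, per-block
#' speed multipliers model drift across blocks, and scheduled errors are
#' inserted with their type's key pattern and phase-specific slowing
#' multipliers around them.
#'
#' @param n_subjects number of subjects (default 20).
#' @param seq a [sequence_spec()].
#' @param layout a [block_layout()] (default: 14 blocks x 60 keys, 15-s
#'   rests).
#' @param base_mean mean inter-press interval, ms (default 250).
#' @param base_cv coefficient of variation of intervals (default 0.25).
#' @param block_multipliers per-block speed multipliers; default a mild
#'   practice speed-up from 1.08 to 0.94 across blocks.
#' @param error_rate per-trial error probability when no explicit schedule
#'   is given (default 0.03).
#' @param error_schedule optional data.frame `subject`, `block`, `trial`,
#'   `type` (`wrong_key`/`incomplete_sequence`/`missing_one_key`),
#'   `ordinal` (first wrong ordinal for `wrong_key`, correct-prefix length
#'   for `incomplete_sequence`).
#' @param type_mix named weights over error types; `missing_one_key`
#'   defaults to zero weight because with a sequence whose last code equals
#'   its first the greedy segmentation re-tiles that pattern as a correct
#'   trial.
#' @param phase_multipliers named list of slowing multipliers: `pre`
#'   (within PreE1), `onset` (into the first error key), `within` (among
#'   error keys), `offset` (out of the last error key), `post1` (within
#'   PostE1), `initiation` (within the block's first trial).  All > 0.
#' @param min_gap minimum spacing between scheduled error trials (default
#'   4, keeping errors mutually isolated; must be >= 2 for unambiguous
#'   ground truth).
#' @param seed default RNG seed.
#' @return An object of class `behavior_gen_spec`.
#' @export
behavior_gen_spec <- function(n_subjects = 20L, seq = sequence_spec(),
                              layout = block_layout(),
                              base_mean = 250, base_cv = 0.25,
                              block_multipliers = NULL,
                              error_rate = 0.03, error_schedule = NULL,
                              type_mix = c(wrong_key = 0.75,
                                           incomplete_sequence = 0.25,
                                           missing_one_key = 0),
                              phase_multipliers = list(
                                pre = 1.0, onset = 1.35, within = 1.5,
                                offset = 2.0, post1 = 1.06,
                                initiation = 1.3),
                              min_gap = 4L, seed = 1L) {
  if (is.null(block_multipliers))
    block_multipliers <- seq(1.08, 0.94, length.out = layout$n_blocks)
  stopifnot(length(block_multipliers) == layout$n_blocks,
            all(block_multipliers > 0),
            all(unlist(phase_multipliers) > 0),
            error_rate >= 0, error_rate <= 1, base_mean > 0, base_cv > 0,
            min_gap >= 2L)
  if (seq$codes[seq$k] == seq$codes[1] &&
      isTRUE(type_mix[["missing_one_key"]] > 0))
    stop("missing_one_key errors cannot be generated when the sequence's ",
         "last code equals its first: the greedy parse re-tiles them")
  if (!is.null(error_schedule)) {
    need <- c("subject", "block", "trial", "type")
    if (!all(need %in% names(error_schedule)))
      stop("error_schedule needs columns ", paste(need, collapse = ", "))
    es <- error_schedule[order(error_schedule$subject, error_schedule$block,
                               error_schedule$trial), , drop = FALSE]
    for (blk in split_blocks(es)) {
      if (any(blk$trial < 2L))
        stop("scheduled errors must be at trial >= 2 (block-initial runs ",
             "are residual, not errors)")
      if (nrow(blk) > 1L && any(diff(blk$trial) < min_gap))
        stop("scheduled errors violate the isolation gap in subject ",
             blk$subject[1], " block ", blk$block[1], " at trials ",
             paste(blk$trial[c(which(diff(blk$trial) < min_gap),
                               which(diff(blk$trial) < min_gap) + 1L)],
                   collapse = ", "))
    }
    if (seq$codes[seq$k] == seq$codes[1] &&
        any(es$type == "missing_one_key"))
      stop("missing_one_key errors cannot be generated for this sequence")
  }
  structure(list(n_subjects = as.integer(n_subjects), seq = seq,
                 layout = layout, base_mean = base_mean, base_cv = base_cv,
                 block_multipliers = block_multipliers,
                 error_rate = error_rate, error_schedule = error_schedule,
                 type_mix = type_mix, phase_multipliers = phase_multipliers,
                 min_gap = as.integer(min_gap), seed = as.integer(seed)),
            class = "behavior_gen_spec")
}

# draw the key pattern of one planned error
error_keys_for <- function(type, ordinal, seq) {
  codes <- seq$codes; k <- seq$k
  if (type == "wrong_key") {
    d <- ordinal
    wrong <- sample(setdiff(seq$alphabet, codes[d]), 1L)
    extra <- sample(0:2, 1L, prob = c(0.6, 0.3, 0.1))
    c(codes[seq_len(d - 1L)], rep(wrong, 1L + extra))
  } else if (type == "incomplete_sequence") {
    codes[seq_len(ordinal)]
  } else if (type == "missing_one_key") {
    codes[seq_len(k - 1L)]
  } else stop("unknown error type: ", type)
}

#' Generate a synthetic keypress session with ground truth
#'
#' Deterministic given the seed.  Scheduled errors are inserted with key
#' patterns that the greedy segmentation provably recovers (wrong-key
#' errors end in repeats of the wrong key; incomplete sequences are bare
#' correct prefixes), so the returned truth labels are exact.
#'
#' @param spec a [behavior_gen_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @return An object of class `behavior_sim`: list with `keypresses`
#'   (data.frame `subject`, `block`, `key`, `onset_ms`), `blocks`
#'   (data.frame `subject`, `block`, `onset_s`, `duration_s`, GO-locked)
#'   and `truth` (list: `trials` ground-truth labels, `spec`, `seed`).
#' @export
gen_behavior <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "behavior_gen_spec"))
  sq <- spec$seq; lay <- spec$layout
  k <- sq$k
  tpb <- lay$keys_per_block %/% k
  sdlog <- sqrt(log(1 + spec$base_cv^2))
  meanlog0 <- log(spec$base_mean) - sdlog^2 / 2
  pm <- spec$phase_multipliers
  subjects <- sprintf("sub%02d", seq_len(spec$n_subjects))
  kp_rows <- list(); tr_rows <- list(); blk_rows <- list()
  with_seed(seed, {
    for (sj in subjects) {
      t_now <- lay$rest_duration * 1000  # first GO after an initial rest
      for (b in seq_len(lay$n_blocks)) {
        # --- plan trials -------------------------------------------------
        if (!is.null(spec$error_schedule)) {
          es <- spec$error_schedule
          es <- es[es$subject == sj & es$block == b, , drop = FALSE]
          err_slots <- es$trial
          err_types <- es$type
          err_ord <- if ("ordinal" %in% names(es)) es$ordinal
                     else rep(NA_integer_, nrow(es))
        } else {
          cand <- which(stats::runif(tpb) < spec$error_rate)
          cand <- cand[cand >= 2L & cand <= tpb - 1L]
          err_slots <- integer(0)
          for (s in cand)
            if (!length(err_slots) || s - err_slots[length(err_slots)] >=
                spec$min_gap) err_slots <- c(err_slots, s)
          w <- spec$type_mix[spec$type_mix > 0]
          err_types <- if (length(err_slots))
            sample(names(w), length(err_slots), replace = TRUE,
                   prob = w) else character(0)
          err_ord <- rep(NA_integer_, length(err_slots))
        }
        plans <- list()
        s <- 1L; nk <- 0L
        while (nk < lay$keys_per_block) {
          if (s %in% err_slots) {
            i <- match(s, err_slots)
            ord <- err_ord[i]
            if (is.na(ord))
              ord <- if (err_types[i] == "wrong_key") sample.int(k, 1L)
                     else sample.int(k - 2L, 1L)
            keys <- error_keys_for(err_types[i], ord, sq)
            plans[[s]] <- list(kind = "error", keys = keys,
                               type = err_types[i], ordinal = ord)
          } else {
            plans[[s]] <- list(kind = "correct", keys = sq$codes,
                               type = NA_character_, ordinal = NA_integer_)
          }
          nk <- nk + length(plans[[s]]$keys)
          s <- s + 1L
        }
        # --- flatten to exactly keys_per_block keys, derive truth --------
        all_keys <- unlist(lapply(plans, `[[`, "keys"))
        all_keys <- all_keys[seq_len(lay$keys_per_block)]
        ends <- cumsum(vapply(plans, function(p) length(p$keys), 0L))
        starts <- c(1L, utils::head(ends, -1) + 1L)
        complete <- ends <= lay$keys_per_block
        kinds <- vapply(plans, `[[`, "", "kind")
        last_corr <- max(c(0L, which(complete & kinds == "correct")))
        tr <- list(); ord <- 0L
        for (pi in seq_along(plans)) {
          if (pi <= last_corr) {
            ord <- ord + 1L
            p <- plans[[pi]]
            tr[[ord]] <- data.frame(
              subject = sj, block = b, trial = ord, kind = p$kind,
              error_type = if (p$kind == "error") p$type else NA_character_,
              first_wrong_ordinal = if (p$kind == "error" &&
                                        p$type == "wrong_key") p$ordinal
                                    else NA_integer_,
              first_key = starts[pi], last_key = ends[pi],
              stringsAsFactors = FALSE)
          }
        }
        if (last_corr == 0L || ends[last_corr] < lay$keys_per_block) {
          ord <- ord + 1L
          fk <- if (last_corr == 0L) 1L else ends[last_corr] + 1L
          tr[[ord]] <- data.frame(
            subject = sj, block = b, trial = ord, kind = "residual",
            error_type = NA_character_, first_wrong_ordinal = NA_integer_,
            first_key = fk, last_key = lay$keys_per_block,
            stringsAsFactors = FALSE)
        }
        truth_b <- do.call(rbind, tr)
        # --- phase multiplier per key ------------------------------------
        key_plan <- rep(seq_along(plans),
                        vapply(plans, function(p) length(p$keys), 0L))
        key_plan <- key_plan[seq_len(lay$keys_per_block)]
        is_first_of_plan <- c(TRUE, diff(key_plan) != 0)
        mult <- rep(1, lay$keys_per_block)
        err_plans <- which(kinds == "error")
        for (i in seq_len(lay$keys_per_block)) {
          pi <- key_plan[i]
          first <- is_first_of_plan[i]
          if (kinds[pi] == "error") {
            mult[i] <- if (first) pm$onset else pm$within
          } else if ((pi - 1L) %in% err_plans) {
            mult[i] <- if (first) pm$offset else pm$post1
          } else if ((pi + 1L) %in% err_plans && !first) {
            mult[i] <- pm$pre
          } else if (pi == 1L && !first) {
            mult[i] <- pm$initiation
          }
        }
        mult[1] <- pm$initiation  # GO-to-first-key interval
        # --- draw intervals and onsets -----------------------------------
        iv <- stats::rlnorm(lay$keys_per_block, meanlog0, sdlog) *
          spec$block_multipliers[b] * mult
        onsets <- t_now + cumsum(iv)
        kp_rows[[length(kp_rows) + 1L]] <- data.frame(
          subject = sj, block = b, key = all_keys, onset_ms = onsets,
          stringsAsFactors = FALSE)
        blk_rows[[length(blk_rows) + 1L]] <- data.frame(
          subject = sj, block = b, onset_s = t_now / 1000,
          duration_s = (onsets[length(onsets)] - t_now) / 1000,
          stringsAsFactors = FALSE)
        tr_rows[[length(tr_rows) + 1L]] <- truth_b
        t_now <- onsets[length(onsets)] + lay$rest_duration * 1000
      }
    }
  })
  structure(list(
    keypresses = do.call(rbind, kp_rows),
    blocks = do.call(rbind, blk_rows),
    truth = list(trials = do.call(rbind, tr_rows), spec = spec, seed = seed)),
    class = "behavior_sim")
}

#' BOLD generator specification
#'
#' @param TR repetition time (s, default 2.65).
#' @param n_scans number of volumes; derived from the session extent plus
#'   the HRF support when `NULL`.
#' @param betas named true amplitudes: `block` (sustained), `go`
#'   (transient), plus one entry per event regressor name.
#' @param series_profile numeric vector, one spatial scaling per series
#'   (all true amplitudes of series s are multiplied by
#'   `series_profile[s]`).
#' @param phi AR(1) noise coefficient, `|phi| < 1` (default 0.3).
#' @param sd marginal noise standard deviation (default 1).
#' @param drift_amplitude sinusoidal low-frequency drift amplitude
#'   (default 1).
#' @param drift_period drift period in seconds (default 300, below the
#'   high-pass band edge).
#' @param hrf an [hrf_spec()].
#' @param seed default RNG seed.
#' @return An object of class `bold_gen_spec`.
#' @export
bold_gen_spec <- function(TR = 2.65, n_scans = NULL,
                          betas = c(block = 1, go = 0.5),
                          series_profile = 1, phi = 0.3, sd = 1,
                          drift_amplitude = 1, drift_period = 300,
                          hrf = hrf_spec(), seed = 1L) {
  stopifnot(abs(phi) < 1, sd >= 0, TR > 0, drift_period > 0)
  structure(list(TR = TR, n_scans = n_scans, betas = betas,
                 series_profile = series_profile, phi = phi, sd = sd,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period, hrf = hrf,
                 seed = as.integer(seed)),
            class = "bold_gen_spec")
}

#' Generate synthetic BOLD series with ground truth
#'
#' The noiseless signal is synthesized in continuous time from the
#' closed-form HRF (sticks as shifted kernels, epochs via the kernel's
#' analytic integral), so the generator shares no discretization basis
#' with the analysis-side microtime convolution; low-frequency drift is a
#' sinusoid with a random phase per series (deliberately not the DCT used
#' by the fitter), and noise is AR(1) with the stated marginal SD.
#' Deterministic given the seed.
#'
#' @param events data.frame `onset`, `duration` (s), `regressor`; every
#'   regressor name should have an amplitude in `spec$betas` (absent names
#'   get amplitude 0).
#' @param blocks data.frame `onset`, `duration` (s).
#' @param spec a [bold_gen_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @return An object of class `bold_sim`: list with `Y` (scans x series),
#'   `acq` (an [acquisition_spec()]) and `truth` (list: `betas` matrix
#'   regressors x series, `phi`, `sd`, `spec`, `seed`).
#' @export
gen_bold <- function(events, blocks, spec = bold_gen_spec(),
                     seed = spec$seed) {
  stopifnot(inherits(spec, "bold_gen_spec"))
  TR <- spec$TR
  extent <- max(c(blocks$onset + blocks$duration,
                  if (nrow(events)) events$onset + pmax(events$duration, 0)))
  n <- spec$n_scans %||% as.integer(ceiling((extent + spec$hrf$length) / TR))
  if (nrow(events) && any(events$onset > (n - 1) * TR))
    stop("event(s) beyond the last scan")
  t <- (seq_len(n) - 1) * TR
  S <- length(spec$series_profile)
  regs <- unique(c("block", "go",
                   if (nrow(events)) unique(events$regressor)))
  amp <- stats::setNames(numeric(length(regs)), regs)
  common_amp <- spec$betas[intersect(names(spec$betas), regs)]
  amp[names(common_amp)] <- common_amp
  comp <- matrix(0, n, length(regs), dimnames = list(NULL, regs))
  for (i in seq_len(nrow(blocks))) {
    comp[, "block"] <- comp[, "block"] +
      hrf_integral(t - blocks$onset[i], spec$hrf) -
      hrf_integral(t - blocks$onset[i] - blocks$duration[i], spec$hrf)
    comp[, "go"] <- comp[, "go"] + hrf_value(t - blocks$onset[i], spec$hrf)
  }
  for (i in seq_len(nrow(events))) {
    rg <- events$regressor[i]
    comp[, rg] <- comp[, rg] +
      if (events$duration[i] <= 0) hrf_value(t - events$onset[i], spec$hrf)
      else hrf_integral(t - events$onset[i], spec$hrf) -
        hrf_integral(t - events$onset[i] - events$duration[i], spec$hrf)
  }
  signal <- drop(comp %*% amp)
  Y <- matrix(0, n, S)
  with_seed(seed, {
    for (s in seq_len(S)) {
      noise <- if (spec$sd > 0) {
        z <- stats::rnorm(n + 50L)
        e <- as.numeric(stats::filter(z, spec$phi, method = "recursive"))
        e[-seq_len(50L)] * spec$sd * sqrt(1 - spec$phi^2)
      } else numeric(n)
      drift <- spec$drift_amplitude *
        sin(2 * pi * t / spec$drift_period + stats::runif(1, 0, 2 * pi))
      Y[, s] <- spec$series_profile[s] * signal + drift + noise
    }
  })
  truth_beta <- outer(amp, spec$series_profile)
  structure(list(
    Y = Y,
    acq = acquisition_spec(TR = TR, n_scans = n),
    truth = list(betas = truth_beta, phi = spec$phi, sd = spec$sd,
                 spec = spec, seed = seed)),
    class = "bold_sim")
}

#' Bundled deterministic fixtures
#'
#' Small generated datasets used by the test suite and documentation:
#' `"tiny-session"` (1 subject, 2 short blocks), `"one-error-block"` (one
#' 60-key block with a single eligible error at position 6) and
#' `"study-layout"` (the study layout: 14 blocks x 60 keypresses per
#' subject, TR 2.65 s).
#'
#' @param name fixture name.
#' @return list with `keypresses`, `blocks`, `truth`, `seq`, `layout`,
#'   `acq`.
#' @export
make_fixture <- function(name) {
  registry <- c("tiny-session", "one-error-block", "study-layout")
  if (!name %in% registry)
    stop("unknown fixture '", name, "'; available: ",
         paste(registry, collapse = ", "))
  sq <- sequence_spec()
  if (name == "tiny-session") {
    spec <- behavior_gen_spec(n_subjects = 1L, seq = sq,
                              layout = block_layout(2L, 20L),
                              error_rate = 0.1, seed = 101L)
  } else if (name == "one-error-block") {
    sched <- data.frame(subject = "sub01", block = 1L, trial = 6L,
                        type = "wrong_key", ordinal = 3L,
                        stringsAsFactors = FALSE)
    spec <- behavior_gen_spec(n_subjects = 1L, seq = sq,
                              layout = block_layout(1L, 60L),
                              error_schedule = sched, seed = 202L)
  } else {
    spec <- behavior_gen_spec(n_subjects = 2L, seq = sq,
                              layout = block_layout(14L, 60L), seed = 303L)
  }
  sim <- gen_behavior(spec)
  list(name = name, keypresses = sim$keypresses, blocks = sim$blocks,
       truth = sim$truth, seq = sq, layout = spec$layout,
       acq = acquisition_spec(TR = 2.65))
}
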