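#' Discrete cosine high-pass basis
#'
#' DCT regressors spanning frequencies below `1 / cutoff` Hz, excluding the
#' constant; modeling drift as nuisance regressors is the projection
#' equivalent of pre-filtering and keeps degree-of-freedom bookkeeping
#' explicit.
#'
#' @param n_scans number of scans.
#' @param TR repetition time (s).
#' @param cutoff high-pass cutoff (s).
#' @return matrix `n_scans` x `K-1` (possibly 0 columns).
#' @export
dct_basis <- function(n_scans, TR, cutoff) {
  K <- floor(2 * n_scans * TR / cutoff + 1)
  if (K < 2) return(matrix(0, n_scans, 0))
  t <- 0:(n_scans - 1)
  X <- vapply(seq_len(K - 1), function(r)
    cos(pi * (2 * t + 1) * r / (2 * n_scans)), numeric(n_scans))
  colnames(X) <- paste0("dct", seq_len(K - 1))
  X
}

#' Build the mixed block/event-related design matrix
#'
#' Event regressors are built at microtime resolution (`TR /
#' microtime_bins`), convolved with the canonical HRF and sampled at scan
#' onsets.  Zero-duration events (sticks) are unit impulses, so their
#' convolved column is a superposition of shifted kernels; positive
#' durations are boxcars scaled by the microtime step, approximating the
#' continuous convolution integral (a zero-duration boxcar degenerates to
#' the stick column).  A sustained boxcar spans each performance block, a
#' GO stick marks each block onset, and DCT high-pass columns, unconvolved
#' motion parameters and an intercept are appended as nuisance.
#'
#' @param events data.frame with `onset` (s), `duration` (s), `regressor`
#'   (name); may have zero rows.
#' @param blocks data.frame with `onset`, `duration` (s) per block.
#' @param acq an [acquisition_spec()] with `n_scans` set.
#' @param motion optional matrix `n_scans` x m of motion parameters.
#' @param hrf an [hrf_spec()].
#' @param include_go add the GO-cue stick regressor (default TRUE).
#' @return An object of class `design_matrix`: list with `X` (scans x
#'   columns), `interest` and `nuisance` column names, and `acq`.
#' @export
build_design <- function(events, blocks, acq, motion = NULL,
                         hrf = hrf_spec(), include_go = TRUE) {
  stopifnot(inherits(acq, "acquisition_spec"))
  n <- acq$n_scans
  if (is.null(n)) stop("acq$n_scans must be set")
  TR <- acq$TR
  bins <- acq$microtime_bins
  dt <- TR / bins
  t_max <- (n - 1) * TR
  if (nrow(events)) {
    late <- events$onset > t_max | events$onset < 0
    if (any(late))
      stop("event(s) outside the scanned interval: onset(s) ",
           paste(round(events$onset[late], 3), collapse = ", "))
  }
  n_mt <- n * bins
  kern <- canonical_hrf(hrf, dt)
  conv_mt <- function(u) {
    y <- stats::convolve(u, rev(kern), type = "open")
    y[seq_len(n_mt)]
  }
  scan_idx <- (seq_len(n) - 1L) * bins + 1L
  put <- function(onsets, durations) {
    u <- numeric(n_mt)
    for (i in seq_along(onsets)) {
      if (durations[i] <= 0) {
        # stick: unit impulse at the nearest microtime bin
        a <- min(round(onsets[i] / dt) + 1L, n_mt)
        u[a] <- u[a] + 1
      } else {
        # boxcar: per-bin overlap with [onset, onset + duration]; the
        # half-bin shift makes the discrete convolution a midpoint rule
        # for the continuous integral (left-Riemann bias would otherwise
        # leak into edge-locked regressors such as the GO stick)
        o1 <- onsets[i] + dt / 2; o2 <- onsets[i] + durations[i] + dt / 2
        a <- max(floor(o1 / dt) + 1L, 1L)
        b <- min(ceiling(o2 / dt), n_mt)
        if (b >= a) {
          lo <- (a:b - 1L) * dt
          hi <- (a:b) * dt
          u[a:b] <- u[a:b] + pmax(0, pmin(hi, o2) - pmax(lo, o1))
        }
      }
    }
    conv_mt(u)[scan_idx]
  }
  cols <- list()
  interest <- character(0)
  if (nrow(events)) {
    for (rg in unique(events$regressor)) {
      e <- events[events$regressor == rg, , drop = FALSE]
      cols[[rg]] <- put(e$onset, e$duration)
      interest <- c(interest, rg)
    }
  }
  cols[["block"]] <- put(blocks$onset, blocks$duration)
  interest <- c(interest, "block")
  if (include_go) {
    cols[["go"]] <- put(blocks$onset, rep(0, nrow(blocks)))
    interest <- c(interest, "go")
  }
  nuisance <- character(0)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n) stop("motion parameters must have n_scans rows")
    if (is.null(colnames(motion)))
      colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    for (j in seq_len(ncol(motion))) cols[[colnames(motion)[j]]] <- motion[, j]
    nuisance <- c(nuisance, colnames(motion))
  }
  D <- dct_basis(n, TR, acq$highpass_cutoff)
  for (j in seq_len(ncol(D))) cols[[colnames(D)[j]]] <- D[, j]
  nuisance <- c(nuisance, colnames(D))
  cols[["intercept"]] <- rep(1, n)
  nuisance <- c(nuisance, "intercept")
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(X = X, interest = interest, nuisance = nuisance, acq = acq),
            class = "design_matrix")
}

#' Generate the separate-model suite for a subject
#'
#' To preserve variance otherwise shared between closely spaced trials,
#' adjacent trials are estimated in separate models: one model per trial
#' ordinal of errorless blocks (12 under the study layout), plus one model
#' per role around matched errors (`PreE2`, `PreE1`, `E`, `PostE1`,
#' `PostE2`).  Each role model carries the role's event regressor
#' (`"error"`) and the positionally corresponding matched-control regressor
#' (`"control"`); in `matched_mode = "per_pair"` each pair contributes its
#' own regressor pair (`error_1`/`control_1`, ...), giving a beta series.
#'
#' @param trials single-subject trials data.frame from [parse_session()].
#' @param pairs a `matched_pairs` object for that subject.
#' @param seq a [sequence_spec()].
#' @param layout a [block_layout()].
#' @param onset_policy `"trial_onset"` (default) or `"first_wrong_key"`
#'   (error onsets shifted to the first wrong key; falls back to the trial
#'   onset for errors without one).
#' @param duration_policy `"stick"` (zero duration, default) or
#'   `"actual_duration"` (the trial's own key span).
#' @param matched_mode `"pooled"` (default) or `"per_pair"`.
#' @return list of model specifications, each a list with `model_id`,
#'   `kind` (`"ordinal"`/`"role"`), `ordinal` or `role`, and `events`
#'   (data.frame `onset`, `duration`, `regressor`, seconds).
#' @export
generate_model_suite <- function(trials, pairs, seq, layout,
                                 onset_policy = c("trial_onset",
                                                  "first_wrong_key"),
                                 duration_policy = c("stick",
                                                     "actual_duration"),
                                 matched_mode = c("pooled", "per_pair")) {
  onset_policy <- match.arg(onset_policy)
  duration_policy <- match.arg(duration_policy)
  matched_mode <- match.arg(matched_mode)
  if (length(unique(trials$subject)) > 1L)
    stop("generate_model_suite expects a single subject's trials")
  tpb <- layout$keys_per_block %/% seq$k
  dur <- function(tr) if (duration_policy == "stick") rep(0, nrow(tr))
    else (tr$offset_ms - tr$onset_ms) / 1000
  models <- list()
  # errorless-block trial-ordinal models
  blk_split <- split(trials, trials$block)
  errorless <- names(blk_split)[vapply(blk_split, function(b)
    all(b$kind == "correct"), logical(1))]
  for (j in seq_len(tpb)) {
    ev <- do.call(rbind, lapply(blk_split[errorless], function(b) {
      corr <- b[b$kind == "correct", , drop = FALSE]
      if (nrow(corr) >= j) corr[j, , drop = FALSE] else NULL
    }))
    events <- if (is.null(ev) || !nrow(ev))
      data.frame(onset = numeric(0), duration = numeric(0),
                 regressor = character(0), stringsAsFactors = FALSE)
    else data.frame(onset = ev$onset_ms / 1000, duration = dur(ev),
                    regressor = "sequence", stringsAsFactors = FALSE)
    models[[length(models) + 1L]] <- list(
      model_id = sprintf("trial%02d", j), kind = "ordinal", ordinal = j,
      events = events)
  }
  # error-role models
  p <- pairs$pairs
  p <- p[p$subject == trials$subject[1], , drop = FALSE]
  roles <- c("PreE2", "PreE1", "E", "PostE1", "PostE2")
  offs <- -2:2
  trial_row <- function(blk, tr)
    trials[trials$block == blk & trials$trial == tr, , drop = FALSE]
  for (r in seq_along(roles)) {
    ev <- list()
    for (i in seq_len(nrow(p))) {
      te <- trial_row(p$error_block[i], p$error_center[i] + offs[r])
      tc <- trial_row(p$control_block[i], p$control_center[i] + offs[r])
      if (nrow(te) != 1L || nrow(tc) != 1L) next
      tag <- if (matched_mode == "per_pair") paste0("_", i) else ""
      ev[[length(ev) + 1L]] <- data.frame(
        onset = c(te$onset_ms, tc$onset_ms) / 1000,
        duration = c(dur(te), dur(tc)),
        regressor = paste0(c("error", "control"), tag),
        onset_key = c(te$first_key + ifelse(
          roles[r] == "E" & !is.na(te$first_wrong_ordinal),
          te$first_wrong_ordinal - 1L, 0L), tc$first_key),
        block = c(te$block, tc$block),
        stringsAsFactors = FALSE)
    }
    events <- if (length(ev)) do.call(rbind, ev)
      else data.frame(onset = numeric(0), duration = numeric(0),
                      regressor = character(0), onset_key = integer(0),
                      block = integer(0), stringsAsFactors = FALSE)
    models[[length(models) + 1L]] <- list(
      model_id = paste0("role", roles[r]), kind = "role", role = roles[r],
      events = events, onset_policy = onset_policy,
      duration_policy = duration_policy, matched_mode = matched_mode)
  }
  models
}

# apply the first-wrong-key onset policy to a role model's events using the
# subject's keypress onsets (ms); returns events with updated onsets
apply_onset_policy <- function(model, keypresses) {
  ev <- model$events
  if (is.null(model$onset_policy) ||
      model$onset_policy != "first_wrong_key" || !nrow(ev))
    return(ev)
  for (i in seq_len(nrow(ev))) {
    kp <- keypresses[keypresses$block == ev$block[i], , drop = FALSE]
    kp <- kp[order(kp$onset_ms), , drop = FALSE]
    ev$onset[i] <- kp$onset_ms[ev$onset_key[i]] / 1000
  }
  ev
}
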