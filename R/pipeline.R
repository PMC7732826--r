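#' Run the full analysis pipeline
#'
#' Orchestrates parse -> select/match -> behavior-stats -> (optionally)
#' first-level GLM and group statistics, writing every stage's table to
#' `outdir` with provenance metadata (seed, config hash, package version).
#' Idempotent for a fixed config and seed: re-running produces identical
#' numeric tables.
#'
#' @param config list or YAML file path.  Recognized entries:
#'   `keypress_log` (TSV path) or `simulate` (a list of
#'   [behavior_gen_spec()] arguments), `sequence` (list: `codes`,
#'   `alphabet`), `layout` (list for [block_layout()]), `selection` (list
#'   for [selection_config()]), `acquisition` (list for
#'   [acquisition_spec()]), `glm` (list: `enable`, `onset_policy`,
#'   `duration_policy`, `matched_mode`, plus optional [bold_gen_spec()]
#'   arguments under `simulate`), `rng_seed`, `outdir`.
#' @param outdir output directory (overrides `config$outdir`).
#' @param seed session seed (overrides `config$rng_seed`); fans out to
#'   per-stage seeds via [stage_seed()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(seed %||% config$rng_seed %||% 1L)
  outdir <- outdir %||% config$outdir %||% stop("outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sq <- do.call(sequence_spec, config$sequence %||% list())
  lay <- do.call(block_layout, config$layout %||% list())
  sel <- do.call(selection_config, config$selection %||% list())
  acq_args <- config$acquisition %||% list()

  # --- stage: input -------------------------------------------------------
  if (!is.null(config$keypress_log)) {
    kp <- read_keypress_log(config$keypress_log, sq$alphabet)
    blocks <- blocks_from_keypresses(kp)
    truth <- NULL
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seq <- sq
    sim_args$layout <- lay
    sim_args$seed <- stage_seed(seed, "simulate-behavior")
    bspec <- do.call(behavior_gen_spec, sim_args)
    sim <- gen_behavior(bspec)
    kp <- sim$keypresses
    blocks <- sim$blocks
    truth <- sim$truth
    write_keypress_log(kp, file.path(outdir, "keypresses.tsv"))
    write_tsv(sim$truth$trials, file.path(outdir, "truth_trials.tsv"))
  }

  # --- stage: parse -------------------------------------------------------
  trials <- parse_session(kp, sq)
  write_tsv(trials, file.path(outdir, "trials.tsv"))
  write_events_table(trials, file.path(outdir, "events.tsv"))

  # --- stage: select and match -------------------------------------------
  selres <- select_errors(trials, sel, k = sq$k)
  controls <- enumerate_controls(trials, k = sq$k)
  pairs <- match_positions(selres$periods, controls,
                           stage_seed(seed, "match"))
  sets <- second_matched_set(pairs, controls, stage_seed(seed, "match-set2"))
  write_tsv(rbind(sets$set1$pairs, sets$set2$pairs),
            file.path(outdir, "pairs.tsv"))
  write_tsv(rbind(selres$excluded, pairs$excluded),
            file.path(outdir, "exclusions.tsv"))
  message(nrow(selres$periods), " eligible error(s); ",
          nrow(pairs$pairs), " matched pair(s) in set 1")

  results <- list(trials = trials, selection = selres, pairs = pairs,
                  sets = sets, truth = truth)

  # --- stage: behavior stats ---------------------------------------------
  if (nrow(pairs$pairs)) {
    prof <- period_profile(pairs, trials, kp)
    write_tsv(prof$trial_profile, file.path(outdir, "behavior_profiles.tsv"))
    write_tsv(prof$phase_profile, file.path(outdir, "behavior_phases.tsv"))
    gstats <- behavior_group_stats(prof)
    write_tsv(gstats, file.path(outdir, "behavior_group_stats.tsv"))
    results$profile <- prof
    results$behavior_stats <- gstats
  } else {
    message("no matched pairs; behavioral group stage skipped")
  }

  # --- stage: GLM ---------------------------------------------------------
  glm_cfg <- config$glm %||% list()
  if (isTRUE(glm_cfg$enable)) {
    results$glm <- run_glm_stage(kp, trials, blocks, pairs, sq, lay,
                                 acq_args, glm_cfg, seed, outdir)
  } else {
    message("no BOLD inputs configured; imaging stages skipped")
  }

  meta <- list(seed = seed,
               config_hash = unname(tools::md5sum(
                 textConnection_md5(config))),
               package_version = as.character(
                 utils::packageVersion("tapslip")),
               timestamp_free = TRUE)
  jsonlite::write_json(meta, file.path(outdir, "metadata.json"),
                       auto_unbox = TRUE)
  invisible(results)
}

# md5 of the canonicalized config (serialize to a temp file; md5sum needs one)
textConnection_md5 <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), f)
  f
}

#' Derive performance-block epochs from keypresses
#'
#' When no GO-cue log exists, each block's epoch is taken from its first to
#' its last keypress.
#'
#' @param kp keypress data.frame.
#' @return data.frame `subject`, `block`, `onset_s`, `duration_s`.
#' @export
blocks_from_keypresses <- function(kp) {
  out <- lapply(split_blocks(kp), function(b) data.frame(
    subject = b$subject[1], block = b$block[1],
    onset_s = min(b$onset_ms) / 1000,
    duration_s = (max(b$onset_ms) - min(b$onset_ms)) / 1000,
    stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-level behavioral statistics over a period profile
#'
#' One-sample t tests of the error condition's slowing against zero per
#' role, paired t tests error vs control per role, and a repeated-measures
#' ANOVA over the five roles of the error condition.
#'
#' @param prof result of [period_profile()].
#' @return data.frame of `GroupStat` rows with `measure` and `role`.
#' @export
behavior_group_stats <- function(prof) {
  tp <- prof$trial_profile
  roles <- levels(tp$role)
  rows <- list()
  for (r in roles) {
    e <- tp[tp$role == r & tp$condition == "error", ]
    c_ <- tp[tp$role == r & tp$condition == "control", ]
    m <- merge(e[, c("subject", "slowing")], c_[, c("subject", "slowing")],
               by = "subject", suffixes = c("_e", "_c"))
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) >= 2L) {
      g1 <- group_tests(m$slowing_e, "one_sample")
      g1$measure <- "error_vs_zero"; g1$role <- r
      g2 <- group_tests(as.matrix(m[, c("slowing_e", "slowing_c")]), "paired")
      g2$measure <- "error_vs_control"; g2$role <- r
      rows[[length(rows) + 1L]] <- rbind(g1, g2)
    }
  }
  wide <- stats::reshape(
    tp[tp$condition == "error", c("subject", "role", "slowing")],
    direction = "wide", idvar = "subject", timevar = "role")
  Y <- as.matrix(wide[, -1, drop = FALSE])
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  if (nrow(Y) >= 2L) {
    g3 <- group_tests(Y, "rm_anova")
    g3$measure <- "role_course"; g3$role <- "all"
    rows[[length(rows) + 1L]] <- g3
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# first-level + group GLM stage over (possibly simulated) BOLD series
run_glm_stage <- function(kp, trials, blocks, pairs, sq, lay, acq_args,
                          glm_cfg, seed, outdir) {
  onset_policy <- glm_cfg$onset_policy %||% "trial_onset"
  duration_policy <- glm_cfg$duration_policy %||% "stick"
  matched_mode <- glm_cfg$matched_mode %||% "pooled"
  subjects <- unique(trials$subject)
  roles <- c("PreE2", "PreE1", "E", "PostE1", "PostE2")
  contrast_rows <- list()
  for (sj in subjects) {
    tr_s <- trials[trials$subject == sj, , drop = FALSE]
    kp_s <- kp[kp$subject == sj, , drop = FALSE]
    blk_s <- blocks[blocks$subject == sj, , drop = FALSE]
    blk_df <- data.frame(onset = blk_s$onset_s, duration = blk_s$duration_s)
    models <- generate_model_suite(tr_s, pairs, sq, lay,
                                   onset_policy = onset_policy,
                                   duration_policy = duration_policy,
                                   matched_mode = matched_mode)
    # BOLD: read per-subject series or simulate from the session's events
    if (!is.null(glm_cfg$bold_tsv)) {
      Y <- read_bold_tsv(glm_cfg$bold_tsv[[sj]])
      acq_args$n_scans <- nrow(Y)
      acq <- do.call(acquisition_spec, acq_args)
    } else {
      sim_args <- glm_cfg$simulate %||% list()
      sim_args$seed <- stage_seed(seed, paste0("simulate-bold-", sj))
      bspec <- do.call(bold_gen_spec, sim_args)
      truth_events <- glm_events_truth(tr_s, pairs, sj)
      bsim <- gen_bold(truth_events, blk_df, bspec)
      Y <- bsim$Y
      acq <- bsim$acq
      acq$microtime_bins <- acq_args$microtime_bins %||% acq$microtime_bins
      acq$highpass_cutoff <- acq_args$highpass_cutoff %||% acq$highpass_cutoff
    }
    for (m in models) {
      if (m$kind != "role" || !nrow(m$events)) next
      ev <- apply_onset_policy(m, kp_s)
      des <- build_design(ev[, c("onset", "duration", "regressor")],
                          blk_df, acq)
      fit <- fit_prewhitened(Y, des)
      mc <- matched_contrast(fit)
      contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
        subject = sj, role = m$role, series = seq_len(nrow(mc)),
        value = mc$value, t = mc$t, stringsAsFactors = FALSE)
    }
  }
  if (!length(contrast_rows)) {
    message("no role models could be fit (no matched pairs?)")
    return(NULL)
  }
  cr <- do.call(rbind, contrast_rows)
  write_tsv(cr, file.path(outdir, "glm_matched_contrasts.tsv"))
  # group stage: one-sample t per role (series averaged), phase-course F
  agg <- stats::aggregate(value ~ subject + role, data = cr, FUN = mean)
  wide <- stats::reshape(agg, direction = "wide", idvar = "subject",
                         timevar = "role")
  Y <- as.matrix(wide[, -1, drop = FALSE])
  colnames(Y) <- sub("^value\\.", "", colnames(Y))
  Y <- Y[, intersect(roles, colnames(Y)), drop = FALSE]
  ok <- stats::complete.cases(Y)
  group <- list(roi = second_level(Y[ok, , drop = FALSE]),
                phase = if (sum(ok) >= 2L && ncol(Y) >= 2L)
                  second_level_phase(Y[ok, , drop = FALSE]) else NULL)
  write_tsv(group$roi$table, file.path(outdir, "glm_group_stats.tsv"))
  list(contrasts = cr, group = group)
}

# ground-truth event table for BOLD simulation: error/control role events
glm_events_truth <- function(tr_s, pairs, sj) {
  p <- pairs$pairs
  p <- p[p$subject == sj, , drop = FALSE]
  ev <- list()
  offs <- -2:2
  roles <- c("PreE2", "PreE1", "E", "PostE1", "PostE2")
  for (i in seq_len(nrow(p))) {
    for (r in seq_along(roles)) {
      te <- tr_s[tr_s$block == p$error_block[i] &
                 tr_s$trial == p$error_center[i] + offs[r], , drop = FALSE]
      tc <- tr_s[tr_s$block == p$control_block[i] &
                 tr_s$trial == p$control_center[i] + offs[r], , drop = FALSE]
      if (nrow(te) == 1L)
        ev[[length(ev) + 1L]] <- data.frame(
          onset = te$onset_ms / 1000, duration = 0,
          regressor = paste0("error_", roles[r]), stringsAsFactors = FALSE)
      if (nrow(tc) == 1L)
        ev[[length(ev) + 1L]] <- data.frame(
          onset = tc$onset_ms / 1000, duration = 0,
          regressor = paste0("control_", roles[r]), stringsAsFactors = FALSE)
    }
  }
  if (!length(ev))
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      regressor = character(0), stringsAsFactors = FALSE))
  do.call(rbind, ev)
}
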