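# internal helpers shared across modules

# nearest-integer rounding, halves away from zero (R's round() is banker's)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so callers' random streams
#' are unaffected.  All stochastic operations in the package route through
#' this helper to honour their seed contracts.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a session seed
#'
#' Stable fan-out of one global seed to per-stage seeds by hashing the stage
#' name, so stages re-run in isolation reproduce their in-pipeline streams.
#' Result always lies in `[0, 2^31 - 2]`.
#'
#' @param seed integer session seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  u <- utf8ToInt(stage)
  h <- sum(u * (seq_along(u) * 131)) %% 1000003
  as.integer((abs(seed) + h) %% (.Machine$integer.max - 1))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a data.frame into blocks per (subject, block), preserving order
split_blocks <- function(df) {
  key <- interaction(df$subject, df$block, drop = TRUE, lex.order = TRUE)
  split(df, key)
}
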