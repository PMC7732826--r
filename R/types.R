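#' Target sequence specification
#'
#' Defines the key sequence participants reproduce.  The study instance is a
#' five-element sequence 4-1-3-2-4 tapped on a four-key pad; both sequence
#' and alphabet are configurable.
#'
#' @param codes integer vector of key codes in order; default `c(4,1,3,2,4)`.
#' @param alphabet integer vector of admissible key codes; default `1:4`.
#' @return An object of class `sequence_spec` with fields `codes`, `k`
#'   (sequence length) and `alphabet`.
#' @examples
#' sequence_spec()            # the study sequence, k = 5
#' sequence_spec(c(1, 2), 1:3)
#' @export
sequence_spec <- function(codes = c(4L, 1L, 3L, 2L, 4L), alphabet = 1:4) {
  codes <- as.integer(codes)
  alphabet <- sort(unique(as.integer(alphabet)))
  if (length(codes) < 2L) stop("sequence must have k >= 2 elements")
  if (!all(codes %in% alphabet))
    stop("sequence codes must belong to the key alphabet")
  structure(list(codes = codes, k = length(codes), alphabet = alphabet),
            class = "sequence_spec")
}

#' Block layout of a tapping session
#'
#' @param n_blocks number of performance blocks (study: 14).
#' @param keys_per_block keypresses per block (study: 60).
#' @param rest_duration rest between blocks, seconds (study: 15).
#' @param block_onsets optional numeric vector of GO-cue onsets in seconds
#'   from run start (performance-dependent in real data; recorded by the
#'   generator, derived from keypresses otherwise).
#' @return An object of class `block_layout`.
#' @export
block_layout <- function(n_blocks = 14L, keys_per_block = 60L,
                         rest_duration = 15, block_onsets = NULL) {
  n_blocks <- as.integer(n_blocks)
  keys_per_block <- as.integer(keys_per_block)
  if (n_blocks < 1L || keys_per_block < 1L)
    stop("n_blocks and keys_per_block must be positive")
  if (!is.null(block_onsets) && length(block_onsets) != n_blocks)
    stop("block_onsets must have one onset per block")
  structure(list(n_blocks = n_blocks, keys_per_block = keys_per_block,
                 rest_duration = rest_duration, block_onsets = block_onsets),
            class = "block_layout")
}

#' Eligibility rules for isolated errors
#'
#' Encodes the isolation and size filters: an error must be preceded and
#' followed by at least `min_pre`/`min_post` correct trials in a row (the
#' last error of a block needs only `min_post_if_last` when its following
#' correct run ends the block), must last longer than `min_duration` ms, and
#' must comprise at most `max_keys` keypresses (inclusive).
#'
#' @param min_pre minimum preceding correct trials (default 3).
#' @param min_post minimum following correct trials (default 3).
#' @param min_post_if_last relaxed following count for the block's last
#'   error at the very end of the block (default 2).
#' @param min_duration minimum error duration in ms, exclusive (default 500).
#' @param max_keys maximum error length in keys, inclusive (default 20).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(min_pre = 3L, min_post = 3L,
                             min_post_if_last = 2L,
                             min_duration = 500, max_keys = 20L) {
  if (any(c(min_pre, min_post, min_post_if_last, min_duration, max_keys) <= 0))
    stop("all selection thresholds must be positive")
  if (min_post_if_last > min_post)
    stop("min_post_if_last must not exceed min_post")
  structure(list(min_pre = as.integer(min_pre),
                 min_post = as.integer(min_post),
                 min_post_if_last = as.integer(min_post_if_last),
                 min_duration = min_duration,
                 max_keys = as.integer(max_keys)),
            class = "selection_config")
}

#' fMRI acquisition timing
#'
#' @param TR repetition time in seconds (study: 2.65).
#' @param n_scans number of volumes.
#' @param microtime_bins microtime bins per TR used for HRF convolution
#'   (default 16).
#' @param highpass_cutoff high-pass cutoff in seconds (default 128); must
#'   exceed twice the TR.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(TR = 2.65, n_scans = NULL, microtime_bins = 16L,
                             highpass_cutoff = 128) {
  if (TR <= 0) stop("TR must be positive")
  if (highpass_cutoff <= 2 * TR)
    stop("highpass_cutoff must exceed 2 * TR")
  structure(list(TR = TR, n_scans = if (is.null(n_scans)) NULL
                 else as.integer(n_scans),
                 microtime_bins = as.integer(microtime_bins),
                 highpass_cutoff = highpass_cutoff),
            class = "acquisition_spec")
}

#' Canonical double-gamma HRF parameters
#'
#' Response and undershoot are gamma densities with the stated delays and
#' dispersions (shape = delay/dispersion, scale = dispersion); the undershoot
#' is divided by `ratio`.  The kernel is normalized to unit peak and is
#' supported on `[0, length)` seconds.
#'
#' @param response_delay s (default 6).
#' @param undershoot_delay s (default 16).
#' @param response_dispersion s (default 1).
#' @param undershoot_dispersion s (default 1).
#' @param ratio response:undershoot amplitude ratio (default 6).
#' @param length kernel support in seconds (default 32).
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(response_delay = 6, undershoot_delay = 16,
                     response_dispersion = 1, undershoot_dispersion = 1,
                     ratio = 6, length = 32) {
  stopifnot(response_delay > 0, undershoot_delay > 0,
            response_dispersion > 0, undershoot_dispersion > 0,
            ratio > 0, length > 0)
  structure(list(response_delay = response_delay,
                 undershoot_delay = undershoot_delay,
                 response_dispersion = response_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 ratio = ratio, length = length),
            class = "hrf_spec")
}

#' Spherical region of interest
#'
#' Coordinates are continuous mm in the volume's own frame; voxels are
#' included when their centers lie within `radius` (inclusive) of `center`.
#'
#' @param center numeric length-3, mm.
#' @param radius mm; 6 by default (the study used 4 mm within the basal
#'   ganglia and thalamus).
#' @param name optional label.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, radius = 6, name = NULL) {
  center <- as.numeric(center)
  if (length(center) != 3L) stop("center must be a length-3 mm coordinate")
  if (radius <= 0) stop("radius must be positive")
  structure(list(center = center, radius = radius, name = name),
            class = "roi_spec")
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat("sequence_spec: ", paste(x$codes, collapse = "-"),
      " (k = ", x$k, ", alphabet {", paste(x$alphabet, collapse = ","),
      "})\n", sep = "")
  invisible(x)
}
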