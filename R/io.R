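#' Read a keypress log
#'
#' Reads a tab-separated keypress log with header columns `subject`, `block`,
#' `key`, `onset_ms` (onsets in ms from session start).  Records are stably
#' ordered by subject and block; within each block onsets must be strictly
#' increasing as given, and every key code must belong to the alphabet.
#'
#' @param path file path.
#' @param alphabet admissible key codes (default `1:4`).
#' @return A data.frame with columns `subject`, `block`, `key`, `onset_ms`.
#' @export
read_keypress_log <- function(path, alphabet = 1:4) {
  df <- read_tsv(path)
  need <- c("subject", "block", "key", "onset_ms")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("keypress log is missing column(s): ", paste(miss, collapse = ", "))
  df$subject <- as.character(df$subject)
  df$block <- as.integer(df$block)
  df$key <- as.integer(df$key)
  df$onset_ms <- as.numeric(df$onset_ms)
  bad <- which(!df$key %in% as.integer(alphabet))
  if (length(bad))
    stop("unknown key code ", df$key[bad[1]], " at row ", bad[1])
  # stable reorder by subject/block keeps within-block row order intact
  df <- df[order(df$subject, df$block), , drop = FALSE]
  for (blk in split(seq_len(nrow(df)),
                    interaction(df$subject, df$block, drop = TRUE))) {
    o <- df$onset_ms[blk]
    if (length(o) > 1L && any(diff(o) <= 0)) {
      i <- blk[which(diff(o) <= 0)[1] + 1L]
      stop("onsets not strictly increasing within subject ", df$subject[i],
           " block ", df$block[i], " at row ", i)
    }
  }
  rownames(df) <- NULL
  validate_keypresses(df, alphabet)
  df
}

validate_keypresses <- function(kp, alphabet = 1:4) {
  stopifnot(all(c("subject", "block", "key", "onset_ms") %in% names(kp)))
  if (!all(kp$key %in% as.integer(alphabet)))
    stop("keypress table contains keys outside the alphabet")
  invisible(kp)
}

#' Write a keypress log
#'
#' Inverse of [read_keypress_log()]; the round trip is lossless for all
#' fields (up to float formatting of onsets).
#'
#' @param kp keypress data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_keypress_log <- function(kp, path) {
  write_tsv(kp[, c("subject", "block", "key", "onset_ms")], path)
}

#' Write a BIDS-style events table
#'
#' Converts parsed trials to an events table with columns `onset` and
#' `duration` in seconds, `trial_type`, plus extension columns `subject`,
#' `block`, `ordinal` and `error_type`.  This is the single point where the
#' behavioral ms time base is converted to the imaging seconds time base.
#'
#' @param trials trials data.frame from [parse_session()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(trials, path) {
  ev <- events_from_trials(trials)
  write_tsv(ev, path)
}

#' @rdname write_events_table
#' @export
events_from_trials <- function(trials) {
  if (nrow(trials)) {
    for (blk in split_blocks(trials)) {
      if (nrow(blk) > 1L) {
        if (any(blk$first_key[-1] <= blk$last_key[-nrow(blk)]))
          stop("overlapping trial spans in subject ", blk$subject[1],
               " block ", blk$block[1])
      }
    }
  }
  data.frame(
    onset = trials$onset_ms / 1000,
    duration = (trials$offset_ms - trials$onset_ms) / 1000,
    trial_type = trials$kind,
    subject = trials$subject,
    block = trials$block,
    ordinal = trials$trial,
    error_type = ifelse(is.na(trials$error_type), "n/a", trials$error_type),
    stringsAsFactors = FALSE
  )
}

#' Read an events table written by [write_events_table()]
#' @param path file path.
#' @return events data.frame.
#' @export
read_events_table <- function(path) {
  ev <- read_tsv(path)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events table is missing column(s): ", paste(miss, collapse = ", "))
  ev
}

#' Read a pipeline configuration file
#'
#' YAML mapping with sections `sequence`, `layout`, `acquisition`,
#' `selection`, `glm` and `rng_seed`; all sections optional, defaults apply.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Read a time-by-series BOLD table
#'
#' Tab-separated, one row per scan, one column per series (voxel or ROI).
#'
#' @param path file path.
#' @return numeric matrix, scans x series.
#' @export
read_bold_tsv <- function(path) {
  as.matrix(read_tsv(path))
}

#' Read a six-column motion-parameter table
#' @param path file path (TSV, with or without header).
#' @return numeric matrix, scans x 6.
#' @export
read_motion_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t")[[1]]))))
  m <- as.matrix(utils::read.delim(path, header = has_header, sep = "\t"))
  if (ncol(m) != 6L) stop("motion table must have 6 columns")
  colnames(m) <- paste0("motion", 1:6)
  m
}

#' Read an ROI table (name, x, y, z, radius_mm)
#' @param path TSV file path.
#' @return list of [roi_spec()] objects.
#' @export
read_roi_table <- function(path) {
  df <- read_tsv(path)
  need <- c("name", "x", "y", "z", "radius_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ROI table is missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    roi_spec(c(df$x[i], df$y[i], df$z[i]), df$radius_mm[i], df$name[i]))
}

#' Read a 4D NIfTI volume as a scans-by-voxel matrix
#'
#' Requires the RNifti package.  Returns the time-by-voxel data matrix plus
#' the spatial grid needed for sphere-ROI extraction.
#'
#' @param path NIfTI file path.
#' @return list with `data` (scans x voxels), `dim` (3D grid), `voxel_size`
#'   (mm) and `origin` (mm coordinate of voxel `[1,1,1]`'s center).
#' @export
read_bold_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D BOLD volume")
  dat <- t(matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4]))
  list(data = dat, dim = d[1:3],
       voxel_size = as.numeric(RNifti::pixdim(img))[1:3],
       origin = c(0, 0, 0))
}
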