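# independent oracles used by the tests; none of these share code with the
# implementation paths they check

# maximum number of non-overlapping sequence matches that can tile a stream
# (dynamic program over match positions; the greedy scanner never sees this)
oracle_max_tiling <- function(keys, codes) {
  k <- length(codes)
  n <- length(keys)
  if (n < k) return(0L)
  starts <- which(vapply(seq_len(n - k + 1L), function(i)
    all(keys[i:(i + k - 1L)] == codes), logical(1)))
  # f[i] = max matches using positions >= i
  f <- integer(n + 2L)
  for (i in n:1) {
    f[i] <- f[i + 1L]
    if (i %in% starts && i + k <= n + 1L)
      f[i] <- max(f[i], 1L + f[min(i + k, n + 1L)])
  }
  f[1]
}

# brute-force enumeration of every set of non-overlapping matches (not a
# DP): maximal count over all tilings
oracle_enumerate_tilings <- function(keys, codes) {
  k <- length(codes)
  n <- length(keys)
  starts <- which(vapply(seq_len(max(n - k + 1L, 0L)), function(i)
    all(keys[i:(i + k - 1L)] == codes), logical(1)))
  best <- 0L
  recurse <- function(pos, count) {
    best <<- max(best, count)
    for (s in starts[starts >= pos]) recurse(s + k, count + 1L)
  }
  recurse(1L, 0L)
  best
}

# all key streams of a given length over an alphabet
all_streams <- function(len, alphabet) {
  g <- do.call(expand.grid, rep(list(alphabet), len))
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

# brute-force voxel count for a sphere on a regular grid
oracle_sphere_count <- function(dim, center, radius, voxel_size, origin) {
  cnt <- 0L
  for (i in seq_len(dim[1])) for (j in seq_len(dim[2]))
    for (l in seq_len(dim[3])) {
      pos <- origin + (c(i, j, l) - 1) * voxel_size
      if (sum((pos - center)^2) <= radius^2 + 1e-9) cnt <- cnt + 1L
    }
  cnt
}

# closed-form power of the two-sided one-sample t test
oracle_t_power <- function(delta_over_sigma, n, alpha = 0.05) {
  ncp <- delta_over_sigma * sqrt(n)
  crit <- qt(1 - alpha / 2, n - 1)
  pt(-crit, n - 1, ncp) + pt(crit, n - 1, ncp, lower.tail = FALSE)
}

# build a 60-key single-error block: a correct repetitions, an error run of
# length L (repeats of a key that cannot start or extend a match), then
# correct repetitions to fill; transitions are iv ms apart
single_error_block <- function(a, L, seq, keys_per_block = 60L, iv = 300) {
  codes <- seq$codes
  filler <- setdiff(seq$alphabet, codes[1])[1]
  keys <- c(rep(codes, a), rep(filler, L))
  rem <- keys_per_block - length(keys)
  stopifnot(rem %% seq$k == 0L)
  keys <- c(keys, rep(codes, rem / seq$k))
  data.frame(subject = "s1", block = 1L, key = keys,
             onset_ms = seq_along(keys) * iv, stringsAsFactors = FALSE)
}

# keypress table from explicit keys and onsets
kp_from <- function(keys, onsets, subject = "s1", block = 1L) {
  data.frame(subject = subject, block = block, key = as.integer(keys),
             onset_ms = onsets, stringsAsFactors = FALSE)
}
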