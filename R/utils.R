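# Frame/time conventions used across the package.
#
# Frames are 0-based; frame i covers the half-open interval [i/fs, (i+1)/fs).
# A time window [a, b) therefore contains every frame whose *start* time falls
# inside it. At 5 Hz the "last second of odor" (window [1, 2) s after onset)
# is relative frames 5..9 and the "2 s prior to odor" is frames -10..-1.

# 0-based index of the first frame whose start time is >= t
frame_of_time <- function(t, fs) {
  as.integer(ceiling(t * fs - 1e-9))
}

# 0-based frame indices whose start times fall in [a, b)
frames_in_window <- function(a, b, fs) {
  lo <- frame_of_time(a, fs)
  hi <- frame_of_time(b, fs) - 1L
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

# Analysis window (seconds relative to odor onset) for the lick/no-lick
# paradigm: last 0.5 s of odor plus first 0.5 s of the trace-delay. Shared by
# the behavioral lick-rate quantification and the population decoding window.
anticipatory_window_s <- function(odor_duration_s = 2) {
  c(odor_duration_s - 0.5, odor_duration_s + 0.5)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses (and advances) the current RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Derive a stream of child seeds from one master seed (keeps values < 2^31)
derive_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) + salt + 1000003L * seq_len(n)) %% .Machine$integer.max
}

# Stratified k-fold assignment; returns an integer fold id per observation.
stratified_folds <- function(labels, k, seed = NULL) {
  labels <- as.character(labels)
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < k) {
        abort(sprintf("class '%s' has %d trials, fewer than k = %d folds",
                      lv, length(idx), k))
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Centered moving average with shrinking windows at the boundaries.
moving_average <- function(x, window) {
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
}

`%||%` <- rlang::`%||%`
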