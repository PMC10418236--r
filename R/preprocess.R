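#' Moving-window Gaussian-mixture baseline estimation
#'
#' Estimates the slowly varying baseline fluorescence of each neuron. Within
#' each moving window a two-component Gaussian mixture is fitted to the
#' fluorescence values by EM and the mean of the lowest-mean component is
#' taken as that window's baseline: the low component captures quiescent
#' frames while calcium transients load onto the high component. Window
#' estimates are assigned to window-center frames and linearly interpolated
#' across frames, with constant extrapolation at the edges. Degenerate fits
#' (a component collapsing or taking <2% of the mass) fall back to a
#' percentile estimate of the window.
#'
#' The EM uses a deterministic quantile-based initialisation, so results are
#' reproducible without any random-number stream; `seed` is accepted for
#' interface symmetry but does not change the result.
#'
#' @param F Fluorescence matrix (neurons x frames) or a single trace.
#' @param window_frames Moving-window length in frames (2,500 frames = 500 s
#'   at 5 Hz).
#' @param stride_frames Spacing between window centers.
#' @param n_components Number of mixture components.
#' @param fallback_quantile Percentile used when the mixture fit degenerates.
#' @param seed Unused (the estimator is deterministic); kept for interface
#'   consistency.
#' @return A baseline matrix of the same shape as `F` (strictly positive for
#'   positive input).
#' @export
estimate_moving_baseline <- function(F, window_frames = 2500L,
                                     stride_frames = 500L,
                                     n_components = 2L,
                                     fallback_quantile = 0.2,
                                     seed = NULL) {
  vec_in <- is.null(dim(F))
  if (vec_in) F <- matrix(F, nrow = 1)
  if (!all(is.finite(F))) abort("`F` must be finite")
  n_frames <- ncol(F)
  if (n_frames < 1) abort("`F` must have at least one frame")
  if (window_frames < n_components) {
    abort("`window_frames` must be >= `n_components`")
  }

  if (n_frames <= window_frames) {
    centers0 <- as.integer(floor((n_frames - 1) / 2))
  } else {
    # centers span the full series; edge windows are clipped
    centers0 <- unique(as.integer(c(seq(0, n_frames - 1, by = stride_frames),
                                    n_frames - 1)))
  }
  vals <- .gmm_window_baselines(F, centers0, as.integer(window_frames),
                                as.integer(n_components), 100L, 1e-5,
                                fallback_quantile)
  out <- matrix(0, nrow(F), n_frames)
  if (length(centers0) == 1L) {
    out[] <- vals[, 1]
  } else {
    xs <- centers0 + 1
    for (i in seq_len(nrow(F))) {
      out[i, ] <- approx(xs, vals[i, ], xout = seq_len(n_frames),
                         rule = 2)$y
    }
  }
  if (vec_in) out[1, ] else out
}

#' Compute dF/F against a baseline
#'
#' Elementwise `(F - baseline) / baseline`.
#'
#' @param F Fluorescence matrix (neurons x frames) or trace.
#' @param baseline Baseline of the same shape (strictly positive).
#' @return dF/F of the same shape.
#' @export
compute_dff <- function(F, baseline) {
  if (is.null(dim(F))) F <- matrix(F, nrow = 1)
  if (is.null(dim(baseline))) baseline <- matrix(baseline, nrow = 1)
  stopifnot(all(dim(F) == dim(baseline)))
  bad <- which(apply(baseline <= 0, 1, any))
  if (length(bad)) {
    abort(sprintf("baseline is non-positive for neuron(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  (F - baseline) / baseline
}

#' Preprocess a session to dF/F
#'
#' Convenience wrapper: moving-baseline estimation followed by dF/F.
#'
#' @param session A `recording_session`.
#' @inheritParams estimate_moving_baseline
#' @return The session with elements `dff` and `baseline` added.
#' @export
preprocess_session <- function(session, window_frames = 2500L,
                               stride_frames = 500L, n_components = 2L,
                               fallback_quantile = 0.2) {
  stopifnot(inherits(session, "recording_session"))
  session$baseline <- estimate_moving_baseline(
    session$F, window_frames, stride_frames, n_components, fallback_quantile)
  session$dff <- compute_dff(session$F, session$baseline)
  session
}

#' Epoch dF/F into a trial tensor
#'
#' Slices the dF/F matrix into windows aligned to odor onset. Relative frame
#' 0 is the first frame whose start time is at or after odor onset; the
#' window spans `[-pre_s, +post_s)`. Trials whose window would be truncated
#' by the recording edges are dropped with a warning.
#'
#' @param dff dF/F matrix (neurons x frames) or a preprocessed
#'   `recording_session`.
#' @param schedule Trial schedule (taken from the session when omitted).
#' @param frame_rate_hz Frame rate (taken from the session when omitted).
#' @param pre_s,post_s Window extent before/after odor onset (seconds).
#' @return A `trial_tensor`: list with `values` (neurons x trials x frames),
#'   `rel_frames` (0-based frame offsets relative to onset), `trials` (the
#'   retained schedule rows plus `onset_frame`), `frame_rate_hz`, and
#'   `n_dropped`.
#' @export
epoch_trials <- function(dff, schedule = NULL, frame_rate_hz = NULL,
                         pre_s = 2, post_s = 5) {
  if (inherits(dff, "recording_session")) {
    session <- dff
    if (is.null(session$dff)) {
      abort("session has no `dff`; run preprocess_session() first")
    }
    schedule <- schedule %||% session$schedule
    frame_rate_hz <- frame_rate_hz %||% session$frame_rate_hz
    dff <- session$dff
  }
  if (is.null(schedule) || is.null(frame_rate_hz)) {
    abort("`schedule` and `frame_rate_hz` are required with a matrix input")
  }
  fs <- frame_rate_hz
  rel <- seq.int(-round(pre_s * fs), round(post_s * fs) - 1L)
  n_frames <- ncol(dff)

  onset_frame <- frame_of_time(schedule$onset_s, fs)
  lo <- onset_frame + rel[1]
  hi <- onset_frame + rel[length(rel)]
  keep <- lo >= 0 & hi <= n_frames - 1
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warn(sprintf("dropped %d trial(s) with truncated windows", n_dropped))
  }
  kept <- schedule[keep, , drop = FALSE]
  kept$onset_frame <- onset_frame[keep]

  values <- array(0, dim = c(nrow(dff), nrow(kept), length(rel)))
  for (j in seq_len(nrow(kept))) {
    values[, j, ] <- dff[, kept$onset_frame[j] + rel + 1L, drop = FALSE]
  }
  structure(list(
    values = values,
    rel_frames = rel,
    trials = kept,
    frame_rate_hz = fs,
    n_dropped = n_dropped
  ), class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<trial_tensor> %d neurons x %d trials x %d frames @ %g Hz (rel %d..%d)\n",
    d[1], d[2], d[3], x$frame_rate_hz, min(x$rel_frames), max(x$rel_frames)))
  invisible(x)
}

# mean dF/F per (neuron, trial) over a relative-time window [a, b) seconds
window_trial_means <- function(tensor, window_s) {
  fr <- frames_in_window(window_s[1], window_s[2], tensor$frame_rate_hz)
  idx <- match(fr, tensor$rel_frames)
  if (anyNA(idx)) abort("window extends beyond the epoched tensor")
  sub <- tensor$values[, , idx, drop = FALSE]
  apply(sub, c(1, 2), mean)  # neurons x trials
}

#' Trial-averaged response magnitudes (ddF/F)
#'
#' For every neuron and odor: the trial-averaged mean dF/F over the last
#' odor second minus the trial-averaged mean over the 2 s preceding odor
#' onset. The scaled variant divides each neuron's values by its largest
#' positive ddF/F across odors; neurons with no positive ddF/F get `NaN`
#' scaled values (flagged undefined).
#'
#' @param tensor A `trial_tensor` covering at least `[-2, +2)` s.
#' @param response_window_s Response window relative to onset (defaults to
#'   the last odor second, `[1, 2)`).
#' @param pre_window_s Pre-odor baseline window (defaults to `[-2, 0)`).
#' @return A tibble: `neuron`, `odor_id`, `contingency`, `ddff`,
#'   `ddff_scaled`.
#' @export
response_magnitude <- function(tensor,
                               response_window_s = c(1, 2),
                               pre_window_s = c(-2, 0)) {
  resp <- window_trial_means(tensor, response_window_s)
  pre <- window_trial_means(tensor, pre_window_s)
  labs <- tensor$trials
  odors <- sort(unique(labs$odor_id))
  out <- purrr::map_dfr(odors, function(o) {
    j <- which(labs$odor_id == o)
    if (!length(j)) abort(sprintf("odor %d has zero trials", o))
    tibble::tibble(
      neuron = seq_len(nrow(resp)),
      odor_id = o,
      contingency = labs$contingency[j[1]],
      ddff = rowMeans(resp[, j, drop = FALSE]) -
        rowMeans(pre[, j, drop = FALSE])
    )
  })
  out <- dplyr::group_by(out, .data$neuron)
  out <- dplyr::mutate(out, ddff_scaled = {
    mx <- max(.data$ddff)
    if (mx > 0) .data$ddff / mx else rep(NaN, dplyr::n())
  })
  dplyr::ungroup(out)
}
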