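#' Framewise Wilcoxon responsiveness tests
#'
#' For each neuron and odor, compares the per-trial dF/F at every frame of
#' the 2 s odor period against the pooled pre-odor distribution (all frames
#' in the 2 s before onset across that odor's trials) with a two-sided
#' Wilcoxon rank-sum test. The resulting p-values are Holm-Bonferroni
#' corrected within each (neuron, odor) family of odor frames, controlling
#' the family-wise error rate at `alpha`. Frame direction is the sign of the
#' frame median minus the pooled pre-odor median.
#'
#' @param tensor A `trial_tensor`.
#' @param neurons,odors Optional subsets (defaults: all).
#' @param alpha FWER level.
#' @param odor_window_s Odor period relative to onset (seconds).
#' @param pre_window_s Pre-odor window pooled as the null reference.
#' @return A tibble: `neuron`, `odor_id`, `contingency`, `rel_frame`, `p`,
#'   `p_holm`, `significant`, `direction` (+1 excited / -1 inhibited / 0).
#' @export
framewise_response_test <- function(tensor, neurons = NULL, odors = NULL,
                                    alpha = 0.05,
                                    odor_window_s = c(0, 2),
                                    pre_window_s = c(-2, 0)) {
  fs <- tensor$frame_rate_hz
  odor_fr <- frames_in_window(odor_window_s[1], odor_window_s[2], fs)
  pre_fr <- frames_in_window(pre_window_s[1], pre_window_s[2], fs)
  odor_idx <- match(odor_fr, tensor$rel_frames)
  pre_idx <- match(pre_fr, tensor$rel_frames)
  if (anyNA(odor_idx) || anyNA(pre_idx)) {
    abort("tensor does not cover the odor and pre-odor windows")
  }
  labs <- tensor$trials
  neurons <- neurons %||% seq_len(dim(tensor$values)[1])
  odors <- odors %||% sort(unique(labs$odor_id))

  res <- list()
  for (o in odors) {
    j <- which(labs$odor_id == o)
    if (length(j) < 2) abort(sprintf("odor %d has fewer than 2 trials", o))
    cont <- labs$contingency[j[1]]
    for (nn in neurons) {
      pre_pool <- as.numeric(tensor$values[nn, j, pre_idx])
      pre_med <- median(pre_pool)
      p <- numeric(length(odor_idx))
      dir <- integer(length(odor_idx))
      for (fidx in seq_along(odor_idx)) {
        x <- tensor$values[nn, j, odor_idx[fidx]]
        if (length(unique(c(x, pre_pool))) == 1L) {
          p[fidx] <- 1
          dir[fidx] <- 0L
          warn("all-tied data in framewise test; p set to 1",
               .frequency = "once", .frequency_id = "ov_tied")
        } else {
          p[fidx] <- suppressWarnings(
            wilcox.test(x, pre_pool, exact = FALSE)$p.value)
          dir[fidx] <- sign(median(x) - pre_med)
        }
      }
      p_holm <- p.adjust(p, method = "holm")
      res[[length(res) + 1L]] <- tibble::tibble(
        neuron = nn, odor_id = o, contingency = cont,
        rel_frame = tensor$rel_frames[odor_idx],
        p = p, p_holm = p_holm, significant = p_holm <= alpha,
        direction = dir
      )
    }
  }
  dplyr::bind_rows(res)
}

#' Call odor-responsive neurons
#'
#' A neuron is responsive to an odor when at least `min_frames` odor frames
#' are Holm-Bonferroni significant with a common direction. Neurons whose
#' significant frames mix directions are labelled by the majority sign and
#' flagged (`mixed_direction`); the frame threshold is applied to the
#' majority-sign count.
#'
#' @param tests Output of [framewise_response_test()].
#' @param min_frames Minimum number of significant frames (default 4).
#' @return A tibble per neuron x odor: `n_sig_frames`, `direction`
#'   (`"excited"`, `"inhibited"`, `"none"`), `responsive`, `mixed_direction`,
#'   `p_min`.
#' @export
call_responsiveness <- function(tests, min_frames = 4L) {
  grp <- dplyr::group_by(tests, .data$neuron, .data$odor_id, .data$contingency)
  out <- dplyr::summarise(
    grp,
    n_sig_frames = sum(.data$significant),
    n_pos = sum(.data$significant & .data$direction > 0),
    n_neg = sum(.data$significant & .data$direction < 0),
    p_min = min(.data$p_holm),
    .groups = "drop"
  )
  out$mixed_direction <- out$n_pos > 0 & out$n_neg > 0
  major <- pmax(out$n_pos, out$n_neg)
  out$responsive <- major >= min_frames
  out$direction <- dplyr::case_when(
    !out$responsive ~ "none",
    out$n_pos >= out$n_neg ~ "excited",
    TRUE ~ "inhibited"
  )
  dplyr::select(out, "neuron", "odor_id", "contingency", "n_sig_frames",
                "p_min", "responsive", "direction", "mixed_direction")
}

#' Summaries of responsiveness calls
#'
#' Percent responsive per odor, the framewise timecourse of percent
#' significant, and category counts: responsive to both sucrose-paired odors
#' in the same direction, to exactly one odor, and to three or more odors.
#'
#' @param calls Output of [call_responsiveness()].
#' @param tests Output of [framewise_response_test()] (for the timecourse;
#'   optional).
#' @return A list of tibbles: `percent_by_odor`, `categories`, and (when
#'   `tests` is supplied) `timecourse` (percent of neurons significant per
#'   frame and odor, split by direction).
#' @export
responsiveness_summary <- function(calls, tests = NULL) {
  n_neurons <- dplyr::n_distinct(calls$neuron)
  percent_by_odor <- dplyr::summarise(
    dplyr::group_by(calls, .data$odor_id, .data$contingency),
    pct_responsive = 100 * mean(.data$responsive),
    pct_excited = 100 * mean(.data$responsive & .data$direction == "excited"),
    pct_inhibited = 100 * mean(.data$responsive & .data$direction == "inhibited"),
    .groups = "drop"
  )

  s_ids <- unique(calls$odor_id[grepl("^S_", calls$contingency)])
  per_neuron <- dplyr::summarise(
    dplyr::group_by(calls, .data$neuron),
    n_responsive = sum(.data$responsive),
    both_s_same_dir = {
      s <- .data$responsive[.data$odor_id %in% s_ids]
      d <- .data$direction[.data$odor_id %in% s_ids]
      length(s) == 2 && all(s) && d[1] == d[2]
    },
    .groups = "drop"
  )
  cat_n <- c(sum(per_neuron$both_s_same_dir),
             sum(per_neuron$n_responsive == 1),
             sum(per_neuron$n_responsive >= 3))
  categories <- tibble::tibble(
    category = c("both_S_same_direction", "single_odor", "three_or_more"),
    n = cat_n,
    pct = 100 * cat_n / n_neurons
  )

  out <- list(percent_by_odor = percent_by_odor, categories = categories)
  if (!is.null(tests)) {
    out$timecourse <- dplyr::summarise(
      dplyr::group_by(tests, .data$odor_id, .data$contingency, .data$rel_frame),
      pct_excited = 100 * mean(.data$significant & .data$direction > 0),
      pct_inhibited = 100 * mean(.data$significant & .data$direction < 0),
      .groups = "drop"
    )
  }
  out
}

#' US-window responsiveness
#'
#' Applies the framewise procedure to the window after unconditioned-stimulus
#' delivery (per-trial US-aligned frames) against the pre-odor pool, on
#' trials where the given US was delivered.
#'
#' @param tensor A `trial_tensor` whose window covers the US period.
#' @param us_type `"sucrose"` or `"airpuff"`.
#' @param window_s Length of the post-US window (seconds).
#' @param alpha FWER level.
#' @param min_frames Significant-frame threshold.
#' @return A tibble per neuron: `n_sig_frames`, `responsive`, `direction`.
#' @export
us_response_test <- function(tensor, us_type = "sucrose", window_s = 2,
                             alpha = 0.05, min_frames = 4L) {
  fs <- tensor$frame_rate_hz
  labs <- tensor$trials
  j <- which(labs$us_type == us_type & !is.na(labs$us_time_s))
  if (length(j) < 2) abort(sprintf("fewer than 2 %s trials", us_type))
  pre_idx <- match(frames_in_window(-2, 0, fs), tensor$rel_frames)
  if (anyNA(pre_idx)) abort("tensor does not cover the pre-odor window")

  # per-trial US-aligned relative frames
  us_rel <- frame_of_time(labs$us_time_s[j], fs) - labs$onset_frame[j]
  n_w <- round(window_s * fs)
  n_neurons <- dim(tensor$values)[1]
  out <- tibble::tibble(neuron = seq_len(n_neurons), n_sig_frames = 0L,
                        n_pos = 0L, n_neg = 0L)
  for (nn in seq_len(n_neurons)) {
    slice <- tensor$values[nn, , ]  # trials x frames
    pre_pool <- as.numeric(slice[j, pre_idx])
    pre_med <- median(pre_pool)
    p <- numeric(n_w); dir <- integer(n_w)
    for (w in seq_len(n_w)) {
      rel_f <- us_rel + (w - 1L)
      idx <- match(rel_f, tensor$rel_frames)
      if (anyNA(idx)) abort("tensor does not cover the post-US window")
      x <- slice[cbind(j, idx)]
      if (length(unique(c(x, pre_pool))) == 1L) {
        p[w] <- 1; dir[w] <- 0L
      } else {
        p[w] <- suppressWarnings(wilcox.test(x, pre_pool, exact = FALSE)$p.value)
        dir[w] <- sign(median(x) - pre_med)
      }
    }
    sig <- p.adjust(p, "holm") <= alpha
    out$n_sig_frames[nn] <- sum(sig)
    out$n_pos[nn] <- sum(sig & dir > 0)
    out$n_neg[nn] <- sum(sig & dir < 0)
  }
  out$responsive <- pmax(out$n_pos, out$n_neg) >= min_frames
  out$direction <- dplyr::case_when(
    !out$responsive ~ "none",
    out$n_pos >= out$n_neg ~ "excited",
    TRUE ~ "inhibited"
  )
  dplyr::select(out, "neuron", "n_sig_frames", "responsive", "direction")
}

#' Cross-day US-to-CS transition analysis
#'
#' Fraction of tracked neurons that are US (sucrose) responsive on the early
#' day and responsive to a sucrose-paired odor, with matching sign, on the
#' later day; plus the per-neuron change in response magnitude for
#' sucrose-paired odors between the two days.
#'
#' @param tensor_day1,tensor_day3 `trial_tensor`s from the two days.
#' @param matching A two-column data frame / tibble mapping day-1 neuron ids
#'   (`day1`) to day-3 neuron ids (`day3`).
#' @param alpha,min_frames Responsiveness parameters.
#' @return A list: `transition` (tibble per sucrose-paired odor with the
#'   transition fraction), `delta_magnitude` (per tracked neuron and S odor:
#'   day3 - day1 ddF/F).
#' @export
cross_day_transition <- function(tensor_day1, tensor_day3, matching,
                                 alpha = 0.05, min_frames = 4L) {
  matching <- tibble::as_tibble(matching)
  if (nrow(matching) == 0) abort("`matching` is empty")
  stopifnot(all(c("day1", "day3") %in% names(matching)))

  us1 <- us_response_test(tensor_day1, "sucrose", alpha = alpha,
                          min_frames = min_frames)
  tests3 <- framewise_response_test(tensor_day3, alpha = alpha)
  calls3 <- call_responsiveness(tests3, min_frames = min_frames)
  s_ids <- unique(calls3$odor_id[grepl("^S_", calls3$contingency)])

  trans <- purrr::map_dfr(s_ids, function(o) {
    c3 <- calls3[calls3$odor_id == o, ]
    hit <- vapply(seq_len(nrow(matching)), function(i) {
      u <- us1[us1$neuron == matching$day1[i], ]
      c <- c3[c3$neuron == matching$day3[i], ]
      isTRUE(u$responsive) && isTRUE(c$responsive) &&
        u$direction == c$direction
    }, logical(1))
    tibble::tibble(odor_id = o,
                   contingency = c3$contingency[1],
                   n_tracked = nrow(matching),
                   fraction = mean(hit))
  })

  rm1 <- response_magnitude(tensor_day1)
  rm3 <- response_magnitude(tensor_day3)
  delta <- purrr::map_dfr(s_ids, function(o) {
    m1 <- rm1[rm1$odor_id == o, ]
    m3 <- rm3[rm3$odor_id == o, ]
    tibble::tibble(
      odor_id = o,
      day1_neuron = matching$day1,
      day3_neuron = matching$day3,
      ddff_day1 = m1$ddff[match(matching$day1, m1$neuron)],
      ddff_day3 = m3$ddff[match(matching$day3, m3$neuron)],
      delta = .data$ddff_day3 - .data$ddff_day1
    )
  })
  list(transition = trans, delta_magnitude = delta)
}

#' Identity-line similarity of response magnitudes
#'
#' Quantifies how well the null model "all neurons respond identically to
#' both odors" describes paired response magnitudes: residuals are taken
#' about the y = x line, so `R2 = 1 - sum((y - x)^2) / sum((y - mean(y))^2)`.
#' Values can be negative when the identity line fits worse than the mean.
#'
#' @param rm Output of [response_magnitude()].
#' @param pair Length-2 character vector of contingency labels, e.g.
#'   `c("S_K", "S_T")`.
#' @param scaled Use the scaled ddF/F (default) or raw.
#' @return A one-row tibble: `pair`, `n`, `r_squared`.
#' @export
ddff_similarity <- function(rm, pair, scaled = TRUE) {
  col <- if (scaled) "ddff_scaled" else "ddff"
  wide <- tidyr::pivot_wider(rm[, c("neuron", "contingency", col)],
                             names_from = "contingency",
                             values_from = dplyr::all_of(col))
  if (!all(pair %in% names(wide))) abort("pair labels not found in `rm`")
  x <- wide[[pair[1]]]
  y <- wide[[pair[2]]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("fewer than 3 neurons with finite values")
  r2 <- 1 - sum((y - x)^2) / sum((y - mean(y))^2)
  tibble::tibble(pair = paste(pair, collapse = " vs "),
                 n = length(x), r_squared = r2)
}

#' Fraction of neurons more similar across valence than across identity
#'
#' Fraction of neurons whose response magnitude to the sucrose-paired ketone
#' is closer to the sucrose-paired terpene (same contingency, different
#' structure) than to the control ketone (same structure, different
#' contingency), overall and above magnitude thresholds.
#'
#' @param rm Output of [response_magnitude()].
#' @param target,same_valence,same_structure Contingency labels (defaults
#'   `"S_K"`, `"S_T"`, `"X_K"`).
#' @param thresholds Magnitude thresholds applied to `|ddff(target)|`.
#' @param scaled Use scaled ddF/F.
#' @return A tibble per threshold: `n`, `fraction_valence_closer`.
#' @export
ddff_closeness <- function(rm, target = "S_K", same_valence = "S_T",
                           same_structure = "X_K",
                           thresholds = 0, scaled = TRUE) {
  col <- if (scaled) "ddff_scaled" else "ddff"
  wide <- tidyr::pivot_wider(rm[, c("neuron", "contingency", col)],
                             names_from = "contingency",
                             values_from = dplyr::all_of(col))
  t0 <- wide[[target]]; sv <- wide[[same_valence]]; ss <- wide[[same_structure]]
  keep <- is.finite(t0) & is.finite(sv) & is.finite(ss)
  purrr::map_dfr(thresholds, function(th) {
    k <- keep & abs(t0) >= th
    tibble::tibble(
      threshold = th, n = sum(k),
      fraction_valence_closer = mean(abs(t0 - sv)[k] < abs(t0 - ss)[k])
    )
  })
}
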