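#' Synthesize a full recording session
#'
#' Builds a fluorescence matrix plus behavior streams (licks, locomotion,
#' face features) from a trial schedule and a ground-truth population. Each
#' neuron's trace is
#' `F = F0 * (1 + drift) + amplitude * (drive * kernel) + noise`, truncated at
#' zero, where `drive` is the class-specific spike drive (odor boxcars scaled
#' by tuning, sucrose/airpuff US drives, lick-bout impulses), `kernel` is a
#' difference-of-exponentials calcium kernel normalised to unit area, `drift`
#' is a slow Ornstein-Uhlenbeck baseline wander and `noise` is white Gaussian.
#' Odor-locked drive carries a per-trial multiplicative gain (log-normal) so
#' trial-to-trial response variability resembles real calcium data.
#'
#' Licking is an inhomogeneous Poisson process: a low spontaneous rate, an
#' anticipatory ramp over the final odor second toward reward-predicting
#' odors (scaled by reward probability and a day-dependent learning factor),
#' and a consummatory bout after sucrose. When the lick spout is retracted
#' (lick/no-lick paradigm) anticipatory licking is suppressed until the spout
#' returns, delaying it by about a second. Face features are noisy
#' deterministic functions of the instantaneous lick state.
#'
#' @param schedule A schedule from [build_conditioning_schedule()].
#' @param population A population from [sample_ground_truth_population()].
#' @param seed Optional integer seed; the session is bit-reproducible under a
#'   fixed seed.
#' @param frame_rate_hz Imaging frame rate (Hz).
#' @param tail_s Recording time after the final trial.
#' @param trial_gain_sdlog Log-normal sd of the per-trial response gain
#'   (one shared draw per trial plus an independent draw per neuron).
#' @param valence_state_sd Sd of a per-trial additive fluctuation along the
#'   population's sucrose-template pattern, present on every trial.
#'   Correlated across neurons, it limits how well reward contingency can
#'   be read out from the population no matter how many neurons are pooled
#'   (information-limiting variability).
#' @param identity_pattern_sd Sd of per-trial odor-pattern mixing noise for
#'   identity neurons: each trial's drive mixes in random amounts of the
#'   other odors' identity patterns, limiting population identity decoding
#'   the same way.
#' @param lick_base_rate,lick_peak_rate Spontaneous / peak anticipatory lick
#'   rates (licks per second).
#' @param consummatory_rate,consummatory_s Lick rate and duration after
#'   sucrose delivery.
#' @param animal_id Label carried through to outputs.
#' @return A `recording_session`: list with elements `F` (neurons x frames),
#'   `frame_rate_hz`, `schedule`, `licks` (counts per frame), `locomotion`,
#'   `face` (frames x 6: tongue-tip confidence, mouth-corner confidence,
#'   upper/lower lip x,y), `region`, `animal_id`, `day`, and the
#'   `ground_truth` population.
#' @export
synthesize_session <- function(schedule, population, seed = NULL,
                               frame_rate_hz = 5,
                               tail_s = 15,
                               trial_gain_sdlog = 0.3,
                               valence_state_sd = 0.35,
                               identity_pattern_sd = 0.8,
                               lick_base_rate = 0.1,
                               lick_peak_rate = 6,
                               consummatory_rate = 7,
                               consummatory_s = 1.5,
                               animal_id = "sim01") {
  if (frame_rate_hz <= 0) abort("`frame_rate_hz` must be positive")
  if (any(population$tau_rise_s <= 0) || any(population$tau_decay_s <= 0)) {
    abort("calcium kernel constants must be positive")
  }
  fs <- frame_rate_hz
  config <- attr(population, "config")
  day <- schedule$day[1]
  paradigm <- attr(schedule, "paradigm") %||% "six_odor"

  t_end <- max(schedule$offset_s, schedule$us_time_s, na.rm = TRUE) + tail_s
  n_frames <- frame_of_time(t_end, fs)
  n_neurons <- nrow(population)
  frame_t <- (seq_len(n_frames) - 1) / fs  # frame start times

  with_seed(seed, {
    ## ---- licking --------------------------------------------------------
    rate <- rep(lick_base_rate, n_frames)
    learn <- lick_learning_factor(day, paradigm)
    odor_dur <- attr(schedule, "odor_duration_s") %||% 2
    for (i in seq_len(nrow(schedule))) {
      tr <- schedule[i, ]
      p <- tr$reward_probability
      if (p > 0) {
        ramp_start <- tr$offset_s - 1
        ramp_end <- tr$offset_s
        hold_end <- if (!is.na(tr$us_time_s)) tr$us_time_s else tr$offset_s + 0.3
        idx <- frames_in_window(ramp_start, hold_end, fs) + 1L
        idx <- idx[idx >= 1 & idx <= n_frames]
        tt <- frame_t[idx]
        r <- lick_peak_rate * learn * p *
          pmin(1, pmax(0, (tt - ramp_start) / (ramp_end - ramp_start)))
        # spout-absent odors: no contact licking until the spout returns
        if (!tr$spout_present && !is.na(tr$spout_return_s)) {
          r[tt < tr$spout_return_s] <- 0
        }
        rate[idx] <- rate[idx] + r
      }
      if (!is.na(tr$us_time_s) && tr$us_type == "sucrose") {
        idx <- frames_in_window(tr$us_time_s, tr$us_time_s + consummatory_s,
                                fs) + 1L
        idx <- idx[idx >= 1 & idx <= n_frames]
        rate[idx] <- rate[idx] + consummatory_rate
      }
    }
    licks <- rpois(n_frames, rate / fs)

    # lick-bout onsets: a licked frame preceded by >= 3 silent frames
    licked <- licks > 0
    onset_imp <- numeric(n_frames)
    gap <- 3L
    for (f in which(licked)) {
      prev <- max(1L, f - gap):(f - 1L)
      if (f == 1L || !any(licked[prev])) onset_imp[f] <- 1
    }

    ## ---- stimulus drive -------------------------------------------------
    trial_gain <- rlnorm(nrow(schedule), 0, trial_gain_sdlog)
    odor_box <- matrix(0, n_frames, 6)
    us_suc <- numeric(n_frames)
    us_puff <- numeric(n_frames)
    cs_box <- numeric(n_frames)
    for (i in seq_len(nrow(schedule))) {
      tr <- schedule[i, ]
      g <- trial_gain[i]
      idx <- frames_in_window(tr$onset_s, tr$offset_s, fs) + 1L
      idx <- idx[idx >= 1 & idx <= n_frames]
      odor_box[idx, tr$odor_id] <- odor_box[idx, tr$odor_id] + g
      if (tr$reward_probability > 0) cs_box[idx] <- cs_box[idx] + g
      if (!is.na(tr$us_time_s)) {
        if (tr$us_type == "sucrose") {
          uidx <- frames_in_window(tr$us_time_s, tr$us_time_s + 1, fs) + 1L
          uidx <- uidx[uidx >= 1 & uidx <= n_frames]
          us_suc[uidx] <- us_suc[uidx] + 2 * g
        } else if (tr$us_type == "airpuff") {
          uidx <- frames_in_window(tr$us_time_s, tr$us_time_s + 0.4, fs) + 1L
          uidx <- uidx[uidx >= 1 & uidx <= n_frames]
          us_puff[uidx] <- us_puff[uidx] + 2 * g
        }
      }
    }

    tuning <- effective_tuning(population, schedule)
    drive <- tuning %*% t(odor_box)  # neurons x frames, odor-locked part
    cs_day <- if (!is.null(config)) config$cs_gain_day else 3L
    cs_rows <- population$class == "us_sucrose" & population$cs_gain &
      day >= cs_day
    if (any(cs_rows)) {
      drive[cs_rows, ] <- sweep(drive[cs_rows, , drop = FALSE], 2, cs_box, "+")
    }
    # Per-trial response variability on the odor-locked drive:
    # (1) independent per-neuron multiplicative gain;
    # (2) a correlated fluctuation along the sucrose-template pattern on
    #     every trial (so reward-pattern activity also fluctuates on
    #     unrewarded trials);
    # (3) odor-pattern mixing noise for identity neurons.
    # (2) and (3) are correlated across neurons and therefore cap the
    # population decoding accuracy (information-limiting variability).
    s_cols <- which(vapply(1:6, function(o) {
      rows <- schedule$odor_id == o
      any(rows) && schedule$reward_probability[rows][1] > 0
    }, logical(1)))
    id_rows <- which(population$class == "identity")
    s_template <- if (length(s_cols)) {
      rowMeans(tuning[, s_cols, drop = FALSE])
    } else numeric(n_neurons)
    # the value-state fluctuation rides on value-coding classes only
    s_template[id_rows] <- 0
    for (i in seq_len(nrow(schedule))) {
      idx <- frames_in_window(schedule$onset_s[i], schedule$offset_s[i],
                              fs) + 1L
      idx <- idx[idx >= 1 & idx <= n_frames]
      if (trial_gain_sdlog > 0) {
        g_n <- rlnorm(n_neurons, 0, trial_gain_sdlog)
        drive[, idx] <- drive[, idx] * g_n
      }
      if (valence_state_sd > 0 && length(s_cols)) {
        v_t <- rnorm(1, 0, valence_state_sd)
        drive[, idx] <- drive[, idx] + s_template * v_t
      }
      if (identity_pattern_sd > 0 && length(id_rows)) {
        c_t <- rnorm(6, 0, identity_pattern_sd)
        mix <- as.numeric(tuning[id_rows, , drop = FALSE] %*% c_t)
        drive[id_rows, idx] <- drive[id_rows, idx] + mix
      }
    }
    for (i in seq_len(n_neurons)) {
      cl <- population$class[i]
      if (cl == "us_sucrose") {
        drive[i, ] <- drive[i, ] + us_suc
      } else if (cl == "salience") {
        drive[i, ] <- drive[i, ] + us_puff
      } else if (cl == "lick") {
        drive[i, ] <- drive[i, ] + 5 * onset_imp
      }
    }

    ## ---- calcium convolution, drift, noise ------------------------------
    F <- matrix(0, n_neurons, n_frames)
    a_drift <- exp(-1 / (population$drift_tau_s * fs))
    for (i in seq_len(n_neurons)) {
      k <- calcium_kernel(population$tau_rise_s[i], population$tau_decay_s[i], fs)
      conv <- convolve_causal(drive[i, ], k)
      amp <- population$amplitude[i]
      f0 <- population$f0[i]
      a <- a_drift[i]
      innov_sd <- population$drift_amp[i] * sqrt(1 - a^2)
      drift <- as.numeric(stats::filter(rnorm(n_frames, 0, innov_sd),
                                        a, method = "recursive"))
      noise <- if (population$noise_sd[i] > 0) {
        rnorm(n_frames, 0, population$noise_sd[i])
      } else 0
      F[i, ] <- pmax(0, f0 * (1 + drift) + amp * conv + noise)
    }

    ## ---- face features and locomotion -----------------------------------
    lick_state <- as.numeric(licks > 0)
    clip01 <- function(x) pmin(1, pmax(0, x))
    face <- cbind(
      tongue_conf = clip01(0.05 + 0.9 * lick_state + rnorm(n_frames, 0, 0.08)),
      mouth_conf = clip01(0.10 + 0.8 * lick_state + rnorm(n_frames, 0, 0.08)),
      upper_x = rnorm(n_frames, 0, 0.1),
      upper_y = rnorm(n_frames, 0, 0.1),
      lower_x = rnorm(n_frames, 0, 0.1),
      lower_y = 2 + 3 * lick_state + rnorm(n_frames, 0, 0.1)
    )
    a_loc <- exp(-1 / (20 * fs))
    locomotion <- as.numeric(stats::filter(
      rnorm(n_frames, 0, sqrt(1 - a_loc^2)), a_loc, method = "recursive"))

    structure(list(
      F = F,
      frame_rate_hz = fs,
      schedule = schedule,
      licks = licks,
      locomotion = locomotion,
      face = face,
      region = if (!is.null(config)) config$region else "VP",
      animal_id = animal_id,
      day = day,
      ground_truth = population
    ), class = "recording_session")
  })
}

# Day-dependent anticipatory-licking learning factor. Days 1-3: acquisition;
# days 4-6: re-acquisition after the contingency switch.
lick_learning_factor <- function(day, paradigm) {
  if (paradigm == "lick_nolick") return(1)
  curve <- c(0.05, 0.6, 1, 0.5, 0.8, 1)
  curve[min(max(day, 1), length(curve))]
}

# Difference-of-exponentials kernel, unit area (so a sustained unit drive
# produces a unit-amplitude plateau).
calcium_kernel <- function(tau_rise_s, tau_decay_s, fs) {
  if (tau_rise_s <= 0 || tau_decay_s <= 0) {
    abort("kernel constants must be positive")
  }
  t <- seq(0, 6 * tau_decay_s, by = 1 / fs)
  k <- exp(-t / tau_decay_s) - exp(-t / tau_rise_s)
  k / sum(k)
}

convolve_causal <- function(x, k) {
  n <- length(x)
  L <- length(k)
  padded <- c(rep(0, L - 1), x)
  out <- stats::filter(padded, k, method = "convolution", sides = 1)
  as.numeric(out[(L - 1) + seq_len(n)])
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "<recording_session> %s | %d neurons x %d frames @ %g Hz | day %d | %d trials\n",
    x$region, nrow(x$F), ncol(x$F), x$frame_rate_hz, x$day, nrow(x$schedule)))
  invisible(x)
}
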