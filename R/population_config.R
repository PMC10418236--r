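#' Configuration for a synthetic ground-truth population
#'
#' Defines the mixture of encoding classes and the per-neuron amplitude,
#' kinetics, baseline and noise distributions used by
#' [sample_ground_truth_population()]. Class semantics:
#'
#' * `valence_pos` / `valence_neg`: loading on a single shared
#'   reward-contingency template - the response weight on each odor equals its
#'   reward probability (1 for sucrose-paired odors in the six-odor paradigm),
#'   with near-equal weights on same-contingency odors up to `valence_jitter`.
#'   The population signal these neurons carry is rank one per sign.
#' * `identity`: independent sparse tuning drawn per odor (full-rank across
#'   the population).
#' * `lick`: driven by lick-bout onsets, not odors.
#' * `us_sucrose`: driven by sucrose delivery; a configurable fraction
#'   (`cs_gain_fraction`) additionally acquires a conditioned-stimulus
#'   response to sucrose-paired odors from `cs_gain_day` onwards, emulating
#'   reward-responsive neurons that become reward-cue responsive.
#' * `salience`: equal response to sucrose- and airpuff-paired odors plus a
#'   brief airpuff-US drive (the only aversive drive by default).
#' * `silent`: no stimulus-locked drive.
#'
#' Region presets: `"VP"` is valence-dominated (total valence fraction 0.5,
#' low-rank signal), `"OT_D1"` and `"OT_D2"` are identity-dominated with
#' full-rank tuning, `"identity_only"` is a pure identity population.
#'
#' @param n_neurons Number of neurons.
#' @param region Preset name (`"VP"`, `"OT_D1"`, `"OT_D2"`, `"identity_only"`)
#'   used when `fractions` is `NULL`, and carried as a label.
#' @param fractions Named numeric vector of class fractions summing to 1.
#' @param exact_fractions If `TRUE`, class counts are fixed by largest-remainder
#'   rounding instead of a multinomial draw.
#' @param paradigm Paradigm the population will be recorded in (sets how
#'   valence weights map onto odors).
#' @param amplitude_gain_meanlog,amplitude_gain_sdlog Log-normal parameters of
#'   the response gain (peak calcium transient as a fraction of baseline F0).
#' @param f0_range Uniform range of baseline fluorescence (arbitrary units).
#' @param tau_rise_s,tau_decay_s Calcium kernel rise / decay constants
#'   (jGCaMP7s-like defaults).
#' @param tau_decay_sd_s Between-neuron standard deviation of the decay.
#' @param drift_amp Baseline drift amplitude as a fraction of F0.
#' @param drift_tau_s Baseline drift (Ornstein-Uhlenbeck) timescale.
#' @param noise_frac Per-frame Gaussian noise s.d. as a fraction of F0.
#' @param valence_jitter Multiplicative jitter on valence weights.
#' @param identity_sparsity Probability an identity neuron responds to a
#'   given odor at all.
#' @param identity_inhibitory Probability a responding identity neuron's
#'   weight on a given odor is inhibitory (odor-evoked suppression).
#' @param cs_gain_fraction Fraction of `us_sucrose` neurons that acquire CS
#'   responses.
#' @param cs_gain_day First day on which acquired CS responses are expressed.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_neurons = 130L,
                              region = c("VP", "OT_D1", "OT_D2", "identity_only"),
                              fractions = NULL,
                              exact_fractions = FALSE,
                              paradigm = c("six_odor", "lick_nolick"),
                              amplitude_gain_meanlog = log(0.8),
                              amplitude_gain_sdlog = 0.3,
                              f0_range = c(50, 150),
                              tau_rise_s = 0.2,
                              tau_decay_s = 1.7,
                              tau_decay_sd_s = 0.15,
                              drift_amp = 0.05,
                              drift_tau_s = 100,
                              noise_frac = 0.03,
                              valence_jitter = 0.02,
                              identity_sparsity = 0.5,
                              identity_inhibitory = 0.3,
                              cs_gain_fraction = 0.5,
                              cs_gain_day = 3L) {
  region <- match.arg(region)
  paradigm <- match.arg(paradigm)
  if (is.null(fractions)) fractions <- region_class_fractions(region)
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("class `fractions` must sum to 1 (tolerance 1e-9)")
  }
  if (any(fractions < 0)) abort("class `fractions` must be non-negative")
  unknown <- setdiff(names(fractions), encoding_classes())
  if (length(unknown)) {
    abort(paste0("unknown encoding class(es): ", paste(unknown, collapse = ", ")))
  }
  structure(list(
    n_neurons = as.integer(n_neurons), region = region,
    fractions = fractions, exact_fractions = exact_fractions,
    paradigm = paradigm,
    amplitude_gain_meanlog = amplitude_gain_meanlog,
    amplitude_gain_sdlog = amplitude_gain_sdlog,
    f0_range = f0_range, tau_rise_s = tau_rise_s,
    tau_decay_s = tau_decay_s, tau_decay_sd_s = tau_decay_sd_s,
    drift_amp = drift_amp, drift_tau_s = drift_tau_s,
    noise_frac = noise_frac, valence_jitter = valence_jitter,
    identity_sparsity = identity_sparsity,
    identity_inhibitory = identity_inhibitory,
    cs_gain_fraction = cs_gain_fraction,
    cs_gain_day = as.integer(cs_gain_day)
  ), class = "population_config")
}

encoding_classes <- function() {
  c("valence_pos", "valence_neg", "identity", "lick", "us_sucrose",
    "salience", "silent")
}

region_class_fractions <- function(region) {
  switch(region,
    VP = c(valence_pos = 0.35, valence_neg = 0.15,
           lick = 0.15, us_sucrose = 0.15, salience = 0.05, silent = 0.15),
    OT_D1 = c(valence_pos = 0.10, valence_neg = 0.02, identity = 0.63,
              lick = 0.05, us_sucrose = 0.05, salience = 0.05, silent = 0.10),
    OT_D2 = c(valence_pos = 0.03, valence_neg = 0.02, identity = 0.70,
              lick = 0.05, us_sucrose = 0.05, salience = 0.05, silent = 0.10),
    identity_only = c(identity = 1),
    abort(paste0("unknown region preset: ", region))
  )
}

#' Sample a ground-truth population
#'
#' Draws per-neuron encoding classes and response parameters from a
#' [population_config()]. Class counts follow a multinomial draw, or exact
#' largest-remainder rounding of the fractions when `exact_fractions` is set.
#'
#' @param config A [population_config()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per neuron: `neuron`, `class`,
#'   `valence_loading` (signed loading on the shared contingency template;
#'   0 for non-valence classes), identity tuning weights
#'   `tuning_1`..`tuning_6` (per odor id; nonzero only for identity
#'   neurons), tuning jitter `jitter_1`..`jitter_6` (multiplicative, applied
#'   to contingency-resolved weights), `amplitude` (fluorescence units),
#'   `f0`, `tau_rise_s`, `tau_decay_s`, `drift_amp`, `drift_tau_s`,
#'   `noise_sd`, `cs_gain` (logical). Contingency-dependent tuning is
#'   resolved against a specific schedule by [effective_tuning()]. The
#'   config is attached as attribute `config`.
#' @export
sample_ground_truth_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_neurons
  cls_names <- names(config$fractions)
  with_seed(seed, {
    if (isTRUE(config$exact_fractions)) {
      counts <- largest_remainder_counts(config$fractions, n)
      classes <- sample(rep(cls_names, counts))
    } else {
      classes <- sample(cls_names, n, replace = TRUE, prob = config$fractions)
    }

    # Identity tuning is a fixed property of each neuron (per odorant);
    # valence/salience tuning is a *role* tuning resolved against the
    # session's contingency map at synthesis time, so the same neuron
    # follows the reassigned contingencies after the mid-course switch.
    tuning <- matrix(0, n, 6)
    jitter <- matrix(1, n, 6)
    loading <- numeric(n)
    for (i in seq_len(n)) {
      cl <- classes[i]
      if (cl %in% c("valence_pos", "valence_neg")) {
        loading[i] <- if (cl == "valence_pos") 1 else -1
        jitter[i, ] <- 1 + rnorm(6, 0, config$valence_jitter)
      } else if (cl == "identity") {
        on <- runif(6) < config$identity_sparsity
        if (!any(on)) on[sample.int(6, 1)] <- TRUE
        sgn <- sample(c(1, -1), 6, replace = TRUE,
                      prob = c(1 - config$identity_inhibitory,
                               config$identity_inhibitory))
        w <- rexp(6) * on * sgn
        tuning[i, ] <- w / max(abs(w))
      } else if (cl == "salience") {
        jitter[i, ] <- 1 + rnorm(6, 0, config$valence_jitter)
      }
      # lick / us_sucrose / silent: no odor drive through `tuning`
    }

    cs_gain <- classes == "us_sucrose" &
      runif(n) < config$cs_gain_fraction

    pop <- tibble::tibble(
      neuron = seq_len(n),
      class = classes,
      valence_loading = loading,
      amplitude_gain = rlnorm(n, config$amplitude_gain_meanlog,
                              config$amplitude_gain_sdlog),
      f0 = runif(n, config$f0_range[1], config$f0_range[2]),
      tau_rise_s = rep(config$tau_rise_s, n),
      tau_decay_s = pmax(0.3, rnorm(n, config$tau_decay_s,
                                    config$tau_decay_sd_s)),
      drift_amp = rep(config$drift_amp, n),
      drift_tau_s = rep(config$drift_tau_s, n),
      noise_sd = config$noise_frac * runif(n, config$f0_range[1],
                                           config$f0_range[2]),
      cs_gain = cs_gain
    )
    pop$amplitude <- pop$amplitude_gain * pop$f0
    pop$noise_sd <- config$noise_frac * pop$f0
    colnames(tuning) <- paste0("tuning_", 1:6)
    colnames(jitter) <- paste0("jitter_", 1:6)
    pop <- dplyr::bind_cols(pop, tibble::as_tibble(tuning),
                            tibble::as_tibble(jitter))
    attr(pop, "config") <- config
    pop
  })
}

#' Resolve a population's odor tuning against a schedule
#'
#' Valence neurons weight each odor by its current reward probability
#' (times their signed loading and per-odor jitter); salience neurons weight
#' each odor by `max(reward probability, airpuff pairing)`; identity neurons
#' keep their fixed per-odorant tuning; other classes have no odor drive.
#'
#' @param population A ground-truth population.
#' @param schedule A trial schedule (defines the contingency map).
#' @return A neurons x 6 matrix of drive weights per odor id.
#' @export
effective_tuning <- function(population, schedule) {
  p <- av <- numeric(6)
  for (o in 1:6) {
    rows <- schedule$odor_id == o
    if (!any(rows)) next
    p[o] <- schedule$reward_probability[rows][1]
    av[o] <- as.numeric(any(schedule$us_type[rows] == "airpuff"))
  }
  tuning <- as.matrix(population[, paste0("tuning_", 1:6)])
  jitter <- as.matrix(population[, paste0("jitter_", 1:6)])
  W <- matrix(0, nrow(population), 6)
  for (i in seq_len(nrow(population))) {
    cl <- population$class[i]
    if (cl %in% c("valence_pos", "valence_neg")) {
      W[i, ] <- population$valence_loading[i] * p * jitter[i, ]
    } else if (cl == "salience") {
      W[i, ] <- pmax(p, av) * jitter[i, ]
    } else if (cl == "identity") {
      W[i, ] <- tuning[i, ]
    }
  }
  W
}

largest_remainder_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_idx <- order(raw - counts, decreasing = TRUE)
    counts[order_idx[seq_len(rem)]] <- counts[order_idx[seq_len(rem)]] + 1
  }
  as.integer(counts)
}
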