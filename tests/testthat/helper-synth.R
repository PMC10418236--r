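# Shared fixtures, built in code. Sizes are kept small: the goal is to
# exercise every code path, not to reproduce full-cohort statistics.

tiny_session <- function(n_neurons = 12, n_blocks = 3, day = 6, seed = 42,
                         region = "VP", paradigm = "six_odor",
                         noise_frac = 0.03, ...) {
  seeds <- odorvalence:::derive_seeds(seed, 3)
  sched <- build_conditioning_schedule(paradigm, n_blocks = n_blocks,
                                       day = day, seed = seeds[1])
  pop <- sample_ground_truth_population(
    population_config(n_neurons = n_neurons, region = region,
                      paradigm = paradigm, noise_frac = noise_frac, ...),
    seed = seeds[2])
  synthesize_session(sched, pop, seed = seeds[3])
}

# session -> trial tensor using a light baseline window (sessions are short)
tiny_tensor <- function(session, window_frames = 400, stride_frames = 100) {
  session <- preprocess_session(session, window_frames = window_frames,
                                stride_frames = stride_frames)
  epoch_trials(session)
}

# hand-built trial tensor: values array plus minimal labels, bypassing the
# generator entirely (for closed-form/oracle tests)
manual_tensor <- function(values, contingency, fs = 5,
                          rel_frames = -10:24,
                          reward_probability = NULL) {
  n_trials <- dim(values)[2]
  stopifnot(length(contingency) == n_trials,
            dim(values)[3] == length(rel_frames))
  p_map <- c(S_K = 1, S_T = 1, X_K = 0, X_T = 0, P_K = 0, P_T = 0,
             L_hi = 1, L_lo = 0.5, L_X = 0, N_hi = 1, N_lo = 0.5, N_X = 0)
  rp <- reward_probability %||% unname(p_map[contingency])
  trials <- tibble::tibble(
    trial = seq_len(n_trials),
    odor_id = as.integer(factor(contingency)),
    contingency = contingency,
    reward_probability = rp,
    onset_s = 20 * seq_len(n_trials),
    us_type = ifelse(rp >= 1, "sucrose", "none"),
    us_time_s = ifelse(rp >= 1, 20 * seq_len(n_trials) + 2.2, NA_real_),
    onset_frame = odorvalence:::frame_of_time(20 * seq_len(n_trials), fs)
  )
  structure(list(values = values, rel_frames = rel_frames, trials = trials,
                 frame_rate_hz = fs, n_dropped = 0L),
            class = "trial_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stack two neuron x trial x frame arrays along the neuron axis
abind_neurons <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# brute-force auROC: count concordant pairs, midrank ties
brute_auroc <- function(x_pos, x_neg) {
  tot <- 0
  for (a in x_pos) for (b in x_neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(x_pos) * length(x_neg))
}

# Holm-Bonferroni rejections by explicit threshold enumeration
brute_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) reject[ord[k]] <- TRUE else break
  }
  reject
}
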