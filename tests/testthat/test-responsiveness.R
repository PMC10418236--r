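test_that("Holm-Bonferroni agrees with explicit threshold enumeration", {
  # deterministic example: alpha/(m-k+1) thresholds over m = 10 frames
  p <- c(0.004, 0.006, 0.008, 0.02, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
  expect_equal(which(p.adjust(p, "holm") <= 0.05), which(brute_holm(p)))
  # 0.004 <= 0.05/10 rejects; 0.006 > 0.05/9 stops the step-down
  expect_equal(which(brute_holm(p)), 1L)

  # random p-vectors: p.adjust path == enumeration oracle
  set.seed(41)
  for (i in 1:200) {
    p <- runif(10)^sample(1:4, 1)
    expect_equal(p.adjust(p, "holm") <= 0.05, brute_holm(p))
  }

  # all tiny p-values are all rejected
  expect_true(all(brute_holm(rep(1e-6, 10))))
})

test_that("framewise test finds no significant frames on exchangeable data", {
  set.seed(42)
  values <- array(rnorm(2 * 24 * 35), dim = c(2, 24, 35))
  cont <- rep(c("S_K", "S_T"), each = 12)
  tens <- manual_tensor(values, cont)
  tests <- framewise_response_test(tens)
  expect_true(all(tests$p > 0))
  expect_lt(mean(tests$significant), 0.05)
  calls <- call_responsiveness(tests)
  expect_false(any(calls$responsive))
})

test_that("the >=4 significant frame rule and direction labels", {
  # neuron strongly excited on 5 frames of odor S_K only
  set.seed(43)
  values <- array(rnorm(2 * 24 * 35, 0, 0.1), dim = c(2, 24, 35))
  cont <- rep(c("S_K", "S_T"), each = 12)
  values[1, 1:12, 14:18] <- values[1, 1:12, 14:18] + 3  # rel frames 3..7
  values[2, 1:12, 14:16] <- values[2, 1:12, 14:16] + 3  # only 3 frames
  tens <- manual_tensor(values, cont)
  calls <- call_responsiveness(framewise_response_test(tens))
  c1 <- calls[calls$neuron == 1 & calls$contingency == "S_K", ]
  expect_true(c1$responsive)
  expect_equal(c1$direction, "excited")
  c2 <- calls[calls$neuron == 2 & calls$contingency == "S_K", ]
  expect_false(c2$responsive)  # 3 significant frames are not enough
  # inhibition is labelled as such
  values[1, 1:12, 14:18] <- values[1, 1:12, 14:18] - 6
  calls2 <- call_responsiveness(framewise_response_test(
    manual_tensor(values, cont)))
  expect_equal(calls2$direction[calls2$neuron == 1 &
                                  calls2$contingency == "S_K"], "inhibited")
})

test_that("responsiveness calls are invariant to trial order", {
  ses <- tiny_session(n_neurons = 5, n_blocks = 3, seed = 44)
  tens <- tiny_tensor(ses)
  calls <- call_responsiveness(framewise_response_test(tens))
  perm <- sample(dim(tens$values)[2])
  tens2 <- tens
  tens2$values <- tens$values[, perm, , drop = FALSE]
  tens2$trials <- tens$trials[perm, ]
  calls2 <- call_responsiveness(framewise_response_test(tens2))
  expect_equal(calls, calls2)
})

test_that("responsive-fraction recovery on a high-SNR valence population", {
  sched <- build_conditioning_schedule("six_odor", n_blocks = 30, day = 6,
                                       seed = 45)
  cfg <- population_config(n_neurons = 40,
                           fractions = c(valence_pos = 0.4, silent = 0.6),
                           exact_fractions = TRUE)
  pop <- sample_ground_truth_population(cfg, seed = 46)
  ses <- preprocess_session(synthesize_session(sched, pop, seed = 47),
                            window_frames = 500, stride_frames = 100)
  tens <- epoch_trials(ses)
  calls <- call_responsiveness(framewise_response_test(tens))
  rs <- responsiveness_summary(calls)
  both_s <- rs$categories$pct[rs$categories$category == "both_S_same_direction"]
  expect_lt(abs(both_s - 40), 10)
})

test_that("US-responsive neurons transition to cue responses across days", {
  sched1 <- build_conditioning_schedule("six_odor", n_blocks = 15, day = 1,
                                        seed = 48)
  sched3 <- build_conditioning_schedule("six_odor", n_blocks = 15, day = 3,
                                        seed = 49)
  cfg <- population_config(n_neurons = 30,
                           fractions = c(us_sucrose = 0.6, silent = 0.4),
                           exact_fractions = TRUE, cs_gain_fraction = 0.5,
                           cs_gain_day = 3)
  pop <- sample_ground_truth_population(cfg, seed = 50)
  mk <- function(sch, seed) {
    ses <- preprocess_session(synthesize_session(sch, pop, seed = seed),
                              window_frames = 500, stride_frames = 100)
    epoch_trials(ses)
  }
  t1 <- mk(sched1, 51)
  t3 <- mk(sched3, 52)
  matching <- tibble::tibble(day1 = 1:30, day3 = 1:30)
  res <- cross_day_transition(t1, t3, matching)
  # expected fraction: P(us_sucrose) * P(cs_gain) = 0.6 * 0.5 = 0.3
  truth <- mean(pop$class == "us_sucrose" & pop$cs_gain)
  for (o in unique(res$transition$odor_id)) {
    fr <- res$transition$fraction[res$transition$odor_id == o]
    expect_lt(abs(fr - truth), 0.10)
  }
  expect_error(cross_day_transition(t1, t3, matching[0, ]), "empty")
})

test_that("ddF/F identity-line R^2 matches the closed form and orders populations", {
  # exact agreement with direct evaluation on arbitrary data
  set.seed(53)
  rm_tbl <- tibble::tibble(
    neuron = rep(1:50, 3),
    odor_id = rep(1:3, each = 50),
    contingency = rep(c("S_K", "S_T", "X_K"), each = 50),
    ddff = rnorm(150),
    ddff_scaled = rnorm(150)
  )
  r <- ddff_similarity(rm_tbl, c("S_K", "S_T"))
  w <- tidyr::pivot_wider(rm_tbl[, c("neuron", "contingency", "ddff_scaled")],
                          names_from = "contingency",
                          values_from = "ddff_scaled")
  direct <- 1 - sum((w$S_T - w$S_K)^2) / sum((w$S_T - mean(w$S_T))^2)
  expect_equal(r$r_squared, direct)

  # independent x and y: the identity-line model is penalised (R^2 <= 0 on
  # average over simulations)
  r2s <- vapply(1:100, function(s) {
    set.seed(s)
    tb <- tibble::tibble(neuron = rep(1:100, 2), odor_id = rep(1:2, each = 100),
                         contingency = rep(c("S_K", "S_T"), each = 100),
                         ddff = rnorm(200), ddff_scaled = rnorm(200))
    ddff_similarity(tb, c("S_K", "S_T"))$r_squared
  }, numeric(1))
  expect_lt(mean(r2s), 0)

  expect_error(ddff_similarity(rm_tbl[rm_tbl$neuron < 3, ], c("S_K", "S_T")),
               "3 neurons")
})

test_that("valence populations are more similar across S cues than across ketones", {
  ses <- tiny_session(n_neurons = 40, n_blocks = 30, day = 6, seed = 54,
                      region = "VP")
  tens <- tiny_tensor(ses)
  rm_ <- response_magnitude(tens)
  r_ss <- ddff_similarity(rm_, c("S_K", "S_T"))$r_squared
  r_sx <- ddff_similarity(rm_, c("S_K", "X_K"))$r_squared
  expect_gt(r_ss, r_sx)
  cl <- ddff_closeness(rm_, thresholds = c(0, 0.1))
  expect_gt(cl$fraction_valence_closer[1], 0.5)
})
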