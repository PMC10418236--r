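test_that("lick selectivity fractions: all-S licks and uniform licks", {
  sched <- build_conditioning_schedule("six_odor", n_blocks = 5, day = 3,
                                       seed = 111)
  fs <- 5
  n_frames <- odorvalence:::frame_of_time(max(sched$offset_s) + 15, fs)
  licks_s <- integer(n_frames)
  licks_u <- integer(n_frames)
  for (i in seq_len(nrow(sched))) {
    idx <- odorvalence:::frames_in_window(sched$onset_s[i], sched$offset_s[i],
                                          fs) + 1L
    if (grepl("^S_", sched$contingency[i])) licks_s[idx] <- 2
    licks_u[idx] <- 2
  }
  ls <- lick_selectivity(sched, licks_s, fs)
  expect_true(all(abs(ls$trials$s_fraction_ma - 1) < 1e-12))
  # uniform licking: 2 of 6 odors are sucrose-paired -> fraction 1/3
  # (window spanning the whole session, so composition is exact)
  lu <- lick_selectivity(sched, licks_u, fs, ma_window = 2 * nrow(sched))
  expect_true(all(abs(lu$trials$s_fraction_ma - 1 / 3) < 1e-12))
  # no licks at all: fractions undefined and counted
  l0 <- lick_selectivity(sched, integer(n_frames), fs)
  expect_equal(l0$n_undefined, nrow(sched))
})

test_that("moving average: constant series preserved, output within data range", {
  x <- rep(3.5, 20)
  expect_equal(odorvalence:::moving_average(x, 10), x)
  set.seed(112)
  y <- rnorm(50)
  m <- odorvalence:::moving_average(y, 10)
  expect_true(all(m >= min(y) & m <= max(y)))
})

test_that("learned lick selectivity grows from day 1 to day 3", {
  hits <- vapply(1:100, function(s) {
    seeds <- odorvalence:::derive_seeds(s, 4)
    frac_of <- function(day) {
      ses <- tiny_session(n_neurons = 1, n_blocks = 6, day = day,
                          seed = seeds[day])
      ls <- lick_selectivity(ses$schedule, ses$licks, ses$frame_rate_hz)
      mean(ls$trials$s_fraction_ma, na.rm = TRUE)
    }
    frac_of(3) > frac_of(1)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("lip distance is the plain Euclidean distance", {
  face <- cbind(tongue_conf = 0, mouth_conf = 0,
                upper_x = 0, upper_y = 0, lower_x = 3, lower_y = 4)
  expect_equal(lip_distance(face), 5)
})

test_that("face-feature lick detection: strong coupling vs no coupling", {
  ses <- tiny_session(n_neurons = 1, n_blocks = 4, day = 3, seed = 113)
  det <- detect_licks_from_face(ses$face, ses$licks, seed = 114)
  expect_gt(det$cv_accuracy, 0.95)
  pred <- predict_licks(det, ses$face)
  expect_equal(length(pred), nrow(ses$face))

  # features shuffled against labels: accuracy collapses to the class prior
  set.seed(115)
  shuf <- ses$face[sample(nrow(ses$face)), ]
  det0 <- detect_licks_from_face(shuf, ses$licks, seed = 116)
  prior <- max(mean(ses$licks > 0), 1 - mean(ses$licks > 0))
  expect_lt(det0$cv_accuracy, prior + 0.03)
  expect_error(detect_licks_from_face(ses$face, rep(0, nrow(ses$face))),
               "single class")
})

test_that("distributed lag model recovers a pure delay and rejects null coupling", {
  set.seed(117)
  x <- rnorm(2000)
  y <- c(rep(0, 3), x[1:1997])  # y(t) = x(t - 3)
  fit <- dlm_predict(y, x, max_lag_frames = 5)
  top <- fit$coefficients[which.max(abs(fit$coefficients$estimate)), ]
  expect_equal(top$lag, 3)
  expect_gt(fit$r2_oos, 0.99)

  r2s <- vapply(1:100, function(s) {
    set.seed(s)
    dlm_predict(rnorm(400), rnorm(400), max_lag_frames = 5)$r2_oos
  }, numeric(1))
  expect_lte(mean(r2s > 0.05), 0.1)

  # zero lags reduce to a static regression
  fit0 <- dlm_predict(y, x, max_lag_frames = 0)
  expect_equal(nrow(fit0$coefficients), 1)
  expect_error(dlm_predict(rnorm(5), rnorm(5), max_lag_frames = 3),
               "exceeds")
})

test_that("lick-coupled neurons predict lick rate; silent neurons do not", {
  sched <- build_conditioning_schedule("six_odor", n_blocks = 6, day = 3,
                                       seed = 118)
  cfg <- population_config(n_neurons = 2,
                           fractions = c(lick = 0.5, silent = 0.5),
                           exact_fractions = TRUE)
  pop <- sample_ground_truth_population(cfg, seed = 119)
  ses <- preprocess_session(synthesize_session(sched, pop, seed = 120),
                            window_frames = 400, stride_frames = 100)
  lick_n <- which(pop$class == "lick")
  silent_n <- which(pop$class == "silent")
  r_lick <- dlm_predict(as.numeric(ses$licks), ses$dff[lick_n, ],
                        max_lag_frames = 10)$r2_oos
  r_sil <- dlm_predict(as.numeric(ses$licks), ses$dff[silent_n, ],
                       max_lag_frames = 10)$r2_oos
  expect_gt(r_lick, r_sil + 0.05)
})

test_that("omission R^2: constructed dependencies land on the right axis", {
  set.seed(121)
  n <- 120
  ps <- sample(c(0, 0.5, 1), n, replace = TRUE)
  lick <- 2 * sample(c(0, 1), n, replace = TRUE) + rnorm(n, 0, 0.2)
  # pure contingency dependence
  y_v <- 1.5 * ps + rnorm(n, 0, 0.3)
  r_v <- omission_r2(y_v, ps, lick)
  expect_gt(r_v$dr2_valence, 0.5)
  expect_lt(r_v$dr2_licking, 0.1)
  # mirror case: pure licking dependence
  y_l <- 1.5 * lick + rnorm(n, 0, 0.3)
  r_l <- omission_r2(y_l, ps, lick)
  expect_gt(r_l$dr2_licking, 0.5)
  expect_lt(r_l$dr2_valence, 0.1)
  # pure noise: both losses small (small-sample bias only)
  null_dr2 <- vapply(1:100, function(s) {
    set.seed(s)
    y0 <- rnorm(n)
    r <- omission_r2(y0, ps, lick)
    max(r$dr2_valence, r$dr2_licking)
  }, numeric(1))
  expect_lt(mean(null_dr2), 0.05)
  # nested fits: losses are non-negative
  expect_gte(r_v$dr2_valence, -1e-10)
  expect_gte(r_v$dr2_licking, -1e-10)
  # constant regressor flagged
  rc <- omission_r2(y_v, rep(1, n), lick)
  expect_true(rc$constant_regressor)
  expect_error(omission_r2(y_v[1:5], ps[1:5], lick[1:5]), "10 trials")
})

test_that("accuracy-versus-behavior models recover injected effects", {
  set.seed(122)
  n <- 75
  d_lick <- runif(n)
  d_ps <- sample(c(0, 0.5, 1), n, replace = TRUE)
  acc <- 0.5 + 0.3 * d_ps + rnorm(n, 0, 0.05)
  fit <- accuracy_vs_behavior(data.frame(accuracy = acc, d_lick = d_lick,
                                         d_ps = d_ps))
  td <- tidy(fit)
  slope <- td$estimate[td$model == "contingency" & td$term == "d_ps"]
  expect_lt(abs(slope - 0.3), 0.05)
  gl <- glance(fit)
  expect_lt(gl$r_squared[gl$model == "lick"], 0.1)
  expect_gt(gl$r_squared[gl$model == "contingency"], 0.5)

  # constant accuracies: zero slopes and R^2
  fit0 <- accuracy_vs_behavior(data.frame(accuracy = rep(0.7, n),
                                          d_lick = d_lick, d_ps = d_ps))
  gl0 <- glance(fit0)
  expect_true(all(gl0$r_squared == 0))

  # joint dependence: the combined model beats both single models
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    a <- 0.5 + 0.2 * d_ps + 0.15 * d_lick + rnorm(n, 0, 0.05)
    g <- glance(accuracy_vs_behavior(
      data.frame(accuracy = a, d_lick = d_lick, d_ps = d_ps)))
    g$r_squared[g$model == "combined"] > max(g$r_squared[g$model != "combined"])
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  expect_error(accuracy_vs_behavior(
    data.frame(accuracy = acc, d_lick = rep(1, n), d_ps = d_ps)),
    "rank-deficient")
})

test_that("anticipatory window is shared between behavior and decoding", {
  aw <- odorvalence:::anticipatory_window_s()
  expect_equal(aw, c(1.5, 2.5))
  # the same frames at 5 Hz for both modules
  fr <- odorvalence:::frames_in_window(aw[1], aw[2], 5)
  expect_equal(fr, 8:12)
})
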