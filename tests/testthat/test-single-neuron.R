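test_that("rank auROC equals brute-force concordant-pair counting", {
  # frozen worked example: A = {2,4,6}, B = {1,3,5}; concordant pairs are
  # (2>1), (4>1), (4>3), (6>1), (6>3), (6>5) -> 6 of 9
  expect_equal(brute_auroc(c(2, 4, 6), c(1, 3, 5)), 6 / 9)
  x <- c(1, 3, 5, 2, 4, 6)
  pos <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(odorvalence:::rank_auroc(x, pos), 6 / 9)

  # 1,000 random small instances incl. ties (midrank convention)
  set.seed(61)
  for (i in 1:1000) {
    n_a <- sample(2:8, 1); n_b <- sample(2:8, 1)
    vals <- sample(1:6, n_a + n_b, replace = TRUE)  # heavy ties
    pos <- c(rep(TRUE, n_a), rep(FALSE, n_b))
    expect_equal(odorvalence:::rank_auroc(vals, pos),
                 brute_auroc(vals[pos], vals[!pos]))
  }
})

test_that("oriented auROC matches a fitted logistic classifier's ROC", {
  skip_if_not_installed("pROC")
  set.seed(62)
  for (i in 1:25) {
    x <- rnorm(40, mean = ifelse(runif(1) < 0.5, 0.8, -0.8) *
                 rep(c(1, 0), each = 20))
    y <- rep(c(1, 0), each = 20)
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    scores <- predict(fit, type = "link")
    oracle <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                          direction = "<", levels = c(0, 1)))))
    ours <- odorvalence:::oriented_auroc(x, y == 1)$auroc
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("auROC behaves on constructed tensors", {
  # perfectly separated feature -> auROC 1
  values <- array(0, dim = c(1, 24, 35))
  cont <- rep(c("S_K", "X_K"), each = 12)
  values[1, 1:12, 16:20] <- 1 + 0.01 * (1:12)
  tens <- manual_tensor(values, cont)
  r <- single_neuron_auroc(tens, 1, c("X_K", "S_K"))
  expect_equal(r$auroc, 1.0)

  # zero-variance feature -> 0.5 with flag
  values0 <- array(0.3, dim = c(1, 24, 35))
  r0 <- single_neuron_auroc(manual_tensor(values0, cont), 1, c("X_K", "S_K"))
  expect_equal(r0$auroc, 0.5)
  expect_true(r0$zero_variance)

  # invariance to strictly monotone transforms of the per-trial feature
  # (tensor constant within each trial, so the transform is monotone on the
  # window means)
  set.seed(63)
  values3 <- aperm(array(rep(rnorm(24), 35), dim = c(24, 1, 35)), c(2, 1, 3))
  t3 <- manual_tensor(values3, cont)
  a3 <- single_neuron_auroc(t3, 1, c("X_K", "S_K"))$auroc
  t4 <- t3
  t4$values <- exp(3 * t3$values)
  a4 <- single_neuron_auroc(t4, 1, c("X_K", "S_K"))$auroc
  expect_equal(a3, a4)
})

test_that("there are 15 pairs per neuron with 6 odors", {
  ses <- tiny_session(n_neurons = 3, n_blocks = 5, seed = 64)
  tens <- tiny_tensor(ses)
  a <- all_pair_aurocs(tens)
  expect_equal(nrow(a), 3 * 15)
  expect_equal(dplyr::n_distinct(a$pair), 15)
})

test_that("permutation null: determinism, chance-level p, extreme-statistic p", {
  values <- array(0, dim = c(1, 60, 35))
  cont <- rep(c("S_K", "X_K"), each = 30)
  values[1, 1:30, 16:20] <- 1 + 0.01 * (1:30)  # perfect separation
  set.seed(65)
  values[1, , 1:15] <- rnorm(60 * 15)
  tens <- manual_tensor(values, cont)
  r <- auroc_shuffle_null(tens, 1, c("X_K", "S_K"), n_shuffles = 2000,
                          seed = 66)
  expect_equal(r$auroc, 1.0)
  expect_lt(r$p, 1e-3)
  r2 <- auroc_shuffle_null(tens, 1, c("X_K", "S_K"), n_shuffles = 2000,
                           seed = 66)
  expect_identical(r, r2)

  # a chance-level feature has p around 0.5
  valn <- array(rnorm(60 * 35), dim = c(1, 60, 35))
  tn <- manual_tensor(valn, cont)
  obs <- single_neuron_auroc(tn, 1, c("X_K", "S_K"))$auroc
  rn <- auroc_shuffle_null(tn, 1, c("X_K", "S_K"), n_shuffles = 2000,
                           seed = 67)
  expect_gt(rn$p, 0.2)
  expect_error(auroc_shuffle_null(tn, 1, c("X_K", "S_K"), n_shuffles = 50),
               "100")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(68)
  cont <- rep(c("S_K", "X_K"), each = 15)
  ps <- vapply(1:300, function(i) {
    values <- array(rnorm(30 * 35), dim = c(1, 30, 35))
    tens <- manual_tensor(values, cont)
    auroc_shuffle_null(tens, 1, c("X_K", "S_K"), n_shuffles = 199,
                       seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("quadrant categorisation matches its definitions", {
  sc <- tibble::tibble(neuron = 1:4,
                       auroc_intervalence = c(0.9, 0.9, 0.6, 0.6),
                       auroc_intravalence = c(0.6, 0.9, 0.9, 0.6))
  q <- categorize_quadrants(sc, theta = 0.75)
  expect_equal(q$label, c("valence", "identity", "identity_S_only",
                          "uninformative"))
  comp <- quadrant_composition(q)
  expect_equal(comp$fraction, rep(0.25, 4))
  # a stricter threshold can only shrink the valence fraction
  q9 <- categorize_quadrants(sc, theta = 0.95)
  expect_lte(sum(q9$label == "valence"), sum(q$label == "valence"))
})

test_that("true valence neurons land in the valence quadrant", {
  sched <- build_conditioning_schedule("six_odor", n_blocks = 30, day = 6,
                                       seed = 69)
  cfg <- population_config(n_neurons = 30,
                           fractions = c(valence_pos = 0.5, silent = 0.5),
                           exact_fractions = TRUE)
  pop <- sample_ground_truth_population(cfg, seed = 70)
  ses <- preprocess_session(synthesize_session(sched, pop, seed = 71),
                            window_frames = 500, stride_frames = 100)
  tens <- epoch_trials(ses)
  a <- all_pair_aurocs(tens)
  sc <- tibble::tibble(
    neuron = sort(unique(a$neuron)),
    auroc_intervalence = a$auroc[a$pair == "S_K vs X_K"],
    auroc_intravalence = a$auroc[a$pair == "S_K vs S_T"])
  q <- categorize_quadrants(sc)
  val_neurons <- pop$neuron[pop$class == "valence_pos"]
  expect_gte(mean(q$label[q$neuron %in% val_neurons] == "valence"), 0.7)
})

test_that("single-neuron multinomial confusion separates coding schemes", {
  # feature identical across odors -> rows near chance (1/6 each)
  set.seed(72)
  values <- array(rnorm(1 * 60 * 35, 0, 0.3), dim = c(1, 60, 35))
  cont <- rep(c("S_K", "S_T", "X_K", "X_T", "P_K", "P_T"), each = 10)
  tens <- manual_tensor(values, cont)
  m <- single_neuron_mnr_confusion(tens, 1, seed = 73)
  expect_lt(abs(mean(diag(m$confusion)) - 1 / 6), 0.12)

  # one-hot responsive neuron: its odor's row beats the others
  values2 <- values
  values2[1, cont == "P_K", 16:20] <- values2[1, cont == "P_K", 16:20] + 5
  m2 <- single_neuron_mnr_confusion(manual_tensor(values2, cont), 1,
                                    seed = 74)
  expect_gt(m2$confusion["P_K", "P_K"], 0.8)
  expect_gt(m2$confusion["P_K", "P_K"], mean(diag(m2$confusion)[-5]))

  # a valence neuron confuses the two sucrose cues more than the ketones
  values3 <- values
  s_tr <- cont %in% c("S_K", "S_T")
  values3[1, s_tr, 16:20] <- values3[1, s_tr, 16:20] + 4
  m3 <- single_neuron_mnr_confusion(manual_tensor(values3, cont), 1,
                                    seed = 75)
  expect_gt(m3$summary$s_pair_confusion, m3$summary$ketone_confusion)
  expect_error(single_neuron_mnr_confusion(
    manual_tensor(values[, cont != "P_K", , drop = FALSE],
                  cont[cont != "P_K"]), 1), "6 odors")
})
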