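make_pair_tensor <- function(sep, n_per = 30, n_neurons = 8, seed = 1,
                             labels = c("S_K", "X_K")) {
  set.seed(seed)
  cont <- rep(labels, each = n_per)
  values <- array(rnorm(n_neurons * 2 * n_per * 35),
                  dim = c(n_neurons, 2 * n_per, 35))
  mu <- rnorm(n_neurons)
  mu <- sep * mu / sqrt(sum(mu^2))
  for (j in which(cont == labels[1])) values[, j, 16:20] <-
      values[, j, 16:20] + mu
  manual_tensor(values, cont)
}

test_that("widely separated classes decode perfectly; shuffled labels at chance", {
  tens <- make_pair_tensor(sep = 30)
  r <- population_pair_classifier(tens, c("S_K", "X_K"), seed = 2)
  expect_equal(r$accuracy, 1.0)

  accs <- vapply(1:60, function(s) {
    set.seed(s + 500)
    tens0 <- make_pair_tensor(sep = 0, seed = s + 900)
    population_pair_classifier(tens0, c("S_K", "X_K"), seed = s)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.42)
  expect_lt(mean(accs), 0.58)
})

test_that("the SVM-RBF learner also separates and the per-frame variant works", {
  tens <- make_pair_tensor(sep = 30)
  r <- population_pair_classifier(tens, c("S_K", "X_K"), learner = "svm_rbf",
                                  seed = 3)
  expect_gt(r$accuracy, 0.9)
  tc <- population_pair_classifier(tens, c("S_K", "X_K"), per_frame = TRUE,
                                   seed = 4)
  expect_equal(nrow(tc), 35)
  # signal frames (rel 5..9) beat pre-odor frames
  expect_gt(mean(tc$accuracy[tc$rel_frame %in% 5:9]),
            mean(tc$accuracy[tc$rel_frame < 0]) + 0.3)
})

test_that("population permutation null: extreme statistic and determinism", {
  tens <- make_pair_tensor(sep = 30)
  r <- population_shuffle_null(tens, c("S_K", "X_K"), n_shuffles = 200,
                               seed = 5)
  expect_lt(r$p, 0.01)
  r2 <- population_shuffle_null(tens, c("S_K", "X_K"), n_shuffles = 200,
                                seed = 5)
  expect_identical(r, r2)
  expect_error(population_shuffle_null(tens, c("S_K", "X_K"),
                                       n_shuffles = 10), "100")
})

test_that("population null p-values are calibrated across sessions", {
  ps <- vapply(1:40, function(s) {
    tens0 <- make_pair_tensor(sep = 0, n_per = 12, n_neurons = 5,
                              seed = s + 2000)
    population_shuffle_null(tens0, c("S_K", "X_K"), n_shuffles = 199,
                            seed = s)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("765 pairwise classifier jobs for 17 animals x 3 days x 15 pairs", {
  sessions <- tidyr::crossing(animal = sprintf("m%02d", 1:17), day = c(1, 3, 6))
  grid <- pairwise_classifier_grid(sessions)
  expect_equal(nrow(grid), 765)
  expect_equal(dplyr::n_distinct(grid$pair), 15)
})

test_that("generalization matrix: self-consistency and coding-scheme contrast", {
  ses_v <- tiny_session(n_neurons = 40, n_blocks = 10, day = 6, seed = 81,
                        region = "VP")
  tv <- tiny_tensor(ses_v)
  gv <- generalization_matrix(tv, seed = 82)
  expect_equal(dim(gv$accuracy), c(15, 15))
  # ambiguity flags exactly the transfers with an equal-contingency pair
  iv <- gv$pairs$intervalence
  expect_false(any(gv$ambiguous[iv, iv]))
  expect_true(all(gv$ambiguous[!iv, iv]))
  # valence population generalizes across intervalence pairs
  expect_gt(generalized_valence_score(gv), 0.8)

  ses_i <- tiny_session(n_neurons = 40, n_blocks = 10, day = 6, seed = 83,
                        region = "identity_only")
  ti <- tiny_tensor(ses_i)
  gi <- generalization_matrix(ti, seed = 84)
  expect_lt(generalized_valence_score(gi),
            generalized_valence_score(gv) - 0.1)
})

test_that("PCA-restricted decoding: saturation for rank-1 signal, rotation invariance", {
  # rank-1 valence-like signal across 15 neurons
  set.seed(85)
  n_per <- 25
  cont <- rep(c("S_K", "P_K"), each = n_per)
  values <- array(rnorm(15 * 2 * n_per * 35), dim = c(15, 2 * n_per, 35))
  pattern <- abs(rnorm(15)) + 0.5
  for (j in which(cont == "S_K")) values[, j, 16:20] <-
      values[, j, 16:20] + 3 * pattern
  tens <- manual_tensor(values, cont)
  curve <- pca_restricted_decoding(tens, c("P_K", "S_K"), k_neurons = 15,
                                   n_components = c(1, 15),
                                   n_subsamples = 4, seed = 86)
  a1 <- curve$accuracy[curve$n_components == 1]
  a15 <- curve$accuracy[curve$n_components == 15]
  expect_gt(a1, 0.9)
  expect_lt(abs(a1 - a15), 0.05)

  # high-rank signal: PC1 is not enough
  set.seed(87)
  values2 <- array(rnorm(15 * 2 * n_per * 35), dim = c(15, 2 * n_per, 35))
  # per-neuron independent patterns for the two odors
  for (j in which(cont == "S_K")) values2[, j, 16:20] <-
      values2[, j, 16:20] + rnorm(15, 0, 1.2)
  tens2 <- manual_tensor(values2, cont)
  curve2 <- pca_restricted_decoding(tens2, c("P_K", "S_K"), k_neurons = 15,
                                    n_components = c(1, 15),
                                    n_subsamples = 4, seed = 88)
  expect_gt(curve2$accuracy[curve2$n_components == 15],
            curve2$accuracy[curve2$n_components == 1])
  expect_error(pca_restricted_decoding(tens, c("P_K", "S_K"),
                                       k_neurons = 15, n_components = 16),
               "n_components")
})

test_that("adding pure-noise neurons does not inflate CV accuracy", {
  base <- make_pair_tensor(sep = 2.2, n_neurons = 10, seed = 89)
  acc0 <- population_pair_classifier(base, c("S_K", "X_K"), seed = 90)$accuracy
  set.seed(91)
  noise <- array(rnorm(50 * dim(base$values)[2] * 35),
                 dim = c(50, dim(base$values)[2], 35))
  aug <- base
  aug$values <- abind_neurons(base$values, noise)
  acc1 <- population_pair_classifier(aug, c("S_K", "X_K"), seed = 90)$accuracy
  expect_lt(acc1, acc0 + 0.08)
})

test_that("population multinomial confusion reflects the coding scheme", {
  ses <- tiny_session(n_neurons = 40, n_blocks = 10, day = 6, seed = 92,
                      region = "VP")
  tens <- tiny_tensor(ses)
  m <- population_mnr_confusion(tens, seed = 93)
  expect_equal(dim(m$confusion), c(6, 6))
  expect_equal(unname(rowSums(m$confusion)), rep(1, 6))
  ses_i <- tiny_session(n_neurons = 40, n_blocks = 10, day = 6, seed = 94,
                        region = "identity_only")
  m_i <- population_mnr_confusion(tiny_tensor(ses_i), seed = 95)
  expect_gt(m$summary$s_pair_confusion, m_i$summary$s_pair_confusion)
})
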