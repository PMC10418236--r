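# trials x neurons window-mean design for a set of contingency labels
design_features <- function(tensor, labels = NULL, window_s = c(1, 2)) {
  labs <- tensor$trials
  labels <- labels %||% sort(unique(labs$contingency))
  j <- which(labs$contingency %in% labels)
  means <- window_trial_means(tensor, window_s)
  list(X = t(means[, j, drop = FALSE]),
       y = labs$contingency[j],
       reward_probability = labs$reward_probability[j],
       trial = labs$trial[j])
}

# z-score columns of X with (optionally) supplied statistics
scale_cols <- function(X, center = NULL, scale = NULL) {
  center <- center %||% colMeans(X)
  scale <- scale %||% apply(X, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# Fit a binary classifier. `learner`: "logistic" = ridge-penalised logistic
# regression (small fixed lambda; unpenalised logistic is degenerate when
# neurons outnumber trials), "svm_rbf" = RBF-kernel SVM with C = 1 and
# gamma = 1 / (n_features * mean feature variance).
fit_binary_learner <- function(X, y01, learner = "logistic", lambda = 0.01) {
  X <- pad_design(X)
  if (learner == "logistic") {
    fit <- glmnet::glmnet(X, factor(y01, levels = c(0, 1)),
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = FALSE)
    structure(list(fit = fit), class = "ov_logistic")
  } else if (learner == "svm_rbf") {
    v <- mean(apply(X, 2, var))
    if (!is.finite(v) || v <= 0) v <- 1
    fit <- e1071::svm(X, factor(y01, levels = c(0, 1)), kernel = "radial",
                      cost = 1, gamma = 1 / (ncol(X) * v), scale = FALSE)
    structure(list(fit = fit), class = "ov_svm")
  } else {
    abort(sprintf("unknown learner '%s'", learner))
  }
}

predict_binary <- function(model, X) {
  X <- pad_design(X)
  if (inherits(model, "ov_logistic")) {
    as.integer(predict(model$fit, newx = X, type = "class"))
  } else {
    as.integer(as.character(predict(model$fit, X)))
  }
}

# glmnet needs >= 2 columns; single-neuron populations get a zero pad
pad_design <- function(X) {
  if (ncol(X) >= 2) X else cbind(X, pad__ = 0)
}

# Stratified k-fold CV accuracy with fold-wise feature normalisation
# (training-fold statistics only, to avoid leakage).
cv_accuracy <- function(X, y01, k = 5L, seed = NULL, learner = "logistic",
                        lambda = 0.01, normalize = TRUE) {
  fold <- stratified_folds(y01, k, seed)
  accs <- vapply(seq_len(k), function(fk) {
    tr <- fold != fk
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (normalize) {
      sc <- scale_cols(Xtr)
      Xtr <- sc$X
      Xte <- scale_cols(Xte, sc$center, sc$scale)$X
    }
    model <- fit_binary_learner(Xtr, y01[tr], learner, lambda)
    mean(predict_binary(model, Xte) == y01[!tr])
  }, numeric(1))
  mean(accs)
}

#' Population pairwise classifier (cross-validated accuracy)
#'
#' Trains a binary classifier on the simultaneously recorded population's
#' per-trial window-mean dF/F for one odor pair and reports the mean
#' accuracy over stratified k-fold cross-validation. Features are Z-scored
#' per neuron using training-fold statistics only. With `per_frame = TRUE`
#' a separate classifier is trained at each frame relative to odor onset.
#'
#' @param tensor A `trial_tensor`.
#' @param pair Length-2 character vector of contingency labels.
#' @param learner `"logistic"` (ridge-penalised logistic regression) or
#'   `"svm_rbf"`.
#' @param k Number of CV folds.
#' @param seed Fold seed.
#' @param window_s Response window (seconds relative to odor onset).
#' @param lambda Ridge penalty for the logistic learner.
#' @param per_frame Train one classifier per relative frame instead.
#' @return A tibble with `pair`, `learner`, `n_trials`, `accuracy` (one row,
#'   or one per `rel_frame` when `per_frame`).
#' @export
population_pair_classifier <- function(tensor, pair, learner = "logistic",
                                       k = 5L, seed = NULL,
                                       window_s = c(1, 2), lambda = 0.01,
                                       per_frame = FALSE) {
  d <- design_features(tensor, pair)
  y01 <- as.integer(d$y == pair[2])
  if (min(table(y01)) < k) abort("each class needs at least k trials")
  pair_name <- paste(pair, collapse = " vs ")
  if (!per_frame) {
    d <- design_features(tensor, pair, window_s)
    acc <- cv_accuracy(d$X, y01, k, seed, learner, lambda)
    return(tibble::tibble(pair = pair_name, learner = learner,
                          n_trials = length(y01), accuracy = acc))
  }
  j <- which(tensor$trials$contingency %in% pair)
  purrr::map_dfr(seq_along(tensor$rel_frames), function(fi) {
    v <- tensor$values[, j, fi, drop = FALSE]
    Xf <- t(matrix(v, dim(v)[1], dim(v)[2]))
    tibble::tibble(pair = pair_name, learner = learner,
                   rel_frame = tensor$rel_frames[fi],
                   time_s = tensor$rel_frames[fi] / tensor$frame_rate_hz,
                   accuracy = cv_accuracy(Xf, y01, k, seed, learner, lambda))
  })
}

#' Permutation null for a population pairwise classifier
#'
#' Recomputes the cross-validated accuracy under label shuffles; add-one
#' p-value as in [auroc_shuffle_null()].
#'
#' @inheritParams population_pair_classifier
#' @param n_shuffles Number of label shuffles (>= 100).
#' @return A one-row tibble: `pair`, `accuracy`, `p`, `null_mean`,
#'   `null_sd`, `n_shuffles`.
#' @export
population_shuffle_null <- function(tensor, pair, learner = "logistic",
                                    k = 5L, n_shuffles = 10000L, seed = NULL,
                                    window_s = c(1, 2), lambda = 0.01) {
  if (n_shuffles < 100) abort("`n_shuffles` must be >= 100 for usable p resolution")
  d <- design_features(tensor, pair, window_s)
  y01 <- as.integer(d$y == pair[2])
  seeds <- derive_seeds(seed %||% 0L, n_shuffles + 1L)
  obs <- cv_accuracy(d$X, y01, k, seeds[1], learner, lambda)
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      yp <- sample(y01)
      cv_accuracy(d$X, yp, k, seeds[s + 1L], learner, lambda)
    }, numeric(1))
  })
  tibble::tibble(
    pair = paste(pair, collapse = " vs "), accuracy = obs,
    p = (1 + sum(null >= obs)) / (1 + n_shuffles),
    null_mean = mean(null), null_sd = sd(null), n_shuffles = n_shuffles
  )
}

#' Cross-pair generalization matrix
#'
#' Trains a classifier on each odor pair and tests it on every other pair
#' under the contingency-aligned label mapping: the sucrose-contingent
#' (higher reward probability) class of the training pair maps to the
#' sucrose-contingent class of the testing pair. When either pair has no
#' contingency difference the mapping is ambiguous: both orientations are
#' evaluated, the maximum is reported, and the entry is flagged.
#'
#' Off-diagonal entries must come from models never shown the test pair's
#' trials; because a test pair can share an odor (hence trials) with the
#' training pair, transfer models are trained on a stratified half of each
#' odor's trials and transfer is always evaluated on the held-out half.
#' Diagonal entries hold the within-pair cross-validated accuracy on all
#' trials.
#'
#' @inheritParams population_pair_classifier
#' @param holdout_frac Fraction of trials held out (per odor) for transfer
#'   evaluation.
#' @return A list: `accuracy` (15 x 15 matrix, rows = training pair),
#'   `ambiguous` (logical matrix), `pairs` (tibble of pair metadata).
#'   Use [generalized_valence_score()] for the intervalence block mean.
#' @export
generalization_matrix <- function(tensor, learner = "logistic", k = 5L,
                                  seed = NULL, window_s = c(1, 2),
                                  lambda = 0.01, holdout_frac = 0.5) {
  labs <- tensor$trials
  labels <- sort(unique(labs$contingency))
  if (length(labels) < 6) abort("all 6 odors must be present")
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  np <- length(pairs)
  p_of <- function(lab) labs$reward_probability[match(lab, labs$contingency)]
  pair_meta <- purrr::map_dfr(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    tibble::tibble(index = i, name = paste(p, collapse = " vs "),
                   label_a = p[1], label_b = p[2],
                   p_a = p_of(p[1]), p_b = p_of(p[2]),
                   intervalence = p_of(p[1]) != p_of(p[2]))
  })

  d_all <- design_features(tensor, labels, window_s)
  # stratified train/holdout split per odor, shared by all pairs
  hold <- with_seed(seed, {
    h <- logical(length(d_all$y))
    for (lv in labels) {
      idx <- which(d_all$y == lv)
      h[sample(idx, round(holdout_frac * length(idx)))] <- TRUE
    }
    h
  })

  designs <- purrr::map(pairs, function(p) {
    j <- which(d_all$y %in% p)
    d <- list(X = d_all$X[j, , drop = FALSE], y = d_all$y[j],
              hold = hold[j])
    d$y01 <- as.integer(d$y == p[2])
    # positive class = higher reward probability (NA polarity if equal)
    pa <- p_of(p[1]); pb <- p_of(p[2])
    d$pos_label <- if (pa == pb) NA_character_ else p[which.max(c(pa, pb))]
    d
  })

  acc <- matrix(NA_real_, np, np,
                dimnames = list(train = pair_meta$name, test = pair_meta$name))
  amb <- matrix(FALSE, np, np, dimnames = dimnames(acc))
  seeds <- derive_seeds(seed %||% 0L, np)

  for (i in seq_len(np)) {
    di <- designs[[i]]
    acc[i, i] <- cv_accuracy(di$X, di$y01, k, seeds[i], learner, lambda)
    tr <- !di$hold
    sc <- scale_cols(di$X[tr, , drop = FALSE])
    model <- fit_binary_learner(sc$X, di$y01[tr], learner, lambda)
    for (jj in seq_len(np)) {
      if (jj == i) next
      dj <- designs[[jj]]
      te <- dj$hold
      Xte <- scale_cols(dj$X[te, , drop = FALSE], sc$center, sc$scale)$X
      yte <- dj$y01[te]
      pred <- predict_binary(model, Xte)
      if (is.na(di$pos_label) || is.na(dj$pos_label)) {
        # orientation-ambiguous transfer: report the better mapping
        a1 <- mean(pred == yte)
        acc[i, jj] <- max(a1, 1 - a1)
        amb[i, jj] <- TRUE
      } else {
        # map the trained positive (sucrose-contingent) class onto the test
        # pair's sucrose-contingent class
        train_pos_is_b <- di$pos_label == pairs[[i]][2]
        test_pos_is_b <- dj$pos_label == pairs[[jj]][2]
        y_mapped <- if (test_pos_is_b) yte else 1 - yte
        pred_pos <- if (train_pos_is_b) pred else 1 - pred
        acc[i, jj] <- mean(pred_pos == y_mapped)
      }
    }
  }
  list(accuracy = acc, ambiguous = amb, pairs = pair_meta)
}

#' Mean generalized valence decoding
#'
#' Mean accuracy over the off-diagonal block where both the training and
#' the testing pair have unequal sucrose contingency (intervalence pairs).
#'
#' @param gm Output of [generalization_matrix()].
#' @return A single number.
#' @export
generalized_valence_score <- function(gm) {
  iv <- gm$pairs$index[gm$pairs$intervalence]
  block <- gm$accuracy[iv, iv]
  diag(block) <- NA
  mean(block, na.rm = TRUE)
}

#' PCA-restricted population decoding
#'
#' Subsamples `k_neurons` neurons, projects their (Z-scored) pair design
#' onto an increasing number of principal components and reports the
#' cross-validated accuracy at each dimensionality, averaged over
#' subsamples. If a low-dimensional axis carries the discriminative signal,
#' accuracy saturates with the first component(s).
#'
#' @inheritParams population_pair_classifier
#' @param k_neurons Neurons per subsample.
#' @param n_components Component counts to evaluate.
#' @param n_subsamples Number of random neuron subsamples.
#' @return A tibble: `n_components`, `accuracy` (mean over subsamples).
#' @export
pca_restricted_decoding <- function(tensor, pair, k_neurons = 15L,
                                    n_components = seq_len(15L),
                                    n_subsamples = 20L, learner = "logistic",
                                    k = 5L, seed = NULL, window_s = c(1, 2),
                                    lambda = 0.01) {
  if (max(n_components) > k_neurons) {
    abort("`n_components` cannot exceed `k_neurons`")
  }
  d <- design_features(tensor, pair, window_s)
  if (ncol(d$X) < k_neurons) abort("population smaller than `k_neurons`")
  y01 <- as.integer(d$y == pair[2])
  seeds <- derive_seeds(seed %||% 0L, n_subsamples, salt = 77L)
  res <- purrr::map_dfr(seq_len(n_subsamples), function(s) {
    idx <- with_seed(seeds[s], sample.int(ncol(d$X), k_neurons))
    Xs <- scale_cols(d$X[, idx, drop = FALSE])$X
    pc <- prcomp(Xs, center = TRUE, scale. = FALSE)
    purrr::map_dfr(n_components, function(m) {
      tibble::tibble(
        subsample = s, n_components = m,
        accuracy = cv_accuracy(pc$x[, seq_len(m), drop = FALSE], y01, k,
                               seeds[s], learner, lambda, normalize = FALSE))
    })
  })
  dplyr::summarise(dplyr::group_by(res, .data$n_components),
                   accuracy = mean(.data$accuracy), .groups = "drop")
}

#' Population multinomial (6-odor) confusion matrix
#'
#' Cross-validated multinomial regression on the full population design.
#'
#' @inheritParams population_pair_classifier
#' @param decay Weight decay (ridge) for the multinomial fit.
#' @return As [single_neuron_mnr_confusion()].
#' @export
population_mnr_confusion <- function(tensor, window_s = c(1, 2), k = 5L,
                                     seed = NULL, decay = 0.1) {
  d <- design_features(tensor, NULL, window_s)
  if (dplyr::n_distinct(d$y) < 6) abort("all 6 odors required")
  X <- scale_cols(d$X)$X
  df <- data.frame(y = factor(d$y), X)
  pred <- cv_multinom_predict(df, k, seed, decay = decay)
  confusion_from_predictions(df$y, pred)
}

#' Enumerate pairwise-classifier jobs for a cohort
#'
#' One classifier per odor pair per simultaneously recorded session
#' (animal x day): the full six-odor design yields 15 pairs.
#'
#' @param sessions A tibble with one row per recorded session (columns
#'   `animal`, `day`; other columns carried through).
#' @param labels Contingency labels (default: the six-odor set).
#' @return A tibble with one row per (session, pair) job.
#' @export
pairwise_classifier_grid <- function(sessions,
                                     labels = c("S_K", "S_T", "X_K", "X_T",
                                                "P_K", "P_T")) {
  pairs <- utils::combn(sort(labels), 2, simplify = FALSE)
  pair_tbl <- tibble::tibble(
    pair = vapply(pairs, paste, character(1), collapse = " vs "))
  tidyr::crossing(tibble::as_tibble(sessions), pair_tbl)
}
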