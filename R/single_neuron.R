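# Rank-based auROC with midrank tie handling. `x`: feature values,
# `positive`: logical, TRUE for the positive class. Returns P(score_pos >
# score_neg) + 0.5 * P(tie), i.e. the probability a random positive trial
# outranks a random negative one.
rank_auroc <- function(x, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  r <- rank(x)  # midranks
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Oriented auROC: the auROC of the in-sample 1-D logistic classifier's
# scores. For a monotone 1-D model this is the rank auROC of the feature
# with orientation given by the sign of the fitted coefficient, which equals
# the sign of the feature/label covariance.
oriented_auroc <- function(x, positive) {
  if (length(unique(x)) == 1L) {
    return(list(auroc = 0.5, zero_variance = TRUE))
  }
  u <- rank_auroc(x, positive)
  s <- sign(mean(x[positive]) - mean(x[!positive]))
  auc <- if (s > 0) u else if (s < 0) 1 - u else 0.5
  list(auroc = auc, zero_variance = FALSE)
}

#' Single-neuron pairwise odor discrimination (auROC)
#'
#' For one neuron and one odor pair: per-trial mean dF/F over the response
#' window, Z-scored across the pooled trials of the two odors, scored by an
#' in-sample logistic classifier. For a one-predictor monotone model the
#' classifier's auROC equals the rank auROC of the feature oriented by the
#' fitted coefficient's sign, which is how it is computed (midrank tie
#' convention). Chance is 0.5; 1.0 is perfect discrimination.
#'
#' @param tensor A `trial_tensor`.
#' @param neuron Neuron index.
#' @param pair Length-2 character vector of contingency labels (the second
#'   element is the positive class).
#' @param window_s Response window relative to odor onset (default: last
#'   odor second).
#' @return A one-row tibble: `neuron`, `pair`, `auroc`, `n_trials`,
#'   `zero_variance`.
#' @export
single_neuron_auroc <- function(tensor, neuron, pair, window_s = c(1, 2)) {
  f <- pair_features(tensor, pair, window_s)
  x <- f$X[, neuron]
  res <- oriented_auroc(x, f$positive)
  tibble::tibble(neuron = neuron, pair = paste(pair, collapse = " vs "),
                 auroc = res$auroc, n_trials = length(x),
                 zero_variance = res$zero_variance)
}

# Per-trial window-mean features for the two odors of `pair`, Z-scored over
# the pooled trials. Returns list(X = trials x neurons, positive = logical).
pair_features <- function(tensor, pair, window_s = c(1, 2)) {
  labs <- tensor$trials
  stopifnot(length(pair) == 2)
  j <- which(labs$contingency %in% pair)
  if (min(table(factor(labs$contingency[j], levels = pair))) < 5) {
    abort("both odors need at least 5 trials")
  }
  means <- window_trial_means(tensor, window_s)  # neurons x trials
  X <- t(means[, j, drop = FALSE])
  X <- scale(X)
  X[is.nan(X)] <- 0  # zero-variance features
  list(X = X, positive = labs$contingency[j] == pair[2],
       odor = labs$contingency[j], trial = labs$trial[j])
}

#' auROC for every neuron and every odor pair
#'
#' With 6 odors there are 15 pairs per neuron.
#'
#' @inheritParams single_neuron_auroc
#' @param pairs Optional list of label pairs; defaults to all pairs of
#'   contingency labels present.
#' @return A tibble: `neuron`, `pair`, `odor_a`, `odor_b`, `auroc`,
#'   `zero_variance`.
#' @export
all_pair_aurocs <- function(tensor, pairs = NULL, window_s = c(1, 2)) {
  labels <- sort(unique(tensor$trials$contingency))
  pairs <- pairs %||% utils::combn(labels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    f <- pair_features(tensor, p, window_s)
    purrr::map_dfr(seq_len(ncol(f$X)), function(nn) {
      res <- oriented_auroc(f$X[, nn], f$positive)
      tibble::tibble(neuron = nn, pair = paste(p, collapse = " vs "),
                     odor_a = p[1], odor_b = p[2],
                     auroc = res$auroc, zero_variance = res$zero_variance)
    })
  })
}

#' Permutation null for a single-neuron pairwise auROC
#'
#' Re-computes the oriented auROC under `n_shuffles` random label
#' permutations and reports the add-one permutation p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_shuffles)`.
#'
#' @inheritParams single_neuron_auroc
#' @param n_shuffles Number of label shuffles (>= 100; the full-scale
#'   default is 10,000).
#' @param seed Optional integer seed (results are deterministic under it).
#' @return A one-row tibble: `neuron`, `pair`, `auroc`, `p`, `null_mean`,
#'   `null_sd`, `n_shuffles`.
#' @export
auroc_shuffle_null <- function(tensor, neuron, pair, n_shuffles = 10000L,
                               seed = NULL, window_s = c(1, 2)) {
  if (n_shuffles < 100) abort("`n_shuffles` must be >= 100 for usable p resolution")
  f <- pair_features(tensor, pair, window_s)
  x <- f$X[, neuron]
  obs <- oriented_auroc(x, f$positive)$auroc
  n <- length(x)
  n_pos <- sum(f$positive)
  null <- with_seed(seed, {
    r <- rank(x)
    vapply(seq_len(n_shuffles), function(s) {
      idx <- sample.int(n, n_pos)
      pos <- logical(n); pos[idx] <- TRUE
      u <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * (n - n_pos))
      d <- mean(x[pos]) - mean(x[!pos])
      if (d > 0) u else if (d < 0) 1 - u else 0.5
    }, numeric(1))
  })
  tibble::tibble(
    neuron = neuron, pair = paste(pair, collapse = " vs "),
    auroc = obs,
    p = (1 + sum(null >= obs)) / (1 + n_shuffles),
    null_mean = mean(null), null_sd = sd(null),
    n_shuffles = n_shuffles
  )
}

#' Valence/identity quadrant categorisation
#'
#' Joint categorisation of each neuron's intervalence auROC (sucrose-paired
#' vs non-sucrose-paired odor, e.g. S_K vs X_K) and intravalence auROC (the
#' two sucrose-paired odors, S_K vs S_T) at threshold `theta`:
#' `valence` (intervalence > theta only), `identity` (both), `identity_S_only`
#' (intravalence only), `uninformative` (neither).
#'
#' @param scores A tibble with columns `neuron`, `auroc_intervalence`,
#'   `auroc_intravalence` (see [all_pair_aurocs()]).
#' @param theta auROC threshold (default 0.75, halfway between chance and
#'   perfect).
#' @return `scores` with a `label` column; the per-population composition is
#'   available via [quadrant_composition()].
#' @export
categorize_quadrants <- function(scores, theta = 0.75) {
  stopifnot(all(c("auroc_intervalence", "auroc_intravalence") %in%
                  names(scores)))
  inter <- scores$auroc_intervalence > theta
  intra <- scores$auroc_intravalence > theta
  scores$label <- dplyr::case_when(
    inter & !intra ~ "valence",
    inter & intra ~ "identity",
    !inter & intra ~ "identity_S_only",
    TRUE ~ "uninformative"
  )
  attr(scores, "theta") <- theta
  scores
}

#' @rdname categorize_quadrants
#' @param labelled Output of [categorize_quadrants()].
#' @export
quadrant_composition <- function(labelled) {
  lv <- c("valence", "identity", "identity_S_only", "uninformative")
  counts <- table(factor(labelled$label, levels = lv))
  tibble::tibble(label = lv, n = as.integer(counts),
                 fraction = as.numeric(counts) / nrow(labelled))
}

#' Single-neuron multinomial (6-odor) confusion matrix
#'
#' Cross-validated multinomial regression on the per-trial window-mean
#' feature of one neuron; rows are true odors, columns predicted, rows
#' normalised to 1.
#'
#' @inheritParams single_neuron_auroc
#' @param k CV folds.
#' @param seed Fold seed.
#' @return A list: `confusion` (row-normalised matrix with contingency
#'   dimnames), `summary` tibble with mean off-diagonal confusion between
#'   the two sucrose cues (`s_pair_confusion`) and among the three ketones
#'   (`ketone_confusion`).
#' @export
single_neuron_mnr_confusion <- function(tensor, neuron, window_s = c(1, 2),
                                        k = 5L, seed = NULL) {
  means <- window_trial_means(tensor, window_s)
  labs <- tensor$trials$contingency
  if (dplyr::n_distinct(tensor$trials$odor_id) < 6) abort("all 6 odors required")
  df <- data.frame(y = factor(labs), x = means[neuron, ])
  pred <- cv_multinom_predict(df, k, seed)
  confusion_from_predictions(df$y, pred)
}

# shared by single-neuron and population MNR paths
cv_multinom_predict <- function(df, k, seed, decay = 1e-3) {
  fold <- stratified_folds(df$y, k, seed)
  pred <- factor(rep(NA_character_, nrow(df)), levels = levels(df$y))
  for (fk in seq_len(k)) {
    tr <- df[fold != fk, , drop = FALSE]
    te <- df[fold == fk, , drop = FALSE]
    fit <- nnet::multinom(y ~ ., data = tr, trace = FALSE, decay = decay,
                          MaxNWts = 1e5, maxit = 300)
    pred[fold == fk] <- predict(fit, newdata = te)
  }
  pred
}

confusion_from_predictions <- function(truth, pred) {
  tab <- table(truth = truth, pred = pred)
  cm <- sweep(tab, 1, pmax(rowSums(tab), 1), "/")
  cm <- unclass(cm)
  lv <- rownames(cm)
  s_lv <- lv[grepl("^S_", lv)]
  k_lv <- lv[grepl("_K$", lv)]
  s_conf <- if (length(s_lv) == 2) {
    mean(c(cm[s_lv[1], s_lv[2]], cm[s_lv[2], s_lv[1]]))
  } else NA_real_
  k_conf <- if (length(k_lv) >= 2) {
    off <- cm[k_lv, k_lv, drop = FALSE]
    diag(off) <- NA
    mean(off, na.rm = TRUE)
  } else NA_real_
  list(confusion = cm,
       summary = tibble::tibble(s_pair_confusion = s_conf,
                                ketone_confusion = k_conf))
}
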