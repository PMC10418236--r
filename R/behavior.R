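#' Lick selectivity and anticipatory licking
#'
#' Per-trial lick counts during the odor period, the anticipatory lick rate
#' in the shared analysis window (last 0.5 s of odor + first 0.5 s of
#' delay), and the sucrose-cue lick fraction: licks during sucrose-paired
#' odors as a fraction of licks during any odor, smoothed with a centered
#' moving-average over trials (shrinking windows at the edges). Windows with
#' zero odor-period licks give an undefined (`NA`) fraction; the count of
#' such windows is attached.
#'
#' @param schedule Trial schedule.
#' @param licks Lick counts per frame.
#' @param frame_rate_hz Frame rate.
#' @param ma_window Moving-average window in trials (default 10).
#' @return A list: `trials` (tibble with `odor_licks`, `anticipatory_rate`,
#'   `s_fraction_ma`), `by_odor` (mean licks and anticipatory rate per
#'   odor), `n_undefined`.
#' @export
lick_selectivity <- function(schedule, licks, frame_rate_hz, ma_window = 10L) {
  fs <- frame_rate_hz
  n_frames <- length(licks)
  aw <- anticipatory_window_s(attr(schedule, "odor_duration_s") %||% 2)

  count_in <- function(a, b) {
    idx <- frames_in_window(a, b, fs) + 1L
    idx <- idx[idx >= 1 & idx <= n_frames]
    sum(licks[idx])
  }
  tr <- schedule
  tr$odor_licks <- mapply(count_in, tr$onset_s, tr$offset_s)
  tr$anticipatory_licks <- mapply(count_in, tr$onset_s + aw[1],
                                  tr$onset_s + aw[2])
  tr$anticipatory_rate <- tr$anticipatory_licks / (aw[2] - aw[1])
  tr$is_s <- tr$reward_probability > 0

  n <- nrow(tr)
  half_lo <- floor((ma_window - 1) / 2)
  half_hi <- ceiling((ma_window - 1) / 2)
  s_frac <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- max(1, i - half_lo):min(n, i + half_hi)
    tot <- sum(tr$odor_licks[w])
    if (tot > 0) s_frac[i] <- sum(tr$odor_licks[w][tr$is_s[w]]) / tot
  }
  tr$s_fraction_ma <- s_frac

  by_odor <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(tr), .data$odor_id, .data$contingency),
    mean_odor_licks = mean(.data$odor_licks),
    mean_anticipatory_rate = mean(.data$anticipatory_rate),
    .groups = "drop")

  list(trials = tibble::as_tibble(tr), by_odor = by_odor,
       n_undefined = sum(is.na(s_frac)))
}

#' Euclidean distance between upper and lower lip
#'
#' @param face Face-feature matrix with columns `upper_x`, `upper_y`,
#'   `lower_x`, `lower_y` (or a frames x 6 matrix in the session layout).
#' @return Numeric vector of distances per frame.
#' @export
lip_distance <- function(face) {
  cn <- colnames(face)
  if (!is.null(cn) && all(c("upper_x", "upper_y", "lower_x", "lower_y") %in% cn)) {
    ux <- face[, "upper_x"]; uy <- face[, "upper_y"]
    lx <- face[, "lower_x"]; ly <- face[, "lower_y"]
  } else {
    ux <- face[, 3]; uy <- face[, 4]; lx <- face[, 5]; ly <- face[, 6]
  }
  unname(sqrt((ux - lx)^2 + (uy - ly)^2))
}

#' Frame-wise lick detection from face features
#'
#' Logistic-regression detector on three face metrics: tongue-tip tracking
#' confidence, mouth-corner confidence, and the Euclidean distance between
#' the upper and lower lip. Trained against lick-sensor ground truth with
#' stratified k-fold cross-validation; the returned model can then infer
#' licking on frames where the sensor is unavailable (spout retracted).
#'
#' @param face Frames x 6 face-feature matrix (session layout).
#' @param lick_labels Ground-truth lick indicator per frame (logical or
#'   counts).
#' @param k CV folds.
#' @param seed Fold seed.
#' @param train_frames Optional frame subset with valid sensor data.
#' @return A list: `model` (glm), `cv_accuracy`, `confusion` (2 x 2
#'   row-normalised), `features` (the design used).
#' @export
detect_licks_from_face <- function(face, lick_labels, k = 5L, seed = NULL,
                                   train_frames = NULL) {
  y <- as.integer(as.numeric(lick_labels) > 0)
  feats <- data.frame(
    tongue_conf = face[, 1],
    mouth_conf = face[, 2],
    lip_dist = lip_distance(face)
  )
  if (!is.null(train_frames)) {
    feats <- feats[train_frames, , drop = FALSE]
    y <- y[train_frames]
  }
  if (length(unique(y)) < 2) abort("training labels contain a single class")
  fold <- stratified_folds(y, k, seed)
  pred <- integer(length(y))
  for (fk in seq_len(k)) {
    fit <- glm(y ~ ., data = cbind(y = y, feats)[fold != fk, ],
               family = binomial())
    pred[fold == fk] <- as.integer(
      predict(fit, newdata = feats[fold == fk, , drop = FALSE],
              type = "response") > 0.5)
  }
  model <- glm(y ~ ., data = cbind(y = y, feats), family = binomial())
  tab <- table(truth = factor(y, 0:1), pred = factor(pred, 0:1))
  list(model = model,
       cv_accuracy = mean(pred == y),
       confusion = sweep(tab, 1, pmax(rowSums(tab), 1), "/"),
       features = feats)
}

#' @rdname detect_licks_from_face
#' @param detector Output of `detect_licks_from_face()`.
#' @param frames Optional frame subset (e.g. spout-absent frames).
#' @export
predict_licks <- function(detector, face, frames = NULL) {
  feats <- data.frame(
    tongue_conf = face[, 1],
    mouth_conf = face[, 2],
    lip_dist = lip_distance(face)
  )
  if (!is.null(frames)) feats <- feats[frames, , drop = FALSE]
  as.integer(predict(detector$model, newdata = feats, type = "response") > 0.5)
}

#' Distributed lag model prediction
#'
#' Ordinary least-squares regression of a target series on lagged copies of
#' one or more predictor series (lags `-max_lag_frames` to
#' `+max_lag_frames`), fitted on the first `train_frac` of the session by
#' time and evaluated on the held-out remainder (out-of-sample R^2 =
#' `1 - SS_res / SS_tot` about the test-segment mean).
#'
#' @param target Numeric series (e.g. lick rate).
#' @param predictors Numeric vector or frames x p matrix (e.g. neuron dF/F
#'   or face features).
#' @param max_lag_frames Maximum lag in frames (0 = static regression).
#' @param train_frac Fraction of frames (by time) used for fitting.
#' @return A list: `coefficients` (tibble: `predictor`, `lag`, `estimate`),
#'   `r2_oos`, `r2_train`, `model`.
#' @export
dlm_predict <- function(target, predictors, max_lag_frames = 10L,
                        train_frac = 0.8) {
  if (max_lag_frames < 0) abort("`max_lag_frames` must be >= 0")
  predictors <- as.matrix(predictors)
  n <- length(target)
  if (2 * max_lag_frames + 1 >= n) abort("lag window exceeds series length")
  lags <- seq.int(-max_lag_frames, max_lag_frames)
  cols <- list()
  for (p in seq_len(ncol(predictors))) {
    for (l in lags) {
      shifted <- rep(NA_real_, n)
      src <- seq_len(n) - l
      ok <- src >= 1 & src <= n
      shifted[ok] <- predictors[src[ok], p]
      nm <- sprintf("p%d_lag_%s%d", p, if (l < 0) "m" else "p", abs(l))
      cols[[nm]] <- shifted
    }
  }
  df <- data.frame(y = target, cols)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  n_keep <- nrow(df)
  n_train <- floor(train_frac * n_keep)
  if (n_train < ncol(df) + 1) abort("not enough frames to fit the lag model")
  tr <- df[seq_len(n_train), , drop = FALSE]
  te <- df[(n_train + 1):n_keep, , drop = FALSE]
  fit <- lm(y ~ ., data = tr)
  pred <- predict(fit, newdata = te)
  r2_oos <- 1 - sum((te$y - pred)^2) / sum((te$y - mean(te$y))^2)
  coefs <- coef(fit)[-1]
  meta <- do.call(rbind, strsplit(sub("^p", "", names(coefs)), "_lag_"))
  lag_sign <- ifelse(substr(meta[, 2], 1, 1) == "m", -1L, 1L)
  list(
    coefficients = tibble::tibble(
      predictor = as.integer(meta[, 1]),
      lag = lag_sign * as.integer(substring(meta[, 2], 2)),
      estimate = unname(coefs)),
    r2_oos = r2_oos,
    r2_train = summary(fit)$r.squared,
    model = fit
  )
}

#' Variance partitioning between reward contingency and licking vigor
#'
#' Fits three linear models to a neuron's per-trial response: contingency
#' only, licking only, and both plus their interaction. Reports the loss in
#' R^2 when either variable (and its interaction) is omitted from the full
#' model: `dr2_valence = r2_full - r2_licking_only` and
#' `dr2_licking = r2_full - r2_contingency_only`. For nested in-sample fits
#' both losses are non-negative.
#'
#' @param response Per-trial response (e.g. anticipatory-window ddF/F).
#' @param contingency Per-trial reward probability P(S).
#' @param licking Per-trial anticipatory lick rate.
#' @return A one-row tibble: `r2_full`, `r2_contingency`, `r2_licking`,
#'   `dr2_valence`, `dr2_licking`, `n_trials`, `constant_regressor`.
#' @export
omission_r2 <- function(response, contingency, licking) {
  df <- data.frame(y = response, v = contingency, l = licking)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 10) abort("at least 10 trials required")
  const_v <- var(df$v) == 0
  const_l <- var(df$l) == 0
  if (const_v || const_l) {
    return(tibble::tibble(
      r2_full = NA_real_, r2_contingency = NA_real_, r2_licking = NA_real_,
      dr2_valence = NA_real_, dr2_licking = NA_real_,
      n_trials = nrow(df), constant_regressor = TRUE))
  }
  r2 <- function(f) summary(lm(f, data = df))$r.squared
  r2_v <- r2(y ~ v)
  r2_l <- r2(y ~ l)
  r2_full <- r2(y ~ v * l)
  tibble::tibble(
    r2_full = r2_full, r2_contingency = r2_v, r2_licking = r2_l,
    dr2_valence = r2_full - r2_l, dr2_licking = r2_full - r2_v,
    n_trials = nrow(df), constant_regressor = FALSE)
}

#' Per-neuron omission R^2 over a trial tensor
#'
#' Computes per-trial responses (anticipatory-window mean minus pre-odor
#' mean) for every neuron and applies [omission_r2()] against the trial
#' reward probability and anticipatory lick rate.
#'
#' @param tensor A `trial_tensor` (lick/no-lick paradigm).
#' @param licks Lick counts per frame for the same session.
#' @param response_window_s Response window (defaults to the shared
#'   anticipatory window).
#' @return A tibble, one row per neuron, with the [omission_r2()] columns.
#' @export
omission_r2_population <- function(tensor, licks,
                                   response_window_s = NULL) {
  fs <- tensor$frame_rate_hz
  aw <- anticipatory_window_s()
  response_window_s <- response_window_s %||% aw
  resp <- window_trial_means(tensor, response_window_s) -
    window_trial_means(tensor, c(-2, 0))
  labs <- tensor$trials
  n_frames <- length(licks)
  lick_rate <- vapply(seq_len(nrow(labs)), function(i) {
    idx <- frames_in_window(labs$onset_s[i] + aw[1],
                            labs$onset_s[i] + aw[2], fs) + 1L
    idx <- idx[idx >= 1 & idx <= n_frames]
    sum(licks[idx]) / (aw[2] - aw[1])
  }, numeric(1))
  purrr::map_dfr(seq_len(nrow(resp)), function(nn) {
    out <- omission_r2(resp[nn, ], labs$reward_probability, lick_rate)
    out$neuron <- nn
    out
  })
}

#' Pairwise decoding accuracy versus behavioral and value differences
#'
#' Fits pairwise classifier accuracies to (1) the range-normalised
#' difference in anticipatory licking, (2) the difference in reward
#' contingency P(S), and (3) both plus their interaction, by ordinary least
#' squares. Under value-and-vigor coding the combined model outperforms
#' both single-variable models.
#'
#' @param data A data frame with columns `accuracy`, `d_lick`
#'   (range-normalised), `d_ps`.
#' @return An object of class `behavior_accuracy_fit` with [tidy()] and
#'   [glance()] methods; element `fits` holds the three `lm` objects.
#' @export
accuracy_vs_behavior <- function(data) {
  stopifnot(all(c("accuracy", "d_lick", "d_ps") %in% names(data)))
  if (nrow(data) < 10) abort("at least 10 accuracy observations required")
  fits <- list(
    lick = lm(accuracy ~ d_lick, data = data),
    contingency = lm(accuracy ~ d_ps, data = data),
    combined = lm(accuracy ~ d_lick * d_ps, data = data)
  )
  if (any(vapply(fits, function(f) any(is.na(coef(f))), logical(1)))) {
    abort("rank-deficient design: a regressor is constant or collinear")
  }
  structure(list(fits = fits, n = nrow(data)),
            class = "behavior_accuracy_fit")
}

#' @export
print.behavior_accuracy_fit <- function(x, ...) {
  g <- glance(x)
  cat("<behavior_accuracy_fit> n =", x$n, "\n")
  print(g)
  invisible(x)
}

#' @rdname accuracy_vs_behavior
#' @param x A `behavior_accuracy_fit`.
#' @param ... Unused.
#' @export
tidy.behavior_accuracy_fit <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(nm) {
    s <- summary(x$fits[[nm]])$coefficients
    tibble::tibble(model = nm, term = rownames(s),
                   estimate = s[, 1], std_error = s[, 2],
                   p_value = s[, 4])
  })
}

#' @rdname accuracy_vs_behavior
#' @export
glance.behavior_accuracy_fit <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(nm) {
    fit <- x$fits[[nm]]
    s <- summary(fit)
    r2 <- s$r.squared
    ar2 <- s$adj.r.squared
    if (var(fit$model[[1]]) == 0) r2 <- ar2 <- 0  # nothing to explain
    tibble::tibble(model = nm,
                   r_squared = if (is.finite(r2)) r2 else 0,
                   adj_r_squared = if (is.finite(ar2)) ar2 else 0,
                   n = x$n)
  })
}

#' Range-normalised pairwise lick differences
#'
#' For each odor pair: the absolute difference in mean anticipatory lick
#' rate, divided by the maximum pairwise difference (per animal/session),
#' and the absolute difference in reward probability.
#'
#' @param lick_summary Output of [lick_selectivity()].
#' @return A tibble: `pair`, `d_lick` (range-normalised), `d_ps`.
#' @export
pairwise_behavior_differences <- function(lick_summary) {
  by_odor <- lick_summary$by_odor
  sched <- lick_summary$trials
  p_of <- sched$reward_probability[match(by_odor$odor_id, sched$odor_id)]
  pairs <- utils::combn(seq_len(nrow(by_odor)), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(ij) {
    tibble::tibble(
      pair = paste(sort(c(by_odor$contingency[ij[1]],
                          by_odor$contingency[ij[2]])), collapse = " vs "),
      d_lick = abs(by_odor$mean_anticipatory_rate[ij[1]] -
                     by_odor$mean_anticipatory_rate[ij[2]]),
      d_ps = abs(p_of[ij[1]] - p_of[ij[2]])
    )
  })
  mx <- max(out$d_lick)
  if (mx > 0) out$d_lick <- out$d_lick / mx
  out
}
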