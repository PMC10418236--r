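#' Pairwise population distance trajectories
#'
#' Per odor: per-trial dF/F is baseline-subtracted (each trial's mean over
#' the 2 s before odor onset) and averaged across trials, yielding one
#' population vector per frame. For each odor pair and frame the Euclidean
#' distance between the two vectors is computed and normalised to the
#' maximum distance over all pairs and frames (so the maximum is exactly 1
#' per session/animal). Single-neuron populations reduce to the absolute
#' difference.
#'
#' @param tensor A `trial_tensor` (>= 2 odors).
#' @param pre_window_s Baseline window used for subtraction.
#' @return A tibble: `pair`, `rel_frame`, `time_s`, `distance`,
#'   `distance_norm`; attribute `max_distance`.
#' @export
distance_trajectories <- function(tensor, pre_window_s = c(-2, 0)) {
  labs <- tensor$trials
  odors <- sort(unique(labs$contingency))
  if (length(odors) < 2) abort("at least 2 odors required")
  pre <- window_trial_means(tensor, pre_window_s)  # neurons x trials
  n_frames <- length(tensor$rel_frames)

  # trial-averaged baseline-subtracted response: neurons x frames per odor
  avg <- purrr::map(odors, function(o) {
    j <- which(labs$contingency == o)
    sub <- tensor$values[, j, , drop = FALSE] -
      array(pre[, j], dim = c(nrow(pre), length(j), n_frames))
    apply(sub, c(1, 3), mean)
  })
  names(avg) <- odors

  pairs <- utils::combn(odors, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    dmat <- avg[[p[1]]] - avg[[p[2]]]
    if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1)
    tibble::tibble(
      pair = paste(p, collapse = " vs "),
      rel_frame = tensor$rel_frames,
      time_s = tensor$rel_frames / tensor$frame_rate_hz,
      distance = sqrt(colSums(dmat^2))
    )
  })
  mx <- max(out$distance)
  out$distance_norm <- if (mx > 0) out$distance / mx else 0
  attr(out, "max_distance") <- mx
  out
}

#' Hierarchical clustering of pooled trial-averaged responses
#'
#' Each neuron's trial-averaged response to the 6 odors is Z-scored over its
#' concatenated 6-odor trace, then averaged within three time bins per odor
#' (first odor second, last odor second, first post-odor second), yielding
#' an 18-element feature vector. Neurons are clustered by agglomerative
#' hierarchical clustering (Euclidean distance, Ward linkage) and the tree
#' cut to `K` clusters. Clusters are relabelled in descending order of their
#' mean response to sucrose-paired odors for stable reporting.
#'
#' @param tensors A `trial_tensor` or a named list of them (pooled across
#'   regions; names used as region labels).
#' @param K Number of clusters.
#' @return A list: `assignments` (tibble: `region`, `neuron`, `cluster`),
#'   `features` (matrix neurons x 18), `cluster_traces` (tibble: `cluster`,
#'   `contingency`, `rel_frame`, `time_s`, `mean_z`), `composition` (tibble:
#'   cluster x region counts), `n_dropped` (zero-variance neurons removed).
#' @export
cluster_pooled_responses <- function(tensors, K = 6L) {
  if (inherits(tensors, "trial_tensor")) tensors <- list(pooled = tensors)
  feats <- list(); traces <- list(); regions <- character(0)

  for (rn in names(tensors)) {
    tensor <- tensors[[rn]]
    fs <- tensor$frame_rate_hz
    labs <- tensor$trials
    odors <- sort(unique(labs$contingency))
    stopifnot(length(odors) == 6)
    # trial-averaged traces per odor: neurons x frames x odors
    ta <- purrr::map(odors, function(o) {
      j <- which(labs$contingency == o)
      apply(tensor$values[, j, , drop = FALSE], c(1, 3), mean)
    })
    concat <- do.call(cbind, ta)  # neurons x (frames * 6)
    mu <- rowMeans(concat)
    sdv <- apply(concat, 1, sd)
    z <- (concat - mu) / sdv  # rows with sd 0 become NaN, dropped below

    bins <- list(first_odor = frames_in_window(0, 1, fs),
                 last_odor = frames_in_window(1, 2, fs),
                 first_post = frames_in_window(2, 3, fs))
    n_fr <- length(tensor$rel_frames)
    f <- matrix(NA_real_, nrow(z), 18)
    cn <- character(18)
    col <- 1
    for (oi in seq_along(odors)) {
      for (bi in seq_along(bins)) {
        idx <- (oi - 1) * n_fr + match(bins[[bi]], tensor$rel_frames)
        f[, col] <- rowMeans(z[, idx, drop = FALSE])
        cn[col] <- paste(odors[oi], names(bins)[bi], sep = ".")
        col <- col + 1
      }
    }
    colnames(f) <- cn
    feats[[rn]] <- f
    traces[[rn]] <- z
    regions <- c(regions, rep(rn, nrow(f)))
  }

  features <- do.call(rbind, feats)
  zs <- do.call(rbind, traces)
  neuron <- unlist(lapply(feats, function(f) seq_len(nrow(f))))
  ok <- stats::complete.cases(features)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warn(sprintf("dropped %d neuron(s) with zero-variance responses", n_dropped))
  }
  features <- features[ok, , drop = FALSE]
  zs <- zs[ok, , drop = FALSE]
  regions <- regions[ok]
  neuron <- neuron[ok]

  hc <- hclust(dist(features), method = "ward.D2")
  cl <- cutree(hc, k = K)

  # stable ordering: descending mean response to sucrose-paired odors
  odors <- sort(unique(tensors[[1]]$trials$contingency))
  s_cols <- grepl("^S_|_hi\\.", colnames(features)) &
    grepl("last_odor", colnames(features))
  if (!any(s_cols)) s_cols <- grepl("last_odor", colnames(features))
  mean_s <- vapply(seq_len(K), function(kk) {
    mean(features[cl == kk, s_cols, drop = FALSE])
  }, numeric(1))
  relabel <- match(cl, order(mean_s, decreasing = TRUE))

  tensor1 <- tensors[[1]]
  n_fr <- length(tensor1$rel_frames)
  cluster_traces <- purrr::map_dfr(seq_len(K), function(kk) {
    rows <- which(relabel == kk)
    m <- colMeans(zs[rows, , drop = FALSE])
    rel <- rep(tensor1$rel_frames, times = length(odors))
    tibble::tibble(
      cluster = kk,
      contingency = rep(odors, each = n_fr),
      rel_frame = rel,
      time_s = rel / tensor1$frame_rate_hz,
      mean_z = m
    )
  })

  assignments <- tibble::tibble(region = regions, neuron = neuron,
                                cluster = relabel)
  composition <- dplyr::count(assignments, .data$cluster, .data$region)
  list(assignments = assignments, features = features,
       cluster_traces = cluster_traces, composition = composition,
       n_dropped = n_dropped)
}

#' Participation ratio
#'
#' Dimensionality of a neural dataset: `PR = (sum(lambda))^2 / sum(lambda^2)`
#' where `lambda` are the eigenvalues of the neuron-by-neuron covariance
#' matrix. PR is 1 when a single principal component carries all variance
#' and equals the number of neurons when variance is spread isotropically.
#' Invariant to orthogonal rotations of the neuron basis and to global
#' scaling.
#'
#' @param activity Matrix, samples (frames) x neurons.
#' @return A single number in `[1, n_neurons]`.
#' @export
participation_ratio <- function(activity) {
  activity <- as.matrix(activity)
  if (nrow(activity) < 2) abort("at least 2 samples required")
  ev <- eigen(cov(activity), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  sum(ev)^2 / sum(ev^2)
}

# PR from a covariance matrix (used by the subsampling path)
pr_from_cov <- function(C) {
  ev <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
  sum(ev)^2 / sum(ev^2)
}

#' Subsampled participation ratio
#'
#' Mean PR over random subsamples of `k` neurons (without replacement),
#' which removes the dependence of PR on the number of recorded neurons
#' when comparing populations of different size. The covariance of a column
#' subsample equals the corresponding submatrix of the full covariance, so
#' the full covariance is computed once.
#'
#' @param activity Matrix, samples x neurons.
#' @param k Neurons per subsample (default 15).
#' @param n_repeats Number of subsamples (default 1,000).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `k`, `n_repeats`, `pr_mean`, `pr_sd`.
#' @export
subsampled_pr <- function(activity, k = 15L, n_repeats = 1000L, seed = NULL) {
  activity <- as.matrix(activity)
  n <- ncol(activity)
  if (k > n) abort("`k` exceeds the population size")
  C <- cov(activity)
  prs <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      idx <- sample.int(n, k)
      pr_from_cov(C[idx, idx])
    }, numeric(1))
  })
  tibble::tibble(k = k, n_repeats = n_repeats,
                 pr_mean = mean(prs), pr_sd = sd(prs))
}

#' @rdname subsampled_pr
#' @param ks Grid of subsample sizes for the PR-versus-n curve; the curve is
#'   also reported normalised by `k`.
#' @export
pr_vs_n <- function(activity, ks, n_repeats = 1000L, seed = NULL) {
  seeds <- derive_seeds(seed %||% 0L, length(ks), salt = 13L)
  purrr::map_dfr(seq_along(ks), function(i) {
    r <- subsampled_pr(activity, ks[i], n_repeats, seeds[i])
    r$pr_norm <- r$pr_mean / ks[i]
    r
  })
}
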