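#' Default pipeline configuration
#'
#' All analysis thresholds default to the values the analyses were designed
#' around: FWER level 0.05, auROC threshold 0.75, 5 CV folds, 10,000 label
#' shuffles, 15-neuron subsamples with 1,000 repeats, and a 2,500-frame
#' baseline window. The paradigm and population blocks set the simulated
#' cohort.
#'
#' @param seed Master seed for the run.
#' @return A nested list (`run_config`).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    paradigm = list(name = "six_odor", n_blocks = 30L, day = 6L),
    population = list(region = "VP", n_neurons = 130L),
    acquisition = list(frame_rate_hz = 5),
    analysis = list(
      alpha = 0.05,
      theta = 0.75,
      k_folds = 5L,
      n_shuffles = 10000L,
      k_subsample = 15L,
      n_repeats = 1000L,
      baseline_window_frames = 2500L,
      baseline_stride_frames = 500L,
      n_components = 2L,
      n_clusters = 6L,
      compute_nulls = FALSE
    )
  )
}

#' Validate a pipeline configuration
#'
#' Schema validation only; no side effects. Returns `TRUE` for a valid
#' config or a character vector of error messages naming the offending
#' field paths.
#'
#' @param config A config list or a path to a YAML file.
#' @return `TRUE` or a character vector of errors.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  need <- function(path, pred, msg) {
    parts <- strsplit(path, "\\$")[[1]]
    val <- config
    for (p in parts) {
      if (!is.list(val) || is.null(val[[p]])) {
        errs <<- c(errs, sprintf("missing field: %s", path))
        return(invisible(NULL))
      }
      val <- val[[p]]
    }
    if (!pred(val)) errs <<- c(errs, sprintf("%s: %s", path, msg))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  pos1 <- function(x) num1(x) && x > 0
  need("seed", num1, "must be a single number")
  need("paradigm$name",
       function(x) x %in% c("six_odor", "lick_nolick"), "unknown paradigm")
  need("paradigm$n_blocks", pos1, "must be positive")
  need("paradigm$day", pos1, "must be positive")
  need("population$region", function(x)
    x %in% c("VP", "OT_D1", "OT_D2", "identity_only"), "unknown region")
  need("population$n_neurons", pos1, "must be positive")
  need("acquisition$frame_rate_hz", pos1, "must be positive")
  need("analysis$alpha", function(x) num1(x) && x > 0 && x < 1,
       "must be in (0,1)")
  need("analysis$theta", function(x) num1(x) && x > 0.5 && x < 1,
       "must be in (0.5,1)")
  need("analysis$k_folds", function(x) num1(x) && x >= 2, "must be >= 2")
  need("analysis$n_shuffles", function(x) num1(x) && x >= 0,
       "must be non-negative")
  need("analysis$k_subsample", pos1, "must be positive")
  need("analysis$n_repeats", pos1, "must be positive")
  need("analysis$baseline_window_frames", function(x) num1(x) && x >= 2,
       "must be >= 2")
  if (length(errs)) errs else TRUE
}

#' Run the full simulate-preprocess-analyze pipeline
#'
#' Simulates a cohort session from the config, preprocesses it, and writes
#' the analysis bundle as CSV tables plus a JSON manifest (config hash,
#' seeds, package version): responsiveness calls, response magnitudes and
#' similarity, single-neuron auROCs and quadrant composition, population
#' pairwise accuracies and the generalization matrix, participation-ratio
#' summaries, distance trajectories, cluster assignments, and the behavior
#' (licking) tables. Outputs are byte-identical across runs with the same
#' config.
#'
#' @param config A config list (see [default_config()]) or YAML path.
#' @param out_dir Output directory.
#' @return The output directory, invisibly; the bundle is on disk.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  ok <- validate_config(config)
  if (!isTRUE(ok)) {
    abort(paste0("invalid config:\n", paste("-", ok, collapse = "\n")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analysis
  seeds <- derive_seeds(config$seed, 12L)
  log_lines <- character(0)
  say <- function(stage, ...) {
    log_lines <<- c(log_lines, paste0("[", stage, "] ", sprintf(...)))
  }

  # --- simulate -----------------------------------------------------------
  sched <- build_conditioning_schedule(
    config$paradigm$name, n_blocks = config$paradigm$n_blocks,
    day = config$paradigm$day, seed = seeds[1])
  pop <- sample_ground_truth_population(
    population_config(n_neurons = config$population$n_neurons,
                      region = config$population$region,
                      paradigm = config$paradigm$name),
    seed = seeds[2])
  session <- synthesize_session(sched, pop, seed = seeds[3],
                                frame_rate_hz = config$acquisition$frame_rate_hz)
  say("simulate", "%d neurons, %d trials", nrow(session$F), nrow(sched))

  # --- preprocess ---------------------------------------------------------
  session <- preprocess_session(session,
                                window_frames = an$baseline_window_frames,
                                stride_frames = an$baseline_stride_frames,
                                n_components = an$n_components)
  tensor <- epoch_trials(session)
  say("preprocess", "%d trials epoched, %d dropped",
      dim(tensor$values)[2], tensor$n_dropped)

  # --- responsiveness -----------------------------------------------------
  tests <- framewise_response_test(tensor, alpha = an$alpha)
  calls <- call_responsiveness(tests)
  rsum <- responsiveness_summary(calls, tests)
  readr::write_csv(calls, file.path(out_dir, "responsiveness.csv"))
  readr::write_csv(rsum$percent_by_odor,
                   file.path(out_dir, "responsiveness_percent.csv"))

  # --- response magnitudes ------------------------------------------------
  rm_tbl <- response_magnitude(tensor)
  readr::write_csv(rm_tbl, file.path(out_dir, "response_magnitude.csv"))
  labels <- sort(unique(tensor$trials$contingency))
  sim_tbl <- if (all(c("S_K", "S_T", "X_K") %in% labels)) {
    dplyr::bind_rows(ddff_similarity(rm_tbl, c("S_K", "S_T")),
                     ddff_similarity(rm_tbl, c("S_K", "X_K")))
  } else NULL
  if (!is.null(sim_tbl)) {
    readr::write_csv(sim_tbl, file.path(out_dir, "ddff_similarity.csv"))
  }

  # --- single-neuron decoding --------------------------------------------
  aurocs <- all_pair_aurocs(tensor)
  readr::write_csv(aurocs, file.path(out_dir, "single_neuron_auroc.csv"))
  inter_pair <- if ("S_K" %in% labels) c("X_K", "S_K") else c("N_X", "N_hi")
  intra_pair <- if ("S_K" %in% labels) c("S_K", "S_T") else c("N_hi", "L_hi")
  scores <- tibble::tibble(
    neuron = sort(unique(aurocs$neuron)),
    auroc_intervalence = aurocs$auroc[aurocs$pair ==
      paste(sort(inter_pair), collapse = " vs ")],
    auroc_intravalence = aurocs$auroc[aurocs$pair ==
      paste(sort(intra_pair), collapse = " vs ")]
  )
  quad <- categorize_quadrants(scores, theta = an$theta)
  readr::write_csv(quad, file.path(out_dir, "quadrants.csv"))
  readr::write_csv(quadrant_composition(quad),
                   file.path(out_dir, "quadrant_composition.csv"))

  # --- population decoding -----------------------------------------------
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  pop_acc <- purrr::map_dfr(seq_along(pairs), function(i) {
    population_pair_classifier(tensor, pairs[[i]], k = an$k_folds,
                               seed = derive_seeds(seeds[4], i)[1])
  })
  if (isTRUE(an$compute_nulls) && an$n_shuffles >= 100) {
    nulls <- purrr::map_dfr(list(inter_pair, intra_pair), function(p) {
      population_shuffle_null(tensor, sort(p), k = an$k_folds,
                              n_shuffles = an$n_shuffles, seed = seeds[5])
    })
    readr::write_csv(nulls, file.path(out_dir, "population_nulls.csv"))
  }
  readr::write_csv(pop_acc, file.path(out_dir, "population_accuracy.csv"))
  gm <- generalization_matrix(tensor, k = an$k_folds, seed = seeds[6])
  gm_tbl <- tibble::as_tibble(gm$accuracy, rownames = "train_pair")
  readr::write_csv(gm_tbl, file.path(out_dir, "generalization_matrix.csv"))
  say("decode", "generalized valence score %.3f", generalized_valence_score(gm))

  # --- geometry -----------------------------------------------------------
  dtraj <- distance_trajectories(tensor)
  readr::write_csv(dtraj, file.path(out_dir, "distance_trajectories.csv"))
  clus <- cluster_pooled_responses(tensor, K = an$n_clusters)
  readr::write_csv(clus$assignments, file.path(out_dir, "clusters.csv"))
  k_pr <- min(an$k_subsample, nrow(session$dff))
  pr_tbl <- subsampled_pr(t(session$dff), k = k_pr,
                          n_repeats = an$n_repeats, seed = seeds[7])
  pr_tbl$pr_full <- participation_ratio(t(session$dff))
  readr::write_csv(pr_tbl, file.path(out_dir, "participation_ratio.csv"))

  # --- behavior -----------------------------------------------------------
  ls <- lick_selectivity(session$schedule, session$licks,
                         session$frame_rate_hz)
  readr::write_csv(ls$by_odor, file.path(out_dir, "licking_by_odor.csv"))
  readr::write_csv(
    dplyr::select(ls$trials, "trial", "odor_id", "contingency",
                  "odor_licks", "anticipatory_rate", "s_fraction_ma"),
    file.path(out_dir, "licking_trials.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("odorvalence")),
    config = config,
    config_hash = rlang::hash(config),
    stage_seeds = seeds,
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
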