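#' Odor sets for the two conditioning paradigms
#'
#' Six monomolecular odorants, three ketones and three terpenes. In the
#' six-odor paradigm each reward contingency group (sucrose `S`, control `X`,
#' airpuff `P`) contains one ketone and one terpene, so contingency is
#' decoupled from chemical class. Days 1-3 use the original contingency map;
#' from day 4 on every odor has a reassigned contingency. In the lick/no-lick
#' paradigm the lick spout is retracted during three of the odors (`N` odors)
#' and reward probability (0 / 0.5 / 1) occurs exactly once per spout state.
#'
#' @param paradigm `"six_odor"` or `"lick_nolick"`.
#' @param day Imaging day (only used by the six-odor paradigm: days 1-3
#'   original contingencies, days 4-6 switched).
#' @return A tibble with one row per odor: `odor_id`, `odor_name`,
#'   `chemical_class` (`"ketone"`/`"terpene"`), `contingency` (e.g. `"S_K"`,
#'   `"L_hi"`), `us_type`, `reward_probability`, `spout_present`.
#' @export
#' @examples
#' odor_specs("six_odor", day = 1)
#' odor_specs("lick_nolick")
odor_specs <- function(paradigm = c("six_odor", "lick_nolick"), day = 1L) {
  paradigm <- match.arg(paradigm)
  base <- tibble::tibble(
    odor_id = 1:6,
    odor_name = c("hexanone", "heptanone", "octanone",
                  "terpinene", "pinene", "limonene"),
    chemical_class = rep(c("ketone", "terpene"), each = 3)
  )
  if (paradigm == "six_odor") {
    if (day < 1) abort("`day` must be >= 1")
    grp <- if (day <= 3) {
      # hexanone/terpinene unpaired; heptanone/pinene sucrose;
      # octanone/limonene airpuff
      c("X", "S", "P", "X", "S", "P")
    } else {
      # switched: heptanone/limonene unpaired; octanone/terpinene sucrose;
      # hexanone/pinene airpuff
      c("P", "X", "S", "S", "P", "X")
    }
    suffix <- ifelse(base$chemical_class == "ketone", "K", "T")
    base$contingency <- paste(grp, suffix, sep = "_")
    base$us_type <- unname(c(S = "sucrose", X = "none", P = "airpuff")[grp])
    base$reward_probability <- as.numeric(grp == "S")
    base$spout_present <- TRUE
  } else {
    # spout-present (L) triplet: hexanone 0%, heptanone 50%, pinene 100%;
    # spout-absent (N) triplet: terpinene 0%, limonene 50%, octanone 100%
    base$spout_present <- base$odor_name %in% c("hexanone", "heptanone", "pinene")
    prob <- c(hexanone = 0, heptanone = 0.5, pinene = 1,
              terpinene = 0, limonene = 0.5, octanone = 1)
    base$reward_probability <- unname(prob[base$odor_name])
    lvl <- c("X", "lo", "hi")[match(base$reward_probability, c(0, 0.5, 1))]
    base$contingency <- paste0(ifelse(base$spout_present, "L_", "N_"), lvl)
    base$us_type <- ifelse(base$reward_probability > 0, "sucrose", "none")
  }
  base
}

#' Build a randomized block-design conditioning schedule
#'
#' Trials are organised into blocks, each containing every odor exactly once
#' in uniformly random order. Inter-trial intervals are uniform on 12-18 s and
#' odor delivery lasts 2 s. In the six-odor paradigm the unconditioned
#' stimulus (sucrose or airpuff) arrives 0.1-0.3 s after odor offset; in the
#' lick/no-lick paradigm sucrose is delivered probabilistically after a longer
#' 1.1-1.3 s delay, and for spout-absent odors the lick spout is retracted
#' 0.2 s before odor onset and returns 0.1 s before the earliest possible
#' reward time. A post-hoc check re-draws block orders that would produce more
#' than two consecutive presentations of the same odor across block
#' boundaries (with one trial per odor per block, runs longer than two are
#' already impossible, so the check is a guard, not a constraint in practice).
#'
#' @param paradigm `"six_odor"` or `"lick_nolick"`.
#' @param n_blocks Number of blocks (30 in the full paradigm: 30 trials/odor).
#' @param day Imaging day; selects the six-odor contingency map.
#' @param seed Optional integer seed for reproducible schedules.
#' @param iti_range Inter-trial interval range in seconds.
#' @param odor_duration_s Odor delivery duration in seconds.
#' @param lead_in_s Time before the first trial.
#' @return A tibble with one row per trial: block, odor metadata, onset /
#'   offset / US times (s), spout retract/return times (s, `NA` when the
#'   spout never moves) and the ITI following the trial. Attributes:
#'   `paradigm`, `day`, `odor_specs`.
#' @export
#' @examples
#' sched <- build_conditioning_schedule("six_odor", n_blocks = 2, day = 1, seed = 1)
#' nrow(sched)  # 12 trials: each odor once per block
build_conditioning_schedule <- function(paradigm = c("six_odor", "lick_nolick"),
                                        n_blocks = 30L,
                                        day = 1L,
                                        seed = NULL,
                                        iti_range = c(12, 18),
                                        odor_duration_s = 2,
                                        lead_in_s = 15) {
  paradigm <- match.arg(paradigm)
  if (n_blocks < 1) abort("`n_blocks` must be >= 1")
  specs <- odor_specs(paradigm, day = day)
  n_odors <- nrow(specs)

  with_seed(seed, {
    order_ids <- integer(0)
    for (b in seq_len(n_blocks)) {
      repeat {
        blk <- sample(specs$odor_id)
        cand <- c(order_ids, blk)
        runs <- rle(cand)$lengths
        if (all(runs <= 2)) { order_ids <- cand; break }
      }
    }
    n_trials <- length(order_ids)
    iti <- runif(n_trials, iti_range[1], iti_range[2])
    us_delay <- if (paradigm == "six_odor") runif(n_trials, 0.1, 0.3) else
      runif(n_trials, 1.1, 1.3)

    sched <- specs[match(order_ids, specs$odor_id), ]
    sched$trial <- seq_len(n_trials)
    sched$block <- rep(seq_len(n_blocks), each = n_odors)
    onset <- lead_in_s + c(0, cumsum(odor_duration_s + iti))[seq_len(n_trials)]
    sched$onset_s <- onset
    sched$offset_s <- onset + odor_duration_s
    sched$iti_s <- iti

    # realised US outcome (probabilistic in the lick/no-lick paradigm)
    delivered <- sched$us_type != "none" &
      runif(n_trials) <= sched$reward_probability |
      (paradigm == "six_odor" & sched$us_type == "airpuff")
    sched$us_type <- ifelse(sched$us_type == "none", "none",
                            ifelse(delivered, sched$us_type, "none"))
    sched$us_time_s <- ifelse(sched$us_type == "none", NA_real_,
                              sched$offset_s + us_delay)

    if (paradigm == "lick_nolick") {
      earliest_us <- sched$offset_s + 1.1
      sched$spout_retract_s <- ifelse(sched$spout_present, NA_real_,
                                      sched$onset_s - 0.2)
      sched$spout_return_s <- ifelse(sched$spout_present, NA_real_,
                                     earliest_us - 0.1)
    } else {
      sched$spout_retract_s <- NA_real_
      sched$spout_return_s <- NA_real_
    }

    sched <- dplyr::select(
      sched, "trial", "block", "odor_id", "odor_name", "chemical_class",
      "contingency", "reward_probability", "spout_present", "onset_s",
      "offset_s", "us_type", "us_time_s", "spout_retract_s", "spout_return_s",
      "iti_s"
    )
    sched$day <- as.integer(day)
    attr(sched, "paradigm") <- paradigm
    attr(sched, "odor_duration_s") <- odor_duration_s
    sched
  })
}
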