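#' Write / read a session container
#'
#' Plain-text session layout: a directory holding `F.csv` (neurons x
#' frames fluorescence), `schedule.csv`, `behavior.csv` (per-frame licks
#' and locomotion), `face.csv` (per-frame face features), `meta.json`
#' (frame rate, region, animal, day, paradigm) and, when present,
#' `ground_truth.csv` with the synthetic per-neuron encoding classes and
#' parameters.
#'
#' @param session A `recording_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; `read_session()` returns the reconstructed
#'   `recording_session`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(session$F, .name_repair = "minimal"),
                   file.path(dir, "F.csv"), col_names = FALSE)
  readr::write_csv(session$schedule, file.path(dir, "schedule.csv"))
  readr::write_csv(
    tibble::tibble(frame = seq_along(session$licks) - 1L,
                   licks = session$licks,
                   locomotion = session$locomotion),
    file.path(dir, "behavior.csv"))
  readr::write_csv(tibble::as_tibble(session$face),
                   file.path(dir, "face.csv"))
  meta <- list(frame_rate_hz = session$frame_rate_hz, region = session$region,
               animal_id = session$animal_id, day = session$day,
               paradigm = attr(session$schedule, "paradigm"),
               odor_duration_s = attr(session$schedule, "odor_duration_s"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  if (!is.null(session$ground_truth)) {
    readr::write_csv(session$ground_truth, file.path(dir, "ground_truth.csv"))
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  F <- as.matrix(readr::read_csv(file.path(dir, "F.csv"), col_names = FALSE,
                                 show_col_types = FALSE))
  dimnames(F) <- NULL
  sched <- readr::read_csv(file.path(dir, "schedule.csv"),
                           show_col_types = FALSE)
  attr(sched, "paradigm") <- meta$paradigm
  attr(sched, "odor_duration_s") <- meta$odor_duration_s
  beh <- readr::read_csv(file.path(dir, "behavior.csv"),
                         show_col_types = FALSE)
  face <- as.matrix(readr::read_csv(file.path(dir, "face.csv"),
                                    show_col_types = FALSE))
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) {
    readr::read_csv(gt_path, show_col_types = FALSE)
  } else NULL
  structure(list(
    F = F, frame_rate_hz = meta$frame_rate_hz, schedule = sched,
    licks = beh$licks, locomotion = beh$locomotion, face = face,
    region = meta$region, animal_id = meta$animal_id, day = meta$day,
    ground_truth = gt
  ), class = "recording_session")
}
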