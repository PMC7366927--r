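#' Trial-level data structures and tabular I/O
#'
#' An effort dataset couples three tables:
#' \describe{
#'   \item{trials}{one row per trial: identifiers, dummy-coded condition
#'     (`stimulation`, `reward_type`, `reward_magnitude`, `difficulty`, all
#'     0/1), post-trial `wanting` and `exertion` ratings on a visual analog
#'     scale, the extracted motivation indices (`invigoration` in %/s,
#'     `maintenance` in % of the participant maximum), bout summaries, and
#'     `tokens_earned`.}
#'   \item{participants}{one row per participant: `stim_order` (1 = taVNS
#'     session first), `stim_side` (1 = left ear), `max_press_frequency`
#'     (presses/s). Order and side are mean-centered downstream before they
#'     enter any model.}
#'   \item{press}{optional long table of press-rate series, keyed by
#'     (participant, session, trial_index, sample_index), `value` in % of
#'     the participant maximum.}
#' }
#'
#' @name trial_data
NULL

trial_columns <- c(
  "participant", "session", "trial_index",
  "stimulation", "reward_type", "reward_magnitude", "difficulty",
  "wanting", "exertion",
  "invigoration", "maintenance",
  "n_work_segments", "mean_work_len", "mean_rest_len",
  "tokens_earned"
)

participant_columns <- c("participant", "stim_order", "stim_side",
                         "max_press_frequency")

press_columns <- c("participant", "session", "trial_index",
                   "sample_index", "value")

#' Construct an effort dataset object
#'
#' @param trials tibble of trial records (see [trial_data]).
#' @param participants tibble of participant records.
#' @param press optional long tibble of press-rate series.
#' @param vas_scale upper bound of the visual analog scales; the rating scale
#'   is carried as metadata rather than assumed (default 10).
#' @param truth optional ground-truth parameter tables (attached by the
#'   simulator, used by recovery harnesses).
#' @param config optional [task_config()] the data were generated/recorded
#'   under.
#' @return object of class `effort_dataset`.
#' @export
effort_dataset <- function(trials, participants, press = NULL,
                           vas_scale = 10, truth = NULL, config = NULL) {
  trials <- validate_trials(as_tibble(trials), vas_scale = vas_scale)
  participants <- validate_participants(as_tibble(participants))
  if (!is.null(press)) press <- validate_press(as_tibble(press))
  structure(
    list(trials = trials, participants = participants, press = press,
         vas_scale = vas_scale, truth = truth, config = config),
    class = "effort_dataset"
  )
}

#' @export
print.effort_dataset <- function(x, ...) {
  cat("<effort_dataset>\n")
  cat(sprintf("  participants: %d\n", nrow(x$participants)))
  cat(sprintf("  trials:       %d (%d sessions x up to %d trials)\n",
              nrow(x$trials), length(unique(x$trials$session)),
              max(x$trials$trial_index)))
  cat(sprintf("  press series: %s\n",
              if (is.null(x$press)) "not stored" else
                format(nrow(x$press), big.mark = ",")))
  cat(sprintf("  VAS scale:    0-%g\n", x$vas_scale))
  if (!is.null(x$truth)) cat("  ground truth: attached\n")
  invisible(x)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_field("%s table is missing column(s): %s", what,
               paste(missing, collapse = ", "))
  }
}

row_check <- function(ok, df, field, what) {
  bad <- which(!ok & !is.na(ok))
  if (length(bad)) {
    stop_field("%s row %d: field '%s' violates its invariant (value %s)",
               what, bad[1], field, format(df[[field]][bad[1]]))
  }
}

#' Validate a trials table
#'
#' Checks the schema and every row invariant: binary condition codes, session
#' in 1..2, trial index in 1..48, finite indices, maintenance in \[0, 150\]
#' (relative frequency may transiently exceed 100% of the practice-estimated
#' maximum), ratings within the VAS range, non-negative integer tokens.
#' Ratings may be missing (`NA`); downstream models drop them listwise.
#'
#' @param trials tibble of trial records.
#' @param vas_scale VAS upper bound.
#' @return the validated tibble (invisibly identical to the input).
#' @export
validate_trials <- function(trials, vas_scale = 10) {
  check_columns(trials, trial_columns, "trials")
  trials$participant <- as.character(trials$participant)
  trials$session <- as.integer(trials$session)
  trials$trial_index <- as.integer(trials$trial_index)
  for (f in setdiff(trial_columns,
                    c("participant", "session", "trial_index"))) {
    trials[[f]] <- as.numeric(trials[[f]])
  }
  w <- "trials"
  binary <- c("stimulation", "reward_type", "reward_magnitude", "difficulty")
  for (f in binary) row_check(trials[[f]] %in% c(0, 1), trials, f, w)
  row_check(trials$session %in% c(1, 2), trials, "session", w)
  row_check(trials$trial_index >= 1 & trials$trial_index <= 48 &
              trials$trial_index == round(trials$trial_index),
            trials, "trial_index", w)
  row_check(is.finite(trials$invigoration) | is.na(trials$invigoration),
            trials, "invigoration", w)
  row_check((trials$maintenance >= 0 & trials$maintenance <= 150) |
              is.na(trials$maintenance), trials, "maintenance", w)
  for (f in c("wanting", "exertion")) {
    row_check((trials[[f]] >= 0 & trials[[f]] <= vas_scale) |
                is.na(trials[[f]]), trials, f, w)
  }
  row_check(trials$tokens_earned >= 0 &
              trials$tokens_earned == round(trials$tokens_earned),
            trials, "tokens_earned", w)
  trials[trial_columns]
}

#' Validate a participants table
#' @param participants tibble of participant records.
#' @return the validated tibble.
#' @export
validate_participants <- function(participants) {
  check_columns(participants, participant_columns, "participants")
  participants$participant <- as.character(participants$participant)
  for (f in c("stim_order", "stim_side", "max_press_frequency")) {
    participants[[f]] <- as.numeric(participants[[f]])
  }
  w <- "participants"
  row_check(participants$stim_order %in% c(0, 1), participants,
            "stim_order", w)
  row_check(participants$stim_side %in% c(0, 1), participants,
            "stim_side", w)
  row_check(participants$max_press_frequency > 0, participants,
            "max_press_frequency", w)
  if (anyDuplicated(participants$participant)) {
    stop_field("participants table has duplicated participant ids")
  }
  participants[participant_columns]
}

validate_press <- function(press) {
  check_columns(press, press_columns, "press")
  press$participant <- as.character(press$participant)
  press$session <- as.integer(press$session)
  press$trial_index <- as.integer(press$trial_index)
  press$sample_index <- as.integer(press$sample_index)
  press$value <- as.numeric(press$value)
  row_check(press$value >= 0, press, "value", "press")
  press[press_columns]
}

#' Read an effort dataset from CSV tables
#'
#' Files are UTF-8 comma-separated with a `.` decimal mark, one row per trial;
#' press-rate series live in a sidecar long-format CSV keyed by
#' (participant, session, trial_index, sample_index). Missing ratings are
#' encoded as empty fields.
#'
#' @param trials_csv path to the trials table.
#' @param participants_csv path to the participants table.
#' @param press_csv optional path to the press-series sidecar.
#' @param vas_scale VAS upper bound metadata (default 10).
#' @return an [effort_dataset()].
#' @export
read_session_table <- function(trials_csv, participants_csv,
                               press_csv = NULL, vas_scale = 10) {
  for (p in c(trials_csv, participants_csv, press_csv)) {
    if (!file.exists(p)) stop_field("file not found: %s", p)
  }
  # base strtod parsing is correctly rounded, so numeric fields written at
  # shortest round-trip precision read back bit-identically
  trials <- utils::read.csv(trials_csv)
  participants <- utils::read.csv(participants_csv)
  press <- if (!is.null(press_csv)) utils::read.csv(press_csv)
  effort_dataset(trials, participants, press, vas_scale = vas_scale)
}

#' Write an effort dataset to CSV tables
#'
#' Deterministic column order and row order (participant, session,
#' trial_index); numeric fields round-trip through [read_session_table()] to
#' within 1e-9 (readr writes full double precision).
#'
#' @param dataset an [effort_dataset()].
#' @param trials_csv,participants_csv,press_csv output paths; `press_csv` is
#'   only written when the dataset stores press series.
#' @return invisibly, the paths written.
#' @export
write_session_table <- function(dataset, trials_csv, participants_csv,
                                press_csv = NULL) {
  stopifnot(inherits(dataset, "effort_dataset"))
  trials <- dplyr::arrange(dataset$trials, .data$participant, .data$session,
                           .data$trial_index)
  readr::write_csv(trials[trial_columns], trials_csv, progress = FALSE)
  readr::write_csv(
    dplyr::arrange(dataset$participants, .data$participant),
    participants_csv, progress = FALSE)
  written <- c(trials_csv, participants_csv)
  if (!is.null(dataset$press) && !is.null(press_csv)) {
    press <- dplyr::arrange(dataset$press, .data$participant, .data$session,
                            .data$trial_index, .data$sample_index)
    readr::write_csv(press[press_columns], press_csv, progress = FALSE)
    written <- c(written, press_csv)
  }
  invisible(written)
}
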