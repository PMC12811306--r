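# Readers, writers and normalizers for the three interchange tables.
# Dialect: comma-separated, UTF-8, one header row.

SAMPLE_COLS <- c("participant_id", "trial_id", "t_ms", "x_px", "y_px")
TRIAL_COLS <- c(
  "participant_id", "trial_id", "stimulus_id", "food_type", "classification",
  "response_side", "presentation_index", "start_x_px", "start_y_px",
  "click_x_px", "click_y_px"
)
PARTICIPANT_COLS_FIXED <- c(
  "participant_id", "age", "gender", "education", "condition",
  "uti_item_1", "uti_item_2", "uti_item_3"
)

FOOD_TYPES <- c("healthy", "unhealthy")
CLASSIFICATIONS <- c("tasty", "not_tasty")
RESPONSE_SIDES <- c("left", "right")
CONDITIONS <- c("none", "utilitarian", "hedonic")

check_header <- function(found, required, path, what) {
  missing <- setdiff(required, found)
  if (length(missing) > 0) {
    stop(sprintf(
      "%s file '%s' is missing required column(s): %s",
      what, path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

check_numeric_parse <- function(raw, parsed, cols, path) {
  for (col in cols) {
    bad <- which(!is.na(raw[[col]]) & is.na(parsed[[col]]))
    if (length(bad) > 0) {
      # +1 for the header row: report the physical line in the file
      stop(sprintf(
        "file '%s': non-numeric value '%s' in column '%s' at line %d",
        path, raw[[col]][bad[1]], col, bad[1] + 1L
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

normalize_level <- function(x, allowed, col) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("[ -]", "_", out)
  bad <- which(!is.na(out) & !(out %in% allowed))
  if (length(bad) > 0) {
    stop(sprintf(
      "column '%s': unknown value '%s' (allowed: %s)",
      col, x[bad[1]], paste(allowed, collapse = ", ")
    ), call. = FALSE)
  }
  out
}

read_delim_raw <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

to_num <- function(x) suppressWarnings(as.numeric(x))

#' Read a cursor sample log
#'
#' Reads the long-format cursor log: one row per 10-ms cursor sample, keyed
#' by participant and trial, with the time stamp in milliseconds since
#' tracking started and the cursor position in screen pixels.
#'
#' @param path Path to a CSV file with columns
#'   `participant_id, trial_id, t_ms, x_px, y_px`.
#' @return A tibble with the five columns above; identifiers as character,
#'   the rest numeric. Row order is preserved as read.
#' @seealso [validate_dataset()] for the cross-table invariant checks.
#' @export
read_samples <- function(path) {
  raw <- read_delim_raw(path)
  check_header(names(raw), SAMPLE_COLS, path, "sample log")
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    trial_id = as.character(raw$trial_id),
    t_ms = to_num(raw$t_ms),
    x_px = to_num(raw$x_px),
    y_px = to_num(raw$y_px)
  )
  check_numeric_parse(raw, out, c("t_ms", "x_px", "y_px"), path)
  out
}

#' Read a trial table
#'
#' One row per trial: which stimulus was shown, its food type, the
#' classification the participant made, the response-box side clicked, and
#' the observed start and click pixels that anchor the per-trial coordinate
#' remap. `food_type`, `classification` and `response_side` are case-folded
#' to the canonical lowercase levels.
#'
#' @param path Path to a CSV file with columns
#'   `participant_id, trial_id, stimulus_id, food_type, classification,
#'   response_side, presentation_index, start_x_px, start_y_px, click_x_px,
#'   click_y_px`.
#' @return A tibble with those columns, factors normalized to
#'   `healthy/unhealthy`, `tasty/not_tasty`, `left/right`.
#' @export
read_trials <- function(path) {
  raw <- read_delim_raw(path)
  check_header(names(raw), TRIAL_COLS, path, "trial table")
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    trial_id = as.character(raw$trial_id),
    stimulus_id = as.character(raw$stimulus_id),
    food_type = normalize_level(raw$food_type, FOOD_TYPES, "food_type"),
    classification = normalize_level(raw$classification, CLASSIFICATIONS,
                                     "classification"),
    response_side = normalize_level(raw$response_side, RESPONSE_SIDES,
                                    "response_side"),
    presentation_index = to_num(raw$presentation_index),
    start_x_px = to_num(raw$start_x_px),
    start_y_px = to_num(raw$start_y_px),
    click_x_px = to_num(raw$click_x_px),
    click_y_px = to_num(raw$click_y_px)
  )
  check_numeric_parse(raw, out,
                      c("presentation_index", "start_x_px", "start_y_px",
                        "click_x_px", "click_y_px"), path)
  out
}

#' Read a participant table
#'
#' One row per participant: demographics, experimental condition, the three
#' explicit UTI scale items (1-7 Likert) and the food-frequency
#' questionnaire items `ffq_1 .. ffq_K` (1-8 frequency categories,
#' 1 = rarely or never, 8 = 5+ times a day).
#'
#' @param path Path to a CSV file with columns
#'   `participant_id, age, gender, education, condition, uti_item_1..3,
#'   ffq_1..ffq_K`. `K` is inferred from the header.
#' @return A tibble; `condition` normalized to
#'   `none/utilitarian/hedonic`, items numeric.
#' @export
read_participants <- function(path) {
  raw <- read_delim_raw(path)
  check_header(names(raw), PARTICIPANT_COLS_FIXED, path, "participant table")
  ffq_cols <- grep("^ffq_[0-9]+$", names(raw), value = TRUE)
  ffq_cols <- ffq_cols[order(as.integer(sub("^ffq_", "", ffq_cols)))]
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    age = to_num(raw$age),
    gender = as.character(raw$gender),
    education = as.character(raw$education),
    condition = normalize_level(raw$condition, CONDITIONS, "condition")
  )
  num_cols <- c(paste0("uti_item_", 1:3), ffq_cols)
  for (col in num_cols) out[[col]] <- to_num(raw[[col]])
  check_numeric_parse(raw, out, c("age", num_cols), path)
  out
}

#' Write the interchange tables
#'
#' Plain CSV writers for the three tables; numeric fields keep full
#' precision so a write-then-read round trip is the identity to within
#' 1e-6.
#'
#' @param x A tibble as returned by the corresponding reader.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_samples <- function(x, path) {
  readr::write_csv(x[SAMPLE_COLS], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_trials <- function(x, path) {
  readr::write_csv(x[TRIAL_COLS], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_participants <- function(x, path) {
  ffq_cols <- grep("^ffq_[0-9]+$", names(x), value = TRUE)
  readr::write_csv(x[c(PARTICIPANT_COLS_FIXED, ffq_cols)], path,
                   progress = FALSE)
  invisible(path)
}
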