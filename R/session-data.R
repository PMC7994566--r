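#' @importFrom rlang .data %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows across all_of n
#' @importFrom tibble tibble as_tibble
NULL

# Task definitions: admissible category labels per task. t1/t2 are simple
# fluency tasks (one category); t3 is the switching task (two categories
# alternating within the trial).
.task_categories <- list(
  t1 = "animals",
  t2 = "jobs",
  t3 = c("sports", "fruits")
)

.codes <- c("correct", "repetition_error", "category_error")

#' Normalize a produced word form
#'
#' Trims surrounding whitespace, lower-cases and applies Unicode NFC
#' normalization. Compounds are kept verbatim; lookup variants are the
#' lexical resource's concern.
#'
#' @param word Character vector of raw word forms.
#' @return Character vector of normalized forms.
#' @export
normalize_word <- function(word) {
  stringr::str_to_lower(stringr::str_trim(enc2utf8(as.character(word))))
}

#' Validate a fluency session table
#'
#' Checks the invariants of coded semantic verbal fluency sessions: known
#' task ids, codes from the coding taxonomy, non-negative non-overlapping
#' token intervals within the task duration, category labels present on
#' every switching-task token and admissible for the task, and
#' `category_error` codes confined to the switching task. Tokens are
#' returned sorted by onset within each (participant, task) session; if
#' any were out of order a warning is raised.
#'
#' @param sessions A data frame with columns `participant_id`, `task`,
#'   `word`, `onset`, `offset`, `code`, `category`.
#' @param duration Task duration in seconds (default 120).
#' @return The validated session tibble, tokens sorted by onset.
#' @export
validate_sessions <- function(sessions, duration = 120) {
  sessions <- as_tibble(sessions)
  required <- c("participant_id", "task", "word", "onset", "offset", "code", "category")
  missing_cols <- setdiff(required, names(sessions))
  if (length(missing_cols) > 0) {
    stop("session table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  sessions <- mutate(sessions,
    .row = seq_len(n()),
    participant_id = as.character(.data$participant_id),
    task = as.character(.data$task),
    word = normalize_word(.data$word),
    category = dplyr::if_else(is.na(.data$category) | .data$category == "",
                              NA_character_, as.character(.data$category))
  )

  bad <- function(mask, what) {
    if (any(mask, na.rm = TRUE)) {
      rows <- sessions$.row[which(mask)]
      stop(what, " (row", if (length(rows) > 1) "s", " ",
           paste(utils::head(rows, 5), collapse = ", "),
           if (length(rows) > 5) ", ..." else "", ")", call. = FALSE)
    }
  }
  bad(!sessions$task %in% names(.task_categories), "unknown task id")
  bad(!sessions$code %in% .codes, "unknown token code")
  bad(is.na(sessions$word) | sessions$word == "", "empty word")
  bad(is.na(sessions$onset) | is.na(sessions$offset), "missing timing")
  bad(sessions$onset < 0, "negative onset")
  bad(sessions$offset < sessions$onset, "token offset before onset")
  bad(sessions$offset > duration + 1e-9, "token extends past task duration")
  bad(sessions$task == "t3" & is.na(sessions$category),
      "switching-task token without category label")
  bad(sessions$task != "t3" & sessions$code == "category_error",
      "category_error code outside the switching task")
  cat_ok <- purrr::map2_lgl(sessions$task, sessions$category,
                            ~ is.na(.y) || .y %in% .task_categories[[.x]])
  bad(!cat_ok, "category label not admissible for task")

  out <- sessions |>
    group_by(.data$participant_id, .data$task) |>
    arrange(.data$onset, .by_group = TRUE) |>
    ungroup()
  if (!identical(out$.row, sessions$.row)) {
    warning("tokens were not sorted by onset; sessions returned sorted",
            call. = FALSE)
  }
  overlap <- out |>
    group_by(.data$participant_id, .data$task) |>
    summarise(bad = any(diff_gap(.data$onset, .data$offset) < -1e-9),
              .groups = "drop")
  if (any(overlap$bad)) {
    who <- overlap[overlap$bad, ]
    stop("overlapping token intervals in session ",
         paste(who$participant_id, who$task, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  select(out, -".row")
}

# gaps between consecutive tokens: onset[k+1] - offset[k]; numeric(0) for n<2
diff_gap <- function(onset, offset) {
  n <- length(onset)
  if (n < 2) return(numeric(0))
  onset[-1] - offset[-n]
}

#' Read coded fluency sessions from a transcript table
#'
#' The transcript dialect is a UTF-8 TSV with header
#' `participant_id  task  word  onset_s  offset_s  code  category`, one row
#' per produced token; `code` is one of `correct`, `repetition_error`,
#' `category_error`; `category` is empty except for switching-task rows.
#'
#' @param path Path to the TSV file.
#' @param duration Task duration in seconds (default 120).
#' @return A validated session tibble (columns `participant_id`, `task`,
#'   `word`, `onset`, `offset`, `code`, `category`), one row per token,
#'   sorted by onset within each participant x task session.
#' @export
read_sessions <- function(path, duration = 120) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    task = readr::col_character(),
    word = readr::col_character(),
    onset_s = readr::col_double(),
    offset_s = readr::col_double(),
    code = readr::col_character(),
    category = readr::col_character()
  ))
  validate_sessions(
    dplyr::rename(raw, onset = "onset_s", offset = "offset_s"),
    duration = duration
  )
}

#' Write a session table in the transcript dialect
#'
#' @param sessions A validated session tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  sessions |>
    dplyr::rename(onset_s = "onset", offset_s = "offset") |>
    select(all_of(c("participant_id", "task", "word",
                    "onset_s", "offset_s", "code", "category"))) |>
    readr::write_tsv(path, na = "")
  invisible(path)
}

#' Read one fluency session from a Praat TextGrid
#'
#' Parses a TextGrid (long or short text format) and turns every non-empty
#' interval of the requested interval tier into a token. Interval text is
#' normalized (trimmed, lower-cased); all tokens receive `code = "correct"`
#' since error coding is edited downstream. Point tiers are ignored.
#'
#' @param path Path to the TextGrid file.
#' @param tier_name Name of the interval tier holding word tokens.
#' @param participant_id,task Identifiers to stamp on the session.
#' @return A session tibble in the transcript layout.
#' @export
read_textgrid <- function(path, tier_name, participant_id, task) {
  tiers <- parse_textgrid(path)
  if (!tier_name %in% names(tiers)) {
    stop("tier '", tier_name, "' not found; available tiers: ",
         paste(names(tiers), collapse = ", "), call. = FALSE)
  }
  iv <- tiers[[tier_name]]
  iv <- iv[normalize_word(iv$text) != "", , drop = FALSE]
  out <- tibble(
    participant_id = rep(as.character(participant_id), nrow(iv)),
    task = rep(task, nrow(iv)),
    word = normalize_word(iv$text),
    onset = iv$xmin,
    offset = iv$xmax,
    code = rep("correct", nrow(iv)),
    category = rep(NA_character_, nrow(iv))
  )
  if (task == "t3") {
    # a switching-task TextGrid still needs category coding downstream;
    # leave labels NA and skip the t3 category invariant here
    return(out)
  }
  validate_sessions(out, duration = max(120, max(iv$xmax, 0)))
}

# Minimal TextGrid parser: returns a named list of data.frames
# (xmin, xmax, text), one per IntervalTier. Handles the long format
# (item [k]: ... intervals [j]:) and the short format (bare values).
parse_textgrid <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  if (!grepl("ooTextFile", txt)) stop("not a Praat TextGrid file: ", path)
  tiers <- list()
  if (grepl("item\\s*\\[", txt)) {
    # long format
    item_starts <- grep("^\\s*item\\s*\\[\\d+\\]\\s*:", lines)
    item_starts <- c(item_starts, length(lines) + 1L)
    if (length(item_starts) < 2) return(tiers)
    for (k in seq_len(length(item_starts) - 1L)) {
      block <- lines[item_starts[k]:(item_starts[k + 1L] - 1L)]
      cls <- grep("class\\s*=", block, value = TRUE)[1]
      if (is.na(cls) || !grepl("IntervalTier", cls)) next
      nm <- sub('.*name\\s*=\\s*"([^"]*)".*', "\\1",
                grep("name\\s*=", block, value = TRUE)[1])
      get_num <- function(key, ln) as.numeric(sub(paste0(".*", key, "\\s*=\\s*"), "", ln))
      xmin <- get_num("xmin", grep("xmin\\s*=", block, value = TRUE))
      xmax <- get_num("xmax", grep("xmax\\s*=", block, value = TRUE))
      text <- sub('.*text\\s*=\\s*"(.*)"\\s*$', "\\1",
                  grep("text\\s*=", block, value = TRUE))
      # first xmin/xmax pair is the tier's own range
      if (length(xmin) > length(text)) { xmin <- xmin[-1]; xmax <- xmax[-1] }
      tiers[[nm]] <- data.frame(xmin = xmin, xmax = xmax, text = text,
                                stringsAsFactors = FALSE)
    }
  } else {
    # short format: after the 8-line header, tiers follow as
    # "IntervalTier" / name / xmin / xmax / n / then n triples.
    vals <- lines[-seq_len(7)]
    i <- 1L
    unq <- function(x) sub('^\\s*"(.*)"\\s*$', "\\1", x)
    while (i <= length(vals)) {
      if (grepl("IntervalTier", vals[i])) {
        nm <- unq(vals[i + 1L])
        n <- as.integer(vals[i + 4L])
        idx <- i + 4L + seq_len(n * 3L)
        trip <- matrix(vals[idx], ncol = 3L, byrow = TRUE)
        tiers[[nm]] <- data.frame(
          xmin = as.numeric(trip[, 1]), xmax = as.numeric(trip[, 2]),
          text = unq(trip[, 3]), stringsAsFactors = FALSE)
        i <- i + 5L + n * 3L
      } else if (grepl("TextTier", vals[i])) {
        n <- as.integer(vals[i + 4L])
        i <- i + 5L + n * 2L
      } else {
        i <- i + 1L
      }
    }
  }
  tiers
}

#' Default executive-function variable registry
#'
#' The 68-variable registry distributing the executive-function battery's
#' variables over 14 tests and 5 domains (cognitive flexibility, working
#' memory, inhibition, attention, vigilance). Variable names are the
#' package's own; the registry is an editable TSV so a study can swap in
#' its actual battery layout.
#'
#' @param path Optional path to a registry TSV (columns `variable`, `test`,
#'   `domain`, `polarity`, `kind`); defaults to the bundled registry.
#' @return A tibble with one row per EF variable.
#' @export
ef_schema <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ef_schema.tsv", package = "fluencyEF")
  schema <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("variable", "test", "domain", "polarity") %in% names(schema)))
  if (anyDuplicated(schema$variable)) stop("duplicate variable names in EF schema")
  schema
}

#' Read an executive-function score table
#'
#' Wide UTF-8 TSV, one row per participant, one column per EF variable as
#' registered in the battery schema.
#'
#' @param path Path to the score TSV.
#' @param schema Battery registry tibble (default: [ef_schema()]).
#' @param on_unknown What to do with score columns absent from the schema:
#'   `"error"` or `"warn"` (drop with a warning).
#' @return A tibble `participant_id` + one numeric column per schema
#'   variable, with the schema attached as attribute `"schema"`.
#' @export
read_ef_scores <- function(path, schema = ef_schema(), on_unknown = c("error", "warn")) {
  on_unknown <- match.arg(on_unknown)
  scores <- readr::read_tsv(path, col_types = readr::cols(
    participant_id = readr::col_character(), .default = readr::col_double()))
  if (anyDuplicated(scores$participant_id)) {
    stop("duplicate participant rows in EF score table")
  }
  unknown <- setdiff(names(scores), c("participant_id", schema$variable))
  if (length(unknown) > 0) {
    msg <- paste("EF score columns not in schema:", paste(unknown, collapse = ", "))
    if (on_unknown == "error") stop(msg) else {
      warning(msg, "; dropped", call. = FALSE)
      scores <- select(scores, -all_of(unknown))
    }
  }
  absent <- setdiff(schema$variable, names(scores))
  if (length(absent) > 0) {
    stop("EF score table missing schema variables: ", paste(absent, collapse = ", "))
  }
  scores <- select(scores, all_of(c("participant_id", schema$variable)))
  attr(scores, "schema") <- schema
  scores
}

#' Read a demographics table
#'
#' UTF-8 TSV with columns `participant_id`, `sex` (0/1), `age` (years) and
#' `education` (ordinal 1-4: middle school, job training, high-school
#' diploma, university degree).
#'
#' @param path Path to the TSV.
#' @param age_range Admissible age range in years.
#' @return A tibble with one row per participant.
#' @export
read_demographics <- function(path, age_range = c(18, 90)) {
  demo <- readr::read_tsv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    sex = readr::col_double(), age = readr::col_double(),
    education = readr::col_double()))
  if (!all(demo$education %in% 1:4)) stop("education must be ordinal 1-4")
  if (!all(demo$age >= age_range[1] & demo$age <= age_range[2])) {
    stop("age outside configured range [", age_range[1], ", ", age_range[2], "]")
  }
  if (anyDuplicated(demo$participant_id)) stop("duplicate participant rows in demographics")
  demo
}
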