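# Telemetry ingestion: event logs, food taxonomy, cohort outcome tables.
#
# An event log holds one record per game click: who (child_id), when
# (session, date, time), where (level) and what (status text). The seven
# recognised status descriptions map onto the symbol alphabet
# {S, 1, 2, 3, 4, 5, E}; a "reads food fact" record marks a nutrition-fact
# view on the post-level summary screen and carries a food_id.

# canonical status text -> sequence symbol
.status_symbols <- c(
  "player starts the level"                      = "S",
  "player finishes the level"                    = "E",
  "player consumes good food to generate shield" = "1",
  "robot killed by good food shields"            = "2",
  "player shoots bad food ammo"                  = "3",
  "robot killed by bad food shots"               = "4",
  "player hit by bad food robot"                 = "5"
)

.status_fact <- "player reads food fact"

.norm_status <- function(x) stringr::str_squish(tolower(x))

#' Sequence state alphabet
#'
#' The seven states of the gameplay chain, in canonical order: level start
#' `S`, avatar actions `1`-`5` (good-food shield, robot killed by shield,
#' bad-food shot, robot killed by shot, avatar hit), and level end `E`.
#'
#' @return Character vector of length 7.
#' @export
markov_states <- function() c("S", "1", "2", "3", "4", "5", "E")

#' Map an event description to its sequence symbol
#'
#' Status text is matched against the seven recognised descriptions after
#' lower-casing and whitespace normalisation, so `"player STARTS the level "`
#' labels as `S`.
#'
#' @param status Character vector of event descriptions.
#' @return Character vector of symbols in `markov_states()`.
#' @examples
#' label_event("Player consumes good food to generate shield")
#' @export
label_event <- function(status) {
  sym <- unname(.status_symbols[.norm_status(status)])
  if (anyNA(sym)) {
    bad <- unique(status[is.na(sym)])
    pt_abort(
      paste0("Unrecognised event status: ", paste(sQuote(bad), collapse = ", ")),
      class = "playtrace_label_error", status = bad
    )
  }
  sym
}

# event_class for a status; NA when unrecognised (collected as rejects)
.classify_status <- function(status) {
  n <- .norm_status(status)
  sym <- unname(.status_symbols[n])
  dplyr::case_when(
    n == .status_fact ~ "fact_read",
    sym == "S" ~ "level_start",
    sym == "E" ~ "level_end",
    !is.na(sym) ~ "avatar_action",
    TRUE ~ NA_character_
  )
}

#' Parse a telemetry clock string to an instant
#'
#' The native log format stamps events as `HH-MM-SS-mmm` (24-hour clock,
#' millisecond suffix) alongside a `M/D` date column; combining the two gives
#' a total order that survives midnight. ISO-8601 datetimes are accepted via
#' `format = "iso8601"`.
#'
#' @param time Character vector of clock strings.
#' @param date Optional character vector of dates, `M/D` or `YYYY-MM-DD`.
#'   Recycled against `time`. Defaults to the epoch day.
#' @param year Assumed year for `M/D` dates (logs omit it).
#' @param format `"hms_ms"` (default) or `"iso8601"`.
#' @return POSIXct (UTC) vector, millisecond resolution.
#' @examples
#' parse_timestamp("09-20-19-775", date = "7/10")
#' @export
parse_timestamp <- function(time, date = NULL, year = 2019,
                            format = c("hms_ms", "iso8601")) {
  format <- match.arg(format)
  if (format == "iso8601") {
    out <- as.POSIXct(time, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(out) & !anyNA(time)) {
      pt_abort("Malformed ISO-8601 timestamp.", "playtrace_parse_error")
    }
    return(out)
  }
  m <- stringr::str_match(time, "^(\\d{2})-(\\d{2})-(\\d{2})-(\\d{3})$")
  if (anyNA(m[, 1])) {
    bad <- unique(time[is.na(m[, 1])])
    pt_abort(
      paste0("Malformed time string (expected HH-MM-SS-mmm): ",
             paste(sQuote(utils::head(bad, 3)), collapse = ", ")),
      class = "playtrace_parse_error", field = "time", value = bad
    )
  }
  hh <- as.integer(m[, 2]); mm <- as.integer(m[, 3])
  ss <- as.integer(m[, 4]); ms <- as.integer(m[, 5])
  if (any(hh > 23)) pt_abort("Hour out of range in time field.",
                             "playtrace_parse_error", field = "hour")
  if (any(mm > 59)) pt_abort("Minute out of range in time field.",
                             "playtrace_parse_error", field = "minute")
  if (any(ss > 59)) pt_abort("Second out of range in time field.",
                             "playtrace_parse_error", field = "second")
  day <- .parse_log_date(date %||% "1970-01-01", year)
  day + hh * 3600 + mm * 60 + ss + ms / 1000
}

.parse_log_date <- function(date, year = 2019) {
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", date)
  md  <- stringr::str_match(date, "^(\\d{1,2})/(\\d{1,2})$")
  out <- rep(as.POSIXct(NA), length(date))
  out[iso] <- as.POSIXct(date[iso], tz = "UTC")
  ok <- !is.na(md[, 1])
  out[ok] <- as.POSIXct(
    sprintf("%04d-%02d-%02d", year, as.integer(md[ok, 2]), as.integer(md[ok, 3])),
    tz = "UTC"
  )
  if (anyNA(out)) {
    pt_abort(
      paste0("Malformed date (expected M/D or YYYY-MM-DD): ",
             paste(sQuote(unique(date[is.na(out)])), collapse = ", ")),
      class = "playtrace_parse_error", field = "date"
    )
  }
  out
}

.required_event_cols <- c("child_id", "session", "level", "date", "time", "status")

#' Read a telemetry event log
#'
#' Reads CSV or JSON-lines telemetry, classifies each record
#' (`level_start`, `level_end`, `avatar_action`, `fact_read`), parses
#' timestamps and returns events sorted by child, session and time. Sorting
#' is stable: records with identical timestamps keep file order. Records
#' whose status text is not recognised are removed from the result but
#' collected into a rejects report attached as `attr(x, "rejects")`, with a
#' warning — they are never silently dropped.
#'
#' @param path File path (or connection) to read.
#' @param dialect `"csv"` or `"jsonl"`.
#' @param year Assumed year for `M/D` log dates.
#' @return Tibble with columns `child_id`, `session`, `level`, `date`,
#'   `time`, `status`, `food_id`, `timestamp`, `event_class`, `label`
#'   (symbol, `NA` for fact reads).
#' @export
read_event_log <- function(path, dialect = c("csv", "jsonl"), year = 2019) {
  dialect <- match.arg(dialect)
  raw <- if (dialect == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) tibble() else
      as_tibble(jsonlite::stream_in(textConnection(lines), verbose = FALSE))
  }
  missing <- setdiff(.required_event_cols, names(raw))
  if (length(missing) > 0 && nrow(raw) == 0 && ncol(raw) == 0) {
    # empty jsonl file: no schema to violate, return empty canonical tibble
    return(.finish_events(tibble(
      child_id = character(), session = integer(), level = integer(),
      date = character(), time = character(), status = character(),
      food_id = character()
    ), year))
  }
  if (length(missing) > 0) {
    pt_abort(paste0("Event log is missing required column(s): ",
                    paste(missing, collapse = ", ")),
             class = "playtrace_schema_error", missing = missing)
  }
  if (!"food_id" %in% names(raw)) raw$food_id <- NA_character_
  events <- raw %>%
    mutate(
      child_id = as.character(.data$child_id),
      session  = as.integer(.data$session),
      level    = as.integer(stringr::str_extract(as.character(.data$level), "\\d+")),
      date     = as.character(.data$date),
      time     = as.character(.data$time),
      status   = as.character(.data$status),
      food_id  = dplyr::na_if(as.character(.data$food_id), "")
    ) %>%
    select(dplyr::all_of(c(.required_event_cols, "food_id")))
  .finish_events(events, year)
}

.finish_events <- function(events, year = 2019) {
  events$event_class <- .classify_status(events$status)
  rejects <- events[is.na(events$event_class), , drop = FALSE]
  if (nrow(rejects) > 0) {
    warn(sprintf("%d event(s) had unrecognised status text; see attr(x, 'rejects').",
                 nrow(rejects)))
    events <- events[!is.na(events$event_class), , drop = FALSE]
  }
  events$label <- NA_character_
  nonfact <- events$event_class != "fact_read"
  if (any(nonfact)) events$label[nonfact] <- label_event(events$status[nonfact])
  if (any(events$event_class == "fact_read" & is.na(events$food_id))) {
    pt_abort("fact_read events must carry a food_id.",
             class = "playtrace_schema_error")
  }
  if (any(nonfact & !is.na(events$food_id))) {
    pt_abort("Only fact_read events may carry a food_id.",
             class = "playtrace_schema_error")
  }
  events$timestamp <- if (nrow(events)) {
    parse_timestamp(events$time, events$date, year = year)
  } else {
    as.POSIXct(character(), tz = "UTC")
  }
  out <- events %>%
    mutate(.ord = dplyr::row_number()) %>%
    arrange(.data$child_id, .data$session, .data$timestamp, .data$.ord) %>%
    select(-".ord")
  attr(out, "rejects") <- as_tibble(rejects[setdiff(names(rejects), c("event_class", "label"))])
  out
}

#' Write a telemetry event log
#'
#' Writes the raw log columns so that `read_event_log()` round-trips to an
#' identical event list (both dialects).
#'
#' @param events Event tibble as returned by [read_event_log()] (derived
#'   columns are ignored on write).
#' @param path Output file path.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return The number of records written.
#' @export
write_event_log <- function(events, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  cols <- c(.required_event_cols, "food_id")
  out <- as_tibble(events)[, intersect(cols, names(events)), drop = FALSE]
  if (dialect == "csv") {
    readr::write_csv(out, path, na = "")
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    if (nrow(out) > 0) jsonlite::stream_out(as.data.frame(out), con, verbose = FALSE)
  }
  nrow(out)
}

#' Load a food taxonomy
#'
#' A taxonomy maps each `food_id` appearing in fact-read events to `"good"`
#' (healthy) or `"bad"` (unhealthy). Accepts a YAML/JSON file, a named
#' character vector (`c(water = "good", ...)`), or a list of the form
#' `list(good = c(...), bad = c(...))`. Duplicate entries with the same class
#' are deduplicated; conflicting entries are an error.
#'
#' @param source Path, named character vector, or list (see above).
#' @return Tibble with columns `food_id`, `class`.
#' @examples
#' load_food_taxonomy(c(water = "good", chips = "bad"))
#' @export
load_food_taxonomy <- function(source) {
  if (is.character(source) && is.null(names(source)) && length(source) == 1) {
    source <- if (grepl("\\.ya?ml$", source)) {
      yaml::read_yaml(source)
    } else {
      jsonlite::fromJSON(source)
    }
  }
  if (is.character(source) && !is.null(names(source))) {
    source <- as.list(source)
  }
  tab <- if (is.list(source) && all(names(source) %in% c("good", "bad"))) {
    tibble(
      food_id = as.character(unlist(source, use.names = FALSE)),
      class = rep(names(source), lengths(source))
    )
  } else {
    tibble(food_id = names(source),
           class = as.character(unlist(source, use.names = FALSE)))
  }
  if (nrow(tab) == 0) return(tibble(food_id = character(), class = character()))
  if (!all(tab$class %in% c("good", "bad"))) {
    pt_abort("Taxonomy classes must be 'good' or 'bad'.",
             class = "playtrace_taxonomy_error")
  }
  tab <- distinct(tab)
  dup <- tab %>% count(.data$food_id) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    pt_abort(paste0("Food(s) mapped to conflicting classes: ",
                    paste(dup$food_id, collapse = ", ")),
             class = "playtrace_taxonomy_error", foods = dup$food_id)
  }
  arrange(tab, .data$food_id)
}

#' Default study food taxonomy
#'
#' The three healthy/unhealthy food pairs offered in the trial's
#' post-session choice task.
#'
#' @return Tibble with columns `food_id`, `class` (3 good, 3 bad foods).
#' @export
default_taxonomy <- function() {
  load_food_taxonomy(c(
    water = "good", cashews = "good", raisins = "good",
    Nimbooz = "bad", chips = "bad", chocolate = "bad"
  ))
}

#' Prepare a cohort outcome table
#'
#' Validates per-child records and derives the pooled outcomes: `good_choice`
#' (healthy items chosen over both days, 0-4), `good_id` (healthy items
#' identified over both surveys, 0-8), and day-2 minus day-1 change scores.
#' A child is `complete` for a given outcome family only if both days are
#' observed; incomplete children are retained but flagged, and downstream
#' group comparisons and regressions use complete cases only.
#'
#' @param children Data frame with columns `child_id`, `group`
#'   (`"treatment"`/`"control"`), `good_choice_day1`, `good_choice_day2`,
#'   `good_id_day1`, `good_id_day2`; optionally `school`, `good_base`,
#'   `gender`, `bmi`.
#' @return Tibble with derived columns appended.
#' @export
prepare_outcomes <- function(children) {
  need <- c("child_id", "group", "good_choice_day1", "good_choice_day2",
            "good_id_day1", "good_id_day2")
  missing <- setdiff(need, names(children))
  if (length(missing) > 0) {
    pt_abort(paste0("Cohort table is missing column(s): ",
                    paste(missing, collapse = ", ")),
             class = "playtrace_schema_error", missing = missing)
  }
  if (!all(children$group %in% c("treatment", "control"))) {
    pt_abort("group must be 'treatment' or 'control'.",
             class = "playtrace_schema_error")
  }
  .chk_range <- function(x, lo, hi, what) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) pt_abort(sprintf("%s out of range [%d, %d].", what, lo, hi),
                           class = "playtrace_schema_error")
  }
  .chk_range(children$good_choice_day1, 0, 2, "good_choice_day1")
  .chk_range(children$good_choice_day2, 0, 2, "good_choice_day2")
  .chk_range(children$good_id_day1, 0, 4, "good_id_day1")
  .chk_range(children$good_id_day2, 0, 4, "good_id_day2")
  out <- as_tibble(children) %>%
    mutate(
      good_choice = .data$good_choice_day1 + .data$good_choice_day2,
      good_id = .data$good_id_day1 + .data$good_id_day2,
      good_choice_change = .data$good_choice_day2 - .data$good_choice_day1,
      good_id_change = .data$good_id_day2 - .data$good_id_day1,
      complete_choice = !is.na(.data$good_choice_day1) & !is.na(.data$good_choice_day2),
      complete_id = !is.na(.data$good_id_day1) & !is.na(.data$good_id_day2)
    )
  if (!"school" %in% names(out)) out$school <- NA_character_
  if (!"good_base" %in% names(out)) out$good_base <- NA_integer_
  out
}
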