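# Encoding telemetry into per-level symbol sequences.
#
# A "play" is one contiguous encounter of one level by one child: it starts
# at a level_start event (symbol S), collects the chronological avatar-action
# symbols, and ends at level_end (E) or at the last logged event if the
# session stopped mid-level. Fact-read events happen on the post-level
# summary screen and are excluded from the symbols.

#' Build per-level symbol sequences from an event log
#'
#' Splits each child-session's chronologically ordered events into contiguous
#' level episodes and encodes each as a symbol string over
#' `{S, 1, 2, 3, 4, 5, E}`. An episode must open with a level-start event;
#' a level-end without a preceding start, an end that is not the final event
#' of its episode, or a level whose events resume after being abandoned
#' mid-episode (interleaving) raise a structural error.
#'
#' @param events Event tibble from [read_event_log()] or
#'   [generate_cohort()]; fact reads are ignored here.
#' @return Tibble with one row per play: `child_id`, `session`, `level`,
#'   `encounter_index` (1-based repetition counter per child and level,
#'   across sessions), `start_time`, `symbols`, `length`, `n_transitions`,
#'   `completed`.
#' @examples
#' ev <- generate_cohort(synth_config(n_children = 4), seed = 1)$events
#' build_level_sequences(ev)
#' @export
build_level_sequences <- function(events) {
  ev <- as_tibble(events) %>%
    filter(.data$event_class != "fact_read") %>%
    mutate(.ord = dplyr::row_number()) %>%
    arrange(.data$child_id, .data$session, .data$timestamp, .data$.ord)
  if (nrow(ev) == 0) {
    return(tibble(child_id = character(), session = integer(), level = integer(),
                  encounter_index = integer(), start_time = as.POSIXct(character(), tz = "UTC"),
                  symbols = character(), length = integer(),
                  n_transitions = integer(), completed = logical()))
  }
  ev <- ev %>%
    group_by(.data$child_id, .data$session) %>%
    mutate(.episode = cumsum(.data$label == "S" |
                               .data$level != dplyr::lag(.data$level, default = -1L))) %>%
    ungroup()

  plays <- ev %>%
    group_by(.data$child_id, .data$session, .data$.episode) %>%
    summarise(
      level = .data$level[1],
      start_time = .data$timestamp[1],
      symbols = paste(.data$label, collapse = ""),
      .groups = "drop"
    )

  bad_start <- !startsWith(plays$symbols, "S")
  if (any(bad_start)) {
    b <- plays[bad_start, ][1, ]
    pt_abort(sprintf(
      "Level events without a level start (child %s, session %d, level %d).",
      b$child_id, b$session, b$level), class = "playtrace_structure_error")
  }
  n_e <- stringr::str_count(plays$symbols, "E")
  bad_e <- n_e > 1 | (n_e == 1 & !endsWith(plays$symbols, "E"))
  if (any(bad_e)) {
    b <- plays[bad_e, ][1, ]
    pt_abort(sprintf(
      "Level end is not the unique final event of its play (child %s, session %d, level %d).",
      b$child_id, b$session, b$level), class = "playtrace_structure_error")
  }
  plays$completed <- endsWith(plays$symbols, "E")

  # interleaving: within a session a level may only reappear after a
  # completed episode of that level (a clean replay), never mid-level
  inter <- plays %>%
    group_by(.data$child_id, .data$session, .data$level) %>%
    filter(dplyr::n() > 1, any(!.data$completed & dplyr::row_number() < dplyr::n())) %>%
    ungroup()
  if (nrow(inter) > 0) {
    b <- inter[1, ]
    pt_abort(sprintf(
      "Interleaved plays of level %d within child %s, session %d.",
      b$level, b$child_id, b$session), class = "playtrace_structure_error")
  }

  plays %>%
    mutate(length = nchar(.data$symbols),
           n_transitions = count_transitions(.data$symbols)) %>%
    group_by(.data$child_id, .data$level) %>%
    arrange(.data$session, .data$start_time, .by_group = TRUE) %>%
    mutate(encounter_index = dplyr::row_number()) %>%
    ungroup() %>%
    arrange(.data$child_id, .data$session, .data$start_time) %>%
    select("child_id", "session", "level", "encounter_index", "start_time",
           "symbols", "length", "n_transitions", "completed")
}

#' Count state transitions in a symbol sequence
#'
#' A transition is an adjacent ordered pair whose two symbols differ;
#' repeats of the same state (for example a run of bad-food shots `33`) are
#' not transitions. `"S124331E"` has 7 adjacent pairs, one of which is the
#' self-pair `3->3`, hence 6 transitions.
#'
#' @param symbols Character vector of symbol strings.
#' @return Integer vector of transition counts.
#' @examples
#' count_transitions("S124331E") # 6
#' @export
count_transitions <- function(symbols) {
  vapply(strsplit(symbols, ""), function(s) {
    n <- length(s)
    if (n < 2) return(0L)
    sum(s[-1] != s[-n])
  }, integer(1))
}

#' Keep only each child's first encounter of each level
#'
#' Play-pattern analysis uses the earliest play of each level by each child,
#' across both sessions; replays are dropped. Idempotent.
#'
#' @param plays Tibble from [build_level_sequences()].
#' @return Tibble with exactly one row per distinct (child, level) pair.
#' @export
filter_first_encounters <- function(plays) {
  if ("encounter_index" %in% names(plays)) {
    return(filter(plays, .data$encounter_index == 1L))
  }
  plays %>%
    group_by(.data$child_id, .data$level) %>%
    arrange(.data$session, .data$start_time, .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup()
}
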