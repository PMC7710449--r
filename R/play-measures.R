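# Per-child gameplay measures in the MDA (mechanics, dynamics, aesthetics)
# tradition, adapted to mechanics, dynamics, strategies and food learning:
#
#   level_max      highest level reached over both sessions      (mechanics)
#   avg_seqlen     mean symbol-sequence length per level played  (mechanics)
#   avg_transition mean state-changing pairs per level played    (dynamics)
#   shield_prop    smoothed share of robot kills won by shield   (strategies)
#   avg_gfact      good-food facts read per level played         (food learning)
#   avg_bfact      bad-food facts read per level played          (food learning)
#
# All measures are computed on first-encounter plays only.

#' Smoothed proportion of robot kills achieved by shield
#'
#' Of all robots a child destroyed, the share destroyed by the good-food
#' shield (state 2) rather than by bad-food shots (state 4). Symmetric
#' additive smoothing keeps the proportion a legal fraction strictly inside
#' (0, 1) even for children who never destroyed a robot one way:
#' `(sum2 + alpha) / (sum2 + sum4 + 2 * alpha)`.
#'
#' @param sum2 Count of shield kills (symbol `2`), nonnegative.
#' @param sum4 Count of shot kills (symbol `4`), nonnegative.
#' @param alpha Smoothing constant, >= 0; must be positive when
#'   `sum2 + sum4 = 0`. Default 0.5 (a Jeffreys-style half-count).
#' @return Numeric proportion(s).
#' @examples
#' shield_kill_proportion(0, 165) # ~0.003
#' @export
shield_kill_proportion <- function(sum2, sum4, alpha = 0.5) {
  stopifnot(all(sum2 >= 0), all(sum4 >= 0), alpha >= 0)
  if (alpha == 0 && any(sum2 + sum4 == 0)) {
    pt_abort("Proportion undefined: no kills observed and alpha = 0.",
             class = "playtrace_degenerate_error")
  }
  (sum2 + alpha) / (sum2 + sum4 + 2 * alpha)
}

#' Compute per-child gameplay measures
#'
#' Summarises each child's first-encounter plays into the six gameplay
#' measures. Fact-read counts are taken from the event log, restricted to
#' the post-level screens of the retained (first-encounter) plays, and
#' divided by the number of levels played — children who read no facts
#' score 0.
#'
#' @param plays Tibble from [build_level_sequences()]; replays are dropped
#'   internally unless `first_encounters_only = FALSE`.
#' @param fact_events Optional event tibble (only `fact_read` rows are
#'   used). When omitted, `avg_gfact`/`avg_bfact` are 0.
#' @param taxonomy Tibble from [load_food_taxonomy()]; required when
#'   `fact_events` contains fact reads. A fact read for an unmapped food is
#'   an error.
#' @param alpha Smoothing for [shield_kill_proportion()].
#' @param first_encounters_only Restrict to first encounters (default).
#' @return Tibble, one row per child: `child_id`, `level_max`,
#'   `avg_seqlen`, `avg_transition`, `shield_prop`, `avg_gfact`,
#'   `avg_bfact`, `n_levels`, plus raw `sum2`, `sum4` kill counts.
#' @export
compute_play_measures <- function(plays, fact_events = NULL, taxonomy = NULL,
                                  alpha = 0.5, first_encounters_only = TRUE) {
  if (nrow(plays) == 0) {
    pt_abort("No plays supplied.", class = "playtrace_input_error")
  }
  if (first_encounters_only) plays <- filter_first_encounters(plays)
  measures <- plays %>%
    group_by(.data$child_id) %>%
    summarise(
      level_max = max(.data$level),
      avg_seqlen = mean(.data$length),
      avg_transition = mean(.data$n_transitions),
      sum2 = sum(stringr::str_count(.data$symbols, "2")),
      sum4 = sum(stringr::str_count(.data$symbols, "4")),
      n_levels = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(shield_prop = shield_kill_proportion(.data$sum2, .data$sum4, alpha))

  facts <- if (is.null(fact_events)) NULL else
    filter(as_tibble(fact_events), .data$event_class == "fact_read")
  if (!is.null(facts) && nrow(facts) > 0) {
    if (is.null(taxonomy)) {
      pt_abort("fact_events supplied without a taxonomy.",
               class = "playtrace_taxonomy_error")
    }
    unmapped <- setdiff(unique(facts$food_id), taxonomy$food_id)
    if (length(unmapped) > 0) {
      pt_abort(paste0("Fact read for unmapped food(s): ",
                      paste(unmapped, collapse = ", ")),
               class = "playtrace_taxonomy_error", foods = unmapped)
    }
    fact_counts <- facts %>%
      semi_join(plays, by = c("child_id", "session", "level")) %>%
      left_join(taxonomy, by = "food_id") %>%
      group_by(.data$child_id) %>%
      summarise(gfact = sum(.data$class == "good"),
                bfact = sum(.data$class == "bad"), .groups = "drop")
    measures <- measures %>%
      left_join(fact_counts, by = "child_id") %>%
      mutate(avg_gfact = dplyr::coalesce(.data$gfact, 0L) / .data$n_levels,
             avg_bfact = dplyr::coalesce(.data$bfact, 0L) / .data$n_levels) %>%
      select(-"gfact", -"bfact")
  } else {
    measures$avg_gfact <- 0
    measures$avg_bfact <- 0
  }
  measures %>%
    select("child_id", "level_max", "avg_seqlen", "avg_transition",
           "shield_prop", "avg_gfact", "avg_bfact", "n_levels", "sum2", "sum4")
}

.measure_cols <- c("level_max", "avg_seqlen", "avg_transition",
                   "shield_prop", "avg_gfact", "avg_bfact")

#' Cohort summary of the gameplay measures
#'
#' Min, mean, max, sample variance (n-1 denominator) and coefficient of
#' variation (100 * sd / mean, percent) for each gameplay measure.
#'
#' @param measures Tibble from [compute_play_measures()] (at least 2
#'   children).
#' @return Tibble, one row per measure.
#' @export
summarize_measures <- function(measures) {
  if (nrow(measures) < 2) {
    pt_abort("Need at least 2 children to summarise measures.",
             class = "playtrace_input_error")
  }
  measures %>%
    tidyr::pivot_longer(dplyr::all_of(intersect(.measure_cols, names(measures))),
                        names_to = "measure", values_to = "value") %>%
    group_by(.data$measure) %>%
    summarise(
      min = min(.data$value),
      mean = mean(.data$value),
      max = max(.data$value),
      variance = var(.data$value),
      cv = ifelse(mean(.data$value) > 0,
                  100 * sd(.data$value) / mean(.data$value), NA_real_),
      .groups = "drop"
    ) %>%
    mutate(measure = factor(.data$measure, levels = .measure_cols)) %>%
    arrange(.data$measure) %>%
    mutate(measure = as.character(.data$measure))
}

#' Distribution of the gameplay measures across a cohort
#'
#' @param measures Tibble from [compute_play_measures()].
#' @return A ggplot object: one histogram facet per measure.
#' @export
plot_measure_distributions <- function(measures) {
  long <- measures %>%
    tidyr::pivot_longer(dplyr::all_of(intersect(.measure_cols, names(measures))),
                        names_to = "measure", values_to = "value")
  ggplot(long, aes(x = .data$value)) +
    geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    facet_wrap(~measure, scales = "free") +
    labs(x = NULL, y = "children") +
    theme_minimal()
}
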