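# End-to-end orchestration: sequences -> Markov chain -> measures ->
# group comparisons -> association screen -> regressions, with
# CONSORT-style accounting of who entered and left each analysis.
#
# Site exclusions are deliberately asymmetric: play-pattern analyses
# (sequences, chain, measures) run on every site that produced telemetry,
# while outcome analyses honour `exclude_schools` — matching a trial in
# which one site's behavioural outcomes are unusable but its telemetry is
# fine.

#' Pipeline configuration
#'
#' @param first_encounters_only Analyse only each child's first encounter
#'   of each level (default TRUE).
#' @param alpha Smoothing for [shield_kill_proportion()].
#' @param exclude_schools Sites excluded from outcome (group-comparison and
#'   association) analyses; telemetry analyses keep all sites.
#' @param level_filter Optional single level for the Markov chain (e.g. 1
#'   for a first-level-only chain); `NULL` pools all levels.
#' @param se_type_linear,se_type_poisson Robust-SE flavours.
#' @param min_prob Edge threshold stored with the chain summary.
#' @param mw_mode Mann-Whitney mode for group comparisons.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(first_encounters_only = TRUE,
                            alpha = 0.5,
                            exclude_schools = character(),
                            level_filter = NULL,
                            se_type_linear = "HC1",
                            se_type_poisson = "HC0",
                            min_prob = 0.1,
                            mw_mode = "auto") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full telemetry-to-outcomes pipeline
#'
#' @param events Event tibble ([read_event_log()] / [generate_cohort()]
#'   schema) or a path to a CSV event log.
#' @param children Cohort outcome table (tibble or CSV path).
#' @param taxonomy Food taxonomy (tibble, path, or named vector).
#' @param config A [pipeline_config()].
#' @return A `playtrace_bundle` list with elements `plays`,
#'   `first_encounters`, `markov`, `edges`, `measures`, `measure_summary`,
#'   `comparisons`, `screen`, `dist_fit`, `selected_terms`, `models`,
#'   `manifest`, `config`. Deterministic given inputs and config.
#' @export
run_pipeline <- function(events, children, taxonomy = default_taxonomy(),
                         config = pipeline_config()) {
  if (is.character(events)) events <- read_event_log(events)
  if (is.character(children)) {
    children <- readr::read_csv(children, show_col_types = FALSE)
  }
  if (!inherits(taxonomy, "data.frame")) taxonomy <- load_food_taxonomy(taxonomy)
  children <- prepare_outcomes(children)

  plays <- build_level_sequences(events)
  fe <- if (config$first_encounters_only) filter_first_encounters(plays) else plays
  markov_plays <- if (is.null(config$level_filter)) fe else
    filter(fe, .data$level %in% config$level_filter)
  markov <- estimate_transition_matrix(markov_plays)
  measures <- compute_play_measures(fe, events, taxonomy, alpha = config$alpha,
                                    first_encounters_only = FALSE)
  measure_summary <- summarize_measures(measures)

  outcome_children <- filter(children,
                             !.data$school %in% config$exclude_schools)
  comparisons <- compare_groups(outcome_children, mode = config$mw_mode)
  screen <- screen_associations(measures, outcome_children)
  assoc_dat <- .analysis_frame(measures, outcome_children)
  dist_fit <- distribution_fit_aic(assoc_dat$good_choice)
  selected <- stepwise_select(assoc_dat, "good_choice",
                              candidates = .measure_cols)
  models <- fit_choice_models(measures, outcome_children,
                              se_type_linear = config$se_type_linear,
                              se_type_poisson = config$se_type_poisson)

  manifest <- tibble(
    stage = c("children_in", "children_excluded_school",
              "children_missing_outcome_day", "children_outcome_analyzed",
              "treatment_children_with_telemetry", "sequences_total",
              "sequences_first_encounter", "association_n"),
    n = c(nrow(children),
          sum(children$school %in% config$exclude_schools),
          sum(!outcome_children$complete_choice),
          sum(outcome_children$complete_choice),
          dplyr::n_distinct(plays$child_id),
          nrow(plays), nrow(fe), nrow(assoc_dat)),
    note = c("cohort table rows",
             paste0("schools: ", paste(config$exclude_schools, collapse = ", ")),
             "missing a choice outcome day (post-exclusion)",
             "complete choice outcomes (post-exclusion)",
             "children contributing sequences (all sites)",
             "all plays", "after first-encounter filter",
             "treatment, complete outcome, telemetry")
  )

  structure(
    list(plays = plays, first_encounters = fe, markov = markov,
         edges = filter_by_probability(markov, config$min_prob),
         measures = measures, measure_summary = measure_summary,
         comparisons = comparisons, screen = screen, dist_fit = dist_fit,
         selected_terms = selected, models = models,
         manifest = manifest, config = config),
    class = "playtrace_bundle"
  )
}

#' @export
print.playtrace_bundle <- function(x, ...) {
  cat("playtrace pipeline bundle\n")
  print(as.data.frame(x$manifest), row.names = FALSE)
  invisible(x)
}

.bundle_parts <- c("plays", "first_encounters", "markov", "measures",
                   "measure_summary", "comparisons", "screen", "models",
                   "manifest")

.md_table <- function(df, digits = 4) {
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", formatC(v, digits = digits,
                                                    format = "g"))
    else as.character(v)
  }
  cells <- purrr::map_dfc(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Write pipeline outputs to disk
#'
#' Emits the bundle's tables as CSV files and/or a single markdown report
#' (`report.md`) whose tables carry the same numbers, rounded for display.
#'
#' @param bundle A `playtrace_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param format Any of `"csv"`, `"markdown"`.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(bundle, dir, format = c("csv", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  missing <- setdiff(.bundle_parts, names(bundle))
  missing <- c(missing,
               .bundle_parts[vapply(intersect(.bundle_parts, names(bundle)),
                                    function(p) is.null(bundle[[p]]) ||
                                      (is.data.frame(bundle[[p]]) && nrow(bundle[[p]]) == 0 &&
                                         p %in% c("measures", "measure_summary")),
                                    logical(1))])
  if (length(missing) > 0) {
    pt_abort(paste0("Bundle is incomplete; missing piece(s): ",
                    paste(unique(missing), collapse = ", ")),
             class = "playtrace_input_error", missing = unique(missing))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tables <- list(
    plays = bundle$plays,
    first_encounters = bundle$first_encounters,
    measures = bundle$measures,
    measure_summary = bundle$measure_summary,
    group_comparisons = bundle$comparisons,
    association_screen = bundle$screen,
    regression_models = tidy(bundle$models),
    transition_probabilities = tidy(bundle$markov),
    manifest = bundle$manifest
  )
  if ("csv" %in% format) {
    for (nm in names(tables)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      out <- tables[[nm]]
      if ("start_time" %in% names(out)) {
        out$start_time <- format(out$start_time, "%Y-%m-%d %H:%M:%OS3", tz = "UTC")
      }
      readr::write_csv(out, p, na = "")
      paths <- c(paths, p)
    }
  }
  if ("markdown" %in% format) {
    md <- c("# Gameplay telemetry analysis report", "")
    for (nm in setdiff(names(tables), c("plays", "first_encounters",
                                        "transition_probabilities"))) {
      md <- c(md, paste0("## ", gsub("_", " ", nm)), "",
              .md_table(as_tibble(tables[[nm]])), "")
    }
    p <- file.path(dir, "report.md")
    writeLines(md, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
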