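# Pooled first-order Markov chain over the seven gameplay states.
#
# The chain is discrete and time-homogeneous: adjacent symbol pairs are
# pooled over all sequences, and each row of the transition matrix is the
# raw proportion of observed moves out of that state. E is absorbing (its
# outgoing row is all zero) and nothing re-enters S.

.validate_symbols <- function(symbols) {
  ok <- grepl("^S[1-5]*E?$", symbols)
  if (!all(ok)) {
    pt_abort(paste0("Invalid symbol string(s): ",
                    paste(sQuote(utils::head(symbols[!ok], 3)), collapse = ", ")),
             class = "playtrace_structure_error")
  }
  invisible(symbols)
}

#' Estimate the pooled gameplay transition matrix
#'
#' Counts every adjacent ordered symbol pair across all supplied sequences
#' (self-pairs included) and row-normalises to transition probabilities.
#' Rows never observed leaving (other than the absorbing end state `E`) are
#' reported as undefined — all-zero, with the state listed in
#' `$undefined_rows` — rather than smoothed or set uniform.
#'
#' @param plays Tibble with a `symbols` column (as from
#'   [build_level_sequences()]) or a character vector of symbol strings.
#' @return A `playtrace_markov` object: list with `states`, `counts`
#'   (7x7 integer), `probs` (7x7), `n_sequences`, `n_pairs`,
#'   `undefined_rows`.
#' @examples
#' tm <- estimate_transition_matrix("S124331E")
#' tm$probs["1", "2"] # 0.5
#' @export
estimate_transition_matrix <- function(plays) {
  symbols <- if (is.character(plays)) plays else plays$symbols
  if (length(symbols) == 0) {
    pt_abort("No sequences supplied.", class = "playtrace_input_error")
  }
  .validate_symbols(symbols)
  states <- markov_states()
  chars <- strsplit(symbols, "")
  from <- unlist(lapply(chars, function(s) s[-length(s)]))
  to <- unlist(lapply(chars, function(s) s[-1]))
  counts <- table(factor(from, levels = states), factor(to, levels = states))
  counts <- matrix(as.integer(counts), 7, 7, dimnames = list(states, states))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  undefined <- setdiff(states[rs == 0], "E")
  structure(
    list(states = states, counts = counts, probs = probs,
         n_sequences = length(symbols), n_pairs = sum(counts),
         undefined_rows = undefined),
    class = "playtrace_markov"
  )
}

#' @export
print.playtrace_markov <- function(x, digits = 3, ...) {
  cat(sprintf("Gameplay Markov chain: %d states, %d sequences, %d observed pairs\n",
              length(x$states), x$n_sequences, x$n_pairs))
  print(round(x$probs, digits))
  if (length(x$undefined_rows) > 0) {
    cat("Undefined (never-exited) rows:", paste(x$undefined_rows, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.playtrace_markov <- function(x, ...) {
  tibble(
    from = rep(x$states, times = length(x$states)),
    to = rep(x$states, each = length(x$states)),
    count = as.integer(x$counts[cbind(rep(seq_along(x$states), times = 7),
                                      rep(seq_along(x$states), each = 7))]),
    prob = x$probs[cbind(rep(seq_along(x$states), times = 7),
                         rep(seq_along(x$states), each = 7))]
  )
}

#' @export
glance.playtrace_markov <- function(x, ...) {
  tibble(n_states = length(x$states), n_sequences = x$n_sequences,
         n_pairs = x$n_pairs, n_undefined_rows = length(x$undefined_rows))
}

#' Keep transition edges above a probability threshold
#'
#' Returns the sparse edge list of transitions with probability strictly
#' greater than `threshold` — the usual way to draw a simplified chain
#' diagram (for instance, edges with probability above 0.1).
#'
#' @param tm A `playtrace_markov` object.
#' @param threshold Probability cut, in `[0, 1]`.
#' @return Tibble `from`, `to`, `prob`, sorted by decreasing probability.
#' @export
filter_by_probability <- function(tm, threshold) {
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  tidy(tm) %>%
    filter(.data$prob > threshold) %>%
    arrange(dplyr::desc(.data$prob)) %>%
    select("from", "to", "prob")
}

#' Simulate one play sequence from a transition matrix
#'
#' Starts at `S` and draws each next symbol from the current state's row
#' until the absorbing end state `E` is reached or `max_len` symbols have
#' been emitted. Hitting an undefined (all-zero) row before `E` also stops
#' the walk; both cases are flagged via `attr(x, "truncated")`.
#'
#' @param tm A `playtrace_markov` object, or a 7x7 row-stochastic matrix
#'   with `markov_states()` dimnames.
#' @param max_len Maximum number of symbols (>= 2).
#' @param seed Optional integer seed for a self-contained draw; by default
#'   the current RNG stream is used.
#' @return A symbol string; `attr(, "truncated")` is `TRUE` if the walk was
#'   cut short.
#' @export
simulate_sequence <- function(tm, max_len = 400, seed = NULL) {
  probs <- if (inherits(tm, "playtrace_markov")) tm$probs else tm
  states <- markov_states()
  stopifnot(is.matrix(probs), all(dim(probs) == c(7, 7)), max_len >= 2)
  if (abs(sum(probs["S", ]) - 1) > 1e-8) {
    pt_abort("S row of the transition matrix must sum to 1.",
             class = "playtrace_input_error")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  cum <- t(apply(probs, 1, cumsum))
  idx <- .walk_chain(cum, max_len)
  res <- paste(states[idx], collapse = "")
  attr(res, "truncated") <- states[idx[length(idx)]] != "E"
  res
}

# inverse-CDF walk over precomputed cumulative rows; state 1 = S, 7 = E
.walk_chain <- function(cum, max_len) {
  path <- integer(max_len)
  path[1] <- 1L
  cur <- 1L
  n <- 1L
  while (n < max_len) {
    row <- cum[cur, ]
    tot <- row[7]
    if (tot <= 0) break  # undefined row: walk cannot continue
    cur <- sum(row < stats::runif(1) * tot) + 1L
    n <- n + 1L
    path[n] <- cur
    if (cur == 7L) break
  }
  path[seq_len(n)]
}

#' Simulate many play sequences
#'
#' @param tm As in [simulate_sequence()].
#' @param n Number of sequences.
#' @param max_len Maximum symbols per sequence.
#' @param seed Optional integer seed.
#' @return Character vector of length `n`.
#' @export
simulate_sequences <- function(tm, n, max_len = 400, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  vapply(seq_len(n), function(i) as.character(simulate_sequence(tm, max_len)),
         character(1))
}

#' Heatmap of a gameplay transition matrix
#'
#' @param object A `playtrace_markov` object.
#' @param min_prob Hide cells at or below this probability (default 0 shows
#'   every observed transition).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.playtrace_markov <- function(object, min_prob = 0, ...) {
  dat <- tidy(object) %>%
    filter(.data$prob > min_prob) %>%
    mutate(from = factor(.data$from, levels = rev(object$states)),
           to = factor(.data$to, levels = object$states))
  ggplot(dat, aes(x = .data$to, y = .data$from, fill = .data$prob)) +
    geom_tile(colour = "grey80") +
    geom_text(aes(label = sprintf("%.2f", .data$prob)), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(x = "to state", y = "from state", fill = "P",
         title = sprintf("Gameplay transition probabilities (n = %d sequences)",
                         object$n_sequences)) +
    theme_minimal()
}
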