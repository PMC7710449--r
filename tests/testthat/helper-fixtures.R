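# Shared fixtures and independent brute-force oracles.

# The published worked example: eight timestamped events of one level-1 play.
# Note rows 4-5: the shot-kill is logged 100 ms before the shot itself.
table3_lines <- function() {
  c("child_id,session,level,date,time,status",
    "K1,1,1,7/10,09-20-19-775,Player starts the level",
    "K1,1,1,7/10,09-20-26-482,Player consumes good food to generate shield",
    "K1,1,1,7/10,09-20-28-956,Robot killed by good food shields",
    "K1,1,1,7/10,09-21-10-714,Robot killed by bad food shots",
    "K1,1,1,7/10,09-21-10-814,Player shoots bad food ammo",
    "K1,1,1,7/10,09-21-10-894,Player shoots bad food ammo",
    "K1,1,1,7/10,09-21-14-717,Player consumes good food to generate shield",
    "K1,1,1,7/10,09-21-20-281,Player finishes the level")
}

table3_events <- function() {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(table3_lines(), f)
  read_event_log(f)
}

# minimal event-log writer for hand-built fixtures
events_from_rows <- function(...) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("child_id,session,level,date,time,status", ...), f)
  read_event_log(f)
}

# Exact Mann-Whitney oracle: full enumeration of group labelings.
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  dist <- apply(utils::combn(length(pooled), n1), 2, u_of)
  min(1, 2 * min(mean(dist <= u_obs), mean(dist >= u_obs)))
}

# Kendall tau-b oracle: O(n^2) pair counting with tie adjustment.
kendall_brute_force <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Transition-count oracle: explicit pair enumeration.
transitions_brute_force <- function(symbols) {
  s <- strsplit(symbols, "")[[1]]
  if (length(s) < 2) return(0L)
  n <- 0L
  for (i in seq_len(length(s) - 1)) if (s[i] != s[i + 1]) n <- n + 1L
  n
}

# Pair-count oracle for transition matrices.
pair_counts_brute_force <- function(symbols) {
  states <- markov_states()
  counts <- matrix(0L, 7, 7, dimnames = list(states, states))
  for (sym in symbols) {
    s <- strsplit(sym, "")[[1]]
    for (i in seq_len(length(s) - 1)) {
      counts[s[i], s[i + 1]] <- counts[s[i], s[i + 1]] + 1L
    }
  }
  counts
}
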