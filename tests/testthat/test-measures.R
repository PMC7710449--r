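test_that("shield-kill proportion follows the smoothed fraction", {
  expect_equal(shield_kill_proportion(1, 1, alpha = 0), 0.5)
  expect_equal(shield_kill_proportion(0, 0, alpha = 0.5), 0.5)
  # a never-shield child with many shot kills sits just above zero
  expect_equal(round(shield_kill_proportion(0, 165, alpha = 0.5), 3), 0.003)
  expect_error(shield_kill_proportion(0, 0, alpha = 0),
               class = "playtrace_degenerate_error")
  # strictly monotone: increasing in shield kills, decreasing in shot kills
  s2 <- shield_kill_proportion(0:20, 5)
  expect_true(all(diff(s2) > 0))
  s4 <- shield_kill_proportion(5, 0:20)
  expect_true(all(diff(s4) < 0))
  expect_true(all(s2 > 0 & s2 < 1))
})

test_that("per-child measures reduce plays by hand-checkable arithmetic", {
  ev <- events_from_rows(
    "K1,1,1,7/10,10-00-00-000,Player starts the level",
    "K1,1,1,7/10,10-00-01-000,Player consumes good food to generate shield",
    "K1,1,1,7/10,10-00-02-000,Robot killed by good food shields",
    "K1,1,1,7/10,10-00-03-000,Robot killed by bad food shots",
    "K1,1,1,7/10,10-00-04-000,Player shoots bad food ammo",
    "K1,1,1,7/10,10-00-05-000,Player shoots bad food ammo",
    "K1,1,1,7/10,10-00-06-000,Player consumes good food to generate shield",
    "K1,1,1,7/10,10-00-07-000,Player finishes the level",
    "K1,1,2,7/10,10-01-00-000,Player starts the level",
    "K1,1,2,7/10,10-01-01-000,Player finishes the level"
  )
  m <- compute_play_measures(build_level_sequences(ev))
  expect_equal(m$level_max, 2L)
  expect_equal(m$avg_seqlen, 5)        # (8 + 2) / 2
  expect_equal(m$avg_transition, 3.5)  # (6 + 1) / 2
  expect_equal(m$n_levels, 2L)
  expect_equal(m$avg_gfact, 0)
  expect_equal(m$avg_bfact, 0)
  expect_equal(m$sum2, 1L)
  expect_equal(m$sum4, 1L)
  expect_equal(m$shield_prop, 0.5)
})

test_that("fact reads average over levels played and respect the taxonomy", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "child_id,session,level,date,time,status,food_id",
    "K1,1,1,7/10,10-00-00-000,Player starts the level,",
    "K1,1,1,7/10,10-00-01-000,Player finishes the level,",
    "K1,1,1,7/10,10-00-02-000,Player reads food fact,water",
    "K1,1,1,7/10,10-00-03-000,Player reads food fact,raisins",
    "K1,1,1,7/10,10-00-04-000,Player reads food fact,chips",
    "K1,1,2,7/10,10-01-00-000,Player starts the level,",
    "K1,1,2,7/10,10-01-01-000,Player finishes the level,",
    "K1,1,2,7/10,10-01-02-000,Player reads food fact,water"
  ), f)
  ev <- read_event_log(f)
  m <- compute_play_measures(build_level_sequences(ev), ev, default_taxonomy())
  expect_equal(m$avg_gfact, 1.5)  # 3 good reads over 2 levels
  expect_equal(m$avg_bfact, 0.5)

  unknown <- dplyr::mutate(ev, food_id = ifelse(!is.na(food_id), "pizza", food_id))
  expect_error(
    compute_play_measures(build_level_sequences(ev), unknown, default_taxonomy()),
    class = "playtrace_taxonomy_error"
  )
})

test_that("cohort summary reproduces published-scale mean/variance/CV identities", {
  # two-point constructions with a prescribed sample mean and variance:
  # {m - s/sqrt(2), m + s/sqrt(2)} has sample mean m and variance s^2
  two_point <- function(m, v) m + c(-1, 1) * sqrt(v / 2)
  measures <- tibble::tibble(
    child_id = c("a", "b"),
    level_max = two_point(14.78, 21.73),
    avg_seqlen = two_point(65.77, 893.28),
    avg_transition = two_point(22.51, 76.70),
    shield_prop = two_point(0.17, 0.05),
    avg_gfact = two_point(0.43, 0.18),
    avg_bfact = two_point(0.12, 0.02)
  )
  s <- summarize_measures(measures)
  cv <- function(m) s$cv[s$measure == m]
  expect_equal(round(cv("level_max"), 2), 31.54)
  expect_equal(round(cv("avg_seqlen"), 2), 45.44)
  expect_equal(round(cv("avg_transition"), 2), 38.91)
  expect_equal(round(cv("avg_gfact"), 2), 98.67)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))

  expect_error(summarize_measures(measures[1, ]),
               class = "playtrace_input_error")
})

test_that("constant measures and scaling behave as CV requires", {
  base <- tibble::tibble(
    child_id = letters[1:4],
    level_max = c(3, 5, 7, 9),
    avg_seqlen = rep(10, 4),
    avg_transition = c(2, 3, 4, 5),
    shield_prop = c(.1, .2, .3, .4),
    avg_gfact = c(0, 1, 2, 3),
    avg_bfact = c(1, 1, 2, 2)
  )
  s <- summarize_measures(base)
  expect_equal(s$variance[s$measure == "avg_seqlen"], 0)
  expect_equal(s$cv[s$measure == "avg_seqlen"], 0)
  # scale invariance of the CV
  scaled <- dplyr::mutate(base, dplyr::across(-child_id, ~ .x * 7.3))
  expect_equal(summarize_measures(scaled)$cv, s$cv)
})

test_that("measure computation defaults to first encounters", {
  ev <- events_from_rows(
    "K1,1,1,7/10,10-00-00-000,Player starts the level",
    "K1,1,1,7/10,10-00-01-000,Player finishes the level",
    "K1,2,1,7/17,10-00-00-000,Player starts the level",
    "K1,2,1,7/17,10-00-01-000,Player shoots bad food ammo",
    "K1,2,1,7/17,10-00-02-000,Player finishes the level"
  )
  plays <- build_level_sequences(ev)
  m <- compute_play_measures(plays)
  expect_equal(m$n_levels, 1L)     # replay excluded
  expect_equal(m$avg_seqlen, 2)    # the first encounter only
  m_all <- compute_play_measures(plays, first_encounters_only = FALSE)
  expect_equal(m_all$n_levels, 2L)
})
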