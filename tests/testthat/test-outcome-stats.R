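test_that("Mann-Whitney U follows the min convention with exact small-sample p", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-10)  # 2/6 of labelings
  expect_equal(res$method, "exact")

  # identical multisets: degenerate, p = 1
  same <- mann_whitney_u(c(2, 2, 2), c(2, 2))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  expect_error(mann_whitney_u(numeric(), 1:3), class = "playtrace_input_error")
})

test_that("exact p-values agree with full permutation enumeration", {
  set.seed(7)
  for (ns in list(c(3, 4), c(5, 5), c(8, 8))) {
    a <- rnorm(ns[1]); b <- rnorm(ns[2], mean = 0.8)
    res <- mann_whitney_u(a, b, mode = "exact")
    expect_equal(res$p_value, mw_enumeration_p(a, b), tolerance = 1e-10)
  }
})

test_that("normal approximation tracks the exact test at study-arm sizes", {
  set.seed(11)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  p_exact <- mann_whitney_u(a, b, mode = "exact")$p_value
  p_approx <- mann_whitney_u(a, b, mode = "normal_approx")$p_value
  expect_lt(abs(p_exact - p_approx), 0.02)
})

test_that("Cohen's d reproduces published change-score effect sizes", {
  # change in identification: (-0.26 - 0.23) / pooled SD
  expect_equal(round(cohens_d_from_summary(-0.26, 0.59, 27, 0.23, 1.12, 31), 2),
               -0.54)
  # change in choice (SD magnitude 0.93; a printed negative SD is a typo)
  expect_equal(round(cohens_d_from_summary(-0.11, 0.93, 27, -0.13, 1.02, 31), 2),
               0.02)
  expect_equal(cohens_d_from_summary(1, 2, 10, 1, 3, 10), 0)
  expect_error(cohens_d_from_summary(1, 0, 10, 2, 0, 10),
               class = "playtrace_degenerate_error")
  # antisymmetry under group swap
  d1 <- cohens_d_from_summary(2.48, 1.19, 27, 1.10, 1.08, 31)
  d2 <- cohens_d_from_summary(1.10, 1.08, 31, 2.48, 1.19, 27)
  expect_equal(d1, -d2)
})

test_that("sample-size and power computations are mutually consistent", {
  expect_equal(required_sample_size(0.50, 0.05, 0.80, "one"), 102L)
  expect_equal(required_sample_size(0.50, 0.05, 0.80, "two"), 128L)

  # power at the returned n clears the target; two fewer children misses it
  for (sided in c("one", "two")) {
    n <- required_sample_size(0.45, 0.05, 0.80, sided)
    expect_gte(achieved_power(0.45, n / 2, n / 2, 0.05, sided), 0.80)
    expect_lt(achieved_power(0.45, n / 2 - 1, n / 2 - 1, 0.05, sided), 0.80)
  }

  # more power demands more children at a fixed effect
  expect_gt(required_sample_size(0.5, 0.05, 0.90, "one"),
            required_sample_size(0.5, 0.05, 0.80, "one"))
})

test_that("achieved power behaves like the noncentral-t analysis it is", {
  # the trial's own numbers: d = 1.25 with arms of 27 and 31
  expect_gt(achieved_power(1.25, 27, 31, 0.05, "two"), 0.99)
  expect_gt(achieved_power(1.25, 27, 31, 0.05, "one"), 0.99)
  # null effect: power equals the test size
  expect_equal(achieved_power(0, 20, 20, 0.05, "two"), 0.05, tolerance = 1e-10)
  # monotone in n
  pw <- vapply(c(10, 20, 40, 80), function(n) achieved_power(0.5, n, n),
               numeric(1))
  expect_true(all(diff(pw) > 0))
  # equal-arm case agrees with the standard power solver
  expect_equal(achieved_power(0.6, 25, 25, 0.05, "two"),
               power.t.test(n = 25, delta = 0.6, sd = 1, strict = TRUE)$power,
               tolerance = 1e-8)
})

test_that("Cohen's kappa matches hand-computed agreement tables", {
  expect_equal(cohens_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1))$kappa, 1)
  # p_o = 0.5, p_e = 0.5 -> zero chance-corrected agreement
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))$kappa, 0)
  # 2x2 table {yy: 20, yn: 5, ny: 10, nn: 15}: p_o = .7, p_e = .5
  r1 <- rep(c("y", "y", "n", "n"), c(20, 5, 10, 15))
  r2 <- rep(c("y", "n", "y", "n"), c(20, 5, 10, 15))
  expect_equal(cohens_kappa(r1, r2)$kappa, 0.4)
  # both raters constant and identical: flagged, kappa 1
  const <- cohens_kappa(rep("a", 5), rep("a", 5))
  expect_true(const$degenerate)
  expect_equal(const$kappa, 1)
  expect_error(cohens_kappa(1:3, 1:4), class = "playtrace_input_error")
})

test_that("kappa agrees with an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(3)
  for (i in 1:10) {
    r1 <- sample(0:2, 40, replace = TRUE)
    r2 <- ifelse(runif(40) < 0.6, r1, sample(0:2, 40, replace = TRUE))
    expect_equal(cohens_kappa(r1, r2)$kappa,
                 e1071::classAgreement(table(r1, r2))$kappa,
                 tolerance = 1e-10)
  }
})

test_that("group comparisons use complete cases and report both arms", {
  co <- generate_cohort(synth_config(n_children = 120), seed = 17)
  cmp <- compare_groups(co$children)
  expect_equal(nrow(cmp), 4)
  expect_true(all(c("good_choice", "good_id") %in% cmp$outcome))
  row <- cmp[cmp$outcome == "good_choice", ]
  kids <- co$children
  expect_equal(row$n_t, sum(kids$group == "treatment" & kids$complete_choice))
  expect_equal(row$n_c, sum(kids$group == "control" & kids$complete_choice))
  # the generated treatment effect on choice is positive
  expect_gt(row$mean_t, row$mean_c)
  expect_gt(row$cohens_d, 0)
})
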