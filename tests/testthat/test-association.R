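test_that("Kendall tau matches brute-force pair counting", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau(1:3, 3:1)$tau, -1)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2))$tau, 1 / 3, tolerance = 1e-10)
  expect_error(kendall_tau(rep(1, 5), 1:5), class = "playtrace_degenerate_error")

  set.seed(5)
  for (i in 1:15) {
    n <- sample(5:20, 1)
    x <- sample(1:6, n, replace = TRUE)   # tied data exercises tau-b
    y <- x + sample(-2:2, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(kendall_tau(x, y)$tau, kendall_brute_force(x, y),
                 tolerance = 1e-10)
  }
})

test_that("Kendall tau is symmetric and rank-invariant", {
  set.seed(8)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  expect_equal(kendall_tau(x, y)$tau, kendall_tau(y, x)$tau)
  # invariant under strictly monotone transforms
  expect_equal(kendall_tau(exp(x), y)$tau, kendall_tau(x, y)$tau)
  expect_equal(kendall_tau(x, rank(y))$tau, kendall_tau(x, y)$tau)
})

test_that("distribution choice by AIC uses the closed-form likelihoods", {
  fit <- distribution_fit_aic(c(0, 1, 2))
  # Poisson at lambda = 1: loglik = -3 + log(1/2), AIC = 2 - 2 * loglik
  expect_equal(round(fit$aic_poisson, 2), 9.39)
  expect_equal(fit$aic_poisson, 2 - 2 * sum(dpois(0:2, 1, log = TRUE)))

  # tight symmetric counts (variance << mean): normal wins
  set.seed(2)
  y <- pmax(0, round(rnorm(200, mean = 20, sd = 1.5)))
  expect_equal(distribution_fit_aic(y)$family, "normal")

  # genuinely Poisson counts: Poisson wins in nearly every replicate
  wins <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    distribution_fit_aic(rpois(200, 2))$family == "poisson"
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  expect_error(distribution_fit_aic(c(0.5, 1.2)), class = "playtrace_input_error")
  expect_true(distribution_fit_aic(rep(3L, 10))$degenerate)
})

test_that("stepwise selection keeps real effects and discards pure noise", {
  set.seed(101)
  n <- 200
  dat <- tibble::tibble(
    x_true = rnorm(n), x_n1 = rnorm(n), x_n2 = rnorm(n), x_n3 = rnorm(n)
  )
  dat$y <- 1 + 1 * dat$x_true + rnorm(n, sd = 0.5)
  sel <- stepwise_select(dat, "y", c("x_true", "x_n1", "x_n2", "x_n3"))
  expect_true("x_true" %in% sel)

  # exhaustive-subset oracle: best-AIC subset must contain the true term
  subsets <- unlist(lapply(0:4, function(k)
    utils::combn(c("x_true", "x_n1", "x_n2", "x_n3"), k, simplify = FALSE)),
    recursive = FALSE)
  aics <- vapply(subsets, function(s) {
    f <- if (length(s) == 0) y ~ 1 else stats::reformulate(s, "y")
    AIC(lm(f, dat))
  }, numeric(1))
  expect_setequal(sel, subsets[[which.min(aics)]])

  # pure noise: median selected-set size over seeds is zero
  sizes <- vapply(1:50, function(i) {
    set.seed(2000 + i)
    nd <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                         y = rnorm(n))
    length(stepwise_select(nd, "y", c("a", "b", "c")))
  }, numeric(1))
  expect_equal(median(sizes), 0)
})

test_that("forced terms survive selection and collinear candidates are dropped", {
  set.seed(55)
  n <- 120
  dat <- tibble::tibble(g = rbinom(n, 1, .5), x = rnorm(n))
  dat$dup <- 2 * dat$x          # exactly collinear
  dat$y <- rnorm(n)             # g has no effect
  sel <- stepwise_select(dat, "y", c("x"), forced = "g")
  expect_true("g" %in% sel)
  expect_warning(
    sel2 <- stepwise_select(dat, "y", c("x", "dup")),
    "collinear"
  )
  expect_equal(attr(sel2, "dropped"), "dup")
})

test_that("robust linear fits recover noiseless and noisy truths", {
  dat <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  fit <- fit_linear_robust(dat, y ~ x)
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_true(fit$degenerate)  # zero residual variance flagged

  dat$x2 <- 2 * dat$x
  expect_error(fit_linear_robust(dat, y ~ x + x2),
               class = "playtrace_rank_error")

  # coverage: each coefficient within 3 robust SEs of truth in >= 95% of seeds
  ok <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    n <- 25
    X <- cbind(rnorm(n), rnorm(n))
    y <- 2.4 + 1.2 * X[, 1] - 8.4 * X[, 2] + rnorm(n)
    d <- tibble::tibble(y = y, x1 = X[, 1], x2 = X[, 2])
    f <- fit_linear_robust(d, y ~ x1 + x2)
    abs(f$coefficients$estimate - c(2.4, 1.2, -8.4)) <=
      3 * f$coefficients$robust_se
  }, logical(3))
  expect_true(all(rowMeans(ok) >= 0.95))
})

test_that("HC1 errors exceed classical errors under heteroskedasticity", {
  set.seed(77)
  n <- 300
  x <- runif(n, 1, 5)
  y <- 1 + 0.5 * x + rnorm(n, sd = x^2 / 5)
  d <- tibble::tibble(x = x, y = y)
  fit <- fit_linear_robust(d, y ~ x)
  classical <- summary(lm(y ~ x, d))$coefficients["x", "Std. Error"]
  robust <- fit$coefficients$robust_se[fit$coefficients$term == "x"]
  expect_gt(robust, classical)
})

test_that("Poisson fits use the log link with sandwich errors", {
  d <- tibble::tibble(y = c(1L, 2L, 3L))
  fit <- fit_poisson_robust(d, y ~ 1)
  expect_equal(fit$coefficients$estimate, log(2), tolerance = 1e-8)

  expect_error(fit_poisson_robust(tibble::tibble(y = c(1.5, 2)), y ~ 1),
               class = "playtrace_input_error")

  zero <- fit_poisson_robust(tibble::tibble(y = rep(0L, 10)), y ~ 1)
  expect_true(zero$degenerate)
  expect_false(zero$converged)

  # recovery within 3 robust SEs of the generating coefficients
  ok <- vapply(1:200, function(i) {
    set.seed(4000 + i)
    n <- 500
    x <- rnorm(n)
    y <- rpois(n, exp(0.3 + 0.5 * x))
    f <- fit_poisson_robust(tibble::tibble(x = x, y = y), y ~ x)
    all(abs(f$coefficients$estimate - c(0.3, 0.5)) <=
          3 * f$coefficients$robust_se)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("noise columns raise AIC in expectation while never hurting fit", {
  set.seed(31)
  worse <- vapply(1:40, function(i) {
    n <- 100
    d <- tibble::tibble(x = rnorm(n), noise = rnorm(n))
    d$y <- 1 + d$x + rnorm(n)
    f0 <- fit_linear_robust(d, y ~ x)
    f1 <- fit_linear_robust(d, y ~ x + noise)
    r0 <- sum(residuals(f0$model)^2); r1 <- sum(residuals(f1$model)^2)
    expect_lte(r1, r0 + 1e-10)      # in-sample fit never degrades
    f1$aic > f0$aic
  }, logical(1))
  expect_gt(mean(worse), 0.5)
})

test_that("the normality check behaves as a calibrated Shapiro-Wilk", {
  rejections <- vapply(1:500, function(i) {
    set.seed(5000 + i)
    normality_check(rnorm(100))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)

  skew_rej <- vapply(1:200, function(i) {
    set.seed(6000 + i)
    normality_check(rexp(100))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(skew_rej), 0.99)

  expect_error(normality_check(c(1, 2)), class = "playtrace_input_error")
  expect_error(normality_check(rep(1, 10)),
               class = "playtrace_degenerate_error")
})

test_that("association screen and model set mirror the analysis layout", {
  co <- generate_cohort(synth_config(n_children = 150, p_missing = 0), seed = 23)
  plays <- filter_first_encounters(build_level_sequences(co$events))
  m <- compute_play_measures(plays, co$events, default_taxonomy())
  sc <- screen_associations(m, co$children)
  expect_equal(nrow(sc), 6)
  expect_true(all(abs(sc$tau) <= 1))

  models <- fit_choice_models(m, co$children)
  expect_named(models, c("normal", "normal_adjusted", "poisson",
                         "poisson_adjusted"))
  td <- tidy(models)
  expect_true(all(c("model", "term", "estimate", "robust_se") %in% names(td)))
  # sign consistency across families for the strongly-signed bad-fact effect
  bfact <- td[td$term == "avg_bfact", ]
  expect_true(all(bfact$estimate < 0))
  g <- glance(models)
  expect_equal(nrow(g), 4)
  expect_false(any(is.na(g$adj_r2[g$family == "normal"])))
  p <- ggplot2::autoplot(models$normal)
  expect_s3_class(p, "ggplot")
})
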