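# Linking gameplay measures to food-choice outcomes: rank-correlation
# screening, AIC distribution choice, stepwise term selection, and normal /
# Poisson regressions with heteroskedasticity-robust standard errors.

#' Kendall rank correlation
#'
#' Tie-adjusted Kendall tau-b with a two-sided test: the exact null
#' distribution for small tie-free samples, otherwise the tie-corrected
#' large-sample normal approximation.
#'
#' @param x,y Equal-length numeric vectors (n >= 2). Either vector having
#'   zero variance is an error (tau undefined).
#' @return One-row tibble: `tau`, `p_value`, `method`.
#' @examples
#' kendall_tau(c(1, 2, 3), c(1, 3, 2)) # tau = 1/3
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    pt_abort("x and y must have equal length >= 2.",
             class = "playtrace_input_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    pt_abort("Kendall tau undefined: an argument has zero variance.",
             class = "playtrace_degenerate_error")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
  tibble(tau = unname(ct$estimate), p_value = ct$p.value,
         method = if (!ties && length(x) < 50) "exact" else "normal_approx")
}

#' Choose between normal and Poisson by AIC of the marginal fit
#'
#' Maximum-likelihood AIC of the outcome's marginal distribution under a
#' normal model (k = 2: mean and ML standard deviation) and a Poisson model
#' (k = 1: rate), as a guide to the regression family for a bounded count
#' outcome.
#'
#' @param y Nonnegative numeric values; the Poisson branch additionally
#'   requires integers.
#' @return One-row tibble: `aic_normal`, `aic_poisson`, `family` (the
#'   argmin), `degenerate` (TRUE when `y` has zero variance, which leaves
#'   the normal likelihood unbounded).
#' @examples
#' distribution_fit_aic(c(0, 1, 2)) # Poisson AIC about 9.39
#' @export
distribution_fit_aic <- function(y) {
  if (length(y) == 0) pt_abort("y is empty.", class = "playtrace_input_error")
  if (any(y < 0)) pt_abort("y must be nonnegative.", class = "playtrace_input_error")
  if (any(y != round(y))) {
    pt_abort("Poisson distribution fit requires integer counts.",
             class = "playtrace_input_error")
  }
  mu <- mean(y)
  sd_mle <- sqrt(mean((y - mu)^2))
  degenerate <- sd_mle == 0
  aic_normal <- if (degenerate) -Inf else {
    2 * 2 - 2 * sum(dnorm(y, mu, sd_mle, log = TRUE))
  }
  aic_poisson <- 2 * 1 - 2 * sum(dpois(y, mu, log = TRUE))
  fam <- if (aic_normal <= aic_poisson) "normal" else "poisson"
  tibble(aic_normal = aic_normal, aic_poisson = aic_poisson,
         family = fam, degenerate = degenerate)
}

#' Bidirectional stepwise term selection by AIC
#'
#' Starts from the full linear model and steps both directions to minimise
#' AIC (the classic `step()` procedure); forced terms are pinned in the
#' lower scope and never dropped. Deterministic given the candidate order;
#' AIC ties keep the current (smaller) model. Candidates that are exactly
#' collinear with earlier columns are dropped with a warning before
#' selection.
#'
#' @param data Data frame holding the response and candidate columns.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate term names.
#' @param forced Optional character vector of terms always kept.
#' @return Character vector of selected terms (forced terms included), with
#'   attributes `aic` (final model AIC) and `dropped` (collinear
#'   candidates removed up front).
#' @export
stepwise_select <- function(data, response, candidates, forced = NULL) {
  stopifnot(length(candidates) >= 1)
  if (nrow(data) <= length(candidates) + 2) {
    pt_abort("Too few rows for stepwise selection over these candidates.",
             class = "playtrace_input_error")
  }
  all_terms <- union(forced, candidates)
  full_f <- stats::reformulate(all_terms, response = response)
  full <- lm(full_f, data = data)
  aliased <- names(coef(full))[is.na(coef(full))]
  dropped <- intersect(candidates, aliased)
  if (length(dropped) > 0) {
    warn(paste0("Dropping collinear candidate(s): ", paste(dropped, collapse = ", ")))
    candidates <- setdiff(candidates, dropped)
    all_terms <- union(forced, candidates)
    full <- lm(stats::reformulate(all_terms, response = response), data = data)
  }
  lower_f <- if (length(forced) > 0) {
    stats::reformulate(forced, response = response)
  } else {
    stats::reformulate("1", response = response)
  }
  sel <- step(full,
              scope = list(lower = lower_f, upper = formula(full)),
              direction = "both", trace = 0)
  kept <- intersect(all_terms, attr(terms(sel), "term.labels"))
  structure(kept, aic = AIC(sel), dropped = dropped)
}

# ---- robust-SE regression fits ---------------------------------------------

.new_fit <- function(family, model, coefs, se_type, adj_r2 = NA_real_,
                     degenerate = FALSE, converged = TRUE) {
  structure(
    list(family = family, model = model, coefficients = coefs,
         se_type = se_type, aic = AIC(model), adj_r2 = adj_r2,
         n = stats::nobs(model), degenerate = degenerate, converged = converged),
    class = "playtrace_fit"
  )
}

.robust_coefs <- function(model, V) {
  ct <- lmtest::coeftest(model, vcov. = V)
  tibble(term = rownames(ct), estimate = unname(ct[, 1]),
         robust_se = unname(ct[, 2]), statistic = unname(ct[, 3]),
         p_value = unname(ct[, 4]))
}

.check_full_rank <- function(model) {
  aliased <- names(coef(model))[is.na(coef(model))]
  if (length(aliased) > 0) {
    pt_abort(paste0("Design is rank deficient; aliased column(s): ",
                    paste(aliased, collapse = ", ")),
             class = "playtrace_rank_error", aliased = aliased)
  }
}

#' Linear regression with heteroskedasticity-robust standard errors
#'
#' Ordinary least squares with HC-type robust standard errors (default HC1)
#' and t-based p-values; reports AIC and adjusted R-squared. A perfect fit
#' (zero residual variance) is flagged as degenerate rather than an error.
#'
#' @param data Data frame.
#' @param formula Model formula (intercept included as usual).
#' @param se_type A `sandwich::vcovHC` type, default `"HC1"`.
#' @return A `playtrace_fit` object; see [tidy.playtrace_fit()].
#' @export
fit_linear_robust <- function(data, formula, se_type = "HC1") {
  model <- lm(formula, data = data)
  .check_full_rank(model)
  degenerate <- sum(residuals(model)^2) < .Machine$double.eps * length(residuals(model))
  V <- if (degenerate) {
    # a perfect fit trips harmless precision warnings inside the sandwich
    suppressWarnings(sandwich::vcovHC(model, type = se_type))
  } else {
    sandwich::vcovHC(model, type = se_type)
  }
  adj_r2 <- suppressWarnings(summary(model)$adj.r.squared)
  .new_fit("normal", model, .robust_coefs(model, V), se_type,
           adj_r2 = adj_r2, degenerate = degenerate)
}

#' Poisson regression with sandwich-robust standard errors
#'
#' Log-link Poisson maximum likelihood with the classical sandwich
#' covariance (robust to overdispersion / variance misspecification) and
#' z-based p-values.
#'
#' @param data Data frame; the response must be nonnegative integers.
#' @param formula Model formula.
#' @param se_type `"HC0"` (classical sandwich, default) or any
#'   `sandwich::vcovHC` type.
#' @return A `playtrace_fit` object. An all-zero response (rate diverging
#'   to zero) or IWLS non-convergence is flagged via `converged = FALSE`
#'   and `degenerate = TRUE`.
#' @export
fit_poisson_robust <- function(data, formula, se_type = "HC0") {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != round(y))) {
    pt_abort("Poisson regression requires a nonnegative integer response.",
             class = "playtrace_input_error")
  }
  model <- suppressWarnings(glm(formula, data = data, family = poisson()))
  .check_full_rank(model)
  degenerate <- all(y == 0) || !model$converged
  V <- sandwich::vcovHC(model, type = se_type)
  .new_fit("poisson", model, .robust_coefs(model, V), se_type,
           degenerate = degenerate, converged = model$converged && !all(y == 0))
}

#' Shapiro-Wilk normality check
#'
#' @param residuals Numeric vector, 3 <= n <= 5000, non-constant.
#' @return One-row tibble: `statistic` (W), `p_value`.
#' @export
normality_check <- function(residuals) {
  n <- length(residuals)
  if (n < 3 || n > 5000) {
    pt_abort("Shapiro-Wilk requires 3 <= n <= 5000.",
             class = "playtrace_input_error")
  }
  if (var(residuals) == 0) {
    pt_abort("Residuals are constant; normality check undefined.",
             class = "playtrace_degenerate_error")
  }
  sw <- shapiro.test(residuals)
  tibble(statistic = unname(sw$statistic), p_value = sw$p.value)
}

# ---- playtrace_fit methods -------------------------------------------------

#' @export
print.playtrace_fit <- function(x, ...) {
  cat(sprintf("%s regression with %s robust SEs (n = %d, AIC = %.2f%s)\n",
              x$family, x$se_type, x$n, x$aic,
              if (!is.na(x$adj_r2)) sprintf(", adj R2 = %.2f", x$adj_r2) else ""))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  if (x$degenerate) cat("NOTE: fit flagged degenerate.\n")
  invisible(x)
}

#' Tidy a robust-SE regression fit
#'
#' @param x A `playtrace_fit`.
#' @param ... Ignored.
#' @return Tibble: `term`, `estimate`, `robust_se`, `statistic`, `p_value`.
#' @export
tidy.playtrace_fit <- function(x, ...) x$coefficients

#' One-row model summary of a robust-SE regression fit
#'
#' @param x A `playtrace_fit`.
#' @param ... Ignored.
#' @return Tibble: `family`, `se_type`, `n`, `aic`, `adj_r2`,
#'   `degenerate`, `converged`.
#' @export
glance.playtrace_fit <- function(x, ...) {
  tibble(family = x$family, se_type = x$se_type, n = x$n, aic = x$aic,
         adj_r2 = x$adj_r2, degenerate = x$degenerate, converged = x$converged)
}

#' Coefficient plot for a robust-SE regression fit
#'
#' Point estimates with +/- 1.96 robust-SE intervals, intercept omitted.
#'
#' @param object A `playtrace_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.playtrace_fit <- function(object, ...) {
  dat <- filter(object$coefficients, .data$term != "(Intercept)")
  ggplot(dat, aes(x = .data$estimate, y = .data$term)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_pointrange(aes(xmin = .data$estimate - 1.96 * .data$robust_se,
                        xmax = .data$estimate + 1.96 * .data$robust_se)) +
    labs(x = "coefficient (95% robust CI)", y = NULL,
         title = sprintf("%s model, %s SEs", object$family, object$se_type)) +
    theme_minimal()
}

# ---- cohort-level conveniences ---------------------------------------------

#' Rank-correlation screen of gameplay measures against an outcome
#'
#' Kendall tau-b of each gameplay measure against the pooled healthy-choice
#' outcome, over treatment children with complete outcomes and telemetry.
#'
#' @param measures Tibble from [compute_play_measures()].
#' @param children Cohort tibble (prepared via [prepare_outcomes()] if
#'   needed).
#' @param outcome Outcome column, default `"good_choice"`.
#' @return Tibble: `measure`, `tau`, `p_value`.
#' @export
screen_associations <- function(measures, children, outcome = "good_choice") {
  dat <- .analysis_frame(measures, children, outcome)
  purrr::map_dfr(intersect(.measure_cols, names(measures)), function(m) {
    kt <- kendall_tau(dat[[m]], dat[[outcome]])
    tibble(measure = m, tau = kt$tau, p_value = kt$p_value)
  })
}

.analysis_frame <- function(measures, children, outcome = "good_choice") {
  if (!all(c("good_choice", "complete_choice") %in% names(children))) {
    children <- prepare_outcomes(children)
  }
  complete_col <- if (grepl("choice", outcome)) "complete_choice" else "complete_id"
  dat <- children %>%
    filter(.data$group == "treatment", .data[[complete_col]]) %>%
    inner_join(measures, by = "child_id")
  if (nrow(dat) < 3) {
    pt_abort("Too few treatment children with telemetry and complete outcomes.",
             class = "playtrace_input_error")
  }
  dat
}

#' Fit the healthy-choice regression models
#'
#' Fits the four standard models of the pooled healthy-choice count on
#' gameplay terms: normal and Poisson, each without and with the
#' baseline-preference adjustment (`good_base`, forced in, never subject to
#' selection). Robust standard errors throughout.
#'
#' @param measures Tibble from [compute_play_measures()].
#' @param children Cohort tibble.
#' @param terms Gameplay regressors, default `c("avg_gfact", "avg_bfact")`.
#' @param adjust Adjustment column for models 2 and 4 (default
#'   `"good_base"`; set `NULL` to skip adjusted models).
#' @param se_type_linear,se_type_poisson Robust-SE flavours.
#' @return Named list of `playtrace_fit` objects (`normal`,
#'   `normal_adjusted`, `poisson`, `poisson_adjusted`), class
#'   `playtrace_model_set`.
#' @export
fit_choice_models <- function(measures, children,
                              terms = c("avg_gfact", "avg_bfact"),
                              adjust = "good_base",
                              se_type_linear = "HC1", se_type_poisson = "HC0") {
  dat <- .analysis_frame(measures, children, "good_choice")
  f0 <- stats::reformulate(terms, response = "good_choice")
  fits <- list(
    normal = fit_linear_robust(dat, f0, se_type_linear),
    poisson = fit_poisson_robust(dat, f0, se_type_poisson)
  )
  if (!is.null(adjust)) {
    if (any(is.na(dat[[adjust]]))) dat <- dat[!is.na(dat[[adjust]]), ]
    f1 <- stats::reformulate(c(terms, adjust), response = "good_choice")
    fits$normal_adjusted <- fit_linear_robust(dat, f1, se_type_linear)
    fits$poisson_adjusted <- fit_poisson_robust(dat, f1, se_type_poisson)
  }
  structure(fits[c(intersect(c("normal", "normal_adjusted", "poisson",
                               "poisson_adjusted"), names(fits)))],
            class = c("playtrace_model_set", "list"))
}

#' @export
tidy.playtrace_model_set <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(fit, nm) {
    mutate(tidy(fit), model = nm, .before = 1)
  })
}

#' @export
glance.playtrace_model_set <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(fit, nm) {
    mutate(glance(fit), model = nm, .before = 1)
  })
}

#' @export
print.playtrace_model_set <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
    cat("\n")
  }
  invisible(x)
}
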