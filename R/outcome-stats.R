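# Trial-arm statistics: distribution-free group comparison, standardized
# effect size, noncentral-t power, and inter-rater agreement.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The reported
#' statistic follows the min convention, `U = min(U1, U2)`. Exact mode uses
#' the null permutation distribution of U (feasible and preferable at trial
#' scale); the normal approximation is tie-corrected with continuity
#' correction. `"auto"` picks exact when both samples are small
#' (`min(n) <= 10`, total `<= 25`) and tie-free.
#'
#' @param a,b Numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return One-row tibble: `u`, `p_value`, `method`, `degenerate` (TRUE
#'   when every value in both groups is identical, in which case p = 1).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) {
    pt_abort("Both samples must be nonempty.", class = "playtrace_input_error")
  }
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u1 <- n1 * n2 + n1 * (n1 + 1) / 2 - sum(r[seq_len(n1)])
  u <- min(u1, n1 * n2 - u1)
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(unique(c(a, b))) == 1) {
    return(tibble(u = u, p_value = 1, method = "degenerate", degenerate = TRUE))
  }
  want_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = min(n1, n2) <= 10 && n1 + n2 <= 25
  )
  use_exact <- want_exact && !ties  # exact null distribution requires no ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  tibble(u = u, p_value = min(1, wt$p.value),
         method = if (use_exact) "exact" else "normal_approx",
         degenerate = FALSE)
}

#' Cohen's d from group summaries
#'
#' Standardized mean difference `(mean_t - mean_c) / s_pooled` with the
#' Bessel-corrected pooled standard deviation
#' `s_pooled = sqrt(((n_t - 1) sd_t^2 + (n_c - 1) sd_c^2) / (n_t + n_c - 2))`.
#'
#' @param mean_t,sd_t,n_t Treatment mean, SD, size (`n_t >= 2`).
#' @param mean_c,sd_c,n_c Control mean, SD, size (`n_c >= 2`).
#' @return Numeric effect size (0 when the means are equal, even if both
#'   SDs are zero).
#' @examples
#' cohens_d_from_summary(-0.26, 0.59, 27, 0.23, 1.12, 31) # about -0.54
#' @export
cohens_d_from_summary <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  stopifnot(n_t >= 2, n_c >= 2, sd_t >= 0, sd_c >= 0)
  diff <- mean_t - mean_c
  if (diff == 0) return(0)
  sp <- sqrt(((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / (n_t + n_c - 2))
  if (sp == 0) {
    pt_abort("Pooled SD is zero with unequal means: effect size is infinite.",
             class = "playtrace_degenerate_error")
  }
  diff / sp
}

#' Cohen's d from raw samples
#'
#' @param a Treatment sample; @param b control sample.
#' @return Numeric effect size.
#' @export
cohens_d <- function(a, b) {
  cohens_d_from_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}

#' Total sample size for a two-sample t-test
#'
#' Smallest even total n (two equal groups, per-group size rounded up) at
#' which the two-sample t-test attains the target power for standardized
#' effect `d`. Defaults to one-sided testing, the design-stage convention
#' for a directional intervention hypothesis.
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param sided `"one"` or `"two"`.
#' @return Integer total sample size.
#' @examples
#' required_sample_size(0.5, 0.05, 0.80, "one") # 102
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.80,
                                 sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  res <- tryCatch(
    power.t.test(delta = d, sd = 1, sig.level = alpha, power = power,
                 type = "two.sample",
                 alternative = if (sided == "one") "one.sided" else "two.sided"),
    error = function(e) pt_abort(
      paste0("Sample size unattainable at these settings: ", conditionMessage(e)),
      class = "playtrace_input_error")
  )
  2L * as.integer(ceiling(res$n))
}

#' Achieved power of a two-sample t-test
#'
#' Noncentral-t power for (possibly unequal) group sizes: noncentrality
#' `d * sqrt(n_t * n_c / (n_t + n_c))` on `n_t + n_c - 2` degrees of
#' freedom.
#'
#' @param d Standardized effect size.
#' @param n_t,n_c Group sizes.
#' @param alpha Significance level.
#' @param sided `"two"` (default) or `"one"`.
#' @return Power in `[0, 1]`; equals `alpha` when `d = 0`.
#' @examples
#' achieved_power(1.25, 27, 31) # > 0.99
#' @export
achieved_power <- function(d, n_t, n_c, alpha = 0.05, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(n_t >= 2, n_c >= 2, alpha > 0, alpha < 1)
  df <- n_t + n_c - 2
  ncp <- d * sqrt(n_t * n_c / (n_t + n_c))
  if (sided == "two") {
    crit <- qt(1 - alpha / 2, df)
    (1 - pt(crit, df, ncp)) + pt(-crit, df, ncp)
  } else {
    crit <- qt(1 - alpha, df)
    1 - pt(crit, df, ncp)
  }
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement from the product of the raters' marginal label frequencies.
#' When both raters assign a single identical label to every item, chance
#' agreement is 1 and kappa is reported as 1 with `degenerate = TRUE`.
#'
#' @param r1,r2 Equal-length label vectors from the two raters.
#' @return One-row tibble: `kappa`, `p_observed`, `p_expected`,
#'   `degenerate`.
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)) # kappa 0
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2) || length(r1) < 1) {
    pt_abort("Raters must supply equal-length, nonempty label vectors.",
             class = "playtrace_input_error")
  }
  levs <- sort(unique(c(as.character(r1), as.character(r2))))
  f1 <- factor(as.character(r1), levels = levs)
  f2 <- factor(as.character(r2), levels = levs)
  p_o <- mean(f1 == f2)
  p_e <- sum(prop.table(table(f1)) * prop.table(table(f2)))
  if (1 - p_e < .Machine$double.eps) {
    return(tibble(kappa = 1, p_observed = p_o, p_expected = p_e,
                  degenerate = TRUE))
  }
  tibble(kappa = (p_o - p_e) / (1 - p_e), p_observed = p_o, p_expected = p_e,
         degenerate = FALSE)
}

#' Treatment-vs-control comparison of trial outcomes
#'
#' For each requested outcome, compares the treatment and control arms with
#' group summaries, a two-sided Mann-Whitney U test and Cohen's d. Only
#' children observed on both days for the relevant outcome family enter the
#' comparison.
#'
#' @param children Cohort tibble; [prepare_outcomes()] is applied if the
#'   derived columns are absent.
#' @param outcomes Any of `"good_choice"`, `"good_id"`,
#'   `"good_choice_change"`, `"good_id_change"`.
#' @param mode Mann-Whitney mode, see [mann_whitney_u()].
#' @return Tibble: one row per outcome with `mean_t`, `sd_t`, `n_t`,
#'   `mean_c`, `sd_c`, `n_c`, `u_statistic`, `p_value`, `cohens_d`.
#' @export
compare_groups <- function(children,
                           outcomes = c("good_choice", "good_id",
                                        "good_choice_change", "good_id_change"),
                           mode = "auto") {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  if (!all(c("good_choice", "complete_choice") %in% names(children))) {
    children <- prepare_outcomes(children)
  }
  purrr::map_dfr(outcomes, function(oc) {
    complete_col <- if (grepl("choice", oc)) "complete_choice" else "complete_id"
    dat <- children %>% filter(.data[[complete_col]])
    t <- dat[[oc]][dat$group == "treatment"]
    c_ <- dat[[oc]][dat$group == "control"]
    if (length(t) < 2 || length(c_) < 2) {
      pt_abort(sprintf("Too few complete cases to compare groups for %s.", oc),
               class = "playtrace_input_error")
    }
    mw <- mann_whitney_u(t, c_, mode = mode)
    tibble(
      outcome = oc,
      mean_t = mean(t), sd_t = sd(t), n_t = length(t),
      mean_c = mean(c_), sd_c = sd(c_), n_c = length(c_),
      u_statistic = mw$u, p_value = mw$p_value,
      cohens_d = cohens_d(t, c_)
    )
  })
}
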