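#' Within-animal mean food intake (adjustment covariate)
#'
#' The arithmetic mean of each animal's realized intake over the study days
#' i = 1..n. The baseline day is excluded: it is the maintenance constant,
#' not a study-day intake.
#'
#' @param intakes A `pf_intakes` object.
#' @return Numeric vector (kcal), one entry per animal in cohort order.
#' @export
compute_within_animal_mean_intake <- function(intakes) {
  stopifnot(inherits(intakes, "pf_intakes"))
  rowMeans(intakes$realized)
}

# Common constructor for fitted-model summaries. Every fit reports the
# treatment coefficient (non_pf = 0, pf = 1), its SE, a two-sided p-value,
# the df used, and a flag ("ok" or the reason a fallback was taken).
new_fit <- function(model_tag, beta1, se, p_value, df, flag = "ok") {
  structure(
    list(model_tag = model_tag, beta1 = beta1, se = se,
         p_value = p_value, df = df, flag = flag),
    class = "pf_fit"
  )
}

#' @export
print.pf_fit <- function(x, ...) {
  cat(sprintf("[%s] beta1 = %.4g (SE %.4g), p = %.4g (df %.4g)%s\n",
              x$model_tag, x$beta1, x$se, x$p_value, x$df,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

treat_indicator <- function(group) {
  g <- as.character(group)
  if (!all(g %in% c("non_pf", "pf"))) {
    stop("group labels must be 'non_pf' or 'pf'", call. = FALSE)
  }
  as.integer(g == "pf")
}

#' Crude linear model: weight change on treatment only
#'
#' Ordinary least squares of the outcome on the treatment indicator
#' (non_pf = 0, pf = 1); with no covariate this is exactly the
#' pooled-variance two-sample t-test. The p-value is two-sided on
#' 2m - 2 residual df.
#'
#' @param outcome Per-animal weight change (grams).
#' @param group Group labels (`non_pf`/`pf`), at least 2 animals per group.
#' @return A `pf_fit` object. If the outcome is degenerate (zero residual
#'   variance), the p-value is reported as 1 with flag `"degenerate"`.
#' @export
fit_crude_lm <- function(outcome, group) {
  treat <- treat_indicator(group)
  if (min(table(treat)) < 2L) {
    stop("need at least 2 animals per group", call. = FALSE)
  }
  fit <- stats::lm(outcome ~ treat)
  summarize_lm(fit, "treat", "crude_lm")
}

#' Intake-adjusted linear model
#'
#' OLS of the outcome on the treatment indicator plus each animal's
#' within-animal mean food intake; p two-sided on 2m - 3 df. If the
#' covariate has zero variance it carries no information and the fit falls
#' back to the crude model (flag `"covariate_constant"`).
#'
#' @inheritParams fit_crude_lm
#' @param covariate Within-animal mean food intake (kcal), per animal.
#' @return A `pf_fit` object (tag `adjusted_lm`).
#' @export
fit_adjusted_lm <- function(outcome, group, covariate) {
  treat <- treat_indicator(group)
  if (stats::sd(covariate) == 0) {
    out <- fit_crude_lm(outcome, group)
    out$model_tag <- "adjusted_lm"
    out$flag <- "covariate_constant"
    return(out)
  }
  fit <- stats::lm(outcome ~ treat + covariate)
  summarize_lm(fit, "treat", "adjusted_lm")
}

summarize_lm <- function(fit, term, tag) {
  co <- stats::coef(summary(fit))
  beta1 <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  p <- co[term, "Pr(>|t|)"]
  if (!is.finite(se) || se <= 0 || !is.finite(p)) {
    return(new_fit(tag, beta1, NA_real_, 1, stats::df.residual(fit),
                   flag = "degenerate"))
  }
  new_fit(tag, beta1, se, p, stats::df.residual(fit))
}

#' Mixed model with a pair random intercept
#'
#' For the individual pair-feeding design: REML fit of the outcome on the
#' treatment indicator with a random intercept per weight-rank pair,
#' accounting for the clusters the pairing creates. The two-sided p-value
#' for the treatment coefficient uses Satterthwaite df by default
#' (`df_method = "residual"` uses a Wald t on 2m - rank df instead; under
#' the null both conventions are reported by the engine's per-iteration
#' table if requested). A variance component estimated at the zero boundary
#' is a valid REML solution and is accepted, not treated as a failure. If
#' the fit errors outright, the model is refit with the pair variance fixed
#' at the boundary — OLS on pair-demeaned data — and flagged.
#'
#' @inheritParams fit_crude_lm
#' @param pairs A `pf_pairs` rank matching from [pair_by_weight()].
#' @param animal_id Animal ids aligning `outcome` with the pairing; defaults
#'   to `1..length(outcome)`.
#' @param df_method `"satterthwaite"` or `"residual"`.
#' @param covariate Optional within-animal mean intake fixed effect (used by
#'   [fit_pair_lmm_adjusted()]).
#' @return A `pf_fit` object (tag `pair_lmm` or `pair_lmm_adjusted`).
#' @export
fit_pair_lmm <- function(outcome, group, pairs,
                         animal_id = seq_along(outcome),
                         df_method = c("satterthwaite", "residual"),
                         covariate = NULL) {
  df_method <- match.arg(df_method)
  if (missing(pairs) || is.null(pairs)) {
    stop("mixed model requires the pairing (see pair_by_weight)",
         call. = FALSE)
  }
  treat <- treat_indicator(group)
  pair_of <- integer(length(outcome))
  pair_of[match(pairs$pf_id, animal_id)] <- pairs$pair
  pair_of[match(pairs$non_pf_id, animal_id)] <- pairs$pair
  if (any(pair_of == 0L)) {
    stop("pairing does not cover every animal", call. = FALSE)
  }
  adjusted <- !is.null(covariate)
  tag <- if (adjusted) "pair_lmm_adjusted" else "pair_lmm"
  if (adjusted && stats::sd(covariate) == 0) {
    out <- fit_pair_lmm(outcome, group, pairs, animal_id, df_method)
    out$model_tag <- tag
    out$flag <- "covariate_constant"
    return(out)
  }
  dat <- data.frame(y = outcome, treat = treat, pair = factor(pair_of))
  form <- if (adjusted) {
    dat$covariate <- covariate
    y ~ treat + covariate + (1 | pair)
  } else {
    y ~ treat + (1 | pair)
  }
  conv_notes <- character(0)
  fit <- tryCatch(
    withCallingHandlers(
      suppressMessages(lmerTest::lmer(form, data = dat, REML = TRUE)),
      warning = function(w) {
        conv_notes <<- c(conv_notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(demeaned_fallback(dat, adjusted, tag))
  co <- stats::coef(summary(fit))
  beta1 <- co["treat", "Estimate"]
  se <- co["treat", "Std. Error"]
  flag <- if (lme4::isSingular(fit)) "boundary_variance" else "ok"
  if (length(conv_notes) > 0L) flag <- paste(flag, "convergence_warning",
                                             sep = "+")
  if (df_method == "satterthwaite") {
    df <- co["treat", "df"]
    p <- co["treat", "Pr(>|t|)"]
  } else {
    df <- length(outcome) - (2L + adjusted)
    p <- 2 * stats::pt(-abs(beta1 / se), df)
  }
  if (!is.finite(p)) {
    return(demeaned_fallback(dat, adjusted, tag))
  }
  new_fit(tag, beta1, se, p, df, flag)
}

#' @rdname fit_pair_lmm
#' @export
fit_pair_lmm_adjusted <- function(outcome, group, pairs, covariate,
                                  animal_id = seq_along(outcome),
                                  df_method = c("satterthwaite", "residual")) {
  fit_pair_lmm(outcome, group, pairs, animal_id, df_method,
               covariate = covariate)
}

# Boundary refit: pair variance pinned at zero is equivalent to OLS on
# pair-demeaned data (fixed-effects within transformation).
demeaned_fallback <- function(dat, adjusted, tag) {
  demean <- function(v) v - stats::ave(v, dat$pair)
  y <- demean(dat$y)
  x <- demean(dat$treat)
  fit <- if (adjusted) {
    stats::lm(y ~ 0 + x + demean(dat$covariate))
  } else {
    stats::lm(y ~ 0 + x)
  }
  co <- stats::coef(summary(fit))
  new_fit(tag, co["x", "Estimate"], co["x", "Std. Error"],
          co["x", "Pr(>|t|)"], stats::df.residual(fit),
          flag = "lmm_fallback")
}
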