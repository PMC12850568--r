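#' Model tags applicable to a design
#'
#' The group design is analysed with two OLS models (crude and
#' intake-adjusted). The individual design adds two mixed models with a
#' pair random intercept, without and with the intake covariate. These map
#' onto the conventional Model 1..4 labels of the summary tables via
#' [model_labels()].
#'
#' @param config A [design_config()] object (or a design string).
#' @return Character vector of model tags.
#' @export
pf_models <- function(config) {
  design <- if (inherits(config, "pf_config")) config$design else config
  switch(design,
    group_pf = c("crude_lm", "adjusted_lm"),
    individual_pf = c("crude_lm", "pair_lmm", "adjusted_lm",
                      "pair_lmm_adjusted"),
    stop("unknown design: ", design)
  )
}

#' @rdname pf_models
#' @export
model_labels <- function(config) {
  tags <- pf_models(config)
  stats::setNames(paste0("Model_", seq_along(tags)), tags)
}

#' Simulate one complete pair-feeding trial
#'
#' Runs the full data-generating pipeline for one iteration — baseline
#' draws, 1:1 randomization, weight-rank pairing (individual design),
#' proposal intakes, truncation, weight recursion — and returns every
#' intermediate object. Deterministic given `(config$seed, iteration)`:
#' the RNG is positioned at the iteration's substream before any draw.
#'
#' @param config A [design_config()] object.
#' @param iteration Iteration index (>= 1), selects the RNG substream.
#' @param stream Optional precomputed RNG state for this iteration (from
#'   [trial_streams()]); overrides derivation from `(seed, iteration)`.
#' @return A list of class `pf_trial` with elements `cohort`, `pairs`
#'   (NULL for the group design), `intakes`, `trajectory`, `outcome`,
#'   `covariate` (within-animal mean intake), `config`, `iteration`.
#' @export
simulate_trial <- function(config, iteration = 1L, stream = NULL) {
  config <- validate_config(config)
  if (is.null(stream)) stream <- trial_stream(config$seed, iteration)
  with_rng_state(stream, {
    cohort <- draw_baseline(config)
    pairs <- if (config$design == "individual_pf") pair_by_weight(cohort)
    proposals <- generate_proposals(config)
    intakes <- if (config$design == "group_pf") {
      apply_group_pf(proposals, cohort, config)
    } else {
      apply_individual_pf(proposals, pairs, cohort, config)
    }
    traj <- update_weights(intakes, cohort, config)
    structure(
      list(cohort = cohort, pairs = pairs, intakes = intakes,
           trajectory = traj, outcome = compute_outcome(traj),
           covariate = compute_within_animal_mean_intake(intakes),
           config = config, iteration = as.integer(iteration)),
      class = "pf_trial"
    )
  })
}

#' Simulate and analyse one trial
#'
#' Fits the requested analysis models to one simulated trial and extracts
#' the two-sided p-value for the treatment coefficient from each, plus the
#' per-trial difference in group mean intake (pair-fed minus non-pair-fed
#' mean of within-animal mean intake) used by [compare_designs()]. Model
#' fitting never aborts a batch: degenerate fits fall back and are flagged.
#'
#' @inheritParams simulate_trial
#' @param models Subset of [pf_models()] tags to fit (default: all models
#'   applicable to the design). An empty character vector skips fitting and
#'   returns only the intake difference.
#' @return A one-row data frame: `iteration`, `design`, `m_per_group`,
#'   `n_days`, one `p_<tag>` and `beta_<tag>` column per fitted model,
#'   `mean_intake_diff`, and `flags` (semicolon-joined non-"ok" flags, or
#'   `""`).
#' @export
run_trial <- function(config, iteration = 1L, stream = NULL,
                      models = pf_models(config)) {
  config <- validate_config(config)
  stopifnot(all(models %in% pf_models(config)))
  trial <- simulate_trial(config, iteration, stream)
  pf <- trial$cohort$group == "pf"
  out <- data.frame(
    iteration = as.integer(iteration),
    design = config$design,
    m_per_group = config$m_per_group,
    n_days = config$n_days,
    mean_intake_diff = mean(trial$covariate[pf]) - mean(trial$covariate[!pf])
  )
  flags <- character(0)
  for (tag in models) {
    fit <- switch(tag,
      crude_lm = fit_crude_lm(trial$outcome, trial$cohort$group),
      adjusted_lm = fit_adjusted_lm(trial$outcome, trial$cohort$group,
                                    trial$covariate),
      pair_lmm = fit_pair_lmm(trial$outcome, trial$cohort$group, trial$pairs,
                              trial$cohort$animal_id,
                              df_method = config$df_method),
      pair_lmm_adjusted = fit_pair_lmm_adjusted(
        trial$outcome, trial$cohort$group, trial$pairs, trial$covariate,
        trial$cohort$animal_id, df_method = config$df_method)
    )
    out[[paste0("p_", tag)]] <- fit$p_value
    out[[paste0("beta_", tag)]] <- fit$beta1
    if (fit$flag != "ok") flags <- c(flags, paste0(tag, ":", fit$flag))
  }
  out$flags <- paste(flags, collapse = ";")
  out
}

#' Chi-square test of an empirical rejection rate against nominal alpha
#'
#' One-sample Pearson goodness-of-fit on the {reject, not-reject} counts
#' against expected counts {alpha K, (1 - alpha) K}, 1 df. No continuity
#' correction by default (negligible at the K used here); set
#' `correct = TRUE` for the Yates-corrected variant.
#'
#' @param rejections Number of iterations with p below alpha.
#' @param n_reps Total iterations K.
#' @param alpha Nominal level.
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic` and `p_value`.
#' @examples
#' test_against_nominal(500, 10000, 0.05)  # observed equals expected
#' @export
test_against_nominal <- function(rejections, n_reps, alpha = 0.05,
                                 correct = FALSE) {
  if (n_reps <= 0) stop("n_reps must be positive", call. = FALSE)
  if (rejections < 0 || rejections > n_reps) {
    stop("rejections must lie in [0, n_reps]", call. = FALSE)
  }
  observed <- c(rejections, n_reps - rejections)
  expected <- c(alpha, 1 - alpha) * n_reps
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1L, lower.tail = FALSE))
}

#' Estimate empirical type I error rates for one scenario
#'
#' Runs the Monte Carlo loop: `n_reps` independent trials, each analysed by
#' the requested models, and for each model the proportion of trials whose
#' treatment p-value falls below `config$alpha`. Each proportion is tested
#' against the nominal level with [test_against_nominal()]. All simulations
#' are under the null (no treatment effect exists in the generator), so the
#' rejection proportion estimates the type I error rate.
#'
#' @inheritParams run_trial
#' @param n_reps Number of iterations (default `config$n_reps`; >= 100 so
#'   the rejection proportion is meaningful).
#' @param progress Print a progress line every 1000 iterations.
#' @return An object of class `pf_t1er`: list with `summary` (data frame:
#'   `model`, `label`, `rejections`, `n_reps`, `t1er`, `chisq_stat`,
#'   `chisq_p`), `results` (the per-iteration table from [run_trial()]),
#'   and `config`.
#' @export
estimate_t1er <- function(config, models = pf_models(config),
                          n_reps = config$n_reps, progress = FALSE) {
  config <- validate_config(config)
  n_reps <- as.integer(n_reps)
  if (n_reps < 100L) {
    stop("n_reps must be at least 100 for a stable rejection proportion",
         call. = FALSE)
  }
  streams <- trial_streams(config$seed, n_reps)
  rows <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    rows[[k]] <- run_trial(config, iteration = k, stream = streams[[k]],
                           models = models)
    if (progress && k %% 1000L == 0L) {
      message(sprintf("  iteration %d / %d", k, n_reps))
    }
  }
  results <- do.call(rbind, rows)
  labels <- model_labels(config)
  summary <- do.call(rbind, lapply(models, function(tag) {
    p <- results[[paste0("p_", tag)]]
    rej <- sum(p < config$alpha)
    chi <- test_against_nominal(rej, n_reps, config$alpha)
    data.frame(model = tag, label = unname(labels[tag]), rejections = rej,
               n_reps = n_reps, t1er = rej / n_reps,
               chisq_stat = chi$statistic, chisq_p = chi$p_value)
  }))
  structure(list(summary = summary, results = results, config = config),
            class = "pf_t1er")
}

#' @export
print.pf_t1er <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Type I error, %s design, %d animals, %d days, K = %d:\n",
              cfg$design, 2L * cfg$m_per_group, cfg$n_days,
              x$summary$n_reps[1L]))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare the intake deficits induced by the two designs
#'
#' For each design and each simulation, computes the difference in group
#' mean intake (pair-fed minus non-pair-fed mean of within-animal mean
#' daily intake, kcal), then tests whether the K per-simulation differences
#' differ between the two designs with a two-sample t-test (Welch by
#' default). No analysis models are fitted, so the comparison is cheap even
#' at large K.
#'
#' @param config_group A `group_pf` [design_config()].
#' @param config_individual An `individual_pf` config sharing `m_per_group`
#'   and `n_days` with `config_group`.
#' @param n_reps Simulations per design (default `config_group$n_reps`).
#' @param ttest `"welch"` (unequal variances) or `"pooled"`.
#' @return Object of class `pf_design_comparison`: list with `diffs_group`,
#'   `diffs_individual` (length-K vectors), per-design `means` and `sds`,
#'   and `t_test` (the `htest` from [stats::t.test()]).
#' @export
compare_designs <- function(config_group, config_individual,
                            n_reps = config_group$n_reps,
                            ttest = c("welch", "pooled")) {
  ttest <- match.arg(ttest)
  config_group <- validate_config(config_group)
  config_individual <- validate_config(config_individual)
  stopifnot(config_group$design == "group_pf",
            config_individual$design == "individual_pf")
  if (config_group$m_per_group != config_individual$m_per_group ||
      config_group$n_days != config_individual$n_days) {
    stop("the two designs must share m_per_group and n_days", call. = FALSE)
  }
  collect <- function(cfg) {
    streams <- trial_streams(cfg$seed, n_reps)
    vapply(seq_len(n_reps), function(k) {
      run_trial(cfg, iteration = k, stream = streams[[k]],
                models = character(0))$mean_intake_diff
    }, numeric(1))
  }
  dg <- collect(config_group)
  di <- collect(config_individual)
  tt <- stats::t.test(di, dg, var.equal = (ttest == "pooled"))
  structure(
    list(diffs_group = dg, diffs_individual = di,
         means = c(group_pf = mean(dg), individual_pf = mean(di)),
         sds = c(group_pf = stats::sd(dg), individual_pf = stats::sd(di)),
         t_test = tt, ttest = ttest, n_reps = n_reps),
    class = "pf_design_comparison"
  )
}

#' @export
print.pf_design_comparison <- function(x, ...) {
  cat(sprintf("Intake deficit (pf - non_pf, kcal/day) over %d simulations:\n",
              x$n_reps))
  cat(sprintf("  group design:      mean %.4f (SD %.4f)\n",
              x$means["group_pf"], x$sds["group_pf"]))
  cat(sprintf("  individual design: mean %.4f (SD %.4f)\n",
              x$means["individual_pf"], x$sds["individual_pf"]))
  cat(sprintf("  %s t-test: t = %.2f, p = %.3g\n", x$ttest,
              x$t_test$statistic, x$t_test$p.value))
  invisible(x)
}
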