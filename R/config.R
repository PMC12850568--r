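#' Simulation scenario configuration
#'
#' Builds and validates the full parameter set for one pair-feeding
#' simulation scenario. Defaults are the murine values used throughout the
#' package: baseline body weight N(33, 0.6^2) grams, baseline (and daily)
#' food intake N(13.3, 0.3^2) kcal, and a calorie-to-weight conversion of
#' `delta = 1/3500` grams per kcal, the standard heuristic that one pound
#' (~3500 kcal) of body mass corresponds to 3500 kcal of surplus intake.
#'
#' The baseline intake distribution doubles as the maintenance requirement:
#' an animal eating exactly its baseline intake every day neither gains nor
#' loses weight.
#'
#' @param m_per_group Animals per group (the pair-fed and the non-pair-fed
#'   group each have this many animals); at least 2.
#' @param n_days Number of study days after baseline; at least 1.
#' @param mu_w,sigma_w Mean and SD (grams) of the baseline weight
#'   distribution.
#' @param mu_f,sigma_f Mean and SD (kcal) of the baseline and daily intake
#'   distribution.
#' @param delta Weight change per kcal of intake above/below maintenance
#'   (grams per kcal); must be positive.
#' @param design `"group_pf"` (pair-fed intake capped at the previous day's
#'   mean non-pair-fed intake) or `"individual_pf"` (animals matched by
#'   baseline weight rank; cap is the partner's previous-day intake).
#' @param alpha Nominal significance level for the treatment test.
#' @param n_reps Default number of Monte Carlo iterations.
#' @param seed Root RNG seed for the scenario; per-iteration substreams are
#'   derived from it (see [trial_stream()]).
#' @param truncation If `FALSE`, the pair-feeding cap is disabled (set to
#'   +Inf). This diagnostic mode makes the two groups exchangeable, so every
#'   analysis model should reject at the nominal rate.
#' @param df_method Degrees-of-freedom method for mixed-model p-values:
#'   `"satterthwaite"` (default) or `"residual"` (Wald t with 2m - rank df).
#'
#' @return An object of class `pf_config` (a validated named list).
#' @examples
#' cfg <- design_config(m_per_group = 8, n_days = 15, seed = 42)
#' cfg
#' @export
design_config <- function(m_per_group = 40L,
                          n_days = 50L,
                          mu_w = 33,
                          sigma_w = 0.6,
                          mu_f = 13.3,
                          sigma_f = 0.3,
                          delta = 1 / 3500,
                          design = c("group_pf", "individual_pf"),
                          alpha = 0.05,
                          n_reps = 10000L,
                          seed = 1L,
                          truncation = TRUE,
                          df_method = c("satterthwaite", "residual")) {
  design <- match.arg(design)
  df_method <- match.arg(df_method)
  cfg <- list(
    m_per_group = as.integer(m_per_group),
    n_days = as.integer(n_days),
    mu_w = as.numeric(mu_w),
    sigma_w = as.numeric(sigma_w),
    mu_f = as.numeric(mu_f),
    sigma_f = as.numeric(sigma_f),
    delta = as.numeric(delta),
    design = design,
    alpha = as.numeric(alpha),
    n_reps = as.integer(n_reps),
    seed = as.integer(seed),
    truncation = isTRUE(truncation),
    df_method = df_method
  )
  class(cfg) <- "pf_config"
  validate_config(cfg)
}

#' @rdname design_config
#' @param cfg A `pf_config` object to validate.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pf_config"))
  bad <- function(field, why) {
    stop(sprintf("invalid configuration: field '%s' %s", field, why),
         call. = FALSE)
  }
  scalar_num <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v)) {
      bad(field, "must be a single finite number")
    }
    v
  }
  for (f in c("m_per_group", "n_days", "mu_w", "sigma_w", "mu_f", "sigma_f",
              "delta", "alpha", "n_reps", "seed")) {
    scalar_num(f)
  }
  if (cfg$m_per_group < 2L) bad("m_per_group", "must be >= 2")
  if (cfg$n_days < 1L) bad("n_days", "must be >= 1")
  if (cfg$sigma_w < 0) bad("sigma_w", "must be >= 0")
  if (cfg$sigma_f < 0) bad("sigma_f", "must be >= 0")
  if (cfg$delta <= 0) bad("delta", "must be > 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) bad("alpha", "must be in (0, 1)")
  if (cfg$n_reps < 1L) bad("n_reps", "must be >= 1")
  # Intakes must stay positive for the model to make physical sense. Draws
  # are not truncated at zero; instead configs where a non-positive draw is
  # non-negligible (mean less than 6 SDs above zero) are rejected outright.
  if (cfg$sigma_f > 0 && cfg$mu_f < 6 * cfg$sigma_f) {
    bad("mu_f", "must be at least 6 * sigma_f so intake draws stay positive")
  }
  if (cfg$sigma_f == 0 && cfg$mu_f <= 0) bad("mu_f", "must be > 0")
  cfg
}

#' @export
print.pf_config <- function(x, ...) {
  cat("Pair-feeding simulation scenario\n")
  cat(sprintf("  design: %s%s\n", x$design,
              if (!x$truncation) " (truncation disabled)" else ""))
  cat(sprintf("  animals: %d per group (%d total), days: %d\n",
              x$m_per_group, 2L * x$m_per_group, x$n_days))
  cat(sprintf("  baseline weight ~ N(%g, %g^2) g, intake ~ N(%g, %g^2) kcal\n",
              x$mu_w, x$sigma_w, x$mu_f, x$sigma_f))
  cat(sprintf("  delta = %g g/kcal, alpha = %g, reps = %d, seed = %d\n",
              x$delta, x$alpha, x$n_reps, x$seed))
  invisible(x)
}

#' Read a scenario configuration from a file
#'
#' Reads a flat key-value file (YAML syntax) whose keys are the arguments of
#' [design_config()]. Keys absent from the file keep their defaults; unknown
#' keys are an error.
#'
#' @param path Path to the configuration file.
#' @param ... Overrides applied after the file is read (same names as
#'   [design_config()] arguments).
#' @return A `pf_config` object.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("configuration file must be a flat key-value map")
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(design_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(design_config, vals)
}

#' Write a scenario configuration to a file
#'
#' @param cfg A `pf_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pf_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}
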