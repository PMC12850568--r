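#' Six-panel distribution figure for one simulated trial
#'
#' Visualises one trial the way pair-feeding simulation results are usually
#' shown: (A) baseline weight and (B) baseline intake histograms by group
#' (overlapping — randomization balances them); (C) intake on one study day
#' (the pair-fed distribution is visibly truncated); (D) daily group mean
#' intake over time (pair-fed consistently below); (E) within-animal mean
#' intake; (F) total weight change.
#'
#' Requires ggplot2 and patchwork (Suggests).
#'
#' @param trial A `pf_trial` from [simulate_trial()].
#' @param day Study day shown in panel C (default: middle of the study).
#' @param path Optional output file (PNG/SVG/PDF via [ggplot2::ggsave()]).
#' @return The assembled patchwork plot (invisibly if written to `path`).
#' @export
render_trial_figure <- function(trial, day = NULL, path = NULL) {
  stopifnot(inherits(trial, "pf_trial"))
  require_figure_pkgs()
  n <- ncol(trial$intakes$realized)
  if (is.null(day)) day <- max(1L, n %/% 2L)
  cohort <- trial$cohort
  df <- data.frame(group = cohort$group,
                   weight0 = cohort$weight0,
                   intake0 = cohort$intake0,
                   intake_day = trial$intakes$realized[, day],
                   mean_intake = trial$covariate,
                   weight_change = trial$outcome)
  hist_panel <- function(var, xlab, tag) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[var]], fill = group)) +
      ggplot2::geom_histogram(alpha = 0.55, position = "identity",
                              bins = 15) +
      ggplot2::labs(x = xlab, y = "Animals", tag = tag) +
      ggplot2::theme_minimal(base_size = 9)
  }
  daily <- stats::aggregate(
    intake ~ day + group,
    data = data.frame(
      day = rep(seq_len(n), each = nrow(df)),
      group = rep(cohort$group, times = n),
      intake = as.vector(trial$intakes$realized)
    ),
    FUN = mean
  )
  line_panel <- ggplot2::ggplot(
    daily, ggplot2::aes(x = day, y = intake, colour = group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Study day", y = "Mean intake (kcal)", tag = "D") +
    ggplot2::theme_minimal(base_size = 9)
  p <- patchwork::wrap_plots(
    hist_panel("weight0", "Baseline weight (g)", "A"),
    hist_panel("intake0", "Baseline intake (kcal)", "B"),
    hist_panel("intake_day", sprintf("Intake, day %d (kcal)", day), "C"),
    line_panel,
    hist_panel("mean_intake", "Within-animal mean intake (kcal)", "E"),
    hist_panel("weight_change", "Weight change (g)", "F"),
    ncol = 2, guides = "collect"
  )
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 8)
    return(invisible(p))
  }
  p
}

#' Histogram comparing the two designs' intake deficits
#'
#' Overlaid histograms of the per-simulation pair-fed minus non-pair-fed
#' mean intake difference for the group and individual designs, annotated
#' with the between-design t-test.
#'
#' @param comparison A `pf_design_comparison` from [compare_designs()].
#' @param path Optional output file.
#' @return The ggplot (invisibly if written to `path`); `NULL` with a
#'   message if the comparison vectors are empty.
#' @export
render_comparison_figure <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "pf_design_comparison"))
  if (length(comparison$diffs_group) == 0L ||
      length(comparison$diffs_individual) == 0L) {
    message("empty comparison vectors; figure skipped")
    return(invisible(NULL))
  }
  require_figure_pkgs()
  df <- data.frame(
    design = rep(c("group_pf", "individual_pf"),
                 c(length(comparison$diffs_group),
                   length(comparison$diffs_individual))),
    diff = c(comparison$diffs_group, comparison$diffs_individual)
  )
  lab <- sprintf("t = %.2f, p = %.2g",
                 comparison$t_test$statistic, comparison$t_test$p.value)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = diff, fill = design)) +
    ggplot2::geom_histogram(alpha = 0.55, position = "identity", bins = 40) +
    ggplot2::labs(x = "Mean intake difference, pf - non_pf (kcal/day)",
                  y = "Simulations", subtitle = lab) +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4)
    return(invisible(p))
  }
  p
}

require_figure_pkgs <- function() {
  for (pkg in c("ggplot2", "patchwork")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop(sprintf("package '%s' is required for figures", pkg),
           call. = FALSE)
    }
  }
}
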