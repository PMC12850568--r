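#' Assemble scenario summaries into a publication-style table
#'
#' Lays out a set of [estimate_t1er()] summaries as one row per scenario
#' with `Model_1..Model_k` type I error columns and matching
#' `p_value_1..p_value_k` chi-square columns, in the conventional layout
#' for reporting pair-feeding simulation results (animals are totals, not
#' per group).
#'
#' @param summaries A list of `pf_t1er` objects sharing a design.
#' @param path Optional CSV output path.
#' @return A data frame with columns `design`, `n_animals`, `n_days`, then
#'   one T1Er and one p-value column per model.
#' @export
render_tables <- function(summaries, path = NULL) {
  if (inherits(summaries, "pf_t1er")) summaries <- list(summaries)
  stopifnot(length(summaries) > 0L,
            all(vapply(summaries, inherits, logical(1), "pf_t1er")))
  rows <- lapply(summaries, function(s) {
    cfg <- s$config
    row <- data.frame(design = cfg$design,
                      n_animals = 2L * cfg$m_per_group,
                      n_days = cfg$n_days)
    for (i in seq_len(nrow(s$summary))) {
      lab <- s$summary$label[i]
      row[[lab]] <- s$summary$t1er[i]
      row[[sub("Model", "p_value", lab)]] <- s$summary$chisq_p[i]
    }
    row
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA_real_
    r[cols]
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' Serialize a scenario table to JSON and back
#'
#' Round-trip helpers for the table produced by [render_tables()]; the
#' round trip is lossless.
#'
#' @param tab A data frame from [render_tables()].
#' @param path JSON file path.
#' @return `write_table_json()` returns `path` invisibly;
#'   `read_table_json()` returns the data frame.
#' @export
write_table_json <- function(tab, path) {
  jsonlite::write_json(tab, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_table_json
#' @export
read_table_json <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full scenario grid and write summary tables
#'
#' Runs both designs over the default grid — total animals {16, 80} by
#' study days {15, 50} — and writes one summary table per design plus a
#' run manifest (JSON) recording the seed, iteration counts, per-scenario
#' rejection counts and model-fit fallback counts.
#'
#' @param seed Root seed; each scenario s uses `seed + s - 1` so scenarios
#'   are independent.
#' @param n_reps Iterations for OLS-only models.
#' @param n_reps_lmm Iterations for mixed-model fits in the individual
#'   design (they dominate run time; a smaller K with correspondingly wider
#'   Monte Carlo error is standard practice).
#' @param out_dir Output directory (created if needed).
#' @param designs,n_animals_grid,n_days_grid Scenario grid overrides
#'   (`n_animals_grid` counts total animals).
#' @param progress Print progress.
#' @return Invisibly, a list of `pf_t1er` objects (one per scenario; for
#'   individual-design scenarios the OLS and LMM runs are merged into one
#'   summary).
#' @export
reproduce_tables <- function(seed = 1L, n_reps = 10000L,
                             n_reps_lmm = n_reps, out_dir = ".",
                             designs = c("group_pf", "individual_pf"),
                             n_animals_grid = c(80L, 16L),
                             n_days_grid = c(50L, 15L),
                             progress = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenarios <- expand.grid(design = designs, n_animals = n_animals_grid,
                           n_days = n_days_grid,
                           stringsAsFactors = FALSE)
  scenarios <- scenarios[order(scenarios$design, -scenarios$n_animals,
                               -scenarios$n_days), ]
  all_t1er <- list()
  manifest <- list(seed = seed, n_reps = n_reps, n_reps_lmm = n_reps_lmm,
                   rng = "L'Ecuyer-CMRG substreams, one per iteration",
                   scenarios = list())
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    cfg <- design_config(m_per_group = sc$n_animals %/% 2L,
                         n_days = sc$n_days, design = sc$design,
                         n_reps = n_reps, seed = seed + s - 1L)
    if (progress) {
      message(sprintf("scenario %d/%d: %s, %d animals, %d days",
                      s, nrow(scenarios), sc$design, sc$n_animals, sc$n_days))
    }
    est <- run_scenario(cfg, n_reps, n_reps_lmm, progress)
    all_t1er[[s]] <- est
    manifest$scenarios[[s]] <- list(
      design = sc$design, n_animals = sc$n_animals, n_days = sc$n_days,
      seed = cfg$seed,
      rejections = stats::setNames(as.list(est$summary$rejections),
                                   est$summary$label),
      n_reps = stats::setNames(as.list(est$summary$n_reps),
                               est$summary$label),
      fallback_fits = sum(est$results$flags != "")
    )
  }
  for (d in designs) {
    keep <- all_t1er[vapply(all_t1er, function(x) x$config$design == d,
                            logical(1))]
    if (length(keep) > 0L) {
      tab <- render_tables(keep,
                           path = file.path(out_dir, paste0(d, "_t1er.csv")))
      write_table_json(tab, file.path(out_dir, paste0(d, "_t1er.json")))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(all_t1er)
}

# One scenario, possibly with a reduced-K mixed-model run merged in.
run_scenario <- function(cfg, n_reps, n_reps_lmm, progress = FALSE) {
  models <- pf_models(cfg)
  ols <- models[!grepl("lmm", models)]
  lmm <- setdiff(models, ols)
  est <- estimate_t1er(cfg, models = ols, n_reps = n_reps,
                       progress = progress)
  if (length(lmm) > 0L) {
    est_lmm <- estimate_t1er(cfg, models = lmm, n_reps = n_reps_lmm,
                             progress = progress)
    est <- merge_t1er(est, est_lmm)
  }
  est
}

# Merge two estimates of the same scenario (different model subsets) into
# one summary, keeping the conventional model order.
merge_t1er <- function(a, b) {
  stopifnot(inherits(a, "pf_t1er"), inherits(b, "pf_t1er"))
  summary <- rbind(a$summary, b$summary)
  order_tags <- pf_models(a$config)
  summary <- summary[match(intersect(order_tags, summary$model),
                           summary$model), ]
  structure(list(summary = summary,
                 results = list(a = a$results, b = b$results),
                 config = a$config),
            class = "pf_t1er")
}
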