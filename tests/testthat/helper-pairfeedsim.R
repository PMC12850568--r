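# Small scenario used where the exact parameter values do not matter.
tiny_config <- function(...) {
  args <- list(m_per_group = 4L, n_days = 5L, n_reps = 100L, seed = 11L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(design_config, args)
}

# Hand-built cohort with prescribed weights/intakes and alternating groups.
manual_cohort <- function(weights, intakes,
                          groups = rep(c("pf", "non_pf"),
                                       length.out = length(weights))) {
  structure(
    data.frame(animal_id = seq_along(weights), weight0 = weights,
               intake0 = intakes,
               group = factor(groups, levels = c("non_pf", "pf"))),
    class = c("pf_cohort", "data.frame")
  )
}

# Monte Carlo standard-error band half-width for a proportion.
prop_band <- function(p, k, n_se = 3) n_se * sqrt(p * (1 - p) / k)
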