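#' Draw a baseline cohort and randomize it to groups
#'
#' Draws baseline body weights and food intakes for `2 * m_per_group`
#' animals, each independently normal with the configured means and SDs,
#' then randomizes the animals 1:1 to the pair-fed (`"pf"`) and
#' non-pair-fed (`"non_pf"`) groups. Weights and intakes are mutually
#' independent. Draws use the current RNG state; seed management is the
#' caller's responsibility (the Monte Carlo engine positions a per-iteration
#' substream before calling this).
#'
#' @param config A [design_config()] object.
#' @return A data frame of class `pf_cohort` with columns `animal_id`,
#'   `weight0` (g), `intake0` (kcal) and `group` (factor, levels
#'   `non_pf`/`pf`), exactly `m_per_group` animals per group.
#' @examples
#' set.seed(1)
#' draw_baseline(design_config(m_per_group = 4, n_days = 5))
#' @export
draw_baseline <- function(config) {
  config <- validate_config(config)
  n_animals <- 2L * config$m_per_group
  cohort <- data.frame(
    animal_id = seq_len(n_animals),
    weight0 = stats::rnorm(n_animals, config$mu_w, config$sigma_w),
    intake0 = stats::rnorm(n_animals, config$mu_f, config$sigma_f)
  )
  randomize_groups(cohort)
}

#' Randomize animals to pair-fed / non-pair-fed groups 1:1
#'
#' Assigns exactly half the animals to each group via a uniformly random
#' balanced split (a random permutation cut in half), guaranteeing equal
#' group sizes — not per-animal coin flips. No other column is modified.
#'
#' @param cohort A data frame with one row per animal (an even number of
#'   rows); any existing `group` column is replaced.
#' @return The cohort with a `group` factor column, class `pf_cohort`.
#' @export
randomize_groups <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 2L)
  n <- nrow(cohort)
  if (n %% 2L != 0L) {
    stop("cohort must have an even number of animals for 1:1 randomization",
         call. = FALSE)
  }
  perm <- sample.int(n)
  grp <- character(n)
  grp[perm[seq_len(n %/% 2L)]] <- "pf"
  grp[perm[(n %/% 2L + 1L):n]] <- "non_pf"
  cohort$group <- factor(grp, levels = c("non_pf", "pf"))
  class(cohort) <- c("pf_cohort", "data.frame")
  cohort
}
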