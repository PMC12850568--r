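#' Update body weights recursively from intake
#'
#' The baseline intake F_j0 is each animal's maintenance requirement, fixed
#' for the whole study. Weight evolves as
#' \deqn{W_{ji} = W_{j,i-1} + (F_{ji} - F_{j0}) \delta}
#' so eating above maintenance gains weight and below loses it, at `delta`
#' grams per kcal. The recursion telescopes: the total weight change is
#' \eqn{\Delta W_j = \delta (\sum_i F_{ji} - n F_{j0})}, which the returned
#' object satisfies to machine precision.
#'
#' @param intakes A `pf_intakes` object (realized intakes are used).
#' @param cohort The `pf_cohort` providing baseline weights.
#' @param config A [design_config()] object (provides `delta`).
#' @return A `pf_trajectory` object: list with `weights` (a
#'   `2m x (n_days + 1)` matrix whose first column is baseline, day 0) and
#'   `weight_change` (final minus baseline weight, grams, per animal).
#' @export
update_weights <- function(intakes, cohort, config) {
  config <- validate_config(config)
  stopifnot(inherits(intakes, "pf_intakes"), is.data.frame(cohort))
  f <- intakes$realized
  if (nrow(f) != nrow(cohort)) {
    stop("intake matrix and cohort disagree on the number of animals",
         call. = FALSE)
  }
  if (anyNA(f) || any(!is.finite(f))) {
    stop("intake matrix has missing or non-finite entries", call. = FALSE)
  }
  increments <- (f - cohort$intake0) * config$delta
  cum <- if (ncol(f) == 1L) increments else t(apply(increments, 1L, cumsum))
  w <- cbind(cohort$weight0, cohort$weight0 + cum)
  colnames(w) <- NULL
  structure(
    list(weights = w, weight_change = w[, ncol(w)] - w[, 1L],
         animal_id = cohort$animal_id, group = cohort$group),
    class = "pf_trajectory"
  )
}

#' Per-animal study outcome: total weight change
#'
#' @param traj A `pf_trajectory` from [update_weights()].
#' @return Numeric vector of final-minus-baseline weight (grams), one entry
#'   per animal in cohort order.
#' @export
compute_outcome <- function(traj) {
  stopifnot(inherits(traj, "pf_trajectory"))
  traj$weight_change
}

#' Long-format trajectory table
#'
#' @param traj A `pf_trajectory`.
#' @return A data frame `animal_id`, `group`, `day` (0 = baseline), `weight`.
#' @export
trajectory_frame <- function(traj) {
  stopifnot(inherits(traj, "pf_trajectory"))
  n1 <- ncol(traj$weights)
  data.frame(
    animal_id = rep(traj$animal_id, times = n1),
    group = rep(as.character(traj$group), times = n1),
    day = rep(0:(n1 - 1L), each = nrow(traj$weights)),
    weight = as.vector(traj$weights)
  )
}
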