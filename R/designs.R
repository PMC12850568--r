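#' Match animals across groups by baseline weight rank
#'
#' For the individual pair-feeding design, animals in each group are ranked
#' by baseline body weight in ascending order and the j-th ranked pair-fed
#' animal is matched to the j-th ranked non-pair-fed animal. Ties (measure
#' zero under continuous draws) are broken by animal id, so the pairing is
#' deterministic given the cohort.
#'
#' @param cohort A `pf_cohort` with equal group sizes.
#' @return A data frame of class `pf_pairs` with columns `pair` (rank),
#'   `pf_id` and `non_pf_id`.
#' @examples
#' set.seed(1)
#' cohort <- draw_baseline(design_config(m_per_group = 3, n_days = 5))
#' pair_by_weight(cohort)
#' @export
pair_by_weight <- function(cohort) {
  stopifnot(inherits(cohort, "data.frame"))
  pf <- cohort[cohort$group == "pf", ]
  np <- cohort[cohort$group == "non_pf", ]
  if (nrow(pf) != nrow(np)) {
    stop("cohort is unbalanced: cannot rank-match unequal groups",
         call. = FALSE)
  }
  pf <- pf[order(pf$weight0, pf$animal_id), ]
  np <- np[order(np$weight0, np$animal_id), ]
  structure(
    data.frame(pair = seq_len(nrow(pf)),
               pf_id = pf$animal_id,
               non_pf_id = np$animal_id),
    class = c("pf_pairs", "data.frame")
  )
}

#' Generate proposal intakes for every animal and day
#'
#' Daily food intakes for both groups are initially drawn from the same
#' normal distribution as the baseline intake, independently across animals
#' and days and independent of the baseline draws. The pair-feeding cap is
#' applied afterwards by [apply_group_pf()] or [apply_individual_pf()].
#'
#' @param config A [design_config()] object.
#' @return A `2m x n_days` numeric matrix; row r is animal id r, column i is
#'   study day i.
#' @export
generate_proposals <- function(config) {
  config <- validate_config(config)
  n_animals <- 2L * config$m_per_group
  matrix(stats::rnorm(n_animals * config$n_days, config$mu_f, config$sigma_f),
         nrow = n_animals, ncol = config$n_days)
}

#' Apply the group pair-feeding truncation rule
#'
#' Each pair-fed animal's intake on day i is capped at the previous day's
#' mean realized intake of the non-pair-fed group; on day 1 the cap is the
#' mean non-pair-fed *baseline* intake (baseline is drawn from the same
#' distribution as study days, so the cap process is stationary from day 1).
#' Non-pair-fed animals are never truncated, so their realized intake equals
#' the proposal — which also means caps never cascade: the cap on day i
#' depends only on non-pair-fed proposals on day i-1.
#'
#' With `truncation = FALSE` in the config (diagnostic mode) the cap is +Inf
#' and the realized matrix reproduces the proposals exactly.
#'
#' @param proposals Proposal matrix from [generate_proposals()].
#' @param cohort The `pf_cohort` the proposals belong to (row r of
#'   `proposals` is `cohort$animal_id` r).
#' @param config A [design_config()] object.
#' @return A `pf_intakes` object: list with elements `realized`, `proposals`,
#'   `cap` (all `2m x n` matrices; `cap` is +Inf on non-pair-fed rows),
#'   `baseline` (the `2m` baseline intakes), `group`, `animal_id`.
#' @export
apply_group_pf <- function(proposals, cohort, config) {
  config <- validate_config(config)
  check_intake_inputs(proposals, cohort, config)
  np <- cohort$group == "non_pf"
  n <- config$n_days
  # Cap for day i: mean non-pf realized intake on day i-1; realized = proposal
  # for non-pf rows, and day 1 falls back to the mean non-pf baseline intake.
  cap_series <- c(mean(cohort$intake0[np]),
                  colMeans(proposals[np, , drop = FALSE])[seq_len(n - 1L)])
  if (!config$truncation) cap_series <- rep(Inf, n)
  cap <- matrix(Inf, nrow = nrow(proposals), ncol = n)
  cap[!np, ] <- matrix(cap_series, nrow = sum(!np), ncol = n, byrow = TRUE)
  realized <- pmin(proposals, cap)
  new_intakes(realized, proposals, cap, cohort)
}

#' Apply the individual pair-feeding truncation rule
#'
#' Each pair-fed animal's intake on day i is capped at its weight-rank
#' partner's realized intake on day i-1; on day 1 the cap is the partner's
#' baseline intake. Non-pair-fed animals are never truncated.
#'
#' @inheritParams apply_group_pf
#' @param pairs The `pf_pairs` rank matching from [pair_by_weight()].
#' @return A `pf_intakes` object (see [apply_group_pf()]).
#' @export
apply_individual_pf <- function(proposals, pairs, cohort, config) {
  config <- validate_config(config)
  check_intake_inputs(proposals, cohort, config)
  if (missing(pairs) || is.null(pairs)) {
    stop("individual pair-feeding requires a pairing (see pair_by_weight)",
         call. = FALSE)
  }
  stopifnot(inherits(pairs, "data.frame"),
            all(c("pf_id", "non_pf_id") %in% names(pairs)))
  n <- config$n_days
  cap <- matrix(Inf, nrow = nrow(proposals), ncol = n)
  pf_rows <- match(pairs$pf_id, cohort$animal_id)
  np_rows <- match(pairs$non_pf_id, cohort$animal_id)
  if (anyNA(pf_rows) || anyNA(np_rows)) {
    stop("pairing refers to animal ids absent from the cohort", call. = FALSE)
  }
  if (config$truncation) {
    # Partner's realized intake equals its proposal (non-pf never truncated).
    partner <- cbind(cohort$intake0[np_rows],
                     proposals[np_rows, seq_len(n - 1L), drop = FALSE])
    cap[pf_rows, ] <- partner
  }
  realized <- pmin(proposals, cap)
  new_intakes(realized, proposals, cap, cohort)
}

new_intakes <- function(realized, proposals, cap, cohort) {
  structure(
    list(realized = realized, proposals = proposals, cap = cap,
         baseline = cohort$intake0, group = cohort$group,
         animal_id = cohort$animal_id),
    class = "pf_intakes"
  )
}

check_intake_inputs <- function(proposals, cohort, config) {
  stopifnot(is.matrix(proposals), is.data.frame(cohort))
  if (nrow(proposals) != nrow(cohort)) {
    stop("proposal matrix and cohort disagree on the number of animals",
         call. = FALSE)
  }
  if (ncol(proposals) != config$n_days) {
    stop("proposal matrix and config disagree on the number of days",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.pf_intakes <- function(x, ...) {
  cat(sprintf("Realized intakes: %d animals x %d days\n",
              nrow(x$realized), ncol(x$realized)))
  cat(sprintf("  truncated entries: %d of %d pair-fed entries\n",
              sum(x$realized < x$proposals),
              sum(x$group == "pf") * ncol(x$realized)))
  invisible(x)
}

#' Long-format audit table of one trial's intakes
#'
#' @param intakes A `pf_intakes` object.
#' @return A data frame with columns `animal_id`, `group`, `day`, `proposal`,
#'   `realized`, `cap`, one row per animal-day, suitable for a CSV dump.
#' @export
intake_frame <- function(intakes) {
  stopifnot(inherits(intakes, "pf_intakes"))
  n <- ncol(intakes$realized)
  data.frame(
    animal_id = rep(intakes$animal_id, times = n),
    group = rep(as.character(intakes$group), times = n),
    day = rep(seq_len(n), each = nrow(intakes$realized)),
    proposal = as.vector(intakes$proposals),
    realized = as.vector(intakes$realized),
    cap = as.vector(intakes$cap)
  )
}
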