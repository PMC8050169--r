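# Monte-Carlo utilities: recovery of the planted standardized exposure ->
# degree effect, confidence-interval coverage, and the type-I rate of the
# interaction test.

#' Monte-Carlo recovery of the planted exposure effect
#'
#' Repeatedly generates a synthetic cohort, runs the filtered connectomes
#' through the degree stage (unmasked whole-brain degree, the scale on
#' which the effect is planted), and fits the adjusted association model.
#' Reports per-replicate estimates, the Monte-Carlo mean and its standard
#' error, and 95% CI coverage of the planted value.
#'
#' The ground-truth effect is conditional on age, BMI and diabetes (the
#' generator's confounders), so the fitted model must adjust for them:
#' `model = 3` (the full covariate set) is the default.
#'
#' @param config A [synth_config()]; replicate r uses seed
#'   `config$seed + r`. For speed, `make_events = FALSE` and
#'   `connectome_mode = "matrix"` are the intended settings.
#' @param n_reps Number of replicates.
#' @param exposure Exposure column (default `"hpa_inv"`, matching
#'   `planted_beta`'s definition on inverted HPA).
#' @param model Adjustment level (default 3).
#' @return List with `estimates` (data frame: `st_beta`, `ci_low`,
#'   `ci_high`, `covered`), `mean_estimate`, `mcse`, `coverage`,
#'   `planted_beta`.
#' @export
simulate_recovery <- function(config, n_reps = 200, exposure = "hpa_inv",
                              model = 3) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    cohort <- generate_cohort(cfg)
    m <- merged_truth_table(cohort)
    fit <- fit_association(m, exposure = exposure, outcome = "whole_brain",
                           model = model)
    rows[[r]] <- fit[, c("st_beta", "ci_low", "ci_high")]
  }
  est <- do.call(rbind, rows)
  est$covered <- est$ci_low <= config$planted_beta &
    config$planted_beta <= est$ci_high
  list(
    estimates = est,
    mean_estimate = mean(est$st_beta),
    mcse = stats::sd(est$st_beta) / sqrt(n_reps),
    coverage = mean(est$covered),
    planted_beta = config$planted_beta
  )
}

#' Type-I error rate of the interaction test under the null
#'
#' Generates cohorts with `planted_interaction = 0`, tests the exposure x
#' modifier product term, and reports the fraction of replicates flagged
#' significant at the interaction alpha of 0.10.
#'
#' @inheritParams simulate_recovery
#' @param modifier Binary modifier column (default `"sex"`).
#' @return List with `p_values`, `rate` (fraction with p <= 0.10), `n_reps`.
#' @export
simulate_interaction_type1 <- function(config, n_reps = 500,
                                       exposure = "hpa_inv",
                                       modifier = "sex", model = 1) {
  config$planted_interaction <- 0
  p <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    cohort <- generate_cohort(cfg)
    m <- merged_truth_table(cohort)
    p[r] <- test_interaction(m, exposure = exposure, outcome = "whole_brain",
                             modifier = modifier, model = model)$interaction_p
  }
  list(p_values = p, rate = mean(p <= 0.10), n_reps = n_reps)
}

# Fast analysis table for statistical replicates: ground-truth activity
# means in place of event-log summaries, unmasked degree profiles from the
# noise-filtered connectomes, covariates, inverted exposures.
merged_truth_table <- function(cohort) {
  cns <- lapply(cohort$connectomes, noise_filter)
  prof <- profiles_to_df(lapply(cns, degree_profile,
                                region_table = cohort$atlas$region_table))
  m <- merge(cohort$truth_summary, prof, by = "participant_id")
  m <- merge(m, cohort$covariates, by = "participant_id")
  add_inverted_exposures(m)
}
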