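# Standardized-beta regression: standardization semantics, nested models,
# the normal-equations oracle, inversion antisymmetry, and interactions.

# small deterministic analysis table with all model covariates
make_analysis_table <- function(n = 150, seed = 101) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("A%03d", 1:n),
    age = rnorm(n, 60, 8), sex = sample(c("female", "male"), n, TRUE),
    education = sample(c("low", "middle", "high"), n, TRUE),
    mri_lag_years = runif(n, 0, 4), wake_min_day = rnorm(n, 945, 50),
    diabetes = rbinom(n, 1, 0.25), bmi = rnorm(n, 26, 4),
    systolic_bp = rnorm(n, 134, 17), antihypertensive_med = rbinom(n, 1, 0.36),
    chol_ratio = rnorm(n, 3.6, 1.1), lipid_med = rbinom(n, 1, 0.3),
    smoking = sample(c("never", "former", "current"), n, TRUE),
    alcohol = sample(c("none", "low", "high"), n, TRUE),
    cvd_history = rbinom(n, 1, 0.13), icv_mm3 = rnorm(n, 1.45e6, 1.2e5),
    hpa_min_day = rgamma(n, 1.8, scale = 13),
    whole_brain = rnorm(n, 20.9, 0.8)
  )
}

test_that("model covariate sets are nested and volumes add ICV", {
  m1 <- model_covariates(1); m2 <- model_covariates(2); m3 <- model_covariates(3)
  expect_true(all(m1 %in% m2))
  expect_true(all(m2 %in% m3))
  expect_true("icv_mm3" %in% model_covariates(1, outcome = "total_brain_volume"))
  expect_false("icv_mm3" %in% model_covariates(1, outcome = "whole_brain"))
})

test_that("standardized beta is invariant to the exposure's units", {
  d <- make_analysis_table()
  d$hpa_inv <- -d$hpa_min_day
  d$hpa_inv_hours <- d$hpa_inv / 60
  f_min <- fit_association(d, exposure = "hpa_inv", outcome = "whole_brain",
                           model = 1)
  f_hr <- fit_association(d, exposure = "hpa_inv_hours",
                          outcome = "whole_brain", model = 1)
  expect_equal(f_min$st_beta, f_hr$st_beta, tolerance = 1e-12)
  expect_equal(f_min$ci_low, f_hr$ci_low, tolerance = 1e-12)
})

test_that("fully standardized unadjusted regression equals Pearson correlation", {
  d <- make_analysis_table()
  d$hpa_inv <- -d$hpa_min_day
  f <- fit_association(d, exposure = "hpa_inv", outcome = "whole_brain",
                       model = 0)
  expect_equal(f$st_beta, cor(d$hpa_inv, d$whole_brain), tolerance = 1e-12)
})

test_that("coefficients match an independent normal-equations solve", {
  d <- make_analysis_table(n = 80)
  d$hpa_inv <- -d$hpa_min_day
  des <- build_design(d, "hpa_inv", "whole_brain", model = 2)
  X <- model.matrix(delete.response(terms(des$formula)), des$frame)
  y <- des$frame$.outcome
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  f <- fit_association(des)
  expect_equal(f$st_beta, unname(beta_oracle[".exposure", 1]),
               tolerance = 1e-8)
})

test_that("a covariate orthogonal to exposure and outcome leaves beta unchanged", {
  d <- make_analysis_table(n = 100)
  d$hpa_inv <- -d$hpa_min_day
  # orthogonalize a random vector against {1, exposure, outcome}
  z <- rnorm(100)
  B <- cbind(1, d$hpa_inv, d$whole_brain)
  d$orth <- as.numeric(z - B %*% solve(crossprod(B), crossprod(B, z)))
  f0 <- fit_association(d, "hpa_inv", "whole_brain", model = 0)
  f1 <- fit_association(d, "hpa_inv", "whole_brain", model = 0,
                        extra_covariates = "orth")
  expect_equal(f0$st_beta, f1$st_beta, tolerance = 1e-8)
})

test_that("inverting the exposure flips the sign of beta and mirrors the CI", {
  co <- generate_cohort(synth_config(n_participants = 150, n_regions = 10,
                                     make_events = FALSE, seed = 55))
  m <- stepconn:::merged_truth_table(co)
  m$hpa_raw <- m$hpa_min_day
  f_inv <- fit_association(m, "hpa_inv", "whole_brain", model = 1)
  f_raw <- fit_association(m, "hpa_raw", "whole_brain", model = 1)
  expect_equal(f_inv$st_beta, -f_raw$st_beta, tolerance = 1e-10)
  expect_equal(f_inv$ci_low, -f_raw$ci_high, tolerance = 1e-10)
  expect_equal(f_inv$ci_high, -f_raw$ci_low, tolerance = 1e-10)
  expect_equal(f_inv$p_value, f_raw$p_value, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  d <- make_analysis_table(n = 60)
  d$hpa_inv <- -d$hpa_min_day
  d$education <- "low"  # single level present
  expect_error(fit_association(d, "hpa_inv", "whole_brain", model = 1),
               "single level|zero variance")
  d2 <- make_analysis_table(n = 60)
  d2$hpa_inv <- -d2$hpa_min_day
  d2$sex <- "female"
  expect_error(test_interaction(d2, "hpa_inv", "whole_brain", "sex",
                                model = 0), "constant")
})

test_that("exposure-only standardization reports outcome-unit effects", {
  d <- make_analysis_table()
  d$hpa_inv <- -d$hpa_min_day
  f_full <- fit_association(d, "hpa_inv", "whole_brain", model = 1)
  f_exp <- fit_association(d, "hpa_inv", "whole_brain", model = 1,
                           standardize = "exposure_only")
  # identical up to the outcome SD rescaling
  des <- build_design(d, "hpa_inv", "whole_brain", model = 1)
  sd_y <- sd(d[stats::complete.cases(d), "whole_brain"])
  expect_equal(f_exp$st_beta / sd_y, f_full$st_beta, tolerance = 1e-8)
})

test_that("interaction test: power for a planted modifier effect", {
  cfg <- synth_config(n_participants = 500, n_regions = 12,
                      planted_interaction = 0.25, make_events = FALSE,
                      seed = 900)
  hits <- 0L
  n_reps <- 20
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
    co <- generate_cohort(cfg_r)
    m <- stepconn:::merged_truth_table(co)
    p <- test_interaction(m, "hpa_inv", "whole_brain", "sex",
                          model = 3)$interaction_p
    hits <- hits + (p <= 0.10)
  }
  expect_gte(hits / n_reps, 0.8)
})
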