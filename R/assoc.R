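# Confounder-adjusted standardized-beta linear models of (inverted)
# physical-activity exposures and sedentary time against degree and volume
# outcomes, with nested covariate models and interaction tests.

# Covariate sets of the three nested models. Volume outcomes (total brain /
# white matter volume) additionally adjust for ICV from model 1 onward.
MODEL_COVARIATES <- list(
  `1` = c("age", "sex", "education", "mri_lag_years", "wake_min_day"),
  `2` = c("diabetes"),
  `3` = c("bmi", "systolic_bp", "antihypertensive_med", "chol_ratio",
          "lipid_med", "smoking", "alcohol", "cvd_history")
)

VOLUME_OUTCOMES <- c("total_brain_volume", "wm_volume")

#' Covariates of a nested adjustment model
#'
#' Model 1 adjusts for age, sex, education level, MRI lag time and wake
#' time; model 2 additionally for diabetes status; model 3 additionally for
#' cardiovascular risk factors (BMI, systolic blood pressure,
#' antihypertensive medication, total-to-HDL-cholesterol ratio,
#' lipid-modifying medication, smoking status, alcohol use, history of
#' CVD). Volume outcomes add ICV at every level.
#'
#' @param model Integer 1, 2 or 3 (0 gives the unadjusted model).
#' @param outcome Outcome variable name; `"total_brain_volume"` and
#'   `"wm_volume"` trigger the ICV adjustment.
#' @param extra_covariates Additional covariate names appended as given.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(model, outcome = "whole_brain",
                             extra_covariates = NULL) {
  stopifnot(model %in% 0:3)  # 0 = unadjusted
  covs <- if (model == 0) character(0) else
    unlist(MODEL_COVARIATES[seq_len(model)], use.names = FALSE)
  if (outcome %in% VOLUME_OUTCOMES) covs <- c(covs, "icv_mm3")
  unique(c(covs, extra_covariates))
}

CATEGORICAL_COVARIATES <- c("sex", "education", "smoking", "alcohol",
                            "diabetes", "antihypertensive_med", "lipid_med",
                            "cvd_history")

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance variable cannot be standardized")
  (x - mean(x)) / s
}

#' Build a regression design for one exposure-outcome-model cell
#'
#' Takes complete-case rows for the cell's variables, z-scores the
#' continuous exposure and (for `standardize = "full"`) the outcome on the
#' analysis sample, and dummy-codes categorical covariates (first level as
#' reference). With `standardize = "exposure_only"` the outcome is left on
#' its natural scale, so the coefficient is the outcome-unit difference per
#' exposure SD.
#'
#' @param data Merged analysis data frame (one row per participant).
#' @param exposure Exposure column name (e.g. `"hpa_inv"`, `"st_min_day"`).
#' @param outcome Outcome column name (e.g. `"whole_brain"`,
#'   `"basal_ganglia"`).
#' @param model Adjustment level 1, 2 or 3.
#' @param standardize `"full"` (default: exposure and outcome z-scored) or
#'   `"exposure_only"`.
#' @param extra_covariates Optional additional covariates.
#' @param interaction Optional name of a binary modifier to interact with
#'   the exposure.
#' @return List with the model `frame`, `formula`, and bookkeeping fields.
#' @export
build_design <- function(data, exposure, outcome, model = 1,
                         standardize = c("full", "exposure_only"),
                         extra_covariates = NULL, interaction = NULL) {
  standardize <- match.arg(standardize)
  covs <- model_covariates(model, outcome, extra_covariates)
  # the modifier's main effect enters through the interaction block below
  if (!is.null(interaction)) covs <- setdiff(covs, interaction)
  vars <- c(exposure, outcome, covs, interaction)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[vars])
  d <- data[cc, vars, drop = FALSE]
  if (nrow(d) < length(vars) + 2) stop("too few complete cases to fit the model")

  frame <- data.frame(row.names = seq_len(nrow(d)))
  frame$.exposure <- zscore(d[[exposure]])
  frame$.outcome <- if (standardize == "full") zscore(d[[outcome]]) else d[[outcome]]
  for (v in covs) {
    if (v %in% CATEGORICAL_COVARIATES || is.character(d[[v]]) || is.factor(d[[v]])) {
      f <- factor(d[[v]])
      if (nlevels(f) < 2) stop("covariate '", v, "' has a single level (zero variance)")
      frame[[v]] <- f
    } else {
      if (stats::sd(d[[v]]) == 0) stop("covariate '", v, "' has zero variance")
      frame[[v]] <- d[[v]]
    }
  }
  rhs <- c(".exposure", covs)
  if (!is.null(interaction)) {
    mod <- d[[interaction]]
    if (length(unique(mod)) < 2) stop("interaction modifier '", interaction,
                                      "' is constant")
    frame$.modifier <- if (is.numeric(mod)) mod else as.integer(factor(mod)) - 1L
    rhs <- c(rhs, ".modifier", ".exposure:.modifier")
  }
  list(
    frame = frame,
    formula = stats::reformulate(rhs, response = ".outcome"),
    exposure = exposure, outcome = outcome, model = model,
    standardize = standardize, interaction = interaction,
    n_used = nrow(frame)
  )
}

#' Fit one association model and extract the standardized coefficient
#'
#' Ordinary least squares on the design from [build_design()]; the reported
#' coefficient is the exposure term, with a two-sided p value and a 95%
#' confidence interval from the t distribution on residual degrees of
#' freedom. When an interaction modifier is present, the p value of the
#' product term is reported as `interaction_p` and flagged significant at
#' p <= 0.10.
#'
#' @param design Result of [build_design()], or a data frame plus the
#'   arguments of [build_design()] passed through `...`.
#' @param ... When `design` is a data frame, forwarded to [build_design()].
#' @param conf_level Confidence level (default 0.95).
#' @return One-row data frame: `exposure`, `outcome`, `model`, `st_beta`,
#'   `ci_low`, `ci_high`, `p_value`, `n_used`, `interaction_p`,
#'   `interaction_significant`.
#' @export
fit_association <- function(design, ..., conf_level = 0.95) {
  if (is.data.frame(design)) design <- build_design(design, ...)
  fit <- stats::lm(design$formula, data = design$frame)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design (singular fit)")
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, ".exposure", level = conf_level)
  int_p <- NA_real_
  if (!is.null(design$interaction)) {
    int_row <- grep("^\\.exposure:\\.modifier$", rownames(sm))
    int_p <- sm[int_row, "Pr(>|t|)"]
  }
  data.frame(
    exposure = design$exposure, outcome = design$outcome,
    model = design$model,
    st_beta = unname(sm[".exposure", "Estimate"]),
    ci_low = ci[1], ci_high = ci[2],
    p_value = unname(sm[".exposure", "Pr(>|t|)"]),
    n_used = design$n_used,
    interaction_p = int_p,
    interaction_significant = if (is.na(int_p)) NA else int_p <= 0.10,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Test exposure-by-modifier interaction
#'
#' Adds an exposure x modifier product term to the adjusted model and
#' reports its two-sided p value; interactions are flagged significant at
#' p <= 0.10.
#'
#' @inheritParams build_design
#' @param modifier Name of the binary modifier column (e.g. `"sex"`,
#'   `"diabetes"`).
#' @return One-row data frame as in [fit_association()], with
#'   `interaction_p` filled.
#' @export
test_interaction <- function(data, exposure, outcome, modifier, model = 1,
                             standardize = "full") {
  design <- build_design(data, exposure, outcome, model,
                         standardize = standardize, interaction = modifier)
  fit_association(design)
}

#' Fit the full exposure x outcome x model association grid
#'
#' @param data Merged analysis data frame.
#' @param exposures Character vector of exposure columns.
#' @param outcomes Character vector of outcome columns.
#' @param models Integer vector of adjustment levels (default 1:3).
#' @param standardize Standardization convention (see [build_design()]).
#' @return Data frame with one row per cell.
#' @export
assoc_grid <- function(data, exposures, outcomes, models = 1:3,
                       standardize = "full") {
  rows <- list()
  for (ex in exposures) for (oc in outcomes) for (m in models) {
    rows[[length(rows) + 1L]] <-
      fit_association(data, exposure = ex, outcome = oc, model = m,
                      standardize = standardize)
  }
  do.call(rbind, rows)
}
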