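# Pipeline orchestration and paper-shaped outputs: stratified descriptive
# tables, association grids, group percent differences, and a run manifest
# with exclusion counts.

#' Percent difference between group means
#'
#' `100 * (mean_high - mean_low) / mean_high`, rounded to one decimal; the
#' high-activity group's mean is the denominator. Vectorized.
#'
#' @param mean_high Mean of the high (reference) group; must be nonzero.
#' @param mean_low Mean of the comparison group.
#' @return Percent difference, one decimal.
#' @examples
#' percent_difference(17.9, 17.7) # 1.1
#' @export
percent_difference <- function(mean_high, mean_low) {
  if (any(mean_high == 0)) stop("high-group mean must be nonzero")
  round(100 * (mean_high - mean_low) / mean_high, 1)
}

#' Stratified descriptive table (mean +/- SD or n [%] with group tests)
#'
#' For each continuous variable: mean +/- SD per stratum and overall, with
#' a between-group p value from one-way ANOVA. For each categorical
#' variable: level counts and percentages per stratum, with a chi-square
#' test p value.
#'
#' @param data Data frame, one row per participant.
#' @param stratum Name of the stratifying column (binary or categorical).
#' @param continuous Character vector of continuous variable names.
#' @param categorical Character vector of categorical variable names.
#' @return Data frame with columns `variable`, `type`, `overall`, one
#'   formatted column per stratum level, and `p_value`.
#' @export
stratified_descriptives <- function(data, stratum, continuous = character(0),
                                    categorical = character(0)) {
  g <- factor(data[[stratum]])
  if (any(table(g) == 0) || nlevels(g) < 2) stop("empty or single stratum")
  lev <- levels(g)
  fmt_cont <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  fmt_cat <- function(x) {
    tab <- table(x)
    paste(sprintf("%s: %d [%.1f]", names(tab), as.integer(tab),
                  100 * as.integer(tab) / length(x)), collapse = "; ")
  }
  rows <- list()
  for (v in continuous) {
    x <- data[[v]]
    p <- summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1]
    row <- data.frame(variable = v, type = "continuous",
                      overall = fmt_cont(x), stringsAsFactors = FALSE)
    for (l in lev) row[[l]] <- fmt_cont(x[g == l])
    row$p_value <- p
    rows[[length(rows) + 1L]] <- row
  }
  for (v in categorical) {
    x <- factor(data[[v]])
    p <- tryCatch(stats::chisq.test(table(g, x))$p.value,
                  warning = function(w) suppressWarnings(
                    stats::chisq.test(table(g, x))$p.value))
    row <- data.frame(variable = v, type = "categorical",
                      overall = fmt_cat(x), stringsAsFactors = FALSE)
    for (l in lev) row[[l]] <- fmt_cat(x[g == l])
    row$p_value <- p
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: the synthetic-cohort
#' configuration (or `NULL` when supplying data directly), the reference
#' network target sparsity, the exposure-to-reference-group assignment, the
#' adjustment models, the exposures/outcomes grid, and the degree
#' convention (reference-masked or unmasked).
#'
#' @param synth A [synth_config()] describing the cohort to generate.
#' @param target_sparsity Reference-network sparsity target (default 0.80).
#' @param models Adjustment levels to fit (default 1:3).
#' @param exposures Exposure columns for the association grid. Activity
#'   exposures are inverted (low activity = risk); sedentary time is not.
#' @param outcomes Outcome columns (degree aggregates).
#' @param reference_groups Named character vector mapping each exposure to
#'   the reference network used for its degree outcomes: physical-activity
#'   exposures use the high-HPA reference, sedentary time the low-ST
#'   tertile reference.
#' @param degree_mode `"masked"` (default) or `"unmasked"` individual
#'   degrees.
#' @param standardize Standardization convention for the models.
#' @param interaction_modifiers Binary modifiers tested for interaction
#'   with each exposure on whole-brain degree (default sex and diabetes).
#' @param seed Optional seed overriding `synth$seed`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            target_sparsity = 0.80,
                            models = 1:3,
                            exposures = c("lpa_inv", "hpa_inv",
                                          "total_pa_inv", "st_min_day"),
                            outcomes = NULL,
                            reference_groups = c(lpa_inv = "high_hpa",
                                                 hpa_inv = "high_hpa",
                                                 total_pa_inv = "high_hpa",
                                                 st_min_day = "low_st"),
                            degree_mode = c("masked", "unmasked"),
                            standardize = c("full", "exposure_only"),
                            interaction_modifiers = c("sex", "diabetes"),
                            seed = NULL) {
  degree_mode <- match.arg(degree_mode)
  standardize <- match.arg(standardize)
  if (target_sparsity <= 0 || target_sparsity >= 1) {
    stop("target_sparsity must be in (0, 1)")
  }
  if (!is.null(seed)) synth$seed <- seed
  structure(
    list(synth = synth, target_sparsity = target_sparsity, models = models,
         exposures = exposures, outcomes = outcomes,
         reference_groups = reference_groups, degree_mode = degree_mode,
         standardize = standardize,
         interaction_modifiers = interaction_modifiers),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the end-to-end pipeline
#'
#' Composes the stages in order: synthetic cohort generation ->
#' accelerometer summaries (wear-day validity, cadence classification) ->
#' individual connectomes (streamline assignment where applicable, noise
#' filter) -> comparison groups and reference networks -> masked degree
#' profiles -> association grid and interaction tests -> descriptive and
#' percent-difference tables. A manifest records the seed, package
#' versions, and participant counts at each exclusion step.
#'
#' @param config A [pipeline_config()].
#' @return A results bundle (list) with `summaries`, `groups`,
#'   `references`, `profiles` (per reference group), `merged` (analysis
#'   tables per reference group), `associations`, `interactions`,
#'   `descriptives`, `percent_differences`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- with_stage("synth", generate_cohort(config$synth))
  n_input <- config$synth$n_participants

  summaries <- with_stage("accel", {
    if (!is.null(cohort$events)) {
      summarize_activity(cohort$events, cohort$wake_windows)
    } else {
      cohort$truth_summary
    }
  })
  n_excluded_wear <- length(attr(summaries, "excluded") %||% character(0))

  connectomes <- with_stage("connectome", {
    cns <- if (config$synth$connectome_mode == "matrix") {
      cohort$connectomes
    } else {
      icv <- stats::setNames(cohort$covariates$icv_mm3,
                             cohort$covariates$participant_id)
      lapply(stats::setNames(nm = names(cohort$streamlines)), function(id) {
        build_connectome(cohort$streamlines[[id]], cohort$atlas, icv[[id]])
      })
    }
    lapply(cns, noise_filter)
  })

  analysis_ids <- intersect(summaries$participant_id, names(connectomes))
  if (!length(analysis_ids)) {
    stop("empty cohort: no participants with both valid wear data and a connectome")
  }
  summaries <- summaries[summaries$participant_id %in% analysis_ids, ]

  groups <- with_stage("refnet", define_groups(summaries))
  region_table <- cohort$atlas$region_table
  used_refs <- unique(config$reference_groups[config$exposures])
  references <- list()
  profiles <- list()
  merged <- list()
  for (ref_label in used_refs) {
    member_ids <- intersect(groups[[ref_label]], analysis_ids)
    if (!length(member_ids)) stop("empty reference group: ", ref_label)
    references[[ref_label]] <- with_stage("refnet",
      build_reference_network(connectomes[member_ids],
                              target_sparsity = config$target_sparsity,
                              group_label = ref_label))
    prof <- lapply(connectomes[analysis_ids], masked_degrees,
                   reference = references[[ref_label]],
                   region_table = region_table,
                   mode = if (config$degree_mode == "masked") "masked" else "unmasked")
    profiles[[ref_label]] <- profiles_to_df(prof)
    m <- merge(summaries, profiles[[ref_label]], by = "participant_id")
    m <- merge(m, cohort$covariates, by = "participant_id")
    merged[[ref_label]] <- add_inverted_exposures(m)
  }

  outcomes <- config$outcomes %||%
    intersect(c("whole_brain", "frontal", "temporal", "parietal", "occipital",
                "basal_ganglia", "primary_motor_cortex"),
              names(profiles[[1]]))

  associations <- with_stage("assoc", {
    rows <- lapply(config$exposures, function(ex) {
      ref_label <- config$reference_groups[[ex]]
      assoc_grid(merged[[ref_label]], exposures = ex, outcomes = outcomes,
                 models = config$models, standardize = config$standardize)
    })
    do.call(rbind, rows)
  })

  interactions <- with_stage("assoc", {
    rows <- list()
    for (ex in config$exposures) for (mod in config$interaction_modifiers) {
      ref_label <- config$reference_groups[[ex]]
      rows[[length(rows) + 1L]] <-
        test_interaction(merged[[ref_label]], exposure = ex,
                         outcome = "whole_brain", modifier = mod,
                         model = max(config$models))
      rows[[length(rows)]]$modifier <- mod
    }
    do.call(rbind, rows)
  })

  desc_data <- merged[[config$reference_groups[["hpa_inv"]] %||% used_refs[1]]]
  descriptives <- with_stage("report", stratified_descriptives(
    desc_data, stratum = "hpa_guideline_high",
    continuous = intersect(c("age", "bmi", "systolic_bp", "chol_ratio",
                             "total_pa_min_day", "lpa_min_day", "hpa_min_day",
                             "st_min_day", "wake_min_day", outcomes),
                           names(desc_data)),
    categorical = intersect(c("sex", "education", "smoking", "alcohol",
                              "diabetes", "cvd_history"), names(desc_data))
  ))

  percent_differences <- with_stage("report", {
    hi <- desc_data$hpa_guideline_high
    vapply(outcomes, function(v) {
      percent_difference(mean(desc_data[[v]][hi]), mean(desc_data[[v]][!hi]))
    }, numeric(1))
  })

  manifest <- list(
    package = "stepconn",
    package_version = as.character(utils::packageVersion("stepconn")),
    r_version = as.character(getRversion()),
    seed = config$synth$seed,
    counts = list(
      n_input = n_input,
      n_excluded_no_valid_day = n_excluded_wear,
      n_with_summary = n_input - n_excluded_wear,
      n_analysis = length(analysis_ids)
    ),
    target_sparsity = config$target_sparsity,
    achieved_sparsity = lapply(references, `[[`, "achieved_sparsity"),
    st_tertile_cut_min_day = groups$st_tertile_cut_min_day,
    degree_mode = config$degree_mode
  )

  list(summaries = summaries, groups = groups, references = references,
       profiles = profiles, merged = merged, associations = associations,
       interactions = interactions, descriptives = descriptives,
       percent_differences = percent_differences, manifest = manifest)
}

#' Write a pipeline results bundle to disk
#'
#' Emits machine-diffable TSV tables (summaries, association grid,
#' interactions, descriptives, percent differences, reference edge lists),
#' a Markdown rendering of the descriptive table, and a JSON manifest.
#'
#' @param bundle Result of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$summaries, file.path(dir, "activity_summaries.tsv"))
  write_tsv(bundle$associations, file.path(dir, "associations.tsv"))
  write_tsv(bundle$interactions, file.path(dir, "interactions.tsv"))
  write_tsv(bundle$descriptives, file.path(dir, "descriptives.tsv"))
  pd <- data.frame(outcome = names(bundle$percent_differences),
                   percent_difference = unname(bundle$percent_differences))
  write_tsv(pd, file.path(dir, "percent_differences.tsv"))
  for (lbl in names(bundle$references)) {
    write_reference_tsv(bundle$references[[lbl]],
                        file.path(dir, paste0("reference_", lbl, ".tsv")))
  }
  writeLines(render_markdown_table(bundle$descriptives),
             file.path(dir, "descriptives.md"))
  write_json_file(bundle$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

# Minimal Markdown table renderer for descriptive tables.
render_markdown_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
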