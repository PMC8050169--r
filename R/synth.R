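# Synthetic cohort generator: label atlases, streamline sets / connectome
# matrices, activPAL-style event logs, and covariate tables with known
# ground truth, so that every downstream stage has a recoverable target.

#' Configuration of the synthetic cohort generator
#'
#' The defaults emulate the study conditions of a large population-based
#' accelerometer + diffusion-MRI cohort: an 8-day wear protocol, a
#' 120-region bilateral parcellation with basal-ganglia and primary-motor
#' groupings on a 2 mm voxel grid, individual connectomes of expected
#' density 0.25, covariate distributions matching the cohort's descriptive
#' table (age 59.6 +/- 8.1 years, 48.4% female, HPA 24 +/- 19 min/day, ...),
#' and a planted standardized effect of inverted HPA (low activity as the
#' risk factor) on whole-brain node degree.
#'
#' @param n_participants Cohort size.
#' @param n_regions Number of atlas regions; must be even and >= 4
#'   (bilateral pairs). Default 120.
#' @param grid_shape Optional integer vector of voxel-grid dimensions; the
#'   minimal grid hosting all region blocks is used when `NULL`.
#' @param voxel_size_mm Isotropic voxel edge length in mm (default 2.0, so
#'   voxel volume 8 mm^3).
#' @param n_days Wear-protocol length in days (default 8).
#' @param planted_beta Standardized effect of *inverted* HPA on whole-brain
#'   node degree (default -0.08: one SD less HPA lowers degree by 0.08 SD).
#' @param planted_interaction Standardized exposure x sex(female)
#'   interaction effect on degree (default 0).
#' @param degree_covariate_effects Named numeric vector of standardized
#'   covariate effects on degree (defaults: age -0.25, bmi -0.05,
#'   diabetes -0.10), making confounder adjustment non-trivial.
#' @param degree_sd Between-participant SD of whole-brain degree on which
#'   effects are planted (default 0.8 degree units).
#' @param base_density Expected density of an individual filtered
#'   connectome (default 0.25).
#' @param edge_noise_sd Log-scale SD of individual tract-volume weights
#'   (default 0.5).
#' @param spurious_edge_rate Probability that an absent edge appears with a
#'   1-2 streamline spurious connection, to exercise the noise filter
#'   (default 0.02).
#' @param connectome_mode `"matrix"` (default; fast direct synthesis of
#'   count/volume matrices) or `"streamlines"` (full voxel-polyline
#'   synthesis exercising the geometric pipeline; intended for small
#'   `n_regions`).
#' @param make_events Generate per-bout event logs and wake windows
#'   (default `TRUE`; switch off for fast statistical replicates, which
#'   then use the ground-truth activity means directly).
#' @param seed RNG seed; every output is deterministic given the seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 200,
                         n_regions = 120,
                         grid_shape = NULL,
                         voxel_size_mm = 2.0,
                         n_days = 8,
                         planted_beta = -0.08,
                         planted_interaction = 0,
                         degree_covariate_effects = c(age = -0.25, bmi = -0.05,
                                                      diabetes = -0.10),
                         degree_sd = 0.8,
                         base_density = 0.25,
                         edge_noise_sd = 0.5,
                         spurious_edge_rate = 0.02,
                         connectome_mode = c("matrix", "streamlines"),
                         make_events = TRUE,
                         seed = 1L) {
  connectome_mode <- match.arg(connectome_mode)
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (n_regions < 4 || n_regions %% 2 != 0) {
    stop("n_regions must be even and >= 4 (bilateral regions)")
  }
  if (base_density < 0 || base_density > 1) stop("base_density must be in [0, 1]")
  if (base_density * n_possible_edges(n_regions) < 1) {
    stop("infeasible config: base_density too low for n_regions (expected < 1 edge)")
  }
  if (degree_sd <= 0) stop("degree_sd must be > 0")
  cfg <- structure(
    list(n_participants = as.integer(n_participants),
         n_regions = as.integer(n_regions),
         grid_shape = grid_shape,
         voxel_size_mm = voxel_size_mm,
         n_days = as.integer(n_days),
         planted_beta = planted_beta,
         planted_interaction = planted_interaction,
         degree_covariate_effects = degree_covariate_effects,
         degree_sd = degree_sd,
         base_density = base_density,
         edge_noise_sd = edge_noise_sd,
         spurious_edge_rate = spurious_edge_rate,
         connectome_mode = connectome_mode,
         make_events = make_events,
         seed = seed),
    class = "synth_config"
  )
  # fail early if the grid cannot host the parcellation
  invisible(atlas_layout(cfg))
  cfg
}

BLOCK_SIZE <- 2L   # voxels per region-block edge
BLOCK_PITCH <- 3L  # block spacing; leaves a 1-voxel background gap

# Lattice layout of region blocks; errors when a user-supplied grid is too
# small.
atlas_layout <- function(config) {
  n <- config$n_regions
  nz <- ceiling(n^(1 / 3))
  ny <- ceiling(sqrt(n / nz))
  nx <- ceiling(n / (ny * nz))
  need <- c(nx, ny, nz) * BLOCK_PITCH + 1L
  grid <- config$grid_shape %||% need
  grid <- as.integer(grid)
  if (length(grid) != 3) stop("grid_shape must have length 3")
  if (any(grid < need)) {
    stop(sprintf("grid too small: need at least %s voxels to host %d region blocks",
                 paste(need, collapse = "x"), n))
  }
  list(dims = c(nx, ny, nz), grid = grid)
}

# Region group labels for a bilateral parcellation of n regions. Odd ids are
# left-hemisphere, even ids right. With >= 9 pairs the first four pairs are
# basal-ganglia analogues (caudate, putamen, pallidum, thalamus), the fifth
# the primary-motor (precentral) pair, and the rest cycle over the four
# lobes and "other"; smaller parcellations carry lobe labels only.
region_metadata <- function(n_regions) {
  pairs <- n_regions / 2
  lobes <- c("frontal", "temporal", "parietal", "occipital", "other")
  if (pairs >= 9) {
    bg_names <- c("Caudate", "Putamen", "Pallidum", "Thalamus")
    pair_group <- c(rep("basal_ganglia", 4), "primary_motor_cortex",
                    rep(lobes, length.out = pairs - 5))
    pair_name <- c(bg_names, "Precentral",
                   paste0(toupper(substr(pair_group[-(1:5)], 1, 1)),
                          substr(pair_group[-(1:5)], 2, 100), "_",
                          stats::ave(seq_len(pairs - 5), pair_group[-(1:5)],
                                     FUN = seq_along)))
  } else {
    pair_group <- rep(lobes[seq_len(min(4, pairs))], length.out = pairs)
    pair_name <- paste0(pair_group, "_", stats::ave(seq_len(pairs), pair_group,
                                                    FUN = seq_along))
  }
  data.frame(
    region_id = seq_len(n_regions),
    name = paste0(rep(pair_name, each = 2), c("_L", "_R")),
    hemisphere = rep(c("L", "R"), pairs),
    group = rep(pair_group, each = 2),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic label atlas
#'
#' Regions are disjoint axis-aligned cuboid blocks (2x2x2 voxels, separated
#' by a one-voxel background gap) on a 3-D voxel grid; only label-lookup
#' semantics matter downstream, so no anatomical realism is attempted.
#' Region metadata assigns each region exactly one group among frontal,
#' temporal, parietal, occipital, basal ganglia (bilateral caudate /
#' putamen / pallidum / thalamus analogues, 8 nodes), primary motor cortex
#' (bilateral precentral analogues, 2 nodes, excluded from the frontal
#' aggregate) and other.
#'
#' @param config A [synth_config()].
#' @return An object of class `brain_atlas`: list with `labels` (3-D
#'   integer array, 0 = background), `voxel_size_mm`, `region_table`, and
#'   `block_origin` (n x 3 matrix of block corner voxels).
#' @export
generate_atlas <- function(config) {
  lay <- atlas_layout(config)
  n <- config$n_regions
  labels <- array(0L, dim = lay$grid)
  origin <- matrix(0L, n, 3)
  k <- 0L
  for (c3 in seq_len(lay$dims[3])) for (c2 in seq_len(lay$dims[2])) {
    for (c1 in seq_len(lay$dims[1])) {
      if (k >= n) break
      k <- k + 1L
      o <- (c(c1, c2, c3) - 1L) * BLOCK_PITCH + 2L
      origin[k, ] <- o
      labels[o[1]:(o[1] + BLOCK_SIZE - 1L),
             o[2]:(o[2] + BLOCK_SIZE - 1L),
             o[3]:(o[3] + BLOCK_SIZE - 1L)] <- k
    }
  }
  structure(
    list(labels = labels, voxel_size_mm = config$voxel_size_mm,
         region_table = region_metadata(n), block_origin = origin),
    class = "brain_atlas"
  )
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("brain_atlas: %d regions on a %s grid (%.2f mm voxels)\n",
              nrow(x$region_table), paste(dim(x$labels), collapse = "x"),
              x$voxel_size_mm))
  invisible(x)
}

# A deterministic voxel inside region r's block, cycled by k.
block_voxel <- function(atlas, r, k) {
  o <- atlas$block_origin[r, ]
  off <- c(k %% BLOCK_SIZE, (k %/% BLOCK_SIZE) %% BLOCK_SIZE,
           (k %/% (BLOCK_SIZE^2)) %% BLOCK_SIZE)
  o + off
}

#' Generate streamline polylines realizing a requested edge list
#'
#' For each requested edge and streamline, a voxel polyline is drawn from a
#' voxel inside region i's block to a voxel inside region j's block (linear
#' interpolation on the grid), so that endpoint-based assignment recovers
#' exactly the requested edges with the requested streamline counts.
#'
#' @param atlas A `brain_atlas`.
#' @param target_edges Data frame with integer columns `i`, `j` (distinct
#'   region ids) and `count` (streamlines per edge, >= 1). An empty table
#'   yields an empty streamline list.
#' @return List of polyline matrices (rows are x, y, z voxel coordinates).
#' @export
generate_streamlines <- function(atlas, target_edges) {
  stopifnot(inherits(atlas, "brain_atlas"))
  if (nrow(target_edges) == 0) return(list())
  if (any(target_edges$i == target_edges$j)) {
    stop("target edges must connect two distinct regions")
  }
  nreg <- nrow(atlas$region_table)
  if (any(target_edges$i < 1 | target_edges$i > nreg |
          target_edges$j < 1 | target_edges$j > nreg)) {
    stop("unreachable region pair: region id outside the atlas")
  }
  if (any(target_edges$count < 1)) stop("streamline counts must be >= 1")
  out <- list()
  for (e in seq_len(nrow(target_edges))) {
    for (s in seq_len(target_edges$count[e])) {
      a <- block_voxel(atlas, target_edges$i[e], s - 1L)
      b <- block_voxel(atlas, target_edges$j[e], s)
      npts <- max(2L, ceiling(max(abs(b - a))) * 2L)
      tfrac <- seq(0, 1, length.out = npts)
      poly <- cbind(a[1] + tfrac * (b[1] - a[1]),
                    a[2] + tfrac * (b[2] - a[2]),
                    a[3] + tfrac * (b[3] - a[3]))
      out[[length(out) + 1L]] <- poly
    }
  }
  out
}

# ---- covariates ---------------------------------------------------------

rcat <- function(n, levels, probs) {
  levels[1L + findInterval(stats::runif(n), cumsum(probs)[-length(probs)])]
}

# Covariate table with the descriptive-table distributions; exposures and
# degree depend on age, BMI and diabetes through configurable effects.
generate_covariates <- function(config) {
  n <- config$n_participants
  age <- stats::rnorm(n, 59.6, 8.1)
  z_age <- (age - 59.6) / 8.1
  sex <- rcat(n, c("female", "male"), c(0.484, 0.516))
  education <- rcat(n, c("low", "middle", "high"), c(0.305, 0.290, 0.405))
  bmi <- stats::rnorm(n, 26.6, 4.2)
  z_bmi <- (bmi - 26.6) / 4.2
  waist <- 94.4 + 0.75 * 12.7 * z_bmi + stats::rnorm(n, 0, 0.6 * 12.7)
  systolic_bp <- 134.0 + 0.3 * 17.3 * z_age + stats::rnorm(n, 0, 17.3 * sqrt(1 - 0.09))
  diastolic_bp <- 76.1 + stats::rnorm(n, 0, 9.7)
  diabetes <- as.integer(stats::runif(n) <
                           stats::plogis(stats::qlogis(0.236) + 0.45 * z_age + 0.40 * z_bmi))
  antihypertensive_med <- as.integer(stats::runif(n) <
                                       stats::plogis(stats::qlogis(0.361) + 0.5 * z_age))
  lipid_med <- as.integer(stats::runif(n) <
                            stats::plogis(stats::qlogis(0.315) + 0.4 * z_age))
  chol_ratio <- stats::rnorm(n, 3.6, 1.1)
  cvd_history <- as.integer(stats::runif(n) <
                              stats::plogis(stats::qlogis(0.127) + 0.5 * z_age))
  smoking <- rcat(n, c("never", "former", "current"), c(0.380, 0.498, 0.122))
  alcohol <- rcat(n, c("none", "low", "high"), c(0.170, 0.572, 0.258))
  mri_lag_years <- pmax(0, stats::rnorm(n, 2.0, 1.2))
  icv_mm3 <- 1.40e6 + 1.0e5 * (sex == "male") + stats::rnorm(n, 0, 1.1e5)
  total_brain_volume <- 0.80 * icv_mm3 + stats::rnorm(n, 0, 3.5e4)
  wm_volume <- 0.35 * icv_mm3 + stats::rnorm(n, 0, 2.5e4)
  data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex, education = education, bmi = bmi, waist = waist,
    systolic_bp = systolic_bp, diastolic_bp = diastolic_bp,
    diabetes = diabetes, antihypertensive_med = antihypertensive_med,
    lipid_med = lipid_med, chol_ratio = chol_ratio,
    cvd_history = cvd_history, smoking = smoking, alcohol = alcohol,
    mri_lag_years = mri_lag_years, icv_mm3 = icv_mm3,
    total_brain_volume = total_brain_volume, wm_volume = wm_volume,
    stringsAsFactors = FALSE
  )
}

# Participant-level true daily-mean activity (minutes/day). HPA is gamma
# (right-skewed, strictly positive, mean 24 sd ~19); LPA and ST are
# truncated normals; exposures decline with age, BMI and diabetes so that
# confounding is present by construction.
generate_activity_truth <- function(config, cov) {
  n <- nrow(cov)
  z_age <- (cov$age - 59.6) / 8.1
  z_bmi <- (cov$bmi - 26.6) / 4.2
  dmc <- cov$diabetes - mean(cov$diabetes)
  mu_hpa <- pmax(2, 24 - 5 * z_age - 3 * z_bmi - 6 * dmc)
  shape <- (24 / 17.9)^2
  hpa <- stats::rgamma(n, shape = shape, scale = mu_hpa / shape)
  lpa <- pmax(5, 100 - 3 * z_age - 3 * z_bmi - 4 * dmc + stats::rnorm(n, 0, 32))
  wake <- pmax(720, stats::rnorm(n, 945, 50))
  st <- 558 + 8 * z_age + 12 * z_bmi + 15 * dmc + stats::rnorm(n, 0, 97)
  st <- pmax(60, pmin(st, wake - lpa - hpa - 30))
  data.frame(
    participant_id = cov$participant_id,
    st_mean = st, lpa_mean = lpa, hpa_mean = hpa,
    total_pa_mean = lpa + hpa,
    standing_mean = wake - st - lpa - hpa,
    wake_mean = wake,
    stringsAsFactors = FALSE
  )
}

# ---- event logs ---------------------------------------------------------

# Split `total_s` integer seconds into k bouts with random proportions,
# each >= 1 s; returns integer durations summing exactly to total_s.
split_bouts <- function(total_s, mean_bout_s) {
  total_s <- as.integer(round(total_s))
  if (total_s <= 0) return(integer(0))
  k <- max(1L, min(total_s, round(total_s / mean_bout_s)))
  w <- stats::rexp(k) + 1e-9
  d <- floor(total_s * w / sum(w))
  d <- pmax(1L, d)
  # repair the total after flooring/clamping
  excess <- sum(d) - total_s
  i <- 1L
  while (excess != 0) {
    take <- if (excess > 0) min(excess, d[i] - 1L) else excess
    d[i] <- d[i] - take
    excess <- excess - take
    i <- i %% k + 1L
  }
  as.integer(d)
}

# One participant-day: partition the wake window into ST/stand/LPA/HPA
# bouts realizing the target class seconds exactly, plus sleep (sedentary)
# filler outside the window. Step counts are floored (LPA) / ceilinged
# (HPA) so that per-bout cadence stays on the intended side of the
# 110 steps/min boundary.
make_day_events <- function(pid, day, wake_start_s, class_s) {
  d_st <- split_bouts(class_s["ST"], 20 * 60)
  d_sd <- split_bouts(class_s["standing"], 10 * 60)
  d_lp <- split_bouts(class_s["LPA"], 8 * 60)
  d_hp <- split_bouts(class_s["HPA"], 6 * 60)
  cls <- c(rep("sed", length(d_st)), rep("stand", length(d_sd)),
           rep("lpa", length(d_lp)), rep("hpa", length(d_hp)))
  dur <- c(d_st, d_sd, d_lp, d_hp)
  ord <- sample.int(length(dur))
  cls <- cls[ord]; dur <- dur[ord]
  start <- wake_start_s + cumsum(c(0L, dur[-length(dur)]))
  steps <- integer(length(dur))
  lp <- cls == "lpa"
  steps[lp] <- floor(stats::runif(sum(lp), 60, 105) * dur[lp] / 60)
  hp <- cls == "hpa"
  steps[hp] <- ceiling(stats::runif(sum(hp), 115, 140) * dur[hp] / 60)
  posture <- c(sed = "sed", stand = "stand", lpa = "step", hpa = "step")[cls]
  wake_end_s <- wake_start_s + sum(dur)
  ev <- data.frame(participant_id = pid, day_index = day,
                   start_s = start, duration_s = dur,
                   posture = unname(posture), steps = steps,
                   stringsAsFactors = FALSE)
  # sleep filler outside the wake window (excluded by wake-window clipping)
  sleep <- data.frame(
    participant_id = pid, day_index = day,
    start_s = c(0L, wake_end_s),
    duration_s = c(wake_start_s, 86400L - wake_end_s),
    posture = "sed", steps = 0L, stringsAsFactors = FALSE)
  sleep <- sleep[sleep$duration_s > 0, ]
  list(events = rbind(ev, sleep), wake_end_s = wake_end_s)
}

# Full event logs + wake windows + per-day ground-truth minutes for the
# whole cohort. The final wear day is short (device removal); a small
# fraction of middle days are short enough to be invalid.
generate_event_logs <- function(config, truth) {
  evs <- list(); wws <- list(); dts <- list()
  for (p in seq_len(nrow(truth))) {
    tr <- truth[p, ]
    for (day in seq_len(config$n_days)) {
      wake_start <- as.integer(round(6.5 * 3600 + stats::rnorm(1, 0, 900)))
      wake_min <- if (day == config$n_days) {
        stats::runif(1, 6 * 60, 16 * 60)        # removal day: often <= 14 h
      } else if (day > 1 && stats::runif(1) < 0.02) {
        stats::runif(1, 7 * 60, 9.9 * 60)       # rare short (invalid) day
      } else {
        tr$wake_mean + stats::rnorm(1, 0, 25)
      }
      day_scale <- wake_min / tr$wake_mean
      tgt <- c(ST = tr$st_mean, standing = tr$standing_mean,
               LPA = tr$lpa_mean, HPA = tr$hpa_mean) * day_scale
      tgt <- tgt + c(stats::rnorm(3, 0, 5 * day_scale), 0)
      tgt <- pmax(tgt, 1)
      class_s <- round(tgt * 60)
      md <- make_day_events(tr$participant_id, day, wake_start, class_s)
      evs[[length(evs) + 1L]] <- md$events
      wws[[length(wws) + 1L]] <- data.frame(
        participant_id = tr$participant_id, day_index = day,
        wake_start_s = wake_start, wake_end_s = md$wake_end_s,
        stringsAsFactors = FALSE)
      dts[[length(dts) + 1L]] <- data.frame(
        participant_id = tr$participant_id, day_index = day,
        st_min = class_s[["ST"]] / 60, standing_min = class_s[["standing"]] / 60,
        lpa_min = class_s[["LPA"]] / 60, hpa_min = class_s[["HPA"]] / 60,
        wake_min = sum(class_s) / 60, stringsAsFactors = FALSE)
    }
  }
  list(events = do.call(rbind, evs),
       wake_windows = do.call(rbind, wws),
       daily_truth = do.call(rbind, dts))
}

# ---- networks -----------------------------------------------------------

# Per-participant target whole-brain degree with the planted standardized
# effects; the binomial realization noise of edge sampling is counted
# toward the outcome's unit variance, and the explicit Gaussian residual
# makes up the remainder.
plant_degree_targets <- function(config, cov, truth, p_e) {
  n <- nrow(cov)
  N <- config$n_regions
  z_x <- as.numeric(scale(invert_exposure(truth$hpa_mean)))
  eff <- function(nm) {
    v <- unname(config$degree_covariate_effects[nm])
    if (length(v) != 1 || is.na(v)) 0 else v
  }
  lin <- config$planted_beta * z_x +
    eff("age") * as.numeric(scale(cov$age)) +
    eff("bmi") * as.numeric(scale(cov$bmi))
  if (stats::sd(cov$diabetes) > 0) {
    lin <- lin + eff("diabetes") * as.numeric(scale(cov$diabetes))
  }
  if (config$planted_interaction != 0) {
    lin <- lin + config$planted_interaction * z_x * (cov$sex == "female")
  }
  v_bin <- (2 / N)^2 * sum(p_e * (1 - p_e))
  g_var <- 1 - stats::var(lin) - v_bin / config$degree_sd^2
  if (g_var < 0) {
    warning("degree_sd too small for the planted effects plus sampling noise; ",
            "residual variance clamped at 0")
    g_var <- 0
  }
  mu_deg <- (2 / N) * sum(p_e)
  t_z <- lin + stats::rnorm(n, 0, sqrt(g_var))
  pmin(pmax(mu_deg + config$degree_sd * t_z, 0.1), N - 1)
}

# Individual networks. Edge presence is Bernoulli with per-edge population
# occurrence probabilities scaled per participant to hit the planted target
# degree in expectation. "matrix" mode emits connectome objects directly;
# "streamlines" mode emits polyline sets realizing the same presence/count
# structure.
generate_networks <- function(config, cov, truth, atlas) {
  n <- nrow(cov)
  N <- config$n_regions
  M <- n_possible_edges(N)
  d <- config$base_density
  p_e <- stats::rbeta(M, 2, 2 * (1 - d) / d)
  p_e <- pmin(p_e, 0.99)
  target_deg <- plant_degree_targets(config, cov, truth, p_e)
  sum_p <- sum(p_e)
  voxvol <- config$voxel_size_mm^3
  connectomes <- list()
  streamlines <- list()
  for (p in seq_len(n)) {
    m_i <- target_deg[p] * N / (2 * sum_p)
    q <- pmin(p_e * m_i, 1)
    present <- stats::runif(M) < q
    count <- integer(M)
    count[present] <- 3L + stats::rpois(sum(present), 4)
    spur <- !present & stats::runif(M) < config$spurious_edge_rate
    count[spur] <- sample(1:2, sum(spur), replace = TRUE)
    if (config$connectome_mode == "matrix") {
      vol <- numeric(M)
      nz <- count > 0
      vol[nz] <- exp(log(600) + stats::rnorm(sum(nz), 0, config$edge_noise_sd)) * voxvol / 8
      cn <- connectome(
        weight = ut_matrix(vol, N) / cov$icv_mm3[p],
        streamline_count = ut_matrix(count, N),
        icv_mm3 = cov$icv_mm3[p], voxel_volume_mm3 = voxvol
      )
      connectomes[[cov$participant_id[p]]] <- cn
    } else {
      pairs <- upper_tri_pairs(N)
      nz <- which(count > 0)
      te <- data.frame(i = pairs$i[nz], j = pairs$j[nz],
                       count = pmin(count[nz], 6L))
      streamlines[[cov$participant_id[p]]] <- generate_streamlines(atlas, te)
    }
  }
  list(connectomes = connectomes, streamlines = streamlines,
       edge_occurrence_probs = p_e, target_degree = target_deg)
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Produces, deterministically for a fixed seed: a label atlas with region
#' metadata; a covariate table drawn from the descriptive-table
#' distributions; true per-participant daily activity (ST / LPA / HPA /
#' standing / wake minutes) with event logs and wake windows realizing it
#' exactly; individual connectomes (or streamline sets) whose edge presence
#' follows per-edge population occurrence probabilities, with whole-brain
#' degree linearly shifted by the planted standardized effect of inverted
#' HPA; and a ground-truth record for recovery tests.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_cohort` with elements `config`, `atlas`,
#'   `covariates`, `truth_summary` (participant-level true activity means,
#'   usable in place of accelerometer summaries for fast statistical
#'   replicates), `events`, `wake_windows` (both `NULL` when
#'   `make_events = FALSE`), `connectomes` (unfiltered; `matrix` mode),
#'   `streamlines` (`streamlines` mode), and `ground_truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  atlas <- generate_atlas(config)
  cov <- generate_covariates(config)
  truth <- generate_activity_truth(config, cov)
  logs <- if (config$make_events) generate_event_logs(config, truth) else NULL
  nets <- generate_networks(config, cov, truth, atlas)
  truth_summary <- data.frame(
    participant_id = truth$participant_id,
    n_valid_days = config$n_days - 1L,
    st_min_day = truth$st_mean,
    standing_min_day = truth$standing_mean,
    lpa_min_day = truth$lpa_mean,
    hpa_min_day = truth$hpa_mean,
    total_pa_min_day = truth$total_pa_mean,
    wake_min_day = truth$wake_mean,
    stringsAsFactors = FALSE
  )
  truth_summary$hpa_guideline_high <- guideline_stratify(truth_summary$hpa_min_day)
  structure(
    list(config = config, atlas = atlas, covariates = cov,
         truth_summary = truth_summary,
         events = logs$events, wake_windows = logs$wake_windows,
         connectomes = nets$connectomes, streamlines = nets$streamlines,
         ground_truth = list(
           participant_truth = truth,
           daily_truth = logs$daily_truth,
           planted_beta = config$planted_beta,
           planted_interaction = config$planted_interaction,
           degree_covariate_effects = config$degree_covariate_effects,
           edge_occurrence_probs = nets$edge_occurrence_probs,
           target_degree = nets$target_degree
         )),
    class = "synth_cohort"
  )
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synth_cohort: %d participants, %d regions (%s mode)%s\n",
              x$config$n_participants, x$config$n_regions,
              x$config$connectome_mode,
              if (is.null(x$events)) ", no event logs" else ""))
  invisible(x)
}
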