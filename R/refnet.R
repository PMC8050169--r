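# Group reference networks: per-edge occurrence across a group's individual
# connectomes, occurrence-based proportional thresholding to a target
# sparsity, comparison-group definitions, and reference-masked degrees.

#' Per-edge occurrence counts across a group of connectomes
#'
#' For each possible edge, the number of group members whose (filtered)
#' individual connectome contains that edge (weight > 0).
#'
#' @param connectomes List of `connectome` objects (or binary adjacency
#'   matrices) on a common parcellation.
#' @return Symmetric integer matrix of occurrence counts.
#' @export
occurrence_matrix <- function(connectomes) {
  stopifnot(length(connectomes) >= 1)
  adjs <- lapply(connectomes, function(cn) {
    if (inherits(cn, "connectome")) cn$weight > 0 else cn > 0
  })
  n <- nrow(adjs[[1]])
  if (any(vapply(adjs, nrow, integer(1)) != n)) {
    stop("connectomes differ in parcellation size")
  }
  occ <- Reduce(`+`, lapply(adjs, function(a) a * 1L))
  diag(occ) <- 0L
  storage.mode(occ) <- "integer"
  occ
}

# Group-mean edge weight, used only to break occurrence ties.
group_mean_weight <- function(connectomes) {
  ws <- lapply(connectomes, function(cn) {
    if (inherits(cn, "connectome")) cn$weight else cn
  })
  Reduce(`+`, ws) / length(ws)
}

#' Proportional thresholding of an occurrence matrix to a target sparsity
#'
#' Retains the `(1 - target_sparsity)` fraction of all possible edges with
#' the highest occurrence across the group (for the default 0.80, the 20%
#' most frequently occurring connections). Only edges observed in at least
#' one member are eligible; when fewer eligible edges exist than retention
#' slots, all eligible edges are kept with a warning and the achieved
#' sparsity exceeds the target. Ties at the cutoff are broken by higher
#' group-mean weight, then lexicographically by `(i, j)`, so the result is
#' deterministic and invariant to participant order.
#'
#' @param occurrence Symmetric integer occurrence matrix
#'   (see [occurrence_matrix()]).
#' @param target_sparsity Target sparsity in (0, 1); default 0.80. A target
#'   of 0 retains the complete graph of eligible edges.
#' @param mean_weight Optional symmetric matrix of group-mean weights for
#'   tie-breaking.
#' @param group_label Label stored with the result.
#' @return A `reference_network`: list with `edge_set` (m x 2 integer
#'   matrix, i < j), `mask` (logical matrix), `occurrence`, `mean_weight`,
#'   `target_sparsity`, `achieved_sparsity`, `n_regions`, `group_label`.
#' @export
proportional_threshold <- function(occurrence, target_sparsity = 0.80,
                                   mean_weight = NULL, group_label = "custom") {
  if (target_sparsity < 0 || target_sparsity >= 1) {
    stop("target_sparsity must be in [0, 1)")
  }
  n <- nrow(occurrence)
  pairs <- upper_tri_pairs(n)
  occ <- occurrence[cbind(pairs$i, pairs$j)]
  mw <- if (is.null(mean_weight)) rep(0, nrow(pairs)) else
    mean_weight[cbind(pairs$i, pairs$j)]
  n_slots <- round((1 - target_sparsity) * n_possible_edges(n))
  eligible <- which(occ > 0)
  if (length(eligible) < n_slots) {
    warning(sprintf(paste0("only %d edges with nonzero occurrence for %d ",
                           "retention slots; keeping all, achieved sparsity ",
                           "will exceed the target"),
                    length(eligible), n_slots))
    keep <- eligible
  } else {
    ord <- order(-occ, -mw, pairs$i, pairs$j)
    ord <- ord[ord %in% eligible]
    keep <- ord[seq_len(n_slots)]
  }
  edge_set <- cbind(i = pairs$i[keep], j = pairs$j[keep])
  edge_set <- edge_set[order(edge_set[, 1], edge_set[, 2]), , drop = FALSE]
  mask <- matrix(FALSE, n, n)
  mask[edge_set] <- TRUE
  mask <- mask | t(mask)
  structure(
    list(edge_set = edge_set, mask = mask, occurrence = occurrence,
         mean_weight = mean_weight, target_sparsity = target_sparsity,
         achieved_sparsity = 1 - nrow(edge_set) / n_possible_edges(n),
         n_regions = n, group_label = group_label),
    class = "reference_network"
  )
}

#' @export
print.reference_network <- function(x, ...) {
  cat(sprintf(paste0("reference_network '%s': %d regions, %d retained edges, ",
                     "target sparsity %.2f, achieved %.4f\n"),
              x$group_label, x$n_regions, nrow(x$edge_set),
              x$target_sparsity, x$achieved_sparsity))
  invisible(x)
}

#' Build a group reference network from individual connectomes
#'
#' Convenience wrapper: occurrence matrix + group-mean weights +
#' proportional thresholding.
#'
#' @inheritParams proportional_threshold
#' @param connectomes List of filtered `connectome` objects of the group
#'   members.
#' @return A `reference_network`.
#' @export
build_reference_network <- function(connectomes, target_sparsity = 0.80,
                                    group_label = "custom") {
  occ <- occurrence_matrix(connectomes)
  mw <- group_mean_weight(connectomes)
  proportional_threshold(occ, target_sparsity, mean_weight = mw,
                         group_label = group_label)
}

#' Define the comparison groups used for reference networks
#'
#' The high-HPA group contains participants meeting the activity guideline
#' (at least 150 min HPA per week, i.e. 21.4 min/day). The low-ST group is
#' the tertile of participants with the lowest mean daily sedentary time;
#' the empirical tertile cut of the supplied cohort is reported alongside.
#'
#' @param summaries Activity-summary data frame
#'   (see [summarize_activity()]).
#' @return List with `high_hpa` (participant ids), `low_st` (participant
#'   ids), and `st_tertile_cut_min_day` (largest ST inside the low tertile).
#' @export
define_groups <- function(summaries) {
  n <- nrow(summaries)
  if (n < 3) stop("at least 3 participants are needed for a tertile split")
  high_hpa <- summaries$participant_id[guideline_stratify(summaries$hpa_min_day)]
  k <- floor(n / 3)
  ord <- order(summaries$st_min_day, summaries$participant_id)
  low_idx <- ord[seq_len(k)]
  list(
    high_hpa = high_hpa,
    low_st = summaries$participant_id[low_idx],
    st_tertile_cut_min_day = max(summaries$st_min_day[low_idx])
  )
}

#' Reference-masked individual degree profile
#'
#' By default, an individual's node degrees count only edges present in both
#' the individual's filtered connectome and the reference edge set
#' (`mode = "masked"`). `mode = "unmasked"` returns the raw individual
#' profile; both are exposed because either convention is defensible.
#'
#' @param cn Individual filtered `connectome`.
#' @param reference A `reference_network` on the same parcellation.
#' @param region_table Region metadata (see [degree_profile()]).
#' @param mode `"masked"` (default) or `"unmasked"`.
#' @return A `degree_profile`.
#' @export
masked_degrees <- function(cn, reference, region_table = NULL,
                           mode = c("masked", "unmasked")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "reference_network"))
  n <- if (inherits(cn, "connectome")) cn$n_regions else nrow(cn)
  if (n != reference$n_regions) stop("parcellation mismatch between connectome and reference")
  mask <- if (mode == "masked") reference$mask else NULL
  degree_profile(cn, region_table, edge_mask = mask)
}
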