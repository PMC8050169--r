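# Individual structural connectomes: streamline-to-edge assignment,
# tract-volume edge weights, ICV normalization, the low-streamline-count
# noise filter, and degree/sparsity metrics.

#' Construct a connectome object
#'
#' A connectome is a weighted undirected network over atlas regions: a
#' symmetric matrix of ICV-normalized tract volumes (dimensionless) plus a
#' parallel symmetric integer matrix of streamline counts.
#'
#' @param weight Symmetric numeric matrix of ICV-normalized tract volumes,
#'   zero diagonal.
#' @param streamline_count Symmetric integer matrix of streamline counts.
#' @param icv_mm3 Intracranial volume in mm^3 used for normalization.
#' @param voxel_volume_mm3 Voxel volume in mm^3 (8 for a 2 mm cubic grid).
#' @param filtered Logical; whether the low-count noise filter has been
#'   applied.
#' @return An object of class `connectome`.
#' @export
connectome <- function(weight, streamline_count, icv_mm3,
                       voxel_volume_mm3 = 8, filtered = FALSE) {
  assert_symmetric_zero_diag(weight, "weight")
  assert_symmetric_zero_diag(streamline_count, "streamline_count")
  stopifnot(nrow(weight) == nrow(streamline_count))
  if (icv_mm3 <= 0) stop("icv_mm3 must be > 0")
  if (any(weight < 0)) stop("weights must be non-negative")
  structure(
    list(weight = weight, streamline_count = streamline_count,
         icv_mm3 = icv_mm3, voxel_volume_mm3 = voxel_volume_mm3,
         n_regions = nrow(weight), filtered = filtered),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  ne <- sum(ut_values(x$weight) > 0)
  cat(sprintf("connectome: %d regions, %d edges%s, ICV %.3g mm^3\n",
              x$n_regions, ne, if (x$filtered) " (noise-filtered)" else "",
              x$icv_mm3))
  invisible(x)
}

# Round continuous polyline coordinates onto the voxel grid and validate
# against the grid dimensions.
polyline_voxels <- function(polyline, grid_dim) {
  v <- round(polyline)
  if (any(v < 1) || any(sweep(v, 2, grid_dim, ">") )) {
    stop("polyline contains voxel indices outside the grid")
  }
  v
}

#' Assign a streamline to a region pair by its endpoints
#'
#' A streamline connects the atlas regions containing its first and last
#' voxels. When either endpoint lies in background (label 0), or both lie in
#' the same region (which would form a self-loop), the streamline is
#' unassigned.
#'
#' @param polyline Numeric matrix with 3 columns (voxel indices, possibly
#'   continuous; rounded to the grid) and at least 2 rows.
#' @param atlas A `brain_atlas` (see [generate_atlas()]) or a 3-D integer
#'   label array.
#' @return Integer vector `c(i, j)` with `i < j`, or `NULL` when unassigned.
#' @export
assign_streamline <- function(polyline, atlas) {
  labels <- if (inherits(atlas, "brain_atlas")) atlas$labels else atlas
  if (!is.matrix(polyline) || ncol(polyline) != 3 || nrow(polyline) < 2) {
    stop("polyline must be a matrix with 3 columns and >= 2 rows")
  }
  v <- polyline_voxels(polyline, dim(labels))
  a <- labels[v[1, 1], v[1, 2], v[1, 3]]
  b <- labels[v[nrow(v), 1], v[nrow(v), 2], v[nrow(v), 3]]
  if (a == 0 || b == 0 || a == b) return(NULL)
  as.integer(sort(c(a, b)))
}

#' Tract volume of one edge from its streamlines
#'
#' The edge weight before normalization: the number of distinct voxels
#' visited by at least one streamline of the edge, multiplied by the voxel
#' volume. Duplicate visits do not count twice (set union).
#'
#' @param polylines List of polyline matrices belonging to one edge.
#' @param voxel_volume_mm3 Voxel volume in mm^3.
#' @param grid_dim Integer vector of grid dimensions (for validation).
#' @return Tract volume in mm^3.
#' @export
edge_tract_volume <- function(polylines, voxel_volume_mm3, grid_dim) {
  stopifnot(length(polylines) >= 1)
  keys <- unlist(lapply(polylines, function(p) {
    v <- polyline_voxels(p, grid_dim)
    paste(v[, 1], v[, 2], v[, 3])
  }))
  length(unique(keys)) * voxel_volume_mm3
}

#' Normalize a tract-volume matrix to intracranial volume
#'
#' Elementwise division by ICV reduces inter-subject variation in head size;
#' the result is dimensionless (mm^3 / mm^3).
#'
#' @param raw Symmetric matrix of tract volumes in mm^3.
#' @param icv_mm3 Intracranial volume in mm^3; must be positive.
#' @return The normalized matrix.
#' @export
normalize_icv <- function(raw, icv_mm3) {
  if (length(icv_mm3) != 1 || !is.finite(icv_mm3) || icv_mm3 <= 0) {
    stop("icv_mm3 must be a single positive number")
  }
  raw / icv_mm3
}

#' Build an individual connectome from streamlines
#'
#' Assigns each streamline to a region pair by its endpoint labels, counts
#' streamlines per edge, computes tract-volume edge weights (union of
#' visited voxels times voxel volume), and normalizes to ICV. The
#' low-streamline-count noise filter is *not* applied here; see
#' [noise_filter()].
#'
#' @param streamlines List of polyline matrices (n x 3 voxel coordinates).
#' @param atlas A `brain_atlas`.
#' @param icv_mm3 Intracranial volume in mm^3.
#' @param assignment `"endpoint"` (default) assigns by first/last voxel
#'   labels; `"passthrough"` assigns the streamline to every pair of
#'   distinct regions it visits (sensitivity mode).
#' @return An unfiltered `connectome`.
#' @export
build_connectome <- function(streamlines, atlas, icv_mm3,
                             assignment = c("endpoint", "passthrough")) {
  assignment <- match.arg(assignment)
  stopifnot(inherits(atlas, "brain_atlas"))
  n <- nrow(atlas$region_table)
  voxvol <- atlas$voxel_size_mm^3
  count <- matrix(0L, n, n)
  by_edge <- list()
  for (s in streamlines) {
    pairs <- if (assignment == "endpoint") {
      p <- assign_streamline(s, atlas)
      if (is.null(p)) NULL else list(p)
    } else {
      v <- polyline_voxels(s, dim(atlas$labels))
      labs <- unique(atlas$labels[v])
      labs <- labs[labs != 0]
      if (length(labs) < 2) NULL else {
        cmb <- utils::combn(sort(labs), 2)
        lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
      }
    }
    for (p in pairs) {
      count[p[1], p[2]] <- count[p[1], p[2]] + 1L
      key <- paste(p[1], p[2])
      by_edge[[key]] <- c(by_edge[[key]], list(s))
    }
  }
  raw <- matrix(0, n, n)
  for (key in names(by_edge)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    raw[ij[1], ij[2]] <- edge_tract_volume(by_edge[[key]], voxvol, dim(atlas$labels))
  }
  raw <- raw + t(raw)
  count <- count + t(count)
  connectome(normalize_icv(raw, icv_mm3), count, icv_mm3, voxvol,
             filtered = FALSE)
}

#' Remove low-streamline-count edges (noise filter)
#'
#' Edges supported by fewer than `min_streamlines` streamlines (by default,
#' regions connected by only one or two streamlines) are removed from both
#' the weight and the count matrix. Idempotent.
#'
#' @param cn A `connectome`.
#' @param min_streamlines Minimum streamline count for an edge to survive
#'   (default 3).
#' @return The filtered `connectome`.
#' @export
noise_filter <- function(cn, min_streamlines = 3) {
  stopifnot(inherits(cn, "connectome"))
  drop <- cn$streamline_count > 0 & cn$streamline_count < min_streamlines
  cn$weight[drop] <- 0
  cn$streamline_count[drop] <- 0L
  cn$filtered <- TRUE
  cn
}

#' Network sparsity of a binary adjacency
#'
#' Sparsity is the fraction of possible node pairs with no edge:
#' `1 - edges / (N (N - 1) / 2)`; sparsity + density = 1.
#'
#' @param adj Symmetric logical/binary adjacency matrix (or a `connectome`,
#'   in which case `weight > 0` is used).
#' @return Sparsity in \[0, 1\].
#' @export
sparsity <- function(adj) {
  if (inherits(adj, "connectome")) adj <- adj$weight > 0
  n <- nrow(adj)
  1 - sum(ut_values(adj) > 0) / n_possible_edges(n)
}

#' Node-degree profile of a connectome
#'
#' Node degree is the number of edges incident to a region (binary: edge
#' presence, not weight). The whole-brain value is the mean degree over all
#' regions; regional values are mean degrees over the member regions of each
#' group (frontal, temporal, parietal, occipital lobes, basal ganglia,
#' primary motor cortex). When `edge_mask` is given, only edges present in
#' both the individual network and the mask are counted (reference-network
#' masking).
#'
#' @param cn A `connectome` (usually noise-filtered) or a binary adjacency
#'   matrix.
#' @param region_table Data frame with columns `region_id` and `group`
#'   (values among `frontal`, `temporal`, `parietal`, `occipital`,
#'   `basal_ganglia`, `primary_motor_cortex`, `other`).
#' @param edge_mask Optional symmetric logical matrix of admissible edges.
#' @return An object of class `degree_profile`: list with `degree` (per-node
#'   integer vector), `whole_brain`, `regional` (named numeric), `sparsity`
#'   and `n_regions`.
#' @export
degree_profile <- function(cn, region_table = NULL, edge_mask = NULL) {
  adj <- if (inherits(cn, "connectome")) cn$weight > 0 else cn > 0
  n <- nrow(adj)
  if (!is.null(edge_mask)) {
    stopifnot(nrow(edge_mask) == n)
    adj <- adj & (edge_mask > 0)
  }
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  regional <- numeric(0)
  if (!is.null(region_table)) {
    groups <- c("frontal", "temporal", "parietal", "occipital",
                "basal_ganglia", "primary_motor_cortex")
    present <- intersect(groups, unique(region_table$group))
    regional <- vapply(present, function(g) {
      ids <- region_table$region_id[region_table$group == g]
      if (!length(ids)) stop("empty region group: ", g)
      mean(deg[ids])
    }, numeric(1))
  }
  structure(
    list(degree = deg, whole_brain = mean(deg), regional = regional,
         sparsity = sparsity(adj), n_regions = n),
    class = "degree_profile"
  )
}

#' @export
print.degree_profile <- function(x, ...) {
  cat(sprintf("degree_profile: %d regions, whole-brain degree %.2f, sparsity %.3f\n",
              x$n_regions, x$whole_brain, x$sparsity))
  if (length(x$regional)) {
    cat("  regional:", paste(sprintf("%s %.2f", names(x$regional), x$regional),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten degree profiles of a cohort into a data frame
#'
#' @param profiles Named list of `degree_profile` objects (names are
#'   participant ids).
#' @return Data frame with `participant_id`, `whole_brain`, one column per
#'   regional group, and `sparsity`.
#' @export
profiles_to_df <- function(profiles) {
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  rows <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    df <- data.frame(participant_id = id, whole_brain = p$whole_brain,
                     stringsAsFactors = FALSE)
    for (g in names(p$regional)) df[[g]] <- p$regional[[g]]
    df$sparsity <- p$sparsity
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
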