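# Readers/writers for the pipeline's plain-text interchange formats:
# event CSV, wake-window CSV, summary/region/connectome/reference TSV,
# streamline CSV, NIfTI label atlas, ground-truth JSON and YAML configs.

#' @name stepconn-io
#' @title File formats of the pipeline
#' @description
#' All tabular artifacts are plain CSV/TSV; the atlas label volume is
#' NIfTI; ground truth and manifests are JSON; pipeline configurations are
#' YAML. Streamlines are long-format CSV (`streamline_id`, `x`, `y`, `z`
#' voxel coordinates, one row per vertex).
NULL

#' @rdname stepconn-io
#' @param events Event-bout table.
#' @param path File path.
#' @export
write_event_csv <- function(events, path) {
  utils::write.csv(validate_bouts(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname stepconn-io
#' @export
read_event_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_bouts(ev)
  ev
}

#' @rdname stepconn-io
#' @param wake_windows Wake-window table.
#' @export
write_wake_csv <- function(wake_windows, path) {
  utils::write.csv(wake_windows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname stepconn-io
#' @export
read_wake_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname stepconn-io
#' @param table A data frame (activity summaries, region metadata,
#'   association results, ...).
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stepconn-io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname stepconn-io
#' @param atlas A `brain_atlas`.
#' @export
write_atlas_nifti <- function(atlas, path) {
  stopifnot(inherits(atlas, "brain_atlas"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- rep(atlas$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname stepconn-io
#' @param region_table Region-metadata table matching the label volume.
#' @export
read_atlas_nifti <- function(path, region_table, voxel_size_mm = NULL) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(img)), dim = dim(img))
  vox <- voxel_size_mm %||% RNifti::pixdim(img)[1]
  structure(
    list(labels = labels, voxel_size_mm = vox, region_table = region_table,
         block_origin = NULL),
    class = "brain_atlas"
  )
}

#' @rdname stepconn-io
#' @param streamlines List of polyline matrices.
#' @export
write_streamlines_csv <- function(streamlines, path) {
  if (!length(streamlines)) {
    utils::write.csv(data.frame(streamline_id = integer(0), x = numeric(0),
                                y = numeric(0), z = numeric(0)),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(seq_along(streamlines), function(k) {
    p <- streamlines[[k]]
    data.frame(streamline_id = k, x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname stepconn-io
#' @export
read_streamlines_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) return(list())
  lapply(split(d, d$streamline_id), function(s) {
    unname(as.matrix(s[, c("x", "y", "z")]))
  })
}

#' @rdname stepconn-io
#' @param cn A `connectome`.
#' @param prefix Path prefix; `<prefix>_weight.tsv`, `<prefix>_count.tsv`
#'   and `<prefix>_meta.json` are written.
#' @export
write_connectome_tsv <- function(cn, prefix) {
  stopifnot(inherits(cn, "connectome"))
  utils::write.table(cn$weight, paste0(prefix, "_weight.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cn$streamline_count, paste0(prefix, "_count.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(icv_mm3 = cn$icv_mm3, voxel_volume_mm3 = cn$voxel_volume_mm3,
         filtered = cn$filtered),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname stepconn-io
#' @export
read_connectome_tsv <- function(prefix) {
  w <- as.matrix(utils::read.delim(paste0(prefix, "_weight.tsv"), header = FALSE))
  k <- as.matrix(utils::read.delim(paste0(prefix, "_count.tsv"), header = FALSE))
  dimnames(w) <- dimnames(k) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  cn <- connectome(w, k, icv_mm3 = meta$icv_mm3,
                   voxel_volume_mm3 = meta$voxel_volume_mm3)
  cn$filtered <- isTRUE(meta$filtered)
  cn
}

#' @rdname stepconn-io
#' @param reference A `reference_network`.
#' @export
write_reference_tsv <- function(reference, path) {
  stopifnot(inherits(reference, "reference_network"))
  n <- reference$n_regions
  pairs <- upper_tri_pairs(n)
  occ <- reference$occurrence[cbind(pairs$i, pairs$j)]
  retained <- reference$mask[cbind(pairs$i, pairs$j)]
  out <- data.frame(i = pairs$i, j = pairs$j, occurrence = occ,
                    retained = retained)
  write_tsv(out[occ > 0 | retained, ], path)
}

#' @rdname stepconn-io
#' @param x A list serialisable to JSON (ground truth, manifest).
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname stepconn-io
#' @export
read_yaml_config <- function(path) {
  yaml::read_yaml(path)
}
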