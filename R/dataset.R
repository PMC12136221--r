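#' Construct a bilateral contrast dataset
#'
#' A `contrast_dataset` holds per-subject, per-epoch contrast estimates for
#' matched left and right cortical hemispheres, together with the vertex
#' coordinates of each hemisphere. Values are BOLD-contrast parameter
#' estimates in arbitrary units; coordinates are Cartesian millimetres.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param epoch_names Character vector of unique epoch labels.
#' @param left_values,right_values Numeric arrays of dimension
#'   `n_subjects x n_epochs x n_vertices`. Both hemispheres must have the
#'   same vertex count.
#' @param left_coords,right_coords Numeric `n_vertices x 3` matrices of
#'   vertex coordinates (mm); must be finite.
#' @return An object of class `contrast_dataset`.
#' @export
contrast_dataset <- function(subject_ids, epoch_names,
                             left_values, right_values,
                             left_coords, right_coords) {
  x <- structure(
    list(subject_ids = as.character(subject_ids),
         epoch_names = as.character(epoch_names),
         left_values = left_values, right_values = right_values,
         left_coords = left_coords, right_coords = right_coords),
    class = "contrast_dataset")
  validate_contrast_dataset(x)
}

validate_contrast_dataset <- function(x) {
  dl <- dim(x$left_values); dr <- dim(x$right_values)
  if (length(dl) != 3L || length(dr) != 3L)
    stop("schema error: hemisphere value arrays must be 3-dimensional ",
         "(subjects x epochs x vertices)", call. = FALSE)
  if (dl[3] != dr[3])
    stop("schema error: left hemisphere has ", dl[3], " vertices but right has ",
         dr[3], call. = FALSE)
  if (!identical(dl, dr))
    stop("schema error: left/right value arrays differ in shape", call. = FALSE)
  if (anyDuplicated(x$subject_ids))
    stop("schema error: duplicated subject ids", call. = FALSE)
  if (anyDuplicated(x$epoch_names))
    stop("schema error: duplicated epoch names", call. = FALSE)
  if (dl[1] != length(x$subject_ids) || dl[2] != length(x$epoch_names))
    stop("schema error: value array shape does not match subject/epoch lists",
         call. = FALSE)
  for (side in c("left_coords", "right_coords")) {
    cc <- x[[side]]
    if (!is.matrix(cc) || ncol(cc) != 3L || nrow(cc) != dl[3])
      stop("schema error: ", side, " must be an n_vertices x 3 matrix",
           call. = FALSE)
    if (!all(is.finite(cc)))
      stop("schema error: non-finite coordinates in ", side, call. = FALSE)
  }
  x
}

#' @export
print.contrast_dataset <- function(x, ...) {
  d <- dim(x$left_values)
  cat("Bilateral contrast dataset\n")
  cat("  subjects:", d[1], "  epochs:", d[2], "  vertices/hemisphere:", d[3], "\n")
  cat("  epochs:", paste(x$epoch_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.contrast_dataset <- function(x) dim(x$left_values)

#' Write a contrast dataset to the native container format
#'
#' The native container is a single-file serialized representation of the
#' validated dataset (format-version tagged). It is lossless: a write/read
#' round trip reproduces all values, identifiers, names, and coordinates
#' bit-for-bit. Vertex indices in all sidecar text formats are 0-based.
#'
#' @param dataset A `contrast_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  validate_contrast_dataset(dataset)
  payload <- list(format = "lateralize-container", version = 1L,
                  data = unclass(dataset))
  saveRDS(payload, path, compress = FALSE)  # large arrays; favor I/O speed
  invisible(path)
}

#' Read a contrast dataset
#'
#' @param path Path to a native container file.
#' @param format `"container"` for the native format. `"cifti_pair"` is
#'   reserved for CIFTI-2 dscalar input and is not available in this build.
#' @return A validated `contrast_dataset`.
#' @export
read_dataset <- function(path, format = c("container", "cifti_pair")) {
  format <- match.arg(format)
  if (format == "cifti_pair")
    stop("format error: CIFTI-2 dscalar reading is not supported in this ",
         "build; convert inputs to the native container format", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$format, "lateralize-container"))
    stop("format error: not a lateralize container: ", path, call. = FALSE)
  validate_contrast_dataset(structure(payload$data, class = "contrast_dataset"))
}

#' Construct a network partition
#'
#' @param labels Integer vector of per-vertex network codes: 1-based indices
#'   into `network_names`, or the background code `-1` for unassigned
#'   vertices (excluded from all network means).
#' @param network_names Ordered character vector of network names; defaults
#'   to the canonical 12-network order.
#' @return An object of class `network_partition`.
#' @export
network_partition <- function(labels, network_names = canonical_networks()) {
  labels <- as.integer(labels)
  bad <- labels != BACKGROUND_CODE & (labels < 1L | labels > length(network_names))
  if (any(bad))
    stop("schema error: partition labels outside 1..", length(network_names),
         " (or background ", BACKGROUND_CODE, ")", call. = FALSE)
  counts <- tabulate(labels[labels != BACKGROUND_CODE], nbins = length(network_names))
  structure(list(labels = labels, network_names = as.character(network_names),
                 empty = counts == 0L),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat("Network partition:", length(x$labels), "vertices,",
      sum(!x$empty), "populated networks\n")
  invisible(x)
}

#' Read a vertex-to-network partition from a text file
#'
#' Accepts either a two-column whitespace/tab-separated file of
#' `(vertex_index, network_name)` with 0-based vertex indices, or a
#' single-column file of one network name per vertex. Vertices absent from a
#' two-column file receive the background code. Names outside the canonical
#' 12-network list are appended after it, with a warning.
#'
#' @param path Path to the partition file.
#' @param n_vertices Total number of vertices (required for the two-column
#'   form; inferred for the one-column form).
#' @return A `network_partition`.
#' @export
read_partition <- function(path, n_vertices = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 1L) {
    names_per_vertex <- as.character(tab[[1]])
    if (is.null(n_vertices)) n_vertices <- length(names_per_vertex)
    if (length(names_per_vertex) != n_vertices)
      stop("schema error: partition file has ", length(names_per_vertex),
           " rows but n_vertices = ", n_vertices, call. = FALSE)
    idx <- seq_len(n_vertices)
  } else {
    if (is.null(n_vertices))
      stop("n_vertices is required for two-column partition files", call. = FALSE)
    vidx <- as.integer(tab[[1]])
    if (any(vidx < 0L) || any(vidx >= n_vertices))
      stop("schema error: vertex index out of range 0..", n_vertices - 1L,
           call. = FALSE)
    names_per_vertex <- rep(NA_character_, n_vertices)
    names_per_vertex[vidx + 1L] <- as.character(tab[[2]])
    idx <- seq_len(n_vertices)
  }
  nets <- canonical_networks()
  extra <- setdiff(unique(stats::na.omit(names_per_vertex)), nets)
  if (length(extra)) {
    warning("partition names outside the canonical 12 networks appended: ",
            paste(extra, collapse = ", "), call. = FALSE)
    nets <- c(nets, extra)
  }
  labels <- match(names_per_vertex, nets)
  labels[is.na(labels)] <- BACKGROUND_CODE
  network_partition(labels, nets)
}

#' Write a partition as two-column text (0-based vertex index, network name)
#'
#' @param partition A `network_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  keep <- partition$labels != BACKGROUND_CODE
  df <- data.frame(vertex = which(keep) - 1L,
                   network = partition$network_names[partition$labels[keep]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
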