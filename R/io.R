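# File I/O: NIfTI volumes and labels, graph TSV/GraphML, feature CSV,
# cohort manifest JSON.

#' Write / read a subject volume as NIfTI-1
#'
#' The 4D data array is stored with the repetition time in the header; the
#' mask travels as a separate 3D volume when `mask_path` is given.
#'
#' @param subject a `subject_volume`.
#' @param path output .nii path.
#' @param mask_path optional path for the binary mask volume.
#' @export
write_subject_nifti <- function(subject, path, mask_path = NULL) {
  img <- RNifti::asNifti(subject$data)
  RNifti::pixdim(img) <- c(1, 1, 1, subject$tr_seconds)
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(subject$mask),
                                             dim = dim(subject$mask))),
                       mask_path)
  }
  invisible(path)
}

#' @rdname write_subject_nifti
#' @param tr_seconds repetition time to attach on read.
#' @param subject_id,condition metadata to attach on read.
#' @export
read_subject_nifti <- function(path, mask_path = NULL, tr_seconds = 3.0,
                               subject_id = basename(path),
                               condition = NA_character_) {
  data <- array(as.numeric(RNifti::readNifti(path)),
                dim = dim(RNifti::readNifti(path)))
  mask <- if (is.null(mask_path)) {
    array(TRUE, dim = dim(data)[1:3])
  } else {
    array(as.numeric(RNifti::readNifti(mask_path)) > 0,
          dim = dim(data)[1:3])
  }
  structure(list(data = data, mask = mask, tr_seconds = tr_seconds,
                 subject_id = subject_id, condition = condition,
                 ground_truth = NULL),
            class = "subject_volume")
}

#' Write / read a label volume as 3D integer NIfTI-1
#'
#' @param labels a `label_volume`.
#' @param path output .nii path.
#' @export
write_labels_nifti <- function(labels, path) {
  RNifti::writeNifti(RNifti::asNifti(labels$labels), path)
  invisible(path)
}

#' @rdname write_labels_nifti
#' @export
read_labels_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  lab <- array(as.integer(round(as.numeric(arr))), dim = dim(arr))
  structure(list(labels = lab, n_regions = max(lab)),
            class = "label_volume")
}

#' Write / read a connectivity graph as weighted edge-list TSV
#'
#' Weights are written as full-precision decimals so the round trip is
#' bit-exact. Undirected graphs store each unordered pair once.
#'
#' @param g a `connectivity_graph`.
#' @param path output .tsv path.
#' @export
write_graph_tsv <- function(g, path) {
  W <- g$weights
  idx <- which(if (g$directed) W > 0 else upper.tri(W) & W > 0,
               arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# directed=%s n_nodes=%d", g$directed, nrow(W)), con)
  writeLines("node_i\tnode_j\tweight", con)
  if (nrow(idx) > 0L) {
    writeLines(sprintf("%d\t%d\t%.17g", g$node_ids[idx[, 1L]],
                       g$node_ids[idx[, 2L]], W[idx]), con)
  }
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  directed <- grepl("directed=TRUE", header)
  n <- as.integer(sub(".*n_nodes=(\\d+).*", "\\1", header))
  tab <- utils::read.delim(path, skip = 1L)
  W <- matrix(0, n, n)
  node_ids <- seq_len(n)
  if (nrow(tab) > 0L) {
    i <- match(tab$node_i, node_ids)
    j <- match(tab$node_j, node_ids)
    W[cbind(i, j)] <- tab$weight
    if (!directed) W[cbind(j, i)] <- tab$weight
  }
  connectivity_graph(W, directed, node_ids)
}

#' Write a connectivity graph as GraphML
#'
#' Method metadata (family, variant name, directedness) is embedded as
#' graph attributes.
#'
#' @param g a `connectivity_graph`.
#' @param path output .graphml path.
#' @export
write_graphml <- function(g, path) {
  ig <- as_igraph(g)
  if (inherits(g$method, "edge_method_spec")) {
    ig <- igraph::set_graph_attr(ig, "family", g$method$family)
    ig <- igraph::set_graph_attr(ig, "variant", g$method$name)
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write / read a feature table as CSV with stable column order
#'
#' @param tbl data.frame of features plus metadata columns.
#' @param path output .csv path.
#' @export
write_features_csv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write a cohort manifest as JSON
#'
#' @param cohort output of [simulate_cohort()].
#' @param path output .json path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  jsonlite::write_json(attr(cohort, "manifest"), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
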