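#' Write the clustered-feature report
#'
#' Writes one row per clustered feature with its cluster label, precursor
#' coordinates, aligned scan, and the ion bins its spectrum occupies
#' (semicolon-separated bin ids). Re-reading with [read_cluster_report()]
#' reproduces the feature-to-cluster mapping exactly.
#'
#' @param x A `dendro_clustering` result from [dendro_cluster()].
#' @param path Output path (tab-separated UTF-8).
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(x, path) {
  stopifnot(inherits(x, "dendro_clustering"))
  clusters <- x$clusters
  if (anyNA(clusters$cluster)) {
    abort("Every clustered feature must carry a cluster label.",
          class = "msdendro_validation_error")
  }
  bins_per_feature <- x$ion_table |>
    dplyr::distinct(.data$feature_id, .data$bin_id) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(bins = paste(sort(.data$bin_id), collapse = ";"),
                     .groups = "drop")
  report <- clusters |>
    dplyr::left_join(x$alignment, by = "feature_id") |>
    dplyr::left_join(bins_per_feature, by = "feature_id") |>
    dplyr::transmute(
      cluster_id = .data$cluster,
      feature_id = .data$feature_id,
      feature_mz = .data$mz,
      feature_rt = .data$rt,
      scan_id = .data$scan_id,
      bins = .data$bins
    ) |>
    dplyr::arrange(.data$cluster_id, .data$feature_id)
  readr::write_tsv(report, path)
  invisible(path)
}

#' Read a clustered-feature report back
#'
#' @param path Path written by [write_cluster_report()].
#' @return A tibble with the report columns; `bins` is a list-column of
#'   integer bin ids.
#' @export
read_cluster_report <- function(path) {
  report <- readr::read_tsv(path, col_types = readr::cols(
    cluster_id = readr::col_integer(),
    feature_id = readr::col_character(),
    feature_mz = readr::col_double(),
    feature_rt = readr::col_double(),
    scan_id = readr::col_character(),
    bins = readr::col_character()
  ))
  report$bins <- lapply(strsplit(report$bins, ";", fixed = TRUE), as.integer)
  report
}

#' Write the alignment/filtering audit file
#'
#' Features that never made it into the clustering are not silently dropped:
#' this writes one row per excluded feature with the reason (`unaligned` --
#' no spectrum within tolerance; `no_surviving_ions` -- all product ions fell
#' below the intensity filter).
#'
#' @param x A `dendro_clustering` result.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_alignment_audit <- function(x, path) {
  stopifnot(inherits(x, "dendro_clustering"))
  audit <- dplyr::bind_rows(
    dplyr::mutate(x$unaligned, reason = "unaligned"),
    dplyr::mutate(x$dropped, reason = "no_surviving_ions")
  )
  readr::write_tsv(dplyr::select(audit, "feature_id", "mz", "rt", "reason"), path)
  invisible(path)
}

#' Export a dendrogram to newick or JSON
#'
#' Newick export writes an ultrametric tree whose root-to-leaf path length for
#' each leaf equals the height of the final merge: branch lengths are parent
#' height minus child height, with leaves at height 0 (two leaves merged at
#' height 0.4 export as `(A:0.4,B:0.4);`). JSON export writes the raw merge
#' list (child codes, height, size) plus the leaf labels, and round-trips
#' exactly.
#'
#' @param tree An `hclust` tree, e.g. from [complete_linkage()].
#' @param labels Leaf labels; defaults to `tree$labels`.
#' @param path Output path.
#' @param format `"newick"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(tree, labels = tree$labels, path,
                              format = c("newick", "json")) {
  format <- match.arg(format)
  n <- nrow(tree$merge) + 1L
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n) {
    abort(sprintf("Tree has %d leaves but %d labels were supplied.",
                  n, length(labels)),
          class = "msdendro_validation_error")
  }
  if (format == "newick") {
    writeLines(build_newick(tree, labels), path)
  } else {
    merges <- lapply(seq_len(nrow(tree$merge)), function(k) {
      list(node_a = tree$merge[k, 1], node_b = tree$merge[k, 2],
           height = tree$height[k], size = subtree_size(tree, k))
    })
    jsonlite::write_json(list(labels = labels, merges = merges), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

subtree_size <- function(tree, k) {
  count <- function(code) {
    if (code < 0) 1L else count(tree$merge[code, 1]) + count(tree$merge[code, 2])
  }
  count(tree$merge[k, 1]) + count(tree$merge[k, 2])
}

build_newick <- function(tree, labels) {
  quote_label <- function(lab) {
    if (grepl("[(),:;'\\s]", lab)) {
      paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
    } else {
      lab
    }
  }
  m <- nrow(tree$merge)
  if (m == 0L) {
    return(paste0(quote_label(labels[1]), ";"))
  }
  node_height <- function(code) if (code < 0) 0 else tree$height[code]
  render <- function(code, parent_height) {
    if (code < 0) {
      sprintf("%s:%.10g", quote_label(labels[-code]), parent_height)
    } else {
      h <- tree$height[code]
      sprintf("(%s,%s):%.10g",
              render(tree$merge[code, 1], h - node_height(tree$merge[code, 1])) ,
              render(tree$merge[code, 2], h - node_height(tree$merge[code, 2])),
              parent_height)
    }
  }
  h_root <- tree$height[m]
  inner <- sprintf("(%s,%s);",
                   render(tree$merge[m, 1], h_root - node_height(tree$merge[m, 1])),
                   render(tree$merge[m, 2], h_root - node_height(tree$merge[m, 2])))
  inner
}
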