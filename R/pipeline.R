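#' Run the full MS/MS spectral clustering workflow
#'
#' End-to-end pipeline: intensity filtering (and optional neutral-loss
#' conversion) of the spectra, feature-to-spectrum alignment within the
#' configured tolerances, dynamic binning of all surviving product ions,
#' construction of the binary feature-by-bin occurrence matrix, pairwise
#' Bray-Curtis or Jaccard distances, complete-linkage clustering, threshold
#' cut, and the per-cluster ion-incidence table.
#'
#' Features with no spectrum within tolerance (`unaligned`) and features whose
#' spectrum lost every product ion to the intensity filter (`dropped`) are
#' excluded from clustering but reported in the result and exportable with
#' [write_alignment_audit()].
#'
#' @param features Feature tibble from [read_feature_list()].
#' @param spectra Spectrum tibble from [read_mgf()].
#' @param config A [dendro_config()].
#' @return A `dendro_clustering` object: a list with elements `config`,
#'   `alignment` (aligned features), `unaligned`, `dropped`, `ion_table`
#'   (feature_id, mz, intensity, bin_id of every surviving ion), `bins`,
#'   `occurrence` (binary matrix), `distance` (`dist`), `tree` (`hclust`),
#'   `clusters` (feature-to-cluster tibble) and `ion_records`
#'   (the [cluster_ion_table()]). Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#' @examples
#' sim <- generate_dataset(synthetic_spec(seed = 7))
#' fit <- dendro_cluster(sim$features, sim$spectra)
#' glance(fit)
#' head(tidy(fit))
#' @export
dendro_cluster <- function(features, spectra, config = dendro_config()) {
  stopifnot(inherits(config, "dendro_config"))
  spectra <- filter_ions(spectra, config)
  if (config$neutral_loss) spectra <- to_neutral_loss(spectra)

  alignment <- align_features(features, spectra, config)
  unaligned <- dplyr::filter(alignment, is.na(.data$scan_id))
  aligned <- dplyr::filter(alignment, !is.na(.data$scan_id))

  # features whose aligned spectrum has no surviving product ions: an all-zero
  # occurrence row would make Bray-Curtis 0/0, so they are dropped with audit
  n_ions <- spectra$n_ions[match(aligned$scan_id, spectra$scan_id)]
  dropped <- aligned[n_ions == 0L, , drop = FALSE]
  aligned <- aligned[n_ions > 0L, , drop = FALSE]
  if (nrow(aligned) < 2L) {
    abort(sprintf(
      "Only %d feature(s) remain after alignment and filtering; need >= 2 to cluster.",
      nrow(aligned)), class = "msdendro_validation_error")
  }

  ion_table <- aligned |>
    dplyr::mutate(spectrum = spectra$ions[match(.data$scan_id, spectra$scan_id)]) |>
    dplyr::select("feature_id", "spectrum") |>
    tidyr::unnest("spectrum")

  bins <- dynamic_bin(ion_table$mz, config$bin_eps)
  ion_table <- assign_bins(ion_table, bins)
  occurrence <- build_occurrence_matrix(ion_table, bins)
  # keep occurrence rows in alignment order
  occurrence <- occurrence[aligned$feature_id, , drop = FALSE]

  distance <- spectral_distance(occurrence, config$metric)
  tree <- complete_linkage(distance)
  clusters <- cut_clusters(tree, config$cut_threshold)
  ion_records <- cluster_ion_table(clusters, occurrence, ion_table, bins)

  structure(
    list(
      config = config,
      alignment = aligned,
      unaligned = unaligned,
      dropped = dropped,
      ion_table = ion_table,
      bins = bins,
      occurrence = occurrence,
      distance = distance,
      tree = tree,
      clusters = clusters,
      ion_records = ion_records
    ),
    class = "dendro_clustering"
  )
}

#' @export
print.dendro_clustering <- function(x, ...) {
  cat("<dendro_clustering>\n")
  cat(sprintf("  features : %d clustered, %d unaligned, %d dropped (no surviving ions)\n",
              nrow(x$alignment), nrow(x$unaligned), nrow(x$dropped)))
  cat(sprintf("  ion bins : %d (gap threshold %g Th)\n", nrow(x$bins),
              x$config$bin_eps))
  cat(sprintf("  clusters : %d at %s distance threshold %g (complete linkage)\n",
              max(x$clusters$cluster), x$config$metric, x$config$cut_threshold))
  invisible(x)
}

#' Tidy a clustering result
#'
#' One row per clustered feature with its cluster label, precursor
#' coordinates, and the aligned scan.
#'
#' @param x A `dendro_clustering` object.
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `cluster`, `mz`, `rt`,
#'   `scan_id`, `delta_mz`, `delta_rt`.
#' @method tidy dendro_clustering
#' @export
tidy.dendro_clustering <- function(x, ...) {
  dplyr::left_join(x$clusters, x$alignment, by = "feature_id") |>
    dplyr::select("feature_id", "cluster", "mz", "rt", "scan_id",
                  "delta_mz", "delta_rt")
}

#' One-row summary of a clustering result
#'
#' @param x A `dendro_clustering` object.
#' @param ... Unused.
#' @return A one-row tibble: feature counts, bin count, cluster count, metric
#'   and threshold used.
#' @method glance dendro_clustering
#' @export
glance.dendro_clustering <- function(x, ...) {
  tibble(
    n_features = nrow(x$alignment) + nrow(x$unaligned) + nrow(x$dropped),
    n_clustered = nrow(x$alignment),
    n_unaligned = nrow(x$unaligned),
    n_dropped = nrow(x$dropped),
    n_bins = nrow(x$bins),
    n_clusters = max(x$clusters$cluster),
    metric = x$config$metric,
    cut_threshold = x$config$cut_threshold
  )
}

#' Dendrogram plot of a clustering result
#'
#' Draws the complete-linkage dendrogram with leaves coloured by flat cluster
#' and a dashed line at the cut threshold.
#'
#' @param object A `dendro_clustering` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dendro_clustering
#' @export
autoplot.dendro_clustering <- function(object, ...) {
  seg <- dendrogram_segments(object$tree)
  leaves <- tibble(
    x = match(seq_along(object$tree$labels), object$tree$order),
    feature_id = object$tree$labels
  ) |>
    dplyr::left_join(object$clusters, by = "feature_id")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend)
    ) +
    ggplot2::geom_point(
      data = leaves,
      ggplot2::aes(x = .data$x, y = 0, colour = factor(.data$cluster))
    ) +
    ggplot2::geom_hline(yintercept = object$config$cut_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = sprintf("%s distance", object$config$metric),
                  colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

# line segments (x, y, xend, yend) of an hclust dendrogram
dendrogram_segments <- function(tree) {
  n <- length(tree$labels)
  leaf_x <- match(seq_len(n), tree$order)
  node_x <- numeric(nrow(tree$merge))
  node_y <- tree$height
  pos <- function(code) if (code < 0) c(leaf_x[-code], 0) else c(node_x[code], node_y[code])
  segs <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    a <- pos(tree$merge[k, 1])
    b <- pos(tree$merge[k, 2])
    node_x[k] <- mean(c(a[1], b[1]))
    segs[[k]] <- tibble(
      x = c(a[1], b[1], a[1]),
      y = c(a[2], b[2], tree$height[k]),
      xend = c(a[1], b[1], b[1]),
      yend = c(tree$height[k], tree$height[k], tree$height[k])
    )
  }
  dplyr::bind_rows(segs)
}
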