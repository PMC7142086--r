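#' Per-cluster ion-incidence table
#'
#' For every (cluster, bin) combination with at least one presence, reports
#' the share of the cluster's features that contain the bin
#' (`percent_present`), the m/z statistics of the raw (pre-binning) ion masses
#' those features contributed to the bin (`mz_average`, `mz_min`, `mz_max`;
#' the average is the unweighted mean over all contributing raw ions), and the
#' bin's incidence across all clustered features (`incidence_count`,
#' `incidence_percent`). Records are sorted by cluster, then descending
#' `percent_present`, then m/z. This is the table used to spot signature
#' fragment ions shared across a compound class.
#'
#' @param clusters Feature-to-cluster tibble from [cut_clusters()].
#' @param occurrence Binary matrix from [build_occurrence_matrix()].
#' @param ion_table Tibble of surviving raw ions with `feature_id`, `mz`,
#'   `bin_id` (see [assign_bins()]).
#' @param bins Bin tibble from [dynamic_bin()].
#' @return A tibble of cluster-ion records, one per (cluster, bin) with
#'   presence, including the bin's `representative_mz`.
#' @export
cluster_ion_table <- function(clusters, occurrence, ion_table, bins) {
  if (!setequal(clusters$feature_id, rownames(occurrence))) {
    abort("`clusters` and `occurrence` must cover the same features.",
          class = "msdendro_validation_error")
  }
  n_total <- nrow(clusters)
  cluster_sizes <- dplyr::count(clusters, .data$cluster, name = "cluster_size")

  presences <- ion_table |>
    dplyr::distinct(.data$feature_id, .data$bin_id) |>
    dplyr::left_join(clusters, by = "feature_id")

  overall <- presences |>
    dplyr::count(.data$bin_id, name = "incidence_count") |>
    dplyr::mutate(incidence_percent = 100 * .data$incidence_count / n_total)

  mz_stats <- ion_table |>
    dplyr::left_join(clusters, by = "feature_id") |>
    dplyr::group_by(.data$cluster, .data$bin_id) |>
    dplyr::summarise(
      mz_average = mean(.data$mz),
      mz_min = min(.data$mz),
      mz_max = max(.data$mz),
      .groups = "drop"
    )

  presences |>
    dplyr::count(.data$cluster, .data$bin_id, name = "n_present") |>
    dplyr::left_join(cluster_sizes, by = "cluster") |>
    dplyr::mutate(percent_present = 100 * .data$n_present / .data$cluster_size) |>
    dplyr::left_join(mz_stats, by = c("cluster", "bin_id")) |>
    dplyr::left_join(overall, by = "bin_id") |>
    dplyr::left_join(dplyr::select(bins, "bin_id", "representative_mz"),
                     by = "bin_id") |>
    dplyr::select("cluster", "bin_id", "representative_mz", "percent_present",
                  "n_present", "cluster_size", "mz_average", "mz_min", "mz_max",
                  "incidence_count", "incidence_percent") |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$percent_present),
                   .data$representative_mz)
}

#' Find diagnostic ion bins for a set of clusters
#'
#' Returns the bins whose `percent_present` is at least `require_percent` in
#' *every* named cluster. With `unique_to` set to one of the named clusters,
#' the bin must additionally be completely absent (0%) from the other named
#' clusters -- the "unique to cluster X" query used to separate sub-class
#' signatures from class-wide signatures.
#'
#' @param records Cluster-ion records from [cluster_ion_table()].
#' @param clusters Integer cluster labels to interrogate.
#' @param require_percent Minimum `percent_present` (default 100, i.e. the ion
#'   is present in every feature of the cluster).
#' @param unique_to Optional single cluster label from `clusters`; switches to
#'   the unique-ion query.
#' @return A tibble of qualifying bins with their `representative_mz`, sorted
#'   by m/z.
#' @export
diagnostic_ions <- function(records, clusters, require_percent = 100,
                            unique_to = NULL) {
  known <- unique(records$cluster)
  if (!all(clusters %in% known)) {
    abort(sprintf("Unknown cluster label(s): %s",
                  paste(setdiff(clusters, known), collapse = ", ")),
          class = "msdendro_validation_error")
  }
  pct <- function(cl) {
    sub <- records[records$cluster == cl, c("bin_id", "percent_present")]
    setNames(sub$percent_present, sub$bin_id)
  }
  if (is.null(unique_to)) {
    qualifying <- NULL
    for (cl in clusters) {
      p <- pct(cl)
      ok <- as.integer(names(p)[p >= require_percent])
      qualifying <- if (is.null(qualifying)) ok else intersect(qualifying, ok)
    }
  } else {
    if (length(unique_to) != 1L || !unique_to %in% clusters) {
      abort("`unique_to` must be a single label from `clusters`.",
            class = "msdendro_validation_error")
    }
    p <- pct(unique_to)
    qualifying <- as.integer(names(p)[p >= require_percent])
    for (cl in setdiff(clusters, unique_to)) {
      present_elsewhere <- as.integer(names(pct(cl)))
      qualifying <- setdiff(qualifying, present_elsewhere)
    }
  }
  records |>
    dplyr::distinct(.data$bin_id, .data$representative_mz) |>
    dplyr::filter(.data$bin_id %in% qualifying) |>
    dplyr::arrange(.data$representative_mz)
}

#' Ion histogram data for one cluster
#'
#' The (representative m/z, percent present) series behind a cluster's ion
#' histogram, in ascending m/z, ready for bar plotting or export.
#'
#' @param records Cluster-ion records from [cluster_ion_table()].
#' @param cluster A single cluster label present in `records`.
#' @return A tibble with `representative_mz` and `percent_present`.
#' @export
histogram_data <- function(records, cluster) {
  if (!cluster %in% records$cluster) {
    abort(sprintf("Unknown cluster label: %s", cluster),
          class = "msdendro_validation_error")
  }
  records[records$cluster == cluster,
          c("representative_mz", "percent_present")] |>
    dplyr::arrange(.data$representative_mz)
}

#' Write one ion-histogram file per cluster
#'
#' Writes `cluster_<label>_ions.tsv` files (representative m/z, percent
#' present, percentages rounded to whole numbers as in the report tables;
#' full precision is retained in the in-memory records).
#'
#' @param records Cluster-ion records from [cluster_ion_table()].
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_ion_histograms <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(sort(unique(records$cluster)), function(cl) {
    path <- file.path(dir, sprintf("cluster_%d_ions.tsv", cl))
    out <- histogram_data(records, cl)
    out$percent_present <- round(out$percent_present)
    readr::write_tsv(out, path)
    path
  }, character(1))
  invisible(paths)
}

#' Bar plot of a cluster's ion incidences
#'
#' @param x A `dendro_clustering` result or a cluster-ion record tibble.
#' @param cluster Cluster label to plot.
#' @return A ggplot object.
#' @export
plot_ion_histogram <- function(x, cluster) {
  records <- if (inherits(x, "dendro_clustering")) x$ion_records else x
  dat <- histogram_data(records, cluster)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$representative_mz,
                                    y = .data$percent_present)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::labs(x = "m/z", y = "% of cluster features",
                  title = sprintf("Cluster %s ion incidences", cluster)) +
    ggplot2::theme_minimal()
}
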