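#' Dynamic gap-based binning of product-ion masses
#'
#' Sorts the pooled product-ion masses of all spectra and walks them once,
#' opening a new bin whenever the difference between two consecutive masses
#' exceeds `bin_eps`. This is 1-D single-linkage clustering cut at `bin_eps`:
#' a bin may span more than `bin_eps` overall (chaining); only consecutive
#' gaps are constrained. The bin's representative m/z is the arithmetic mean
#' of its member masses.
#'
#' @param mz Numeric vector of ion masses (Th), any order, duplicates allowed.
#' @param bin_eps Gap threshold in Th (> 0). Should reflect instrument
#'   precision; the workflow default is 0.0005.
#' @return A tibble of bins ordered by m/z: `bin_id`, `min_mz`, `max_mz`,
#'   `representative_mz`, `n_members`. Empty input gives zero rows.
#' @examples
#' dynamic_bin(c(100.0000, 100.0004, 100.0010), bin_eps = 0.0005)
#' @export
dynamic_bin <- function(mz, bin_eps = 0.0005) {
  if (!is.numeric(bin_eps) || length(bin_eps) != 1L || bin_eps <= 0) {
    abort("`bin_eps` must be a single positive number.",
          class = "msdendro_config_error")
  }
  if (length(mz) == 0L) {
    return(tibble(bin_id = integer(), min_mz = numeric(), max_mz = numeric(),
                  representative_mz = numeric(), n_members = integer()))
  }
  if (any(mz < 0)) {
    abort("Ion masses must be non-negative.", class = "msdendro_validation_error")
  }
  s <- sort(mz)
  bin_id <- cumsum(c(1L, as.integer(diff(s) > bin_eps)))
  tibble(mz = s, bin_id = bin_id) |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      min_mz = min(.data$mz),
      max_mz = max(.data$mz),
      representative_mz = mean(.data$mz),
      n_members = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("bin_id", "min_mz", "max_mz", "representative_mz", "n_members")
}

#' Assign ions to previously built bins
#'
#' Maps each ion mass to the bin whose `[min_mz, max_mz]` interval contains
#' it. Because bins are built from these same masses, an ion falling in no bin
#' indicates an internal inconsistency and is an error.
#'
#' @param ions Tibble with at least a `mz` column (typically also
#'   `feature_id`).
#' @param bins Bin tibble from [dynamic_bin()].
#' @return `ions` with an added integer `bin_id` column.
#' @export
assign_bins <- function(ions, bins) {
  if (nrow(ions) == 0L) {
    ions$bin_id <- integer(0)
    return(ions)
  }
  idx <- findInterval(ions$mz, bins$min_mz)
  ok <- idx >= 1L & ions$mz <= bins$max_mz[pmax(idx, 1L)]
  if (!all(ok)) {
    abort(sprintf("%d ion(s) fall in no bin; bins were not built from these ions.",
                  sum(!ok)),
          class = "msdendro_internal_error")
  }
  ions$bin_id <- bins$bin_id[idx]
  ions
}

#' Build the binary feature-by-bin occurrence matrix
#'
#' Cell `(feature, bin)` is 1 when the feature's aligned spectrum contributed
#' at least one ion to the bin; multiple ions of one spectrum in the same bin
#' count once. Every row and every column has at least one presence by
#' construction (features without surviving ions are excluded upstream; bins
#' are built from these ions).
#'
#' @param binned_ions Tibble with `feature_id` and `bin_id` columns, as from
#'   [assign_bins()].
#' @param bins Bin tibble from [dynamic_bin()]; fixes the column order.
#' @return An integer 0/1 matrix with feature ids as row names and bin ids as
#'   column names.
#' @export
build_occurrence_matrix <- function(binned_ions, bins) {
  features <- unique(binned_ions$feature_id)
  mat <- matrix(0L, nrow = length(features), ncol = nrow(bins),
                dimnames = list(features, as.character(bins$bin_id)))
  pairs <- dplyr::distinct(binned_ions, .data$feature_id, .data$bin_id)
  mat[cbind(match(pairs$feature_id, features),
            match(pairs$bin_id, bins$bin_id))] <- 1L
  if (nrow(mat) > 0L && any(rowSums(mat) == 0L)) {
    abort("Occurrence matrix has an all-zero row.",
          class = "msdendro_internal_error")
  }
  mat
}
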