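#' Pairwise distances between binned spectra
#'
#' Computes pairwise distances between the binary rows of an occurrence
#' matrix. For two presence/absence vectors with `a` shared bins and `b + c`
#' bins private to either spectrum:
#'
#' * Bray-Curtis: `(b + c) / (2a + b + c)` -- on 0/1 data this is the
#'   Sorensen-Dice dissimilarity;
#' * Jaccard: `(b + c) / (a + b + c)`.
#'
#' Both lie in \[0, 1\], are 0 for identical rows and 1 for disjoint rows,
#' and Jaccard >= Bray-Curtis on any pair. Computation goes through
#' [vegan::vegdist()].
#'
#' @param occurrence Binary matrix from [build_occurrence_matrix()]; at least
#'   two rows, no all-zero rows (an all-zero row makes the distance 0/0).
#' @param metric `"braycurtis"` (default) or `"jaccard"`.
#' @return A `stats::dist` object with zero self-distances.
#' @export
spectral_distance <- function(occurrence, metric = c("braycurtis", "jaccard")) {
  metric <- match.arg(metric)
  if (!is.matrix(occurrence) || nrow(occurrence) < 2L) {
    abort("`occurrence` must be a matrix with at least two rows.",
          class = "msdendro_validation_error")
  }
  if (!all(occurrence %in% c(0L, 1L))) {
    abort("`occurrence` must be a binary 0/1 matrix.",
          class = "msdendro_validation_error")
  }
  if (any(rowSums(occurrence) == 0)) {
    abort("All-zero rows have undefined distance; filter them out first.",
          class = "msdendro_validation_error")
  }
  d <- switch(metric,
    braycurtis = vegan::vegdist(occurrence, method = "bray"),
    jaccard = vegan::vegdist(occurrence, method = "jaccard", binary = TRUE)
  )
  d
}
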