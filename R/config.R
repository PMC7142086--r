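#' Pipeline configuration
#'
#' Bundles every tunable of the clustering workflow. Defaults are the settings
#' used for the firefly hemolymph analysis: feature-to-spectrum alignment within
#' m/z 0.005 Th and 6 s retention time, an absolute product-ion intensity floor
#' of 5000 counts, dynamic binning with a consecutive-mass gap threshold of
#' m/z 0.0005 Th, Bray-Curtis distances on presence/absence vectors, and a
#' complete-linkage dendrogram cut at distance 0.7.
#'
#' Exactly one intensity filter may be active per run: the absolute floor
#' (`min_intensity_abs`, counts) or the relative floor (`min_intensity_rel`,
#' fraction of the spectrum base peak in \[0, 1\]). Set the one you do not want
#' to `NULL`.
#'
#' @param mz_tol Alignment tolerance on precursor m/z, in Thomson. Must be > 0.
#' @param rt_tol Alignment tolerance on retention time, in seconds. Must be > 0.
#' @param min_intensity_abs Absolute intensity floor in counts, or `NULL`.
#'   Ions with intensity >= the floor are kept (the floor is admissible).
#' @param min_intensity_rel Relative intensity floor as a fraction of the
#'   spectrum base peak, in \[0, 1\], or `NULL` (default).
#' @param neutral_loss If `TRUE`, spectra are converted to neutral-loss
#'   representation (precursor m/z minus product m/z) before binning.
#' @param bin_eps Dynamic-binning gap threshold in Thomson: a new bin opens when
#'   two consecutive sorted masses differ by more than `bin_eps`. Should reflect
#'   instrument precision.
#' @param metric Distance between binary binned spectra: `"braycurtis"`
#'   (Sorensen-Dice on presence/absence) or `"jaccard"`.
#' @param cut_threshold Dendrogram cut distance in \[0, 1\]. Merges at height
#'   <= the threshold are joined (inclusive).
#'
#' @return A `dendro_config` object (a validated named list).
#' @examples
#' dendro_config()
#' dendro_config(metric = "jaccard", cut_threshold = 0.5)
#' @export
dendro_config <- function(mz_tol = 0.005,
                          rt_tol = 6,
                          min_intensity_abs = 5000,
                          min_intensity_rel = NULL,
                          neutral_loss = FALSE,
                          bin_eps = 0.0005,
                          metric = c("braycurtis", "jaccard"),
                          cut_threshold = 0.7) {
  metric <- match.arg(metric)
  stopifnot(is.logical(neutral_loss), length(neutral_loss) == 1L)
  if (!is.numeric(mz_tol) || length(mz_tol) != 1L || mz_tol <= 0) {
    abort("`mz_tol` must be a single positive number (Thomson).",
          class = "msdendro_config_error")
  }
  if (!is.numeric(rt_tol) || length(rt_tol) != 1L || rt_tol <= 0) {
    abort("`rt_tol` must be a single positive number (seconds).",
          class = "msdendro_config_error")
  }
  if (!is.numeric(bin_eps) || length(bin_eps) != 1L || bin_eps <= 0) {
    abort("`bin_eps` must be a single positive number (Thomson).",
          class = "msdendro_config_error")
  }
  if (!is.null(min_intensity_abs) && !is.null(min_intensity_rel)) {
    abort("At most one of `min_intensity_abs` and `min_intensity_rel` may be set.",
          class = "msdendro_config_error")
  }
  if (!is.null(min_intensity_abs) &&
      (!is.numeric(min_intensity_abs) || min_intensity_abs < 0)) {
    abort("`min_intensity_abs` must be a non-negative number of counts.",
          class = "msdendro_config_error")
  }
  if (!is.null(min_intensity_rel) &&
      (!is.numeric(min_intensity_rel) || min_intensity_rel < 0 ||
         min_intensity_rel > 1)) {
    abort("`min_intensity_rel` must lie in [0, 1].",
          class = "msdendro_config_error")
  }
  if (!is.numeric(cut_threshold) || cut_threshold < 0 || cut_threshold > 1) {
    abort("`cut_threshold` must lie in [0, 1].",
          class = "msdendro_config_error")
  }
  structure(
    list(
      mz_tol = mz_tol,
      rt_tol = rt_tol,
      min_intensity_abs = min_intensity_abs,
      min_intensity_rel = min_intensity_rel,
      neutral_loss = isTRUE(neutral_loss),
      bin_eps = bin_eps,
      metric = metric,
      cut_threshold = cut_threshold
    ),
    class = "dendro_config"
  )
}

#' @export
print.dendro_config <- function(x, ...) {
  cat("<dendro_config>\n")
  cat(sprintf("  alignment : |dm/z| <= %g Th, |dRT| <= %g s\n", x$mz_tol, x$rt_tol))
  if (!is.null(x$min_intensity_abs)) {
    cat(sprintf("  intensity : absolute floor %g counts\n", x$min_intensity_abs))
  } else if (!is.null(x$min_intensity_rel)) {
    cat(sprintf("  intensity : relative floor %g x base peak\n", x$min_intensity_rel))
  } else {
    cat("  intensity : no filter\n")
  }
  cat(sprintf("  binning   : gap threshold %g Th%s\n", x$bin_eps,
              if (x$neutral_loss) " (neutral-loss mode)" else ""))
  cat(sprintf("  clustering: %s distance, complete linkage, cut at %g\n",
              x$metric, x$cut_threshold))
  invisible(x)
}
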