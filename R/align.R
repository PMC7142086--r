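#' Align LC-MS features to MS/MS spectra
#'
#' Matches every feature to at most one spectrum. A spectrum is a candidate
#' when both `|precursor_mz - feature mz| <= mz_tol` and `|rt - feature rt| <=
#' rt_tol` (boundaries inclusive). Among candidates the winner minimises
#' `|dRT|`, with ties broken by smaller `|dm/z|` and finally by scan file
#' order (`scan_index`), which makes the alignment deterministic and invariant
#' to shuffling of the spectrum table. One spectrum may serve several
#' co-eluting isobaric features; each feature gets at most one spectrum.
#'
#' @param features Feature tibble from [read_feature_list()].
#' @param spectra Spectrum tibble from [read_mgf()].
#' @param config A [dendro_config()].
#' @return A tibble with one row per input feature: `feature_id`, `mz`, `rt`,
#'   `scan_id` (`NA` when no spectrum fell within tolerance), `scan_index`,
#'   `delta_mz`, `delta_rt`.
#' @export
align_features <- function(features, spectra, config = dendro_config()) {
  stopifnot(inherits(config, "dendro_config"))
  n <- nrow(features)
  if (nrow(spectra) == 0L) {
    if (n > 0L) {
      warn(sprintf("No spectra supplied: all %d features are unaligned.", n))
    }
    return(tibble(
      feature_id = features$feature_id, mz = features$mz, rt = features$rt,
      scan_id = NA_character_, scan_index = NA_integer_,
      delta_mz = NA_real_, delta_rt = NA_real_
    ))
  }
  scan_id <- character(n)
  scan_index <- integer(n)
  delta_mz <- rep(NA_real_, n)
  delta_rt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dmz <- spectra$precursor_mz - features$mz[i]
    drt <- spectra$rt - features$rt[i]
    cand <- which(!is.na(drt) & abs(dmz) <= config$mz_tol &
                    abs(drt) <= config$rt_tol)
    if (length(cand) == 0L) {
      scan_id[i] <- NA_character_
      scan_index[i] <- NA_integer_
      next
    }
    best <- cand[order(abs(drt[cand]), abs(dmz[cand]),
                       spectra$scan_index[cand])][1]
    scan_id[i] <- spectra$scan_id[best]
    scan_index[i] <- spectra$scan_index[best]
    delta_mz[i] <- dmz[best]
    delta_rt[i] <- drt[best]
  }
  tibble(
    feature_id = features$feature_id, mz = features$mz, rt = features$rt,
    scan_id = scan_id, scan_index = scan_index,
    delta_mz = delta_mz, delta_rt = delta_rt
  )
}

#' Filter product ions by intensity
#'
#' Applies the configured intensity filter to every spectrum. In absolute mode
#' ions with `intensity >= min_intensity_abs` are kept (the floor itself is an
#' admissible value); in relative mode the floor is `min_intensity_rel` times
#' the spectrum's base-peak intensity. Ion order is preserved and the
#' operation is idempotent. Spectra may come out ion-free (`n_ions == 0`);
#' such spectra are excluded from clustering downstream and surface in the
#' audit report.
#'
#' @param spectra Spectrum tibble.
#' @param config A [dendro_config()].
#' @return The spectrum tibble with filtered `ions` and updated `n_ions`.
#' @export
filter_ions <- function(spectra, config = dendro_config()) {
  stopifnot(inherits(config, "dendro_config"))
  if (is.null(config$min_intensity_abs) && is.null(config$min_intensity_rel)) {
    return(spectra)
  }
  spectra$ions <- purrr::map(spectra$ions, function(ions) {
    if (nrow(ions) == 0L) return(ions)
    floor_val <- if (!is.null(config$min_intensity_abs)) {
      config$min_intensity_abs
    } else {
      config$min_intensity_rel * max(ions$intensity)
    }
    ions[ions$intensity >= floor_val, , drop = FALSE]
  })
  spectra$n_ions <- vapply(spectra$ions, nrow, integer(1))
  spectra
}

#' Convert spectra to neutral-loss representation
#'
#' Replaces every product-ion m/z by the neutral loss `precursor_mz - m/z`,
#' drops ions at or above the precursor (non-positive loss), and re-sorts
#' ascending. Intensities are carried through unchanged. A spectrum can be
#' converted only once per run; a second application is rejected.
#'
#' @param spectra Spectrum tibble.
#' @return The spectrum tibble in neutral-loss space (`neutral_loss = TRUE`).
#' @export
to_neutral_loss <- function(spectra) {
  if (any(spectra$neutral_loss)) {
    abort("Spectra are already in neutral-loss representation.",
          class = "msdendro_validation_error")
  }
  if (anyNA(spectra$precursor_mz)) {
    abort("Neutral-loss conversion requires a precursor m/z for every spectrum.",
          class = "msdendro_validation_error")
  }
  spectra$ions <- purrr::map2(spectra$ions, spectra$precursor_mz,
    function(ions, pre) {
      loss <- pre - ions$mz
      keep <- loss > 0
      out <- tibble(mz = loss[keep], intensity = ions$intensity[keep])
      out[order(out$mz), , drop = FALSE]
    })
  spectra$n_ions <- vapply(spectra$ions, nrow, integer(1))
  spectra$neutral_loss <- TRUE
  spectra
}
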