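#' Read MS/MS spectra from a Mascot Generic Format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks into a spectrum table. Header keys are
#' accepted case-insensitively. `PEPMASS` supplies the precursor m/z (first
#' numeric token); retention time is taken from `RTINSECONDS`, or from
#' `RTINMINUTES` multiplied by 60, and is always stored in seconds. Polarity is
#' inferred from the sign of an optional `CHARGE` header (`"+"`, `"-"`), else
#' `"unknown"`. Product ions are re-sorted ascending by m/z; duplicate m/z
#' values are kept as separate ions (deduplication happens later, at binning).
#' Blocks with zero product ions are retained with an empty ion list.
#'
#' @param path Path to an MGF file.
#' @return A tibble with one row per spectrum and columns `scan_id`,
#'   `scan_index` (file order, used as the final alignment tie-break),
#'   `precursor_mz` (Th), `rt` (seconds), `polarity`, `n_ions`, `ions`
#'   (list-column of tibbles with `mz`, `intensity`), and `neutral_loss`
#'   (always `FALSE` on read).
#' @seealso [write_mgf()], [align_features()]
#' @examples
#' mgf <- tempfile(fileext = ".mgf")
#' writeLines(c("BEGIN IONS", "TITLE=scan_1", "PEPMASS=533.2379",
#'              "RTINSECONDS=907.4", "105.0701 8000", "END IONS"), mgf)
#' read_mgf(mgf)
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("MGF file not found: '%s'", path), class = "msdendro_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- which(toupper(lines) == "BEGIN IONS")
  if (length(starts) == 0L) {
    return(empty_spectra())
  }

  spectra <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    from <- starts[b] + 1L
    rel_end <- match("END IONS", toupper(lines[from:length(lines)]))
    if (is.na(rel_end)) {
      abort(sprintf("MGF block %d has no END IONS terminator.", b),
            class = "msdendro_format_error")
    }
    body_idx <- seq(from, from + rel_end - 2L)
    body <- lines[body_idx]

    keep <- nzchar(body) & !startsWith(body, "#")
    body <- body[keep]
    body_idx <- body_idx[keep]
    is_header <- grepl("=", body, fixed = TRUE) & grepl("^[A-Za-z]", body)

    headers <- body[is_header]
    keys <- toupper(sub("=.*$", "", headers))
    vals <- sub("^[^=]*=", "", headers)
    names(vals) <- keys

    peak_lines <- body[!is_header]
    peak_lineno <- body_idx[!is_header]
    peaks <- parse_peak_lines(peak_lines, peak_lineno)

    if (!"PEPMASS" %in% keys) {
      abort(sprintf("MGF block %d is missing a PEPMASS header.", b),
            class = "msdendro_format_error")
    }
    pepmass <- suppressWarnings(
      as.numeric(strsplit(trimws(vals[["PEPMASS"]]), "[[:space:]]+")[[1]][1])
    )
    if (is.na(pepmass) || pepmass <= 0) {
      abort(sprintf("MGF block %d has a non-positive or non-numeric PEPMASS.", b),
            class = "msdendro_format_error")
    }

    rt <- NA_real_
    if ("RTINSECONDS" %in% keys) {
      rt <- suppressWarnings(as.numeric(vals[["RTINSECONDS"]]))
    } else if ("RTINMINUTES" %in% keys) {
      rt <- suppressWarnings(as.numeric(vals[["RTINMINUTES"]])) * 60
    }

    polarity <- "unknown"
    if ("CHARGE" %in% keys) {
      polarity <- if (grepl("-", vals[["CHARGE"]], fixed = TRUE)) "-" else "+"
    }

    scan_id <- if ("TITLE" %in% keys) vals[["TITLE"]] else sprintf("scan_%d", b)

    spectra[[b]] <- tibble(
      scan_id = unname(scan_id),
      scan_index = b,
      precursor_mz = pepmass,
      rt = rt,
      polarity = polarity,
      n_ions = nrow(peaks),
      ions = list(peaks),
      neutral_loss = FALSE
    )
  }
  dplyr::bind_rows(spectra)
}

parse_peak_lines <- function(peak_lines, lineno) {
  if (length(peak_lines) == 0L) {
    return(tibble(mz = numeric(), intensity = numeric()))
  }
  toks <- strsplit(peak_lines, "[[:space:]]+")
  mz <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 1L)))
  intensity <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 2L)))
  bad <- which(is.na(mz) | is.na(intensity))
  if (length(bad) > 0L) {
    abort(sprintf("Non-numeric peak line at line %d: '%s'",
                  lineno[bad[1]], peak_lines[bad[1]]),
          class = "msdendro_format_error")
  }
  if (any(intensity < 0)) {
    abort(sprintf("Negative intensity at line %d.", lineno[which(intensity < 0)[1]]),
          class = "msdendro_format_error")
  }
  ord <- order(mz)
  tibble(mz = mz[ord], intensity = intensity[ord])
}

empty_spectra <- function() {
  tibble(
    scan_id = character(), scan_index = integer(), precursor_mz = numeric(),
    rt = numeric(), polarity = character(), n_ions = integer(),
    ions = list(), neutral_loss = logical()
  )
}

#' Write spectra to a Mascot Generic Format (MGF) file
#'
#' Inverse of [read_mgf()] for fixture generation and export. Peak m/z and
#' intensity are written with 6 decimal places and retention time with 4, so a
#' write/read round trip preserves peaks to 1e-6 Th and RT to 1e-4 s.
#'
#' @param spectra Spectrum tibble as returned by [read_mgf()] (columns
#'   `scan_id`, `precursor_mz`, `rt`, `ions`; `polarity` optional).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    ions <- spectra$ions[[i]]
    block <- c(
      "BEGIN IONS",
      sprintf("TITLE=%s", spectra$scan_id[i]),
      sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]),
      sprintf("RTINSECONDS=%.4f", spectra$rt[i])
    )
    pol <- if ("polarity" %in% names(spectra)) spectra$polarity[i] else "unknown"
    if (identical(pol, "+")) block <- c(block, "CHARGE=1+")
    if (identical(pol, "-")) block <- c(block, "CHARGE=1-")
    if (nrow(ions) > 0L) {
      block <- c(block, sprintf("%.6f %.6f", ions$mz, ions$intensity))
    }
    writeLines(c(block, "END IONS"), con)
  }
  invisible(path)
}
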