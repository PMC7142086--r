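#' Count MS2 scans in an mzML file
#'
#' Counts scans with MS level 2 in an mzML file, optionally restricted to one
#' acquisition polarity. Useful as a raw-data sanity check before alignment
#' (e.g. how many MS/MS scans a polarity-switching DDA run actually acquired).
#' Reading goes through Bioconductor's `mzR`.
#'
#' @param path Path to an mzML file.
#' @param polarity `"any"` (default), `"+"`, or `"-"`. mzML scans without
#'   polarity metadata are counted only under `"any"`.
#' @return A single integer scan count.
#' @examples
#' \dontrun{
#' count_ms2_scans("Ppyr_hemolymph_extract.mzML")            # all MS2 scans
#' count_ms2_scans("Ppyr_hemolymph_extract.mzML", "+")       # positive mode only
#' }
#' @export
count_ms2_scans <- function(path, polarity = c("any", "+", "-")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) {
    abort(sprintf("mzML file not found: '%s'", path), class = "msdendro_io_error")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (!"msLevel" %in% names(hdr) || anyNA(hdr$msLevel)) {
    abort("mzML file carries no per-scan MS level metadata.",
          class = "msdendro_format_error")
  }
  ms2 <- hdr[hdr$msLevel == 2L, , drop = FALSE]
  n <- switch(polarity,
    any = nrow(ms2),
    # mzR polarity coding: 1 = positive, 0 = negative, -1 = unknown
    "+" = sum(ms2$polarity == 1L),
    "-" = sum(ms2$polarity == 0L)
  )
  as.integer(n)
}
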