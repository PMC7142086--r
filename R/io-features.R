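#' Read a feature list
#'
#' Reads the deconvoluted LC-MS feature list that accompanies the MGF spectra.
#' Two encodings are accepted, decided per line:
#'
#' * delimited columns `id`, `mz`, `rt` (tab, comma, or whitespace separated,
#'   no header), or
#' * a single underscore-encoded identifier `<name>_<mz>_<rt>`, where the last
#'   two underscore-separated tokens are the precursor m/z and the retention
#'   time (the `name` part may itself contain underscores). This is the common
#'   `sample_mz_rtminutes` export convention.
#'
#' Retention times are converted to seconds internally. `rt_unit` declares the
#' unit used in the file; the default is `"minutes"`, matching the usual
#' underscore-id convention, and is never guessed from the data.
#'
#' @param path Path to the feature list file.
#' @param rt_unit Unit of the retention-time field in the file: `"minutes"`
#'   (default) or `"seconds"`.
#' @return A tibble with columns `feature_id`, `mz` (Th), `rt` (seconds).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("sample_a_436.269439697265_13.538295", f)
#' read_feature_list(f)  # rt 13.538295 min -> 812.2977 s
#' @export
read_feature_list <- function(path, rt_unit = c("minutes", "seconds")) {
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) {
    abort(sprintf("Feature list not found: '%s'", path),
          class = "msdendro_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(tibble(feature_id = character(), mz = numeric(), rt = numeric()))
  }

  parse_one <- function(line, no) {
    toks <- strsplit(line, "[\t, ]+")[[1]]
    if (length(toks) >= 3L) {
      id <- toks[1]
      mz <- suppressWarnings(as.numeric(toks[2]))
      rt <- suppressWarnings(as.numeric(toks[3]))
    } else if (length(toks) == 1L) {
      parts <- strsplit(line, "_", fixed = TRUE)[[1]]
      if (length(parts) < 3L) {
        abort(sprintf("Line %d: cannot parse '%s' as 'name_mz_rt' or delimited columns.",
                      no, line), class = "msdendro_format_error")
      }
      np <- length(parts)
      id <- line
      mz <- suppressWarnings(as.numeric(parts[np - 1L]))
      rt <- suppressWarnings(as.numeric(parts[np]))
    } else {
      abort(sprintf("Line %d: expected 3 columns or a single encoded id, got 2 tokens.", no),
            class = "msdendro_format_error")
    }
    if (is.na(mz) || is.na(rt)) {
      abort(sprintf("Line %d: non-numeric m/z or retention time in '%s'.", no, line),
            class = "msdendro_format_error")
    }
    tibble(feature_id = id, mz = mz, rt = rt)
  }

  features <- purrr::map2_dfr(lines, lineno, parse_one)
  if (rt_unit == "minutes") features$rt <- features$rt * 60
  dup <- features$feature_id[duplicated(features$feature_id)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate feature id(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "msdendro_validation_error")
  }
  if (any(features$mz <= 0) || any(features$rt < 0)) {
    abort("Feature m/z must be > 0 and retention time >= 0.",
          class = "msdendro_validation_error")
  }
  features
}

#' Write a feature list
#'
#' Companion writer for [read_feature_list()], used mainly by the synthetic
#' data generator.
#'
#' @param features Tibble with `feature_id`, `mz`, `rt` (seconds).
#' @param path Output path.
#' @param encoding `"underscore"` writes one `<feature_id>` per line (ids must
#'   already embed m/z and rt); `"tsv"` writes three tab-separated columns.
#' @param rt_unit Unit to write retention times in for `"tsv"` encoding.
#' @return `path`, invisibly.
#' @export
write_feature_list <- function(features, path,
                               encoding = c("underscore", "tsv"),
                               rt_unit = c("minutes", "seconds")) {
  encoding <- match.arg(encoding)
  rt_unit <- match.arg(rt_unit)
  if (encoding == "underscore") {
    writeLines(features$feature_id, path)
  } else {
    rt <- if (rt_unit == "minutes") features$rt / 60 else features$rt
    writeLines(sprintf("%s\t%.10g\t%.10g", features$feature_id, features$mz, rt),
               path)
  }
  invisible(path)
}
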