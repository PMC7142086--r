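#' Specification for a synthetic MGF + feature-list dataset
#'
#' Describes a deterministic dataset with planted cluster structure: each
#' cluster carries a distinct set of signature product ions realised in every
#' member spectrum with small Gaussian m/z jitter, an optional set of ions
#' shared across all clusters (emulating class-wide diagnostic fragments),
#' uniform background ions private to each spectrum, and a fraction of
#' sub-threshold ions that the intensity filter should remove. Intensities are
#' log-normal (median 20000 counts, sigma 1 on the log scale); signature and
#' shared ions are resampled to stay at or above 5000 counts so the planted
#' structure survives the default absolute filter.
#'
#' The default jitter (sd 0.0001 Th) is roughly instrument precision and less
#' than half the default binning gap threshold (0.0005 Th), which guarantees
#' each planted ion maps to a single bin across all spectra.
#'
#' @param n_clusters Number of planted clusters (>= 1).
#' @param features_per_cluster Features (= spectra) per cluster (>= 1).
#' @param signature_ions_per_cluster Distinct signature ions per cluster.
#' @param shared_ions Ions present in every spectrum of every cluster
#'   (default 0). Shared ions pull clusters together: with the default 6
#'   signature ions, 4 shared ions already drag the between-cluster
#'   Bray-Curtis distance to ~0.69, below the default 0.7 cut.
#' @param mz_jitter_sd Gaussian m/z jitter (Th) applied per realised ion.
#' @param background_ions_per_spectrum Uniform-random background ions added to
#'   each spectrum.
#' @param below_threshold_fraction Fraction (of signature + shared ion count)
#'   of extra ions per spectrum given intensities below 5000 counts.
#' @param precursor_range Precursor m/z range (Th).
#' @param rt_spacing Retention-time spacing between consecutive spectra (s).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters.
#' @param seed Integer seed; fixed seed gives byte-identical output files.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_clusters = 3,
                           features_per_cluster = 5,
                           signature_ions_per_cluster = 6,
                           shared_ions = 0,
                           mz_jitter_sd = 0.0001,
                           background_ions_per_spectrum = 3,
                           below_threshold_fraction = 0.2,
                           precursor_range = c(400, 600),
                           rt_spacing = 30,
                           intensity_meanlog = log(20000),
                           intensity_sdlog = 1,
                           seed = 1L) {
  if (n_clusters < 1 || features_per_cluster < 1) {
    abort("Need at least one cluster and one feature per cluster.",
          class = "msdendro_config_error")
  }
  if (signature_ions_per_cluster < 1) {
    abort("Need at least one signature ion per cluster.",
          class = "msdendro_config_error")
  }
  structure(
    list(
      n_clusters = as.integer(n_clusters),
      features_per_cluster = as.integer(features_per_cluster),
      signature_ions_per_cluster = as.integer(signature_ions_per_cluster),
      shared_ions = as.integer(shared_ions),
      mz_jitter_sd = mz_jitter_sd,
      background_ions_per_spectrum = as.integer(background_ions_per_spectrum),
      below_threshold_fraction = below_threshold_fraction,
      precursor_range = precursor_range,
      rt_spacing = rt_spacing,
      intensity_meanlog = intensity_meanlog,
      intensity_sdlog = intensity_sdlog,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# log-normal intensities resampled to stay at/above `floor_val`
rlnorm_at_least <- function(n, meanlog, sdlog, floor_val) {
  x <- rlnorm(n, meanlog, sdlog)
  for (it in seq_len(50)) {
    low <- x < floor_val
    if (!any(low)) break
    x[low] <- rlnorm(sum(low), meanlog, sdlog)
  }
  pmax(x, floor_val)
}

#' Generate a synthetic dataset with planted cluster structure
#'
#' Realises a [synthetic_spec()] as in-memory tables and (optionally) as
#' standard files: an MGF of MS/MS spectra, an underscore-encoded feature
#' list (retention times in minutes), and a tab-separated ground-truth label
#' file. Feature precursor m/z and retention time match the corresponding
#' spectrum within the default alignment tolerances (m/z offset clamped to
#' 0.004 Th; retention time exact). Signature ion positions are laid out on a
#' spaced grid well separated relative to the binning gap threshold.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, `spectra.mgf`, `features.txt`
#'   and `labels.tsv` are written there.
#' @return A `msdendro_dataset` list: `spectra`, `features`, `labels`
#'   (tibbles), `signature_ions` (tibble of cluster, mz), `shared_ions`
#'   (numeric vector), and `paths` (when written).
#' @examples
#' sim <- generate_dataset(synthetic_spec(seed = 42))
#' sim$labels
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)

  n_sig_total <- spec$n_clusters * spec$signature_ions_per_cluster
  # ion positions on a 0.07 Th grid between 100 and 380 Th, shuffled: distinct
  # planted ions can never fall within one bin of each other
  grid <- seq(100, 380, by = 0.07)
  pool <- sample(grid, n_sig_total + spec$shared_ions)
  signature_ions <- tibble(
    cluster = rep(seq_len(spec$n_clusters), each = spec$signature_ions_per_cluster),
    mz = pool[seq_len(n_sig_total)]
  )
  shared_ions <- if (spec$shared_ions > 0) pool[n_sig_total + seq_len(spec$shared_ions)] else numeric()

  n_feat <- spec$n_clusters * spec$features_per_cluster
  cluster_of <- rep(seq_len(spec$n_clusters), each = spec$features_per_cluster)
  precursor <- runif(n_feat, spec$precursor_range[1], spec$precursor_range[2])
  rt <- 60 + seq_len(n_feat) * spec$rt_spacing

  n_low <- round(spec$below_threshold_fraction *
                   (spec$signature_ions_per_cluster + spec$shared_ions))

  spectra <- purrr::map_dfr(seq_len(n_feat), function(i) {
    planted <- c(signature_ions$mz[signature_ions$cluster == cluster_of[i]],
                 shared_ions)
    planted_mz <- planted + rnorm(length(planted), 0, spec$mz_jitter_sd)
    planted_int <- rlnorm_at_least(length(planted), spec$intensity_meanlog,
                                   spec$intensity_sdlog, 5000)
    bg_mz <- runif(spec$background_ions_per_spectrum, 100, 380)
    bg_int <- rlnorm(spec$background_ions_per_spectrum,
                     spec$intensity_meanlog, spec$intensity_sdlog)
    low_mz <- runif(n_low, 100, 380)
    low_int <- runif(n_low, 100, 4999)
    ions <- tibble(mz = c(planted_mz, bg_mz, low_mz),
                   intensity = c(planted_int, bg_int, low_int))
    ions <- ions[order(ions$mz), , drop = FALSE]
    tibble(
      scan_id = sprintf("scan_%03d", i),
      scan_index = i,
      precursor_mz = precursor[i],
      rt = rt[i],
      polarity = "+",
      n_ions = nrow(ions),
      ions = list(ions),
      neutral_loss = FALSE
    )
  })

  mz_offset <- pmin(pmax(rnorm(n_feat, 0, 0.001), -0.004), 0.004)
  feat_mz <- precursor + mz_offset
  features <- tibble(
    feature_id = sprintf("sim_sample_%.12f_%.6f", feat_mz, rt / 60),
    mz = feat_mz,
    rt = rt
  )
  labels <- tibble(feature_id = features$feature_id, cluster = cluster_of)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      mgf = file.path(dir, "spectra.mgf"),
      features = file.path(dir, "features.txt"),
      labels = file.path(dir, "labels.tsv")
    )
    write_mgf(spectra, paths$mgf)
    write_feature_list(features, paths$features, encoding = "underscore")
    readr::write_tsv(labels, paths$labels)
  }

  structure(
    list(spectra = spectra, features = features, labels = labels,
         signature_ions = signature_ions, shared_ions = shared_ions,
         paths = paths),
    class = "msdendro_dataset"
  )
}

#' Shift all spectrum retention times by a constant
#'
#' Utility for probing the alignment retention-time tolerance boundary: with
#' features generated at the spectra's exact retention times, an offset at or
#' below the tolerance keeps every feature aligned, while a larger offset
#' unaligns all of them.
#'
#' @param dataset A `msdendro_dataset` from [generate_dataset()].
#' @param rt_offset Shift in seconds (may be negative; 0 is the identity).
#' @return The dataset with shifted in-memory spectra (files, if any, are not
#'   rewritten).
#' @export
perturb_alignment <- function(dataset, rt_offset) {
  stopifnot(inherits(dataset, "msdendro_dataset"))
  dataset$spectra$rt <- dataset$spectra$rt + rt_offset
  dataset
}
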