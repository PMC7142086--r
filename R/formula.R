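# Monoisotopic masses (u) and charge-carrier masses used throughout.
# All adduct arithmetic flows from this one table.
.atom_mass <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462)
.electron_mass <- 0.00054858
.proton_mass <- 1.00727646        # H+ (H minus one electron)
.nh4_mass <- 18.03382555          # NH4+ cation
.acn_mass <- 41.02654910          # CH3CN neutral

#' Parse an elemental formula string
#'
#' Accepts formulas over C, H, N, O (e.g. `"C8H9O"`, `"C28H36O10"`).
#'
#' @param formula A single formula string.
#' @return A named integer vector with entries `C`, `H`, `N`, `O`.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)
  parts <- regmatches(formula, tokens)[[1]]
  if (paste(parts, collapse = "") != formula || length(parts) == 0L) {
    abort(sprintf("Cannot parse formula '%s'.", formula),
          class = "msdendro_validation_error")
  }
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L)
  for (p in parts) {
    elem <- sub("[0-9]*$", "", p)
    if (!elem %in% names(counts)) {
      abort(sprintf("Unsupported element '%s' in formula '%s' (C/H/N/O only).",
                    elem, formula), class = "msdendro_validation_error")
    }
    num <- sub("^[A-Za-z]+", "", p)
    counts[elem] <- counts[elem] + if (nzchar(num)) as.integer(num) else 1L
  }
  counts
}

format_formula <- function(c_n, h_n, n_n, o_n) {
  part <- function(sym, k) {
    if (k == 0L) "" else if (k == 1L) sym else paste0(sym, k)
  }
  paste0(part("C", c_n), part("H", h_n), part("N", n_n), part("O", o_n))
}

as_counts <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L)
  counts[names(composition)] <- as.integer(composition)
  if (sum(counts) < 1L) {
    abort("Composition must contain at least one atom.",
          class = "msdendro_validation_error")
  }
  if (any(counts < 0L)) {
    abort("Atom counts must be non-negative.",
          class = "msdendro_validation_error")
  }
  counts
}

#' Monoisotopic mass of a composition
#'
#' Sum of standard monoisotopic atomic masses (C = 12 exactly,
#' H = 1.00782503, N = 14.00307401, O = 15.99491462).
#'
#' @param composition A formula string (`"C28H36O10"`) or named numeric vector
#'   of C/H/N/O counts.
#' @return Mass in Dalton.
#' @examples
#' monoisotopic_mass("H2O")        # 18.0105646
#' monoisotopic_mass("C28H36O10")  # 532.2308471
#' @export
monoisotopic_mass <- function(composition) {
  counts <- as_counts(composition)
  sum(counts * .atom_mass[names(counts)])
}

#' m/z of a singly charged even-electron cation
#'
#' Interprets the composition as the intact ion's composition (charge +1) and
#' subtracts one electron mass from the monoisotopic mass. This is the ion
#' mass convention under which fragment formulas such as C8H9 reproduce
#' observed fragment m/z values; neutral masses do not.
#'
#' @param composition Formula string or named counts of the *ion*.
#' @return Theoretical m/z in Thomson.
#' @examples
#' cation_mz("C8H9")   # 105.0698767
#' cation_mz("C8H9O")  # 121.0647913
#' @export
cation_mz <- function(composition) {
  monoisotopic_mass(composition) - .electron_mass
}

#' Relative mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`. Positive when the observed
#' mass is high. Report tables round to 1 decimal.
#'
#' @param observed Observed m/z (Th).
#' @param theoretical Theoretical m/z (Th), > 0.
#' @return Signed ppm error (full precision).
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Enumerate elemental compositions for an accurate ion mass
#'
#' Exhaustively searches C/H/O (or C/H/N/O) compositions whose singly charged
#' even-electron cation m/z lies within `tolerance_ppm` of the observed m/z,
#' and whose ring-plus-double-bond equivalents (RDBE = C - H/2 + N/2 + 1,
#' computed on the ion composition) fall inside `rdbe_range`. Candidates are
#' returned sorted by absolute ppm error. Default element bounds are C 1-60,
#' H 0-120, N 0-3, O 0-30 with RDBE in \[-0.5, 40\] and no hydrogen-parity
#' filter.
#'
#' @param observed_mz Observed ion m/z (Th).
#' @param tolerance_ppm Search half-window in ppm (> 0); 10 ppm is a typical
#'   Orbitrap worst-case calibration bound.
#' @param mode `"CHO"` (default; N fixed at 0) or `"CHNO"`.
#' @param max_c,max_h,max_n,max_o Per-element upper bounds.
#' @param rdbe_range Length-2 numeric; inclusive RDBE window.
#' @return A tibble sorted by `abs(ppm_error)` with columns `formula`, `c`,
#'   `h`, `n`, `o`, `theoretical_mz`, `ppm_error`, `rdbe`. The number of
#'   compositions in the searched grid is recorded in the `n_searched`
#'   attribute. An empty tibble (zero candidates) is a valid result.
#' @examples
#' enumerate_formulas(105.0701)  # unique hit: C8H9, +2.1 ppm
#' @export
enumerate_formulas <- function(observed_mz, tolerance_ppm = 10,
                               mode = c("CHO", "CHNO"),
                               max_c = 60, max_h = 120, max_n = 3, max_o = 30,
                               rdbe_range = c(-0.5, 40)) {
  mode <- match.arg(mode)
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    abort("`tolerance_ppm` must be positive.", class = "msdendro_config_error")
  }
  if (max_c > 200 || max_h > 400 || max_n > 10 || max_o > 100) {
    abort("Element bounds exceed the configured search ceiling.",
          class = "msdendro_config_error")
  }
  if (mode == "CHO") max_n <- 0
  mz_lo <- observed_mz * (1 - tolerance_ppm * 1e-6)
  mz_hi <- observed_mz * (1 + tolerance_ppm * 1e-6)

  grid <- expand.grid(c = seq_len(max_c), n = 0:max_n, o = 0:max_o,
                      KEEP.OUT.ATTRS = FALSE)
  base <- grid$c * .atom_mass[["C"]] + grid$n * .atom_mass[["N"]] +
    grid$o * .atom_mass[["O"]] - .electron_mass
  # solve the admissible H count window for each (C, N, O) cell
  h_lo <- ceiling((mz_lo - base) / .atom_mass[["H"]] - 1e-9)
  h_hi <- floor((mz_hi - base) / .atom_mass[["H"]] + 1e-9)
  h_lo <- pmax(h_lo, 0)
  h_hi <- pmin(h_hi, max_h)
  keep <- which(h_hi >= h_lo)

  rows <- purrr::map_dfr(keep, function(k) {
    h <- seq(h_lo[k], h_hi[k])
    tibble(c = grid$c[k], h = h, n = grid$n[k], o = grid$o[k],
           theoretical_mz = base[k] + h * .atom_mass[["H"]])
  })
  if (nrow(rows) > 0L) {
    rows <- rows |>
      dplyr::mutate(
        ppm_error = ppm_error(observed_mz, .data$theoretical_mz),
        rdbe = .data$c - .data$h / 2 + .data$n / 2 + 1
      ) |>
      dplyr::filter(abs(.data$ppm_error) <= tolerance_ppm,
                    .data$rdbe >= rdbe_range[1], .data$rdbe <= rdbe_range[2]) |>
      dplyr::mutate(formula = purrr::pmap_chr(
        list(.data$c, .data$h, .data$n, .data$o), format_formula)) |>
      dplyr::select("formula", "c", "h", "n", "o", "theoretical_mz",
                    "ppm_error", "rdbe") |>
      dplyr::arrange(abs(.data$ppm_error))
  } else {
    rows <- tibble(formula = character(), c = integer(), h = integer(),
                   n = integer(), o = integer(), theoretical_mz = numeric(),
                   ppm_error = numeric(), rdbe = numeric())
  }
  attr(rows, "n_searched") <- nrow(grid) * (max_h + 1)
  rows
}

.adduct_table <- tibble::tibble(
  adduct = c("M+H", "M+NH4", "M+ACN+H", "2M+H", "2M+NH4", "3M+NH4"),
  k = c(1L, 1L, 1L, 2L, 2L, 3L),
  added_mass = c(.proton_mass, .nh4_mass, .acn_mass + .proton_mass,
                 .proton_mass, .nh4_mass, .nh4_mass)
)

#' Supported adduct and aggregate-ion types
#'
#' @return A tibble with `adduct` name, the count `k` of neutral molecules in
#'   the aggregate, and the added (electron-corrected) charge-carrier mass.
#' @export
adduct_table <- function() .adduct_table

#' Theoretical m/z of an adduct or aggregate ion
#'
#' `k * M + carrier`, where `M` is the monoisotopic mass of the neutral
#' molecule and the carrier mass is already electron-corrected: M+H adds a
#' proton (1.00727646), M+NH4 adds NH4+ (18.03382555), M+ACN+H adds
#' acetonitrile plus a proton (42.03382555). `2M`/`3M` forms multiply the
#' neutral mass. Adduct names are normalised for spacing ("2 M + NH4" works).
#'
#' @param neutral Formula string or named counts of the neutral molecule M.
#' @param adduct Adduct name, one of `adduct_table()$adduct`.
#' @return Theoretical singly charged m/z (Th).
#' @examples
#' adduct_mz("C28H36O10", "M+H")     # 533.2381235
#' adduct_mz("C28H36O10", "2M+NH4")  # 1082.4955202
#' @export
adduct_mz <- function(neutral, adduct) {
  key <- gsub(" ", "", adduct, fixed = TRUE)
  row <- .adduct_table[.adduct_table$adduct == key, ]
  if (nrow(row) != 1L) {
    abort(sprintf("Unknown adduct '%s'. Supported: %s", adduct,
                  paste(.adduct_table$adduct, collapse = ", ")),
          class = "msdendro_validation_error")
  }
  row$k * monoisotopic_mass(neutral) + row$added_mass
}

#' Annotate features with formula/adduct assignments
#'
#' Joins a table of proposed (formula, adduct) assignments onto a feature list
#' and reports, per feature, the theoretical adduct m/z, the signed ppm error
#' against the observed precursor m/z, and a pass flag at `ppm_gate`. Features
#' without a formula assignment are kept as flagged rows (`pass = NA`), not
#' dropped.
#'
#' @param features Feature tibble (`feature_id`, `mz`, ...).
#' @param assignments Tibble with `feature_id`, `formula`, `adduct` (formula
#'   and/or adduct may be `NA`).
#' @param ppm_gate Absolute ppm threshold for the pass flag (default 2).
#' @return A tibble with `feature_id`, `mz`, `formula`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, `pass`.
#' @export
annotate_features <- function(features, assignments, ppm_gate = 2) {
  out <- dplyr::inner_join(
    dplyr::select(features, "feature_id", "mz"),
    dplyr::select(assignments, "feature_id", "formula", "adduct"),
    by = "feature_id"
  )
  out$theoretical_mz <- NA_real_
  has <- !is.na(out$formula) & !is.na(out$adduct)
  out$theoretical_mz[has] <- purrr::map2_dbl(
    out$formula[has], out$adduct[has], adduct_mz)
  out$ppm_error <- NA_real_
  out$ppm_error[has] <- ppm_error(out$mz[has], out$theoretical_mz[has])
  out$pass <- ifelse(has, abs(out$ppm_error) <= ppm_gate, NA)
  out
}
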