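test_that("monoisotopic masses sum standard atomic masses", {
  expect_equal(monoisotopic_mass("C"), 12)
  expect_equal(monoisotopic_mass("H2O"), 18.0105646, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("C28H36O10"), 532.2308471, tolerance = 1e-7)
  expect_error(monoisotopic_mass("C8H9S"), class = "msdendro_validation_error")
})

test_that("cation m/z subtracts exactly one electron mass", {
  expect_equal(cation_mz("C8H9"), 105.0698767, tolerance = 1e-7)
  expect_equal(cation_mz("C8H9O"), 121.0647913, tolerance = 1e-7)
  set.seed(2)
  for (rep in 1:10) {
    counts <- c(C = sample(1:30, 1), H = sample(0:60, 1),
                N = sample(0:3, 1), O = sample(0:10, 1))
    expect_equal(monoisotopic_mass(counts) - cation_mz(counts), 0.00054858)
  }
  expect_error(cation_mz(c(C = 0, H = 0, N = 0, O = 0)),
               class = "msdendro_validation_error")
})

test_that("ppm errors follow the relative-deviation definition", {
  expect_equal(round(ppm_error(105.0701, cation_mz("C8H9")), 1), 2.1)
  expect_equal(ppm_error(100, 100), 0)
  expect_equal(ppm_error(100.001, 100.000), 10, tolerance = 1e-9)
})

test_that("formula enumeration is exhaustive within bounds (brute-force identity)", {
  brute_force <- function(observed_mz, tol, max_c, max_h, max_o, rdbe_range) {
    hits <- list()
    for (ci in 1:max_c) for (hi in 0:max_h) for (oi in 0:max_o) {
      mz <- ci * 12 + hi * 1.00782503 + oi * 15.99491462 - 0.00054858
      ppm <- (observed_mz - mz) / mz * 1e6
      rdbe <- ci - hi / 2 + 1
      if (abs(ppm) <= tol && rdbe >= rdbe_range[1] && rdbe <= rdbe_range[2]) {
        hits[[length(hits) + 1]] <- data.frame(c = ci, h = hi, o = oi)
      }
    }
    do.call(rbind, hits)
  }
  for (mz in c(105.0701, 151.0392, 413.1965, 532.5)) {
    mine <- enumerate_formulas(mz, 10, mode = "CHO",
                               max_c = 40, max_h = 60, max_o = 12)
    oracle <- brute_force(mz, 10, 40, 60, 12, c(-0.5, 40))
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0L)
    } else {
      expect_equal(nrow(mine), nrow(oracle))
      expect_setequal(paste(mine$c, mine$h, mine$o),
                      paste(oracle$c, oracle$h, oracle$o))
    }
  }
})

test_that("the CHO search ranks candidates by absolute ppm error", {
  res <- enumerate_formulas(121.0648, 10, mode = "CHO")
  expect_equal(res$formula[1], "C8H9O")
  expect_true(all(diff(abs(res$ppm_error)) >= 0))
  expect_true(all(abs(res$ppm_error) <= 10))
  # a pure carbon cation is found at ppm 0
  res_c <- enumerate_formulas(12 - 0.00054858, 10, mode = "CHO")
  expect_equal(res_c$formula[1], "C")
  expect_equal(res_c$ppm_error[1], 0, tolerance = 1e-6)
})

test_that("CHNO mode admits nitrogen and CHO mode does not", {
  # protonated unknown 1 cation: C24H38NO6+
  mz <- adduct_mz("C24H37NO6", "M+H")
  chno <- enumerate_formulas(mz, 2, mode = "CHNO")
  expect_true("C24H38NO6" %in% chno$formula)
  expect_true(all(chno$n <= 3))
  # no C/H/O-only composition sits within 2 ppm of this nitrogen-bearing mass
  expect_equal(nrow(enumerate_formulas(mz, 2, mode = "CHO")), 0L)
  expect_error(enumerate_formulas(100, 10, max_c = 500),
               class = "msdendro_config_error")
})

test_that("adduct masses follow the charge-carrier table", {
  expect_equal(adduct_mz("C28H36O10", "M+H"), 533.2381235, tolerance = 1e-6)
  expect_equal(adduct_mz("C24H37NO6", "M+NH4"), 453.2959132, tolerance = 1e-6)
  expect_equal(adduct_mz("C28H36O10", "2M+NH4"), 1082.4955197, tolerance = 1e-6)
  expect_equal(adduct_mz("C28H36O10", "2 M + NH4"),
               adduct_mz("C28H36O10", "2M+NH4"))  # spacing normalised
  expect_error(adduct_mz("C28H36O10", "M+K"), class = "msdendro_validation_error")
  # M+H minus the neutral mass is the proton mass, for any neutral
  for (f in c("C24H32O8", "C30H40O10", "C24H37NO7")) {
    expect_equal(adduct_mz(f, "M+H") - monoisotopic_mass(f), 1.00727646)
  }
})

test_that("feature annotation reports ppm errors and flags failures", {
  feats <- tibble::tibble(
    feature_id = c("f21", "f21bad", "fnone"),
    mz = c(533.237884521484, 533.237884521484, 400),
    rt = c(1, 1, 1)
  )
  asg <- tibble::tibble(
    feature_id = c("f21", "f21bad", "fnone"),
    formula = c("C28H36O10", "C10H10O", NA),
    adduct = c("M+H", "M+H", NA)
  )
  ann <- annotate_features(feats, asg, ppm_gate = 2)
  expect_true(ann$pass[ann$feature_id == "f21"])
  expect_false(ann$pass[ann$feature_id == "f21bad"])
  expect_true(abs(ann$ppm_error[ann$feature_id == "f21bad"]) > 1e4)
  expect_true(is.na(ann$pass[ann$feature_id == "fnone"]))
  # empty assignment list -> empty report
  expect_equal(nrow(annotate_features(feats, asg[0, ])), 0L)
})
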