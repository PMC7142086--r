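test_that("the closest-RT spectrum wins within tolerances", {
  feats <- tibble::tibble(feature_id = "F1", mz = 533.2379, rt = 907.4)
  sp <- make_spectra(
    make_spectrum("far", 533.2381, 903.0, 100, 1e4),
    make_spectrum("near", 533.2380, 905.0, 100, 1e4)
  )
  al <- align_features(feats, sp)
  expect_equal(al$scan_id, "near")
  expect_equal(al$delta_rt, -2.4)
})

test_that("a feature beyond the m/z tolerance stays unaligned", {
  feats <- tibble::tibble(feature_id = "F1", mz = 533.2379, rt = 907.4)
  sp <- make_spectrum("s", 533.2450, 907.4, 100, 1e4)
  al <- align_features(feats, sp)
  expect_true(is.na(al$scan_id))
})

test_that("RT ties break on smaller |dm/z|, then scan order", {
  feats <- tibble::tibble(feature_id = "F1", mz = 500, rt = 100)
  sp <- make_spectra(
    make_spectrum("wide", 500.004, 102, 100, 1e4),
    make_spectrum("tight", 500.001, 98, 100, 1e4)
  )
  expect_equal(align_features(feats, sp)$scan_id, "tight")

  sp2 <- make_spectra(
    make_spectrum("first", 500.002, 102, 100, 1e4),
    make_spectrum("second", 500.002, 98, 100, 1e4)
  )
  expect_equal(align_features(feats, sp2)$scan_id, "first")
})

test_that("alignment winners are invariant to spectrum input order", {
  sim <- generate_dataset(synthetic_spec(seed = 11))
  cfg <- dendro_config()
  base <- align_features(sim$features, sim$spectra, cfg)
  set.seed(3)
  shuffled <- sim$spectra[sample(nrow(sim$spectra)), ]
  again <- align_features(sim$features, shuffled, cfg)
  expect_equal(again$scan_id, base$scan_id)
  # stored deltas always satisfy the tolerance bounds
  ok <- !is.na(base$scan_id)
  expect_true(all(abs(base$delta_mz[ok]) <= cfg$mz_tol))
  expect_true(all(abs(base$delta_rt[ok]) <= cfg$rt_tol))
})

test_that("an empty spectrum table warns and leaves every feature unaligned", {
  feats <- tibble::tibble(feature_id = c("a", "b"), mz = c(1, 2), rt = c(1, 2))
  empty <- random_spectra(1)[0, ]
  expect_warning(al <- align_features(feats, empty), "unaligned")
  expect_true(all(is.na(al$scan_id)))
})

test_that("absolute intensity filtering keeps ions at or above the floor", {
  sp <- make_spectrum("s", 500, 10, c(100, 101, 102), c(6000, 4999, 5000))
  out <- filter_ions(sp, dendro_config(min_intensity_abs = 5000))
  expect_equal(out$ions[[1]]$intensity, c(6000, 5000))
  # idempotent
  expect_equal(filter_ions(out, dendro_config(min_intensity_abs = 5000)), out)
})

test_that("relative filtering is a fraction of the base peak", {
  sp <- make_spectrum("s", 500, 10, c(100, 101, 102), c(10000, 400, 900))
  cfg <- dendro_config(min_intensity_abs = NULL, min_intensity_rel = 0.05)
  out <- filter_ions(sp, cfg)
  expect_equal(sort(out$ions[[1]]$intensity), c(900, 10000))
})

test_that("a spectrum can lose every ion to the filter", {
  sp <- make_spectrum("s", 500, 10, c(100, 101), c(10, 20))
  out <- filter_ions(sp, dendro_config())
  expect_equal(out$n_ions, 0L)
})

test_that("only one intensity filter can be configured per run", {
  expect_error(dendro_config(min_intensity_abs = 5000, min_intensity_rel = 0.1),
               class = "msdendro_config_error")
  expect_error(dendro_config(min_intensity_abs = NULL, min_intensity_rel = 1.5),
               class = "msdendro_config_error")
})

test_that("neutral-loss conversion subtracts from the precursor and drops non-positive losses", {
  sp <- make_spectrum("s", 500.000, 10, c(105.070, 121.065, 501.0),
                      c(1, 2, 3))
  out <- to_neutral_loss(sp)
  expect_equal(out$ions[[1]]$mz, c(378.935, 394.930))
  expect_equal(out$ions[[1]]$intensity, c(2, 1))  # intensities travel with ions
  expect_true(out$neutral_loss)
  # a second application is rejected
  expect_error(to_neutral_loss(out), class = "msdendro_validation_error")
})

test_that("neutral-loss conversion of an ion-free spectrum is a no-op", {
  sp <- make_spectrum("s", 500, 10, numeric(), numeric())
  expect_equal(to_neutral_loss(sp)$n_ions, 0L)
})
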