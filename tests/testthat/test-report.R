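# small hand-built clustering: 3 features in cluster 1, 2 in cluster 2
toy_report_input <- function() {
  ions <- tibble::tibble(
    feature_id = c("f1", "f2", "f3", "f1", "f4", "f5", "f4"),
    mz = c(135.0434, 135.0443, 135.0448, 200.0, 300.0, 300.0001, 310.0)
  )
  # eps 0.001 so the three 135.04xx masses chain into one bin
  bins <- dynamic_bin(ions$mz, 0.001)
  binned <- assign_bins(ions, bins)
  occ <- build_occurrence_matrix(binned, bins)
  clusters <- tibble::tibble(
    feature_id = c("f1", "f2", "f3", "f4", "f5"),
    cluster = c(1L, 1L, 1L, 2L, 2L)
  )
  list(clusters = clusters, occ = occ, binned = binned, bins = bins)
}

test_that("cluster-ion records report percent present and raw-mass statistics", {
  x <- toy_report_input()
  rec <- cluster_ion_table(x$clusters, x$occ, x$binned, x$bins)
  r135 <- rec[rec$cluster == 1 & abs(rec$representative_mz - 135.044) < 0.01, ]
  expect_equal(r135$percent_present, 100)
  expect_equal(r135$mz_min, 135.0434)
  expect_equal(r135$mz_max, 135.0448)
  expect_equal(r135$mz_average, mean(c(135.0434, 135.0443, 135.0448)))
  # bin present in 1 of 3 cluster-1 features
  r200 <- rec[rec$cluster == 1 & rec$mz_min == 200, ]
  expect_equal(r200$percent_present, 100 / 3)
  # overall incidence counts features across all clusters
  expect_equal(r135$incidence_count, 3L)
  expect_equal(r135$incidence_percent, 60)
})

test_that("percent_present recomputes exactly from the occurrence matrix", {
  x <- toy_report_input()
  rec <- cluster_ion_table(x$clusters, x$occ, x$binned, x$bins)
  for (k in seq_len(nrow(rec))) {
    members <- x$clusters$feature_id[x$clusters$cluster == rec$cluster[k]]
    direct <- 100 * sum(x$occ[members, as.character(rec$bin_id[k])]) /
      length(members)
    expect_equal(rec$percent_present[k], direct)
  }
})

test_that("mz statistics are invariant to feature ordering within a cluster", {
  x <- toy_report_input()
  rec1 <- cluster_ion_table(x$clusters, x$occ, x$binned, x$bins)
  perm <- x$clusters[c(3, 1, 5, 2, 4), ]
  binned_perm <- x$binned[sample(nrow(x$binned)), ]
  rec2 <- cluster_ion_table(perm, x$occ, binned_perm, x$bins)
  expect_equal(rec1, rec2)
})

test_that("a single-feature cluster has all its bins at 100%", {
  ions <- tibble::tibble(feature_id = c("a", "a", "b"), mz = c(100, 110, 100.0001))
  bins <- dynamic_bin(ions$mz, 0.0005)
  binned <- assign_bins(ions, bins)
  occ <- build_occurrence_matrix(binned, bins)
  clusters <- tibble::tibble(feature_id = c("a", "b"), cluster = c(1L, 2L))
  rec <- cluster_ion_table(clusters, occ, binned, bins)
  expect_true(all(rec$percent_present == 100))
})

test_that("diagnostic ions separate shared from cluster-unique signatures", {
  ions <- tibble::tibble(
    feature_id = rep(c("a1", "a2", "b1", "b2"), times = c(3, 3, 2, 2)),
    mz = c(100, 110, 120,   100.0001, 110.0001, 120.0001,  # cluster 1: X Y Z
           100.0002, 110.0002, 100.0003, 110.0003)         # cluster 2: X Y
  )
  bins <- dynamic_bin(ions$mz, 0.0005)
  binned <- assign_bins(ions, bins)
  occ <- build_occurrence_matrix(binned, bins)
  clusters <- tibble::tibble(feature_id = c("a1", "a2", "b1", "b2"),
                             cluster = c(1L, 1L, 2L, 2L))
  rec <- cluster_ion_table(clusters, occ, binned, bins)

  shared <- diagnostic_ions(rec, clusters = c(1, 2), require_percent = 100)
  expect_equal(round(shared$representative_mz), c(100, 110))
  unique_a <- diagnostic_ions(rec, clusters = c(1, 2), require_percent = 100,
                              unique_to = 1)
  expect_equal(round(unique_a$representative_mz), 120)
  expect_error(diagnostic_ions(rec, clusters = 99),
               class = "msdendro_validation_error")
})

test_that("a cluster below the percent requirement is excluded", {
  ions <- tibble::tibble(
    feature_id = c("a1", "a2", "a3", "b1"),
    mz = c(100, 100.0001, 200, 100.0002)
  )
  bins <- dynamic_bin(ions$mz, 0.0005)
  binned <- assign_bins(ions, bins)
  occ <- build_occurrence_matrix(binned, bins)
  clusters <- tibble::tibble(feature_id = c("a1", "a2", "a3", "b1"),
                             cluster = c(1L, 1L, 1L, 2L))
  rec <- cluster_ion_table(clusters, occ, binned, bins)
  # the 100 Th ion is in 2/3 of cluster 1 -> excluded at require 100
  shared <- diagnostic_ions(rec, clusters = c(1, 2), require_percent = 100)
  expect_equal(nrow(shared), 0L)
})

test_that("histogram series are ascending in m/z and recount total presences", {
  x <- toy_report_input()
  rec <- cluster_ion_table(x$clusters, x$occ, x$binned, x$bins)
  h <- histogram_data(rec, 1)
  expect_true(all(diff(h$representative_mz) > 0))
  expect_true(all(h$percent_present > 0 & h$percent_present <= 100))
  n_cluster1 <- sum(x$clusters$cluster == 1)
  expect_equal(sum(h$percent_present * n_cluster1 / 100),
               sum(x$occ[x$clusters$feature_id[x$clusters$cluster == 1], ]))
  expect_error(histogram_data(rec, 42), class = "msdendro_validation_error")
})

test_that("per-cluster histogram files are written with rounded percentages", {
  x <- toy_report_input()
  rec <- cluster_ion_table(x$clusters, x$occ, x$binned, x$bins)
  dir <- withr::local_tempdir()
  paths <- write_ion_histograms(rec, dir)
  expect_true(file.exists(file.path(dir, "cluster_1_ions.tsv")))
  back <- readr::read_tsv(file.path(dir, "cluster_1_ions.tsv"),
                          show_col_types = FALSE)
  expect_equal(back$percent_present, round(histogram_data(rec, 1)$percent_present))
})
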