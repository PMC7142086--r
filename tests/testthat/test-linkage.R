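random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- paste0("L", seq_len(n))
  d
}

test_that("two leaves merge once at their distance; one leaf gives an empty merge list", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- complete_linkage(d)
  expect_equal(nrow(tree$merge), 1L)
  expect_equal(tree$height, 0.3)
  expect_equal(sort(tree$merge[1, ]), c(-2L, -1L))

  single <- complete_linkage(matrix(0, 1, 1, dimnames = list("A", "A")))
  expect_equal(nrow(single$merge), 0L)
  expect_equal(single$order, 1L)
})

test_that("merge heights are non-decreasing and dominate input distances", {
  set.seed(17)
  for (rep in 1:10) {
    d <- random_distance_matrix(10)
    tree <- complete_linkage(d)
    expect_true(all(diff(tree$height) >= -1e-12))
    coph <- as.matrix(cophenetic(tree))[rownames(d), colnames(d)]
    expect_true(all(coph - d >= -1e-12))  # max-linkage dominance
  }
})

test_that("the tree matches stats::hclust complete linkage as a cophenetic matrix", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    d <- stats::as.dist(random_distance_matrix(n))
    mine <- cophenetic(complete_linkage(d))
    reference <- cophenetic(stats::hclust(d, method = "complete"))
    expect_equal(as.matrix(mine)[paste0("L", 1:n), paste0("L", 1:n)],
                 as.matrix(reference)[paste0("L", 1:n), paste0("L", 1:n)],
                 tolerance = 1e-12)
  }
})

test_that("exact ties are broken deterministically by smallest node pair", {
  # four equidistant leaves: every pairwise distance ties at 0.2
  d <- matrix(0.2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tree <- complete_linkage(d)
  expect_equal(tree$merge[1, ], c(-1L, -2L))  # A and B first
  expect_equal(tree$height, rep(0.2, 3))
})

test_that("threshold cuts are inclusive and labelled by leftmost leaf", {
  # merges: (A,B)@0.1, (C,D)@0.2, ((AB),(CD))@0.9
  d <- matrix(0.9, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["C", "D"] <- d["D", "C"] <- 0.2
  diag(d) <- 0
  tree <- complete_linkage(d)
  cut <- cut_clusters(tree, 0.7)
  expect_equal(max(cut$cluster), 2L)
  expect_equal(cut$cluster[cut$feature_id %in% c("A", "B")][1],
               cut$cluster[cut$feature_id == "B"])
  expect_true(cut$cluster[cut$feature_id == "A"] !=
                cut$cluster[cut$feature_id == "C"])
  # inclusive at the exact merge height
  expect_equal(max(cut_clusters(tree, 0.2)$cluster), 2L)
  expect_equal(max(cut_clusters(tree, 0.9)$cluster), 1L)

  # boundary thresholds
  expect_equal(max(cut_clusters(tree, 0)$cluster), 4L)
  expect_equal(max(cut_clusters(tree, 1)$cluster), 1L)
  # labels follow dendrogram leaf order, starting at 1 on the leftmost leaf
  first_leaf <- tree$labels[tree$order[1]]
  expect_equal(cut$cluster[cut$feature_id == first_leaf], 1L)
})

test_that("cut partitions are invariant to leaf permutation", {
  set.seed(53)
  for (rep in 1:10) {
    d <- random_distance_matrix(9)
    t1 <- cut_clusters(complete_linkage(d), 0.6)
    perm <- sample(9)
    dp <- d[perm, perm]
    t2 <- cut_clusters(complete_linkage(dp), 0.6)
    joined <- merge(t1, t2, by = "feature_id")
    expect_true(partitions_equal(joined$cluster.x, joined$cluster.y))
  }
})

test_that("invalid distance matrices are rejected", {
  bad <- matrix(c(0, 0.5, 0.4, 0), 2)
  expect_error(complete_linkage(bad), class = "msdendro_validation_error")
  expect_error(complete_linkage(matrix(c(0, 2, 2, 0), 2)),
               class = "msdendro_validation_error")
})
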