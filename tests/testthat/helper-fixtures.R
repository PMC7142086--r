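# In-code fixtures shared across test files.

make_spectrum <- function(scan_id, precursor_mz, rt, mz, intensity,
                          scan_index = 1L, polarity = "+") {
  ord <- order(mz)
  tibble::tibble(
    scan_id = scan_id, scan_index = scan_index, precursor_mz = precursor_mz,
    rt = rt, polarity = polarity, n_ions = length(mz),
    ions = list(tibble::tibble(mz = mz[ord], intensity = intensity[ord])),
    neutral_loss = FALSE
  )
}

make_spectra <- function(...) {
  out <- dplyr::bind_rows(...)
  out$scan_index <- seq_len(nrow(out))
  out
}

random_spectra <- function(n, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    k <- sample(1:8, 1)
    make_spectrum(sprintf("s%02d", i), runif(1, 100, 900), runif(1, 0, 1200),
                  runif(k, 50, 800), runif(k, 100, 1e6), scan_index = i)
  }))
}

# binary distance formulas computed from first principles; the independent
# oracle for spectral_distance()
binary_distances <- function(u, v) {
  a <- sum(u == 1 & v == 1)
  bc <- sum(u != v)
  c(braycurtis = bc / (2 * a + bc), jaccard = bc / (a + bc))
}

# two labelings describe the same partition iff the label map is a bijection
partitions_equal <- function(p, q) {
  length(p) == length(q) &&
    nrow(unique(data.frame(p, q))) == length(unique(p)) &&
    length(unique(p)) == length(unique(q))
}
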