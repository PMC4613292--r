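test_that("K2P distance matches the closed form on constructed (P, Q) cases", {
  expect_equal(k2p_distance("ACGT", "ACGT")$distance, 0)
  expect_equal(k2p_distance("ACGT", "ACGT")$sites, 4L)

  r <- k2p_distance("AAAAAAAAAA", "AAAAAAAAAG")          # P = 0.1, Q = 0
  expect_equal(r$distance, k2p_closed(0.1, 0), tolerance = 1e-12)
  expect_equal(r$distance, 0.111572, tolerance = 1e-5)

  r <- k2p_distance("AAAAAAAAAA", "AAAAAAAAAC")          # P = 0, Q = 0.1
  expect_equal(r$distance, k2p_closed(0, 0.1), tolerance = 1e-12)
  expect_equal(r$distance, 0.108466, tolerance = 1e-5)

  # grid of exact (P, Q) combinations
  for (cnt in list(c(2, 3), c(5, 0), c(0, 7), c(10, 10))) {
    pq <- seq_pair_pq(cnt[1], cnt[2], 100)
    r <- k2p_distance(pq[1], pq[2])
    expect_equal(r$distance, k2p_closed(cnt[1] / 100, cnt[2] / 100),
                 tolerance = 1e-12)
  }
})

test_that("pairwise deletion drops gap/N columns; degenerate pairs error", {
  r <- k2p_distance("AC-TN", "ACGTA")
  expect_equal(r$sites, 3L)
  expect_equal(r$distance, 0)

  expect_error(k2p_distance("AAAA", "GGGG"), class = "bg_saturation")
  expect_error(k2p_distance("NN--", "AACC"), class = "bg_no_sites")
  expect_error(k2p_distance("ACG", "ACGT"), class = "bg_not_aligned")
})

test_that("K2P is symmetric, near-linear for small divergence, monotone", {
  set.seed(5)
  for (i in 1:10) {
    L <- 200
    a <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    b <- evolve_sequence(a, 0.1)
    expect_identical(k2p_distance(a, b)$distance, k2p_distance(b, a)$distance)
  }
  # first-order agreement d ~ P + Q within 1% when P + Q <= 0.01
  pq <- seq_pair_pq(5, 5, 1000)
  d <- k2p_distance(pq[1], pq[2])$distance
  expect_lt(abs(d - 0.01) / 0.01, 0.01)

  # adding one extra mismatching site never decreases d
  prev <- 0
  for (k in 1:30) {
    pq <- seq_pair_pq(k, k, 200)
    d <- k2p_distance(pq[1], pq[2])$distance
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("distance matrix agrees with an independent implementation", {
  sim <- simulate_genus(n_species = 4, samples_per_species = 3,
                        seq_length = 300, seed = 9)
  dm <- k2p_matrix(sim$alignment)
  expect_equal(dm$distance, t(dm$distance))
  expect_true(all(diag(dm$distance) == 0))

  bin <- ape::as.DNAbin(strsplit(sim$alignment$seq, ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm$distance), unname(ref[dm$ids, dm$ids]),
               tolerance = 1e-12)

  # 2-sequence matrix consistent with the scalar operation
  two <- labeled_alignment(sim$alignment$seq[1:2],
                           sim$alignment$species[1:2])
  dm2 <- k2p_matrix(two)
  expect_equal(dm2$distance[1, 2],
               k2p_distance(two$seq[[1]], two$seq[[2]])$distance)
})

test_that("matrix handles gaps/N via pairwise deletion and saturation policy", {
  aln <- labeled_alignment(c(s1 = "ACGTACGT", s2 = "ACGTAC-T", s3 = "ACNTACGT"),
                           c("x", "y", "z"))
  dm <- k2p_matrix(aln)
  expect_equal(dm$sites["s1", "s2"], 7L)
  expect_equal(dm$sites["s2", "s3"], 6L)
  expect_true(all(dm$distance == 0))

  sat <- labeled_alignment(c(s1 = "AAAA", s2 = "GGGG", s3 = "AAAA"),
                           c("x", "y", "z"))
  expect_error(k2p_matrix(sat), class = "bg_saturation")
  expect_warning(dm2 <- k2p_matrix(sat, on_saturation = "na"), "undefined")
  expect_true(is.na(dm2$distance["s1", "s2"]))
  expect_equal(dm2$distance["s1", "s3"], 0)
})

test_that("identical sequences give an all-zero matrix and writers round-trip", {
  aln <- labeled_alignment(c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC"),
                           c("x", "y", "z"))
  dm <- k2p_matrix(aln)
  expect_true(all(dm$distance == 0))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, tsv)
  tab <- read.delim(tsv, row.names = 1)
  expect_equal(unname(as.matrix(tab)), unname(dm$distance), tolerance = 1e-6)

  phy <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(dm, phy, format = "phylip")
  expect_equal(as.integer(trimws(readLines(phy)[1])), 3L)
})
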