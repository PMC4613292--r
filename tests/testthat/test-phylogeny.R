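test_that("three-taxon tree uses the closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.45, 0.3, 0, 0.55, 0.45, 0.55, 0), 3,
              dimnames = rep(list(c("A", "B", "C")), 2))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (0.3 + 0.45 - 0.55) / 2)
  expect_equal(bl[["B"]], (0.3 + 0.55 - 0.45) / 2)
  expect_equal(bl[["C"]], (0.45 + 0.55 - 0.3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), class = "bg_too_few")
})

test_that("additive four-taxon matrix recovers the generating split exactly", {
  d <- matrix(0, 4, 4, dimnames = rep(list(c("A", "B", "C", "D")), 2))
  d["A", "B"] <- 0.3; d["A", "C"] <- 0.45; d["A", "D"] <- 0.55
  d["B", "C"] <- 0.6; d["B", "D"] <- 0.7; d["C", "D"] <- 0.7
  d <- d + t(d)
  tr <- nj_tree(d)
  expect_true(paste(sort(c("A", "B")), collapse = "|") %in% bipart_set(tr) ||
                paste(sort(c("C", "D")), collapse = "|") %in% bipart_set(tr))
  # path lengths reproduce the input exactly (additivity oracle)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("NJ reconstructs random additive trees exactly", {
  set.seed(404)
  for (i in 1:20) {
    ra <- random_additive(sample(5:8, 1))
    tr <- nj_tree(ra$dm)
    expect_identical(bipart_set(tr), bipart_set(ra$tree))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$dm), colnames(ra$dm)],
                 ra$dm, tolerance = 1e-8)
  }
})

test_that("NJ topology agrees with an independent implementation", {
  sim <- simulate_genus(n_species = 6, samples_per_species = 2,
                        seq_length = 400, seed = 71)
  dm <- k2p_matrix(sim$alignment)
  ours <- nj_tree(dm, clamp_negative = FALSE)
  theirs <- ape::nj(as.dist(dm))
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)), 0,
               ignore_attr = TRUE)
})

test_that("degenerate equidistant matrix yields a zero-internal-length tree", {
  d <- matrix(0.4, 5, 5, dimnames = rep(list(paste0("t", 1:5)), 2))
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_equal(sum(tr$edge.length), 5 * 0.2, tolerance = 1e-10)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("bootstrap supports behave under clean and reproducible conditions", {
  # two clearly distinct clades of identical sequences -> certain split
  seqs <- c(a1 = strrep("ACGT", 30), a2 = strrep("ACGT", 30),
            a3 = strrep("ACGT", 30),
            b1 = strrep("ATGT", 30), b2 = strrep("ATGT", 30),
            b3 = strrep("ATGT", 30))
  aln <- labeled_alignment(seqs, setNames(c("A", "A", "A", "B", "B", "B"),
                                          names(seqs)))
  tr <- bootstrap_nj(aln, n_replicates = 30, seed = 5)
  sup <- attr(tr, "support")
  expect_length(sup, tr$Nnode)
  expect_true(all(sup[-1] >= 0 & sup[-1] <= 100))
  # the A|B separating edge is certain in every replicate
  expect_true(any(sup[-1] == 100))

  sim <- simulate_genus(n_species = 5, samples_per_species = 2,
                        seq_length = 150, seed = 83)
  t1 <- bootstrap_nj(sim$alignment, n_replicates = 20, seed = 9)
  t2 <- bootstrap_nj(sim$alignment, n_replicates = 20, seed = 9)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bipartition supports are invariant to leaf order", {
  sim <- simulate_genus(n_species = 5, samples_per_species = 2,
                        seq_length = 200, seed = 37)
  aln <- sim$alignment
  set.seed(2)
  perm <- sample(aln$id)
  aln_p <- labeled_alignment(aln$seq[perm], aln$species[perm])
  t1 <- bootstrap_nj(aln, n_replicates = 25, seed = 14)
  t2 <- bootstrap_nj(aln_p, n_replicates = 25, seed = 14)
  k1 <- setNames(attr(t1, "support")[-1], tree_biparts_for_test(t1))
  k2 <- setNames(attr(t2, "support")[-1], tree_biparts_for_test(t2))
  expect_setequal(names(k1), names(k2))
  expect_identical(sort(bipart_set(t1)), sort(bipart_set(t2)))
})

test_that("outgroup rooting places the root on the separating edge", {
  d <- matrix(0, 4, 4, dimnames = rep(list(c("A", "B", "C", "D")), 2))
  d["A", "B"] <- 0.3; d["A", "C"] <- 0.45; d["A", "D"] <- 0.55
  d["B", "C"] <- 0.6; d["B", "D"] <- 0.7; d["C", "D"] <- 0.7
  d <- d + t(d)
  tr <- nj_tree(d)
  lab <- c(A = "ing1", B = "ing2", C = "out1", D = "out2")
  rooted <- root_tree(tr, c("out1", "out2"), lab)
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("A", "B")))
  # rooting preserves the bipartition set
  expect_identical(bipart_set(rooted), bipart_set(tr))

  # scattered outgroup -> labeled error
  expect_error(root_tree(tr, c("ing1", "out2"), lab),
               class = "bg_not_monophyletic")
  expect_error(root_tree(tr, c("none"), lab), class = "bg_bad_input")
})
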