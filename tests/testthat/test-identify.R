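simple_scoring <- list(match = 1, mismatch = -1, gap_open = 2, gap_extend = 1)

test_that("local alignment score has the expected boundary behavior", {
  expect_equal(local_alignment_score("ACGTACGTAC", "ACGTACGTAC",
                                     simple_scoring), 10)
  # disjoint alphabets: the empty local alignment wins
  expect_equal(local_alignment_score("AAAA", "GGGG", simple_scoring), 0)
  # gaps in the input are stripped before scoring
  expect_equal(local_alignment_score("AC-GT", "ACGT", simple_scoring), 4)
  # non-nucleotide codes are mismatch-neutral
  expect_equal(local_alignment_score("ACRGT", "ACNGT", simple_scoring), 4)
  expect_error(local_alignment_score("", "ACGT"), class = "bg_empty_input")
})

test_that("local alignment score equals an independent Gotoh DP oracle", {
  expect_equal(local_alignment_score("ACGTACGT", "ACGACGT", simple_scoring),
               sw_oracle("ACGTACGT", "ACGACGT", simple_scoring))
  set.seed(88)
  for (i in 1:20) {
    q <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
               collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
               collapse = "")
    expect_equal(local_alignment_score(q, s, simple_scoring),
                 sw_oracle(q, s, simple_scoring),
                 info = paste(q, s))
    expect_equal(local_alignment_score(q, s, default_scoring()),
                 sw_oracle(q, s, default_scoring()),
                 info = paste(q, s))
  }
})

test_that("nearest-distance verdicts follow the tie rules", {
  d <- matrix(0, 3, 3, dimnames = rep(list(c("q", "a1", "b1")), 2))
  d["q", "a1"] <- d["a1", "q"] <- 0.01
  d["q", "b1"] <- d["b1", "q"] <- 0.05
  d["a1", "b1"] <- d["b1", "a1"] <- 0.06
  lab <- c(q = "A", a1 = "A", b1 = "B")
  expect_equal(identify_nearest("q", d, lab)$verdict, "correct")

  d["q", "b1"] <- d["b1", "q"] <- 0.01          # exact tie across species
  out <- identify_nearest("q", d, lab)
  expect_equal(out$verdict, "ambiguous")
  expect_setequal(out$predicted_species, c("A", "B"))

  lab2 <- c(q = "C", a1 = "A", b1 = "B")        # truth not among hits
  expect_equal(identify_nearest("q", d, lab2)$verdict, "incorrect")

  empty <- identify_nearest("q", d, lab, exclude = c("a1", "b1"))
  expect_equal(empty$verdict, "unidentifiable")
})

test_that("nearest-distance is invariant under monotone distance transforms", {
  sim <- simulate_genus(n_species = 5, samples_per_species = 3,
                        seq_length = 150, seed = 42)
  dm <- k2p_matrix(sim$alignment)
  d <- as.matrix(dm)
  d2 <- d / (1 + d)                              # strictly increasing map
  lab <- sim$alignment$species
  for (q in sim$alignment$id) {
    o1 <- identify_nearest(q, d, lab)
    o2 <- identify_nearest(q, d2, lab, tol = 1e-12)
    expect_identical(o1$verdict, o2$verdict)
    expect_identical(o1$predicted_species, o2$predicted_species)
  }
})

test_that("best-hit verdicts mirror the nearest rules on concordant data", {
  aln <- labeled_alignment(
    c(q = "ACGTACGTACGTACGT", a1 = "ACGTACGTACGTACGT",
      b1 = "ACGTACGTACGTTTTT", c1 = "ACGTTTTTTTTTTTTT"),
    c(q = "A", a1 = "A", b1 = "B", c1 = "C"))
  out <- identify_best_hit("q", aln)
  expect_equal(out$verdict, "correct")
  expect_equal(out$predicted_species, "A")

  # two references tie at the maximum score, one conspecific -> ambiguous
  aln2 <- labeled_alignment(
    c(q = "ACGTACGT", a1 = "ACGTACGT", b1 = "ACGTACGT"),
    c(q = "A", a1 = "A", b1 = "B"))
  out2 <- identify_best_hit("q", aln2)
  expect_equal(out2$verdict, "ambiguous")

  # ranking by score agrees with ranking by distance on separated data
  dm <- k2p_matrix(aln)
  on <- identify_nearest("q", dm, aln$species)
  expect_identical(out$predicted_species, on$predicted_species)
})

test_that("leave-one-out on clean two-species data is fully correct", {
  aln <- labeled_alignment(
    c(a1 = "ACGTACGTACGTACGT", a2 = "ACGTACGTACGTACGT",
      b1 = "ACGTACGTTTTTTTTT", b2 = "ACGTACGTTTTTTTTT"),
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  for (m in c("nearest", "best_hit")) {
    res <- evaluate_loo(aln, method = m)
    expect_equal(res$rates$pct_correct, 100)
    expect_equal(res$rates$pct_incorrect, 0)
    expect_equal(res$rates$pct_correct + res$rates$pct_incorrect +
                   res$rates$pct_ambiguous, 100)
  }
})

test_that("species sharing one haplotype are ambiguous, never incorrect", {
  sim <- simulate_genus(n_species = 6, samples_per_species = 3,
                        n_identical_pairs = 1, seed = 19)
  for (m in c("nearest", "best_hit")) {
    res <- evaluate_loo(sim$alignment, method = m)
    out <- res$outcomes
    affected <- out$true_species %in% c("sp01", "sp02")
    expect_true(all(out$verdict[affected] == "ambiguous"))
    expect_true(all(out$verdict[!affected] == "correct"))
    expect_equal(res$rates$pct_incorrect, 0)
  }
})

test_that("no incorrect verdicts under a positive barcoding gap", {
  sim <- simulate_genus(n_species = 8, samples_per_species = 3, seed = 23)
  dm <- k2p_matrix(sim$alignment)
  tab <- species_gap_table(dm, sim$alignment)
  expect_true(all(tab$separability > tab$heterogeneity))   # gap holds
  res <- evaluate_loo(sim$alignment, method = "nearest", dm = dm)
  expect_equal(res$rates$pct_incorrect, 0)
  expect_equal(res$rates$pct_correct, 100)
})

test_that("singleton species are flagged and can never be correct", {
  aln <- labeled_alignment(
    c(a1 = "ACGTACGTACGTACGT", a2 = "ACGTACGTACGTACGT",
      s1 = "TTTTACGTACGTCCCC"),
    c(a1 = "A", a2 = "A", s1 = "S"))
  res <- evaluate_loo(aln, method = "nearest")
  expect_equal(res$rates$n_singleton_species, 1L)
  expect_false(res$outcomes$verdict[res$outcomes$true_species == "S"] ==
                 "correct")
})
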