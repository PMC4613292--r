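# Shared fixtures and independent oracles, built in code at test time.

# hand-enumerable worked example: species A = {a1, a2}, species B = {b1},
# d(a1,a2) = 0.01, d(a1,b1) = 0.20, d(a2,b1) = 0.22
toy_dm <- function() {
  d <- matrix(0, 3, 3, dimnames = rep(list(c("a1", "a2", "b1")), 2))
  d["a1", "a2"] <- d["a2", "a1"] <- 0.01
  d["a1", "b1"] <- d["b1", "a1"] <- 0.20
  d["a2", "b1"] <- d["b1", "a2"] <- 0.22
  d
}

toy_labels <- function() c(a1 = "A", a2 = "A", b1 = "B")

# closed-form K2P for given transition/transversion proportions
k2p_closed <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

# sampling variance of the K2P distance estimator (delta method)
k2p_variance <- function(P, Q, L) {
  c1 <- 1 / (1 - 2 * P - Q)
  c2 <- 1 / (1 - 2 * Q)
  c3 <- (c1 + c2) / 2
  (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / L
}

# build a sequence pair realizing exact transition/transversion counts
# (on an all-A backbone: A->G transitions, A->C transversions)
seq_pair_pq <- function(n_ts, n_tv, L) {
  a <- rep("A", L)
  b <- a
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "C"
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

# independent affine-gap local alignment DP (Gotoh), matching the package
# scoring convention: a gap of length k costs gap_open + k * gap_extend.
sw_oracle <- function(q, s, scoring) {
  q <- strsplit(q, "")[[1]]; s <- strsplit(s, "")[[1]]
  n <- length(q); m <- length(s)
  go <- scoring$gap_open + scoring$gap_extend  # cost of first gap residue
  ge <- scoring$gap_extend
  sub <- function(x, y) {
    if (x == "N" || y == "N") 0
    else if (x == y) scoring$match else scoring$mismatch
  }
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in q (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in s (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub(q[i - 1], s[j - 1]),
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# per-internal-node canonical bipartitions, ordered like node numbers
# (root first) so they align with the `support` attribute of bootstrap trees
tree_biparts_for_test <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  v <- vapply(pp, function(ix) {
    s <- labs[ix]
    if (ref %in% s) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }, "")
  v[-1]
}

# random additive tree + its exact path-length matrix (oracle for NJ)
random_additive <- function(n_leaves, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_leaves, br = function(k) stats::runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# canonical bipartition set of a phylo tree, independent of the package's
# own encoder (uses ape::prop.part directly on an explicit re-read)
bipart_set <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  pp <- ape::prop.part(ape::unroot(tree))
  sets <- lapply(pp, function(ix) labs[ix])
  out <- vapply(sets, function(s) {
    if (ref %in% s) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }, "")
  sort(unique(out[nchar(out) > 0 &
                    vapply(sets, length, 0L) < length(labs)]))
}
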