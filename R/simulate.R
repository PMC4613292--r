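# K2P site-substitution probabilities after an expected distance d with
# transition/transversion rate ratio kappa: with beta*t = d/(kappa+2) and
# alpha*t = kappa*beta*t,
#   P(transition)        = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta)t}
#   P(each transversion) = 1/4 - 1/4 e^{-4 beta t}
# so that the expected transition/transversion proportions plug back into the
# K2P estimator to give d exactly.
.k2p_site_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  c(ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv_each = 0.25 - 0.25 * e1)
}

.evolve_int <- function(x, branch_length, kappa) {
  if (branch_length == 0) return(x)
  p <- .k2p_site_probs(branch_length, kappa)
  u <- stats::runif(length(x))
  out <- x
  is_purine <- x == 1L | x == 3L          # A or G
  ts <- u < p["ts"]
  tv1 <- !ts & u < p["ts"] + p["tv_each"]
  tv2 <- !ts & !tv1 & u < p["ts"] + 2 * p["tv_each"]
  out[ts] <- ifelse(x[ts] <= 2L, x[ts] + 2L, x[ts] - 2L)   # A<->G, C<->T
  out[tv1] <- ifelse(is_purine[tv1], 2L, 1L)               # -> C or A
  out[tv2] <- ifelse(is_purine[tv2], 4L, 3L)               # -> T or G
  out
}

.int_to_char <- function(x) {
  paste(c("A", "C", "G", "T")[x], collapse = "")
}

#' Evolve a sequence under the two-parameter substitution process
#'
#' Each site substitutes independently under the Kimura two-parameter
#' process, with transition and transversion rates scaled so that the
#' expected number of substitutions per site equals `branch_length` and
#' their ratio equals `kappa`.  Uses the session RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param parent Residue string over `A, C, G, T`.
#' @param branch_length Expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @return The evolved residue string (same length as `parent`).
#' @export
evolve_sequence <- function(parent, branch_length, kappa = 2) {
  if (branch_length < 0)
    bg_stop("branch_length must be non-negative", "bg_bad_input")
  if (kappa <= 0) bg_stop("kappa must be positive", "bg_bad_input")
  x <- unname(.BASE_INT[strsplit(toupper(parent), "", fixed = TRUE)[[1]]])
  if (anyNA(x))
    bg_stop("parent sequence must be over A/C/G/T only", "bg_bad_input")
  .int_to_char(.evolve_int(x, branch_length, kappa))
}

#' Simulate a genus-like sequence family
#'
#' Generates a gap-free, aligned set of sequences with the statistical
#' structure barcode-gap analyses assume: a star phylogeny of species
#' ancestors around a random GC-matched root, with tight within-species and
#' wide between-species K2P divergence.  Branch depths are chosen so that
#' the \emph{expected pairwise} K2P distance is `intra_divergence` within a
#' species and `inter_divergence` between species (species ancestors sit at
#' depth `(inter - intra)/2` from the root, individuals at `intra/2` from
#' their ancestor; K2P distances are additive in expectation).
#'
#' `n_identical_pairs` plants species pairs with no barcode separation: for
#' pair *p*, species `2p-1` and `2p` both receive their shared ancestor
#' haplotype for \emph{all} samples, so every within- and cross-pair
#' distance is exactly zero (the identical-sister-species scenario).
#'
#' The defaults emulate a genus-scale ITS2 study: 64 species, 248 bp, GC
#' 52\%, mean intra-specific K2P 0.007 and inter-specific 0.18.
#'
#' @param n_species Number of species (>= 2).
#' @param samples_per_species Scalar or length-`n_species` vector of sample
#'   counts.
#' @param seq_length Sequence length in bp.
#' @param gc_target GC fraction of the root sequence (matched exactly in
#'   base composition; positions are shuffled).
#' @param intra_divergence,inter_divergence Expected within/between-species
#'   K2P distances; `inter_divergence >= intra_divergence` required.
#' @param kappa Transition/transversion rate ratio.
#' @param n_identical_pairs Number of species pairs forced to share one
#'   identical haplotype (<= `floor(n_species/2)`).
#' @param indel_rate Optional per-site deletion probability applied
#'   independently to each final sequence (gaps written as `-`); off by
#'   default — it exists only to exercise gap handling downstream.
#' @param seed Optional integer seed (sets the session RNG).
#' @return List with `alignment` (a [labeled_alignment]) and `truth`
#'   (configuration echo, per-species table with identical-pair group, and
#'   the matrix of expected between-species divergences).
#' @examples
#' sim <- simulate_genus(n_species = 4, samples_per_species = 3, seed = 1)
#' sim$alignment
#' @export
simulate_genus <- function(n_species = 64, samples_per_species = 6,
                           seq_length = 248, gc_target = 0.52,
                           intra_divergence = 0.007, inter_divergence = 0.18,
                           kappa = 2, n_identical_pairs = 0,
                           indel_rate = 0, seed = NULL) {
  if (n_species < 2) bg_stop("n_species must be >= 2", "bg_bad_input")
  if (length(samples_per_species) == 1L)
    samples_per_species <- rep(as.integer(samples_per_species), n_species)
  if (length(samples_per_species) != n_species || any(samples_per_species < 1L))
    bg_stop("samples_per_species must be a positive scalar or length-n_species vector",
            "bg_bad_input")
  if (intra_divergence < 0 || inter_divergence < 0)
    bg_stop("divergences must be non-negative", "bg_bad_input")
  if (inter_divergence < intra_divergence)
    bg_stop("inter_divergence must be >= intra_divergence", "bg_bad_input")
  if (n_identical_pairs > floor(n_species / 2))
    bg_stop("n_identical_pairs exceeds floor(n_species/2)", "bg_bad_input")
  if (!is.null(seed)) set.seed(seed)

  # GC-matched root: exact base composition (G+C = round(gc_target * L),
  # split evenly within each class), positions shuffled.  Avoids the ~3%
  # single-draw GC variance of i.i.d. sampling at barcode lengths.
  n_gc <- round(gc_target * seq_length)
  n_g <- n_gc %/% 2L
  n_a <- (seq_length - n_gc) %/% 2L
  root <- sample(rep(c(1L, 2L, 3L, 4L),
                     times = c(n_a, n_gc - n_g, n_g,
                               seq_length - n_gc - n_a)))
  anc_depth <- (inter_divergence - intra_divergence) / 2
  tip_depth <- intra_divergence / 2

  species <- sprintf("sp%02d", seq_len(n_species))
  # identical pairs occupy species 1..2k, pair p = (2p-1, 2p)
  group <- rep(NA_integer_, n_species)
  if (n_identical_pairs > 0)
    group[seq_len(2 * n_identical_pairs)] <- rep(seq_len(n_identical_pairs),
                                                 each = 2)
  ancestors <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    if (!is.na(group[i]) && i %% 2 == 0 && !is.na(group[i - 1]) &&
        group[i] == group[i - 1]) {
      ancestors[[i]] <- ancestors[[i - 1]]   # shared pair ancestor
    } else {
      ancestors[[i]] <- .evolve_int(root, anc_depth, kappa)
    }
  }
  seqs <- character(0)
  sp_of <- character(0)
  for (i in seq_len(n_species)) {
    for (j in seq_len(samples_per_species[i])) {
      tip <- if (is.na(group[i])) .evolve_int(ancestors[[i]], tip_depth, kappa)
             else ancestors[[i]]              # planted identical haplotype
      s <- .int_to_char(tip)
      if (indel_rate > 0) {
        del <- stats::runif(seq_length) < indel_rate
        if (any(del)) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          ch[del] <- "-"
          s <- paste(ch, collapse = "")
        }
      }
      seqs <- c(seqs, stats::setNames(s, sprintf("%s_%02d", species[i], j)))
      sp_of <- c(sp_of, species[i])
    }
  }
  expected_inter <- matrix(inter_divergence, n_species, n_species,
                           dimnames = list(species, species))
  diag(expected_inter) <- ifelse(is.na(group), intra_divergence, 0)
  if (n_identical_pairs > 0)
    for (p in seq_len(n_identical_pairs)) {
      i <- 2 * p - 1; j <- 2 * p
      expected_inter[i, j] <- expected_inter[j, i] <- 0
    }
  list(
    alignment = labeled_alignment(seqs, stats::setNames(sp_of, names(seqs))),
    truth = list(
      config = list(n_species = n_species,
                    samples_per_species = samples_per_species,
                    seq_length = seq_length, gc_target = gc_target,
                    intra_divergence = intra_divergence,
                    inter_divergence = inter_divergence, kappa = kappa,
                    n_identical_pairs = n_identical_pairs,
                    indel_rate = indel_rate, seed = seed),
      species = data.frame(species = species,
                           n_samples = samples_per_species,
                           identical_group = group),
      root_gc = mean(root == 2L | root == 3L),
      expected_divergence = expected_inter
    )
  )
}
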