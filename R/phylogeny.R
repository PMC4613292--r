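# Newick-unsafe characters in taxon labels would corrupt the writer
.check_labels <- function(labs) {
  bad <- grepl("[][():;,'\"[:space:]]", labs)
  if (any(bad))
    bg_stop(sprintf("taxon label(s) unsafe for Newick output: %s",
                    paste(labs[bad], collapse = ", ")), "bg_bad_ids")
}

# recursive cluster structure -> Newick (lengths at full precision)
.to_newick <- function(nd) {
  if (!is.null(nd$tip)) return(nd$tip)
  paste0("(", paste(vapply(nd$children, function(ch)
    paste0(.to_newick(ch$node), ":", sprintf("%.16g", ch$len)), ""),
    collapse = ","), ")")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j`.  Deterministic: ties in Q are broken
#' by the lowest (row, column) index pair in the current node ordering.
#' Negative branch-length estimates are clamped to zero by default.  The
#' result is an unrooted tree (trifurcation at the last join) returned as an
#' [ape][ape::read.tree] `phylo` object.
#'
#' @param dm A `k2p_matrix`, symmetric matrix or `dist` over >= 3 taxa.
#' @param clamp_negative Clamp negative branch-length estimates to 0
#'   (default `TRUE`).
#' @return An unrooted `phylo` tree with branch lengths.
#' @examples
#' d <- matrix(c(0, .3, .45, .3, 0, .55, .45, .55, 0), 3,
#'             dimnames = rep(list(c("A", "B", "C")), 2))
#' nj_tree(d)$edge.length  # (d_AB+d_AC-d_BC)/2 etc.
#' @export
nj_tree <- function(dm, clamp_negative = TRUE) {
  D <- as_dist_matrix(dm)
  if (anyNA(D)) bg_stop("distance matrix has missing entries", "bg_bad_input")
  n <- nrow(D)
  if (n < 3L) bg_stop("need at least 3 taxa for a tree", "bg_too_few")
  .check_labels(rownames(D))
  nodes <- lapply(rownames(D), function(l) list(tip = l))
  clamp <- function(x) if (clamp_negative) pmax(x, 0) else x
  while (length(nodes) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    new_node <- list(children = list(list(node = nodes[[i]], len = clamp(li)),
                                     list(node = nodes[[j]], len = clamp(lj))))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    dimnames(D) <- NULL   # node identity is tracked by the nodes list
    nodes <- c(nodes[keep], list(new_node))
  }
  # closed-form star join of the last three nodes
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  root <- list(children = list(list(node = nodes[[1]], len = clamp(la)),
                               list(node = nodes[[2]], len = clamp(lb)),
                               list(node = nodes[[3]], len = clamp(lc))))
  ape::read.tree(text = paste0(.to_newick(root), ";"))
}

# canonical bipartition strings of the internal edges of an (unrooted) tree.
# Each non-root internal node contributes its tip clade; the side not
# containing the reference label (global lexicographic minimum) is kept, so
# the encoding is rooting- and leaf-order-invariant.
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  sets <- lapply(pp, function(ix) labs[ix])
  canon <- vapply(sets, function(s) {
    if (ref %in% s) s <- setdiff(labs, s)
    paste(sort(s), collapse = "\r")
  }, "")
  canon[-1]   # drop the root (full tip set); order matches internal nodes 2..
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Builds the NJ tree from the full-alignment K2P matrix, then resamples
#' alignment columns with replacement `n_replicates` times, rebuilds the NJ
#' tree for each replicate, and annotates each internal edge of the original
#' tree with the percentage of replicates containing the same bipartition.
#' Replicates in which any pairwise distance is undefined (saturation or no
#' comparable sites) are dropped with a warning and the denominator
#' adjusted.
#'
#' @param aln A [labeled_alignment] (aligned, >= 3 records).
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param clamp_negative Passed to [nj_tree()].
#' @return The original NJ `phylo` tree with `node.label` set to rounded
#'   bootstrap percentages (root label empty) and attributes `support`
#'   (numeric per internal node), `n_replicates_valid` and
#'   `n_replicates_dropped`.
#' @export
bootstrap_nj <- function(aln, n_replicates = 1000, seed = NULL,
                         clamp_negative = TRUE) {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_alignment(aln)
  if (nrow(enc) < 3L) bg_stop("need at least 3 sequences", "bg_too_few")
  tree <- nj_tree(.k2p_matrix_int(enc), clamp_negative = clamp_negative)
  orig <- tree_bipartitions(tree)
  counts <- integer(length(orig))
  valid <- 0L; dropped <- 0L
  L <- ncol(enc)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    dm_b <- tryCatch(.k2p_matrix_int(enc[, cols, drop = FALSE]),
                     barcodegap_error = function(e) NULL)
    if (is.null(dm_b)) { dropped <- dropped + 1L; next }
    bp <- tree_bipartitions(nj_tree(dm_b, clamp_negative = clamp_negative))
    counts <- counts + (orig %in% bp)
    valid <- valid + 1L
  }
  if (dropped > 0L)
    warning(sprintf("%d of %d bootstrap replicates dropped (undefined distances); supports use %d replicates",
                    dropped, n_replicates, valid))
  support <- if (valid > 0L) 100 * counts / valid else rep(NA_real_, length(orig))
  tree$node.label <- c("", sprintf("%.0f", support))
  attr(tree, "support") <- c(NA_real_, support)   # per internal node, root first
  attr(tree, "n_replicates_valid") <- valid
  attr(tree, "n_replicates_dropped") <- dropped
  tree
}

#' Root a tree on an outgroup
#'
#' Checks that the outgroup tips form one side of a bipartition of the
#' unrooted tree (monophyly) and places the root on the edge separating
#' outgroup from ingroup.
#'
#' @param tree A `phylo` tree.
#' @param outgroup_species Character vector of outgroup species names (or
#'   tip labels when `labels` is `NULL`).
#' @param labels Optional named id->species vector or [labeled_alignment]
#'   used to translate species names into tip labels.
#' @return A rooted `phylo` tree.
#' @export
root_tree <- function(tree, outgroup_species, labels = NULL) {
  tips <- if (is.null(labels)) intersect(tree$tip.label, outgroup_species)
  else {
    sp <- resolve_labels(labels, tree$tip.label)
    tree$tip.label[sp %in% outgroup_species]
  }
  if (length(tips) == 0L)
    bg_stop("no outgroup tips present in the tree", "bg_bad_input")
  if (length(tips) >= length(tree$tip.label))
    bg_stop("outgroup cannot contain all tips", "bg_bad_input")
  if (length(tips) > 1L && length(tips) < length(tree$tip.label) - 1L) {
    ref <- sort(tree$tip.label)[1]
    want <- tips
    if (ref %in% want) want <- setdiff(tree$tip.label, want)
    key <- paste(sort(want), collapse = "\r")
    if (!key %in% tree_bipartitions(tree))
      bg_stop(sprintf("outgroup is not monophyletic in the unrooted tree: {%s} is not a bipartition",
                      paste(sort(tips), collapse = ", ")), "bg_not_monophyletic")
  }
  ape::root(tree, outgroup = tips, resolve.root = TRUE)
}
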