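#' Split pairwise distances into intra- and inter-specific sets
#'
#' Every unordered sequence pair lands in exactly one of the two lists.
#'
#' @inheritParams divergence_summary
#' @return List with numeric vectors `intra` and `inter`.
#' @export
split_pair_distances <- function(dm, labels) {
  d <- as_dist_matrix(dm)
  sp <- resolve_labels(labels, rownames(d))
  ut <- upper.tri(d)
  same <- outer(sp, sp, "==")
  list(intra = d[ut & same], inter = d[ut & !same])
}

#' Barcoding-gap distribution profile
#'
#' Bins the intra- and inter-specific distance distributions on a common
#' half-open grid `[k*w, (k+1)*w)` (the last bin is closed on the right at
#' the maximum observed distance, which falls in its natural bin), and
#' reports the overlap statistics used to judge a barcoding gap: the
#' percentage of inter-specific distances equal to zero and the percentage
#' strictly below a threshold.  The threshold defaults to the observed
#' maximum intra-specific distance — the natural "gap" boundary.
#'
#' @param intra,inter Numeric distance vectors (from
#'   [split_pair_distances()]).
#' @param bin_width Histogram bin width in distance units (default 0.008).
#' @param below_threshold Threshold for the strict `<` overlap percentage;
#'   `NULL` (default) uses `max(intra)`.
#' @return Object of class `gap_profile`: `breaks`, `intra_counts`,
#'   `inter_counts`, `intra_range`, `inter_range`, `pct_inter_zero`,
#'   `below_threshold`, `pct_inter_below`.
#' @export
gap_profile <- function(intra, inter, bin_width = 0.008,
                        below_threshold = NULL) {
  intra <- as.numeric(intra); inter <- as.numeric(inter)
  if (length(intra) == 0L && length(inter) == 0L)
    bg_stop("no distances to profile", "bg_empty_input")
  if (bin_width <= 0) bg_stop("bin_width must be positive", "bg_bad_input")
  all_d <- c(intra, inter)
  if (any(all_d < 0)) bg_stop("negative distances", "bg_bad_input")
  nbin <- floor(max(all_d) / bin_width) + 1L
  binify <- function(x) tabulate(pmin(floor(x / bin_width) + 1L, nbin), nbin)
  thr <- below_threshold %||% if (length(intra)) max(intra) else NA_real_
  structure(list(
    bin_width = bin_width,
    breaks = bin_width * seq.int(0L, nbin),
    intra_counts = binify(intra),
    inter_counts = binify(inter),
    intra_range = if (length(intra)) range(intra) else c(NA_real_, NA_real_),
    inter_range = if (length(inter)) range(inter) else c(NA_real_, NA_real_),
    n_intra = length(intra), n_inter = length(inter),
    pct_inter_zero = if (length(inter)) 100 * mean(inter == 0) else NA_real_,
    below_threshold = thr,
    pct_inter_below = if (length(inter) && !is.na(thr))
      100 * mean(inter < thr) else NA_real_
  ), class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  cat(sprintf("Barcoding-gap profile (bin width %g):\n", x$bin_width))
  cat(sprintf("  intra: n=%d, range %.3f-%.3f\n", x$n_intra,
              x$intra_range[1], x$intra_range[2]))
  cat(sprintf("  inter: n=%d, range %.3f-%.3f\n", x$n_inter,
              x$inter_range[1], x$inter_range[2]))
  cat(sprintf("  %% inter-specific distances = 0:        %.2f%%\n",
              x$pct_inter_zero))
  cat(sprintf("  %% inter-specific distances < %.3f:    %.2f%%\n",
              x$below_threshold, x$pct_inter_below))
  invisible(x)
}

#' @param x A `gap_profile`.
#' @param ... Passed to [graphics::barplot()].
#' @rdname gap_profile
#' @export
plot.gap_profile <- function(x, ...) {
  rel <- rbind(intra = 100 * x$intra_counts / max(1L, x$n_intra),
               inter = 100 * x$inter_counts / max(1L, x$n_inter))
  mids <- x$breaks[-length(x$breaks)] + x$bin_width / 2
  graphics::barplot(rel, beside = TRUE, names.arg = formatC(mids, format = "g"),
                    col = c("grey75", "grey30"), border = NA, las = 2,
                    xlab = "K2P distance", ylab = "% of pairwise comparisons",
                    ...)
  graphics::legend("topright", fill = c("grey75", "grey30"), border = NA,
                   legend = c("intra-specific", "inter-specific"), bty = "n")
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two distance sets
#'
#' Thin wrapper around [stats::wilcox.test()] applying the conventional
#' barcoding-gap comparison: exact enumeration when both samples are small
#' (n <= 20) and untied, otherwise the tie-corrected normal approximation
#' with continuity correction.  Two-sided.  Pairwise distances are
#' statistically dependent; the p-value is reported descriptively, as is
#' conventional in barcode-gap assessments.
#'
#' @param x,y Numeric vectors.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) branch;
#'   `NULL` chooses automatically.
#' @return List with `statistic` (Mann-Whitney W for `x`), `p_value`
#'   (two-sided) and `exact`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    bg_stop("both samples must be non-empty", "bg_empty_input")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                exact = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- length(x) <= 20L && length(y) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Percentage of multi-sample species with a unique haplotype set
#'
#' A species with >= 2 samples counts as having a "unique sequence" when its
#' set of haplotypes (ungapped residue strings) is disjoint from every other
#' species' haplotype set — i.e. no sequence it carries is shared across a
#' species boundary.
#'
#' @param aln A [labeled_alignment] (outgroup species are excluded).
#' @return List with `pct` (percent of multi-sample species that are unique),
#'   `n_multi`, and a per-species data frame `table`.
#' @export
unique_sequence_species <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  aln <- aln_ingroup(aln)
  hap <- gsub("-", "", aln$seq, fixed = TRUE)
  sp <- aln$species
  sets <- split(hap, sp)
  species <- names(sets)
  uniq <- vapply(species, function(s) {
    others <- unique(unlist(sets[setdiff(species, s)], use.names = FALSE))
    !any(sets[[s]] %in% others)
  }, TRUE)
  multi <- vapply(sets, function(h) length(h) >= 2L, TRUE)
  structure(list(
    pct = if (any(multi)) 100 * mean(uniq[multi]) else NA_real_,
    n_multi = sum(multi),
    table = data.frame(species = species, n_samples = lengths(sets)[species],
                       unique = unname(uniq), row.names = NULL)
  ), class = "unique_sequence_species")
}

#' @export
print.unique_sequence_species <- function(x, ...) {
  cat(sprintf("%.2f%% of %d multi-sample species carry a unique haplotype set\n",
              x$pct, x$n_multi))
  invisible(x)
}
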