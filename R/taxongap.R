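#' Per-species heterogeneity/separability table
#'
#' For each species: \emph{heterogeneity} is the maximum intra-specific K2P
#' distance (0 for singleton species, flagged), \emph{separability} the
#' minimum K2P distance to any heterospecific sequence, and the closest
#' relative is the species attaining that minimum (ties reported
#' lexicographically, comma-joined).  A species is \emph{separable} when its
#' separability strictly exceeds its heterogeneity.  This is the per-taxon
#' view popularized by the TaxonGap tool, computed here on K2P distance
#' rather than a similarity matrix, for consistency with the other stages.
#'
#' @inheritParams divergence_summary
#' @return A `data.frame` of class `species_gap_table` with columns
#'   `species`, `n_samples`, `heterogeneity`, `separability`,
#'   `closest_relative`, `separable`, `singleton`.
#' @export
species_gap_table <- function(dm, labels) {
  d <- as_dist_matrix(dm)
  sp <- resolve_labels(labels, rownames(d))
  if (length(unique(sp)) < 2L)
    bg_stop("need at least 2 species", "bg_too_few")
  per <- species_pair_stats(d, sp)
  out <- data.frame(
    species = names(per),
    n_samples = vapply(per, `[[`, 0L, "n"),
    heterogeneity = vapply(per, function(p)
      if (length(p$intra)) max(p$intra) else 0, 0),
    separability = vapply(per, `[[`, 0, "hetero_min"),
    closest_relative = vapply(per, function(p)
      paste(p$closest, collapse = ","), ""),
    row.names = NULL)
  out$separable <- out$separability > out$heterogeneity
  out$singleton <- out$n_samples == 1L
  class(out) <- c("species_gap_table", "data.frame")
  out
}

#' @export
print.species_gap_table <- function(x, ...) {
  cat(sprintf("Species gap table: %d species, %.1f%% separable\n",
              nrow(x), 100 * mean(x$separable)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @param x A `species_gap_table`.
#' @param ... Passed to [graphics::barplot()].
#' @rdname species_gap_table
#' @export
plot.species_gap_table <- function(x, ...) {
  ord <- order(x$species, decreasing = TRUE)
  m <- t(as.matrix(x[ord, c("heterogeneity", "separability")]))
  graphics::barplot(m, beside = TRUE, horiz = TRUE, names.arg = x$species[ord],
                    col = c("grey75", "grey30"), border = NA, las = 1,
                    xlab = "K2P distance", ...)
  graphics::legend("bottomright", fill = c("grey75", "grey30"), border = NA,
                   legend = c("heterogeneity (max intra)",
                              "separability (min inter)"), bty = "n")
  invisible(x)
}

#' Species pairs with no barcode separation
#'
#' Returns every species whose minimum heterospecific distance is exactly
#' zero (an identical sequence shared across the species boundary), with the
#' partner species carrying the identical haplotype.
#'
#' @inheritParams divergence_summary
#' @return A `data.frame` with columns `species` and `partners`
#'   (comma-joined partner species); zero rows when all species are
#'   separated.
#' @export
inseparable_pairs <- function(dm, labels) {
  d <- as_dist_matrix(dm)
  sp <- resolve_labels(labels, rownames(d))
  per <- species_pair_stats(d, sp)
  hit <- vapply(per, function(p) !is.na(p$hetero_min) && p$hetero_min == 0,
                TRUE)
  data.frame(
    species = names(per)[hit],
    partners = vapply(per[hit], function(p) {
      inside <- which(sp == p$species)
      outside <- which(sp != p$species)
      zero <- unique(sp[outside][apply(d[inside, outside, drop = FALSE], 2,
                                       min) == 0])
      paste(sort(zero), collapse = ",")
    }, ""),
    row.names = NULL)
}
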