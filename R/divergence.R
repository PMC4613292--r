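# resolve labels argument: named character vector (id -> species) or a
# labeled_alignment; returns vector aligned to dm ids, outgroups dropped
# upstream by callers that want them dropped.
resolve_labels <- function(labels, ids) {
  if (inherits(labels, "labeled_alignment")) labels <- labels$species
  if (is.null(names(labels)))
    bg_stop("labels must be a named id->species vector or labeled_alignment",
            "bg_bad_input")
  sp <- labels[ids]
  if (any(is.na(sp)))
    bg_stop(sprintf("no species label for: %s",
                    paste(ids[is.na(sp)], collapse = ", ")), "bg_unlabeled")
  as.character(sp)
}

# per-species distance views used by divergence, gap and taxongap stages
species_pair_stats <- function(d, sp) {
  species <- unique(sp)
  intra_pairs <- numeric(0)
  per <- lapply(species, function(s) {
    inside <- which(sp == s)
    outside <- which(sp != s)
    intra <- if (length(inside) >= 2L) {
      sub <- d[inside, inside, drop = FALSE]
      sub[upper.tri(sub)]
    } else numeric(0)
    hetero <- if (length(outside)) d[inside, outside, drop = FALSE] else NULL
    list(species = s, n = length(inside), intra = intra,
         hetero_mean = if (!is.null(hetero)) mean(hetero) else NA_real_,
         hetero_min = if (!is.null(hetero)) min(hetero) else NA_real_,
         closest = if (!is.null(hetero)) {
           # species of the heterospecific sequence(s) attaining the minimum
           hmin <- min(hetero)
           sort(unique(sp[outside][apply(hetero, 2, min) <= hmin + 1e-12]))
         } else character(0))
  })
  names(per) <- species
  per
}

#' Six-metric divergence summary
#'
#' Computes the standard barcode-evaluation summary of inter-specific
#' divergence and intra-specific variation from a K2P distance matrix and a
#' species labeling:
#' \itemize{
#'   \item \emph{all inter-specific distance}: mean over every heterospecific
#'     sequence pair;
#'   \item \emph{theta prime}: per-species mean distance to all
#'     heterospecific sequences, averaged across species;
#'   \item \emph{minimum inter-specific distance}: per-species minimum
#'     distance to any heterospecific sequence, averaged across species;
#'   \item \emph{all intra-specific distance}: mean over every conspecific
#'     pair (species with >= 2 samples only);
#'   \item \emph{theta}: per-species mean conspecific distance, averaged
#'     across multi-sample species;
#'   \item \emph{coalescent depth}: per-species maximum conspecific distance,
#'     averaged across multi-sample species.
#' }
#' Dispersions are population standard deviations over the pooled items
#' (pairs, or species for the per-species metrics).  Species averaging is
#' unweighted by sample count.  Outgroup species should be removed before
#' calling (done automatically by [barcode_eval()]).
#'
#' @param dm A `k2p_matrix` (or symmetric matrix/dist) over sequence ids.
#' @param labels Named id->species character vector or [labeled_alignment].
#' @return Object of class `divergence_summary` with `*_mean`/`*_sd` fields
#'   for the six metrics, `n_species_total`, `n_species_multi`, and flags
#'   `has_inter`/`has_intra`.  Metrics that cannot be computed (a single
#'   species, or no multi-sample species) are `NA` with the flag `FALSE`.
#' @export
divergence_summary <- function(dm, labels) {
  d <- as_dist_matrix(dm)
  sp <- resolve_labels(labels, rownames(d))
  if (anyNA(d)) bg_stop("distance matrix has missing entries", "bg_bad_input")
  per <- species_pair_stats(d, sp)
  species <- names(per)
  multi <- species[vapply(per, function(p) p$n >= 2L, TRUE)]
  has_inter <- length(species) >= 2L
  has_intra <- length(multi) >= 1L

  inter_pool <- if (has_inter) {
    mask <- outer(sp, sp, "!=") & upper.tri(d)
    d[mask]
  } else numeric(0)
  intra_pool <- unlist(lapply(per[multi], `[[`, "intra"), use.names = FALSE)
  tp <- vapply(per, `[[`, 0, "hetero_mean")
  mi <- vapply(per, `[[`, 0, "hetero_min")
  th <- vapply(per[multi], function(p) mean(p$intra), 0)
  cd <- vapply(per[multi], function(p) max(p$intra), 0)

  structure(list(
    all_inter_mean = if (has_inter) mean(inter_pool) else NA_real_,
    all_inter_sd   = if (has_inter) psd(inter_pool) else NA_real_,
    theta_prime_mean = if (has_inter) mean(tp) else NA_real_,
    theta_prime_sd   = if (has_inter) psd(tp) else NA_real_,
    min_inter_mean = if (has_inter) mean(mi) else NA_real_,
    min_inter_sd   = if (has_inter) psd(mi) else NA_real_,
    all_intra_mean = if (has_intra) mean(intra_pool) else NA_real_,
    all_intra_sd   = if (has_intra) psd(intra_pool) else NA_real_,
    theta_mean = if (has_intra) mean(th) else NA_real_,
    theta_sd   = if (has_intra) psd(th) else NA_real_,
    coalescent_depth_mean = if (has_intra) mean(cd) else NA_real_,
    coalescent_depth_sd   = if (has_intra) psd(cd) else NA_real_,
    n_species_total = length(species),
    n_species_multi = length(multi),
    has_inter = has_inter, has_intra = has_intra,
    per_species = data.frame(
      species = species,
      n_samples = vapply(per, `[[`, 0L, "n"),
      theta_prime = unname(tp), min_inter = unname(mi),
      theta = ifelse(species %in% multi, vapply(per, function(p)
        if (p$n >= 2L) mean(p$intra) else NA_real_, 0), NA_real_),
      coalescent_depth = vapply(per, function(p)
        if (p$n >= 2L) max(p$intra) else NA_real_, 0),
      row.names = NULL)
  ), class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, digits = 3, ...) {
  fmt <- function(m, s) {
    if (is.na(m)) "      --" else sprintf("%.*f ± %.*f", digits, m, digits, s)
  }
  cat("Inter-specific divergence / intra-specific variation (K2P):\n")
  rows <- c("All inter-specific distance" = fmt(x$all_inter_mean, x$all_inter_sd),
            "Theta prime"                 = fmt(x$theta_prime_mean, x$theta_prime_sd),
            "Minimum inter-specific distance" = fmt(x$min_inter_mean, x$min_inter_sd),
            "All intra-specific distance" = fmt(x$all_intra_mean, x$all_intra_sd),
            "Theta"                       = fmt(x$theta_mean, x$theta_sd),
            "Coalescent depth"            = fmt(x$coalescent_depth_mean, x$coalescent_depth_sd))
  for (i in seq_along(rows))
    cat(sprintf("  %-33s %s\n", names(rows)[i], rows[i]))
  cat(sprintf("  (%d species, %d with >= 2 samples)\n",
              x$n_species_total, x$n_species_multi))
  invisible(x)
}

#' @export
as.data.frame.divergence_summary <- function(x, ...) {
  data.frame(
    metric = c("all_inter", "theta_prime", "min_inter",
               "all_intra", "theta", "coalescent_depth"),
    mean = c(x$all_inter_mean, x$theta_prime_mean, x$min_inter_mean,
             x$all_intra_mean, x$theta_mean, x$coalescent_depth_mean),
    sd = c(x$all_inter_sd, x$theta_prime_sd, x$min_inter_sd,
           x$all_intra_sd, x$theta_sd, x$coalescent_depth_sd))
}
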