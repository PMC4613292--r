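#' Full barcode-marker evaluation
#'
#' Runs the complete evaluation on a labeled alignment: sequence
#' characteristics, K2P distance matrix, six-metric divergence summary,
#' barcoding-gap profile with Wilcoxon rank-sum comparison, leave-one-out
#' species identification (nearest distance and/or best local-alignment
#' hit), per-species heterogeneity/separability table with inseparable
#' pairs, and (optionally) a neighbor-joining tree with bootstrap supports,
#' rooted on the outgroup when one is flagged.  All distance-based
#' summaries exclude outgroup sequences; the tree includes them.
#'
#' @param aln A [labeled_alignment] (aligned, >= 2 records).
#' @param bin_width Gap-profile bin width (default 0.008 distance units).
#' @param below_threshold Overlap threshold for the gap profile (`NULL` =
#'   observed intra-specific maximum).
#' @param methods Identification methods to evaluate, subset of
#'   `c("nearest", "best_hit")`.
#' @param scoring Local-alignment scoring scheme, see [default_scoring()].
#' @param bootstrap_replicates Bootstrap replicate count for the tree (0 =
#'   plain NJ tree without supports).
#' @param build_tree Build the NJ tree (default `TRUE`; needs >= 3
#'   sequences).
#' @param on_saturation Passed to [k2p_matrix()].
#' @param seed Optional integer seed (controls the bootstrap resampling).
#' @return Object of class `barcode_eval` with components
#'   `sequence_summary`, `distance` (`k2p_matrix`), `divergence`,
#'   `gap` (`gap_profile`), `wilcoxon`, `unique_species`,
#'   `identification` (named list of `loo_identification`),
#'   `species_gap`, `inseparable`, `tree` and `call` metadata.
#' @examples
#' sim <- simulate_genus(n_species = 5, samples_per_species = 3, seed = 42)
#' ev <- barcode_eval(sim$alignment, bootstrap_replicates = 0,
#'                    methods = "nearest")
#' print(ev)
#' @export
barcode_eval <- function(aln, bin_width = 0.008, below_threshold = NULL,
                         methods = c("nearest", "best_hit"),
                         scoring = default_scoring(),
                         bootstrap_replicates = 0, build_tree = TRUE,
                         on_saturation = c("error", "na"), seed = NULL) {
  stopifnot(inherits(aln, "labeled_alignment"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  ing <- aln_ingroup(aln)
  dm_all <- k2p_matrix(aln, on_saturation = on_saturation)
  dm <- if (length(ing$id) == length(aln$id)) dm_all else {
    d <- dm_all$distance[ing$id, ing$id]
    s <- dm_all$sites[ing$id, ing$id]
    structure(list(distance = d, sites = s, ids = ing$id),
              class = "k2p_matrix")
  }

  pairs <- split_pair_distances(dm, ing$species)
  gap <- if (length(pairs$intra) || length(pairs$inter))
    gap_profile(pairs$intra, pairs$inter, bin_width = bin_width,
                below_threshold = below_threshold) else NULL
  wil <- if (length(pairs$intra) && length(pairs$inter))
    rank_sum_test(pairs$inter, pairs$intra) else NULL

  ident <- lapply(stats::setNames(methods, methods), function(m)
    evaluate_loo(ing, method = m, dm = if (m == "nearest") dm else NULL,
                 scoring = scoring))

  multi_species <- length(unique(ing$species)) >= 2L
  tree <- NULL
  if (build_tree && length(aln$id) >= 3L) {
    tree <- if (bootstrap_replicates > 0)
      bootstrap_nj(aln, n_replicates = bootstrap_replicates)
    else nj_tree(dm_all)
    if (length(aln$outgroup))
      tree <- root_tree(tree, aln$outgroup, aln$species)
  }

  structure(list(
    sequence_summary = summarize_sequences(ing),
    distance = dm_all,
    divergence = if (multi_species || any(table(ing$species) >= 2))
      divergence_summary(dm, ing$species) else NULL,
    gap = gap,
    wilcoxon = wil,
    unique_species = unique_sequence_species(ing),
    identification = ident,
    species_gap = if (multi_species) species_gap_table(dm, ing$species) else NULL,
    inseparable = if (multi_species) inseparable_pairs(dm, ing$species) else NULL,
    tree = tree,
    n_outgroup = length(aln$id) - length(ing$id),
    call = list(bin_width = bin_width, below_threshold = below_threshold,
                methods = methods, scoring = scoring,
                bootstrap_replicates = bootstrap_replicates, seed = seed)
  ), class = "barcode_eval")
}

#' @export
print.barcode_eval <- function(x, ...) {
  cat("Barcode marker evaluation\n=========================\n")
  print(x$sequence_summary)
  if (!is.null(x$divergence)) print(x$divergence)
  if (!is.null(x$gap)) print(x$gap)
  if (!is.null(x$wilcoxon))
    cat(sprintf("  Wilcoxon rank-sum inter vs intra: W = %g, p %s\n",
                x$wilcoxon$statistic,
                if (x$wilcoxon$p_value < 1e-3) "< 0.001"
                else sprintf("= %.3g", x$wilcoxon$p_value)))
  cat("Identification (leave-one-out):\n")
  for (m in x$identification) print(m$rates)
  if (!is.null(x$species_gap))
    cat(sprintf("TaxonGap-style separability: %.1f%% of %d species separable; %d species in inseparable pairs\n",
                100 * mean(x$species_gap$separable), nrow(x$species_gap),
                nrow(x$inseparable)))
  if (!is.null(x$tree))
    cat(sprintf("NJ tree: %d tips%s\n", length(x$tree$tip.label),
                if (!is.null(attr(x$tree, "n_replicates_valid")))
                  sprintf(", bootstrap supports from %d replicates",
                          attr(x$tree, "n_replicates_valid")) else ""))
  invisible(x)
}

#' @export
summary.barcode_eval <- function(object, ...) {
  print(object)
  if (!is.null(object$unique_species)) print(object$unique_species)
  if (!is.null(object$inseparable) && nrow(object$inseparable)) {
    cat("Inseparable species (separability = 0):\n")
    print.data.frame(object$inseparable, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.barcode_eval <- function(x, which = c("gap", "taxongap"), ...) {
  which <- match.arg(which)
  if (which == "gap") {
    if (is.null(x$gap)) bg_stop("no gap profile available", "bg_bad_input")
    plot(x$gap, ...)
  } else {
    if (is.null(x$species_gap)) bg_stop("no species gap table", "bg_bad_input")
    plot(x$species_gap, ...)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# config-driven pipeline

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      bg_stop("reading a config file requires the yaml package", "bg_io")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) bg_stop("config must be a list or YAML path", "bg_bad_input")
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    bg_stop("config must contain exactly one of 'input' or 'simulate'",
            "bg_bad_config")
  config
}

#' Run the evaluation pipeline from a declarative config
#'
#' The config (R list or YAML file path) names either an `input` block
#' (`fasta`, optional `labels` TSV) or a `simulate` block (arguments to
#' [simulate_genus()]), exactly one of the two, plus optional analysis
#' settings (`bin_width`, `below_threshold`, `methods`, `scoring`,
#' `bootstrap_replicates`, `seed`).  Writes all result artifacts under
#' `output_dir`: the simulated FASTA/labels/truth (when simulating), the
#' distance matrix TSV, divergence and identification tables (TSV + JSON),
#' gap profile and Wilcoxon test, species gap table, Newick tree and a run
#' log.  Fully deterministic for a fixed seed.
#'
#' @param config R list or path to a YAML file.
#' @param output_dir Output directory (created if needed); defaults to
#'   `config$output_dir`.
#' @return The [barcode_eval] object, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- validate_config(config)
  output_dir <- output_dir %||% config$output_dir %||%
    bg_stop("config must name an output_dir", "bg_bad_config")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  if (!is.null(seed)) set.seed(as.integer(seed))

  log_lines <- c(sprintf("barcodegap %s | R %s",
                         as.character(utils::packageVersion("barcodegap")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %s", seed %||% "none"))

  if (!is.null(config$simulate)) {
    sim <- do.call(simulate_genus, config$simulate)
    aln <- sim$alignment
    write_labeled_fasta(aln, file.path(output_dir, "alignment.fasta"),
                        file.path(output_dir, "labels.tsv"))
    truth <- sim$truth
    truth$expected_divergence <- NULL   # matrix; species table carries design
    jsonlite::write_json(truth, file.path(output_dir, "truth.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    log_lines <- c(log_lines, "input: simulated (see truth.json)")
  } else {
    aln <- read_labeled_fasta(config$input$fasta, config$input$labels)
    log_lines <- c(log_lines, sprintf("input: %s", config$input$fasta))
  }

  ev <- barcode_eval(
    aln,
    bin_width = config$bin_width %||% 0.008,
    below_threshold = config$below_threshold,
    methods = config$methods %||% c("nearest", "best_hit"),
    scoring = config$scoring %||% default_scoring(),
    bootstrap_replicates = config$bootstrap_replicates %||% 0)

  write_distance_matrix(ev$distance, file.path(output_dir, "distances.tsv"))
  if (!is.null(ev$divergence)) {
    utils::write.table(as.data.frame(ev$divergence),
                       file.path(output_dir, "divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(ev$gap)) {
    g <- ev$gap
    utils::write.table(
      data.frame(bin_lower = g$breaks[-length(g$breaks)],
                 bin_upper = g$breaks[-1],
                 intra = g$intra_counts, inter = g$inter_counts),
      file.path(output_dir, "gap_profile.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(pct_inter_zero = g$pct_inter_zero,
           below_threshold = g$below_threshold,
           pct_inter_below = g$pct_inter_below,
           pct_species_unique_sequence = ev$unique_species$pct,
           wilcoxon = ev$wilcoxon),
      file.path(output_dir, "gap_test.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  for (m in names(ev$identification)) {
    res <- ev$identification[[m]]
    utils::write.table(res$outcomes,
                       file.path(output_dir, sprintf("identification_%s.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(res$rates),
                         file.path(output_dir, sprintf("identification_%s.json", m)),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  if (!is.null(ev$species_gap))
    utils::write.table(ev$species_gap, file.path(output_dir, "species_gap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ev$tree))
    ape::write.tree(ev$tree, file.path(output_dir, "tree.nwk"))
  writeLines(c(log_lines, sprintf("artifacts: %s",
                                  paste(sort(list.files(output_dir)),
                                        collapse = ", "))),
             file.path(output_dir, "run_log.txt"))
  invisible(ev)
}
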