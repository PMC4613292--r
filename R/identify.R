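#' Default local-alignment scoring scheme
#'
#' Integer BLASTN-style scheme: match +2, mismatch -3, gap opening 5, gap
#' extension 2 (a gap of length k costs `gap_open + k * gap_extend`).
#' Non-nucleotide residues are scored 0 against everything
#' (mismatch-neutral).
#'
#' @return Named list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2)
}

.substitution_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(0, 5, 5, dimnames = list(letters, letters))
  m[1:4, 1:4] <- scoring$mismatch
  diag(m)[1:4] <- scoring$match
  m
}

# strip gaps, map anything outside ACGT to the neutral N
.ungap_neutral <- function(s) {
  gsub("[^ACGT]", "N", gsub("-", "", toupper(s), fixed = TRUE))
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under affine gap costs, computed with
#' [Biostrings::pairwiseAlignment()].  Input sequences are ungapped first;
#' residues outside `A/C/G/T` are scored 0 against everything.
#'
#' @param query,subject Residue strings (gaps allowed; removed before
#'   scoring).
#' @param scoring Scoring scheme, see [default_scoring()].
#' @return Numeric optimal local alignment score (0 when no positive-scoring
#'   alignment exists).
#' @examples
#' local_alignment_score("ACGTACGTAC", "ACGTACGTAC",
#'                       list(match = 1, mismatch = -1,
#'                            gap_open = 2, gap_extend = 1))  # 10
#' @export
local_alignment_score <- function(query, subject, scoring = default_scoring()) {
  if (!nzchar(query) || !nzchar(subject))
    bg_stop("sequences must be non-empty", "bg_empty_input")
  q <- .ungap_neutral(query)
  s <- .ungap_neutral(subject)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(q), subject = Biostrings::DNAString(s),
    type = "local", substitutionMatrix = .substitution_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE)
}

# vectorized: query against many references at once
.score_against <- function(query, refs, scoring) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(vapply(refs, .ungap_neutral, "")),
    subject = Biostrings::DNAString(.ungap_neutral(query)),
    type = "local", substitutionMatrix = .substitution_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE)
}

.verdict <- function(true_species, predicted) {
  if (length(predicted) == 0L) "unidentifiable"
  else if (!(true_species %in% predicted)) "incorrect"
  else if (length(predicted) == 1L) "correct"
  else "ambiguous"
}

.outcome <- function(query_id, true_species, predicted, criterion_value) {
  structure(list(query_id = query_id, true_species = true_species,
                 predicted_species = sort(predicted),
                 verdict = .verdict(true_species, predicted),
                 criterion_value = criterion_value),
            class = "identification_outcome")
}

#' @export
print.identification_outcome <- function(x, ...) {
  cat(sprintf("%s (%s): %s -> {%s} [criterion %.6g]\n", x$query_id,
              x$true_species, x$verdict,
              paste(x$predicted_species, collapse = ", "),
              x$criterion_value))
  invisible(x)
}

#' Identify a query by nearest genetic distance
#'
#' The predicted species set contains the species of every reference
#' sequence at the minimum distance from the query (ties within `tol`).
#' Verdicts: `correct` when the set is exactly the true species, `ambiguous`
#' when several species tie at the minimum and the true species is among
#' them, `incorrect` when it is not, `unidentifiable` when no reference
#' remains.
#'
#' @param query_id Sequence id of the query (must be in `dm`).
#' @param dm A `k2p_matrix` (or symmetric matrix) including the query.
#' @param labels Named id->species vector or [labeled_alignment].
#' @param exclude Ids to drop from the reference set (the query itself is
#'   always dropped).
#' @param tol Tie tolerance on distances (default 1e-9).
#' @return An `identification_outcome`.
#' @export
identify_nearest <- function(query_id, dm, labels, exclude = character(),
                             tol = 1e-9) {
  d <- as_dist_matrix(dm)
  if (!query_id %in% rownames(d))
    bg_stop(sprintf("query id not in distance matrix: %s", query_id),
            "bg_bad_input")
  refs <- setdiff(rownames(d), c(query_id, exclude))
  sp <- resolve_labels(labels, c(query_id, refs))
  if (length(refs) == 0L)
    return(.outcome(query_id, sp[1], character(0), NA_real_))
  dq <- d[query_id, refs]
  dmin <- min(dq)
  predicted <- unique(sp[-1][dq <= dmin + tol])
  .outcome(query_id, sp[1], predicted, dmin)
}

#' Identify a query by best local-alignment hit
#'
#' As [identify_nearest()], with "smallest distance" replaced by "highest
#' Smith-Waterman local alignment score" on the ungapped sequences.  Score
#' ties use exact equality (the scheme is integer-valued).
#'
#' @param query_id Sequence id of the query.
#' @param aln A [labeled_alignment] containing the query and references.
#' @param scoring Scoring scheme, see [default_scoring()].
#' @param exclude Ids to drop from the reference set.
#' @return An `identification_outcome` (`criterion_value` is the best
#'   score).
#' @export
identify_best_hit <- function(query_id, aln, scoring = default_scoring(),
                              exclude = character()) {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (!query_id %in% aln$id)
    bg_stop(sprintf("query id not in alignment: %s", query_id), "bg_bad_input")
  refs <- setdiff(aln$id, c(query_id, exclude))
  truth <- unname(aln$species[query_id])
  if (length(refs) == 0L)
    return(.outcome(query_id, truth, character(0), NA_real_))
  sc <- .score_against(aln$seq[query_id], aln$seq[refs], scoring)
  smax <- max(sc)
  predicted <- unique(unname(aln$species[refs][sc == smax]))
  .outcome(query_id, truth, predicted, smax)
}

#' Leave-one-out identification success rates
#'
#' Queries every sequence once against all remaining sequences (the query's
#' own record excluded; conspecific records retained) and aggregates the
#' verdicts into success rates.  Outgroup species are excluded entirely.
#' Singleton species remain in the query set; by construction their queries
#' can never be `correct` (no conspecific reference exists), which is
#' flagged in the result.
#'
#' @param aln A [labeled_alignment] (>= 2 ingroup sequences).
#' @param method `"nearest"` (genetic distance) or `"best_hit"`
#'   (local-alignment score).
#' @param dm Optional precomputed `k2p_matrix` for `method = "nearest"`
#'   (computed from `aln` when `NULL`).
#' @param scoring Scoring scheme for `method = "best_hit"`.
#' @param tol Distance tie tolerance for `method = "nearest"`.
#' @return List of class `loo_identification` with `rates` (class
#'   `success_rates`: `method`, `n_samples`, `n_species`, `pct_correct`,
#'   `pct_incorrect`, `pct_ambiguous`, `n_singleton_species`) and `outcomes`
#'   (one row per query).
#' @export
evaluate_loo <- function(aln, method = c("nearest", "best_hit"), dm = NULL,
                         scoring = default_scoring(), tol = 1e-9) {
  method <- match.arg(method)
  stopifnot(inherits(aln, "labeled_alignment"))
  aln <- aln_ingroup(aln)
  if (length(aln$id) < 2L)
    bg_stop("need at least 2 sequences for leave-one-out", "bg_too_few")
  if (method == "nearest") {
    if (is.null(dm)) dm <- k2p_matrix(aln)
    d <- as_dist_matrix(dm)[aln$id, aln$id]
    out <- lapply(aln$id, function(q) identify_nearest(q, d, aln$species,
                                                       tol = tol))
  } else {
    out <- lapply(aln$id, function(q) identify_best_hit(q, aln, scoring))
  }
  verdicts <- vapply(out, `[[`, "", "verdict")
  outcomes <- data.frame(
    query_id = aln$id,
    true_species = unname(aln$species),
    predicted_species = vapply(out, function(o)
      paste(o$predicted_species, collapse = ","), ""),
    verdict = verdicts,
    criterion_value = vapply(out, `[[`, 0, "criterion_value"),
    row.names = NULL)
  n <- length(verdicts)
  rates <- structure(list(
    method = method,
    n_samples = n,
    n_species = length(unique(aln$species)),
    pct_correct = 100 * mean(verdicts == "correct"),
    pct_incorrect = 100 * mean(verdicts == "incorrect"),
    pct_ambiguous = 100 * mean(verdicts == "ambiguous"),
    n_singleton_species = sum(table(aln$species) == 1L)
  ), class = "success_rates")
  structure(list(rates = rates, outcomes = outcomes),
            class = "loo_identification")
}

#' @export
print.success_rates <- function(x, digits = 1, ...) {
  cat(sprintf("%-12s %4d samples, %3d species: correct %.*f%%, incorrect %.*f%%, ambiguous %.*f%%\n",
              x$method, x$n_samples, x$n_species, digits, x$pct_correct,
              digits, x$pct_incorrect, digits, x$pct_ambiguous))
  if (x$n_singleton_species > 0)
    cat(sprintf("  note: %d singleton species (correct identification impossible by leave-one-out)\n",
                x$n_singleton_species))
  invisible(x)
}

#' @export
print.loo_identification <- function(x, ...) {
  print(x$rates, ...)
  invisible(x)
}
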