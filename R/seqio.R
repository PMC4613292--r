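#' Labeled alignment objects
#'
#' A `labeled_alignment` couples a set of DNA sequences with a species label
#' per sequence and an optional set of outgroup species.  It is the container
#' every analysis stage in the package consumes.  Residues are uppercase over
#' `A, C, G, T`, IUPAC ambiguity codes, `N` and the gap character `-`
#' (ambiguity codes are retained on construction and excluded site-wise at
#' computation time, mirroring pairwise deletion).
#'
#' @param seqs Named character vector of residue strings; names are sequence
#'   ids and must be unique.
#' @param species Character vector of species labels, one per sequence
#'   (recycled names permitted via a named vector keyed by id).
#' @param outgroup Character vector of species names to flag as outgroups
#'   (excluded from divergence/gap/identification summaries, used for tree
#'   rooting).
#' @return An object of class `labeled_alignment`: a list with elements
#'   `id`, `species` (named by id), `seq` (named by id), `aligned` (TRUE when
#'   all residue strings have equal length) and `outgroup`.
#' @examples
#' aln <- labeled_alignment(c(s1 = "ACGT", s2 = "ACGA"),
#'                          species = c("sp_a", "sp_b"))
#' aln$aligned
#' @export
labeled_alignment <- function(seqs, species, outgroup = character()) {
  if (length(seqs) == 0L)
    bg_stop("no sequences supplied", "bg_empty_input")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    bg_stop("all sequences must be named by a sequence id", "bg_bad_ids")
  if (anyDuplicated(ids))
    bg_stop(sprintf("duplicate sequence id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "bg_duplicate_id")
  if (!is.null(names(species))) species <- species[ids]
  if (length(species) != length(seqs) || any(is.na(species)) || any(!nzchar(species)))
    bg_stop("every sequence needs a non-empty species label", "bg_unlabeled")
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  structure(list(
    id = ids,
    species = stats::setNames(as.character(species), ids),
    seq = stats::setNames(as.character(seqs), ids),
    aligned = length(unique(nchar(seqs))) == 1L,
    outgroup = unique(as.character(outgroup))
  ), class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("Labeled alignment: %d sequences, %d species%s\n",
              length(x$id), length(unique(x$species)),
              if (x$aligned) sprintf(", aligned (%d columns)", nchar(x$seq[[1]]))
              else ", unaligned"))
  if (length(x$outgroup))
    cat("  outgroup species:", paste(x$outgroup, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.labeled_alignment <- function(x) length(x$id)

# subset by sequence id (internal)
aln_subset <- function(aln, ids) {
  labeled_alignment(aln$seq[ids], aln$species[ids], aln$outgroup)
}

# drop outgroup sequences (internal); most summaries operate on the ingroup
aln_ingroup <- function(aln) {
  keep <- !(aln$species %in% aln$outgroup)
  if (!any(keep)) bg_stop("no ingroup sequences left", "bg_empty_input")
  if (all(keep)) return(aln)
  labeled_alignment(aln$seq[keep], aln$species[keep], character())
}

#' Read a FASTA file with species labels
#'
#' Sequence ids are the first whitespace-delimited token of each FASTA
#' header.  Species labels come either from a tab-separated file
#' (`id <TAB> species [<TAB> outgroup-flag]`, optional header line) or, when
#' `labels` is `NULL`, from the remainder of the FASTA header after the id
#' token.  Residues are uppercased and `.` gap characters normalized to `-`.
#'
#' @param fasta_path Path to a FASTA file.
#' @param labels Path to a TSV mapping file, or `NULL` to parse species from
#'   headers.
#' @return A [labeled_alignment].  The `aligned` flag records whether all
#'   sequences have equal length.
#' @export
read_labeled_fasta <- function(fasta_path, labels = NULL) {
  if (!file.exists(fasta_path))
    bg_stop(sprintf("FASTA file not found: %s", fasta_path), "bg_io")
  ss <- Biostrings::readBStringSet(fasta_path)
  if (length(ss) == 0L)
    bg_stop(sprintf("empty FASTA file: %s", fasta_path), "bg_empty_input")
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    bg_stop(sprintf("duplicate sequence id(s) in FASTA: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "bg_duplicate_id")
  seqs <- stats::setNames(as.character(ss), ids)
  outgroup <- character()
  if (is.null(labels)) {
    species <- trimws(sub("^\\S+\\s*", "", headers))
    bad <- ids[!nzchar(species)]
    if (length(bad))
      bg_stop(sprintf("unlabeled sequence (no species in header): %s",
                      paste(bad, collapse = ", ")), "bg_unlabeled")
    species <- stats::setNames(species, ids)
  } else {
    tab <- read_labels_tsv(labels)
    missing <- setdiff(ids, tab$id)
    if (length(missing))
      bg_stop(sprintf("unlabeled sequence (id absent from label file): %s",
                      paste(missing, collapse = ", ")), "bg_unlabeled")
    species <- stats::setNames(tab$species, tab$id)[ids]
    if (!is.null(tab$outgroup))
      outgroup <- unique(tab$species[tab$outgroup])
  }
  labeled_alignment(seqs, species, outgroup)
}

# parse an id/species[/outgroup] TSV, tolerating an optional header row
read_labels_tsv <- function(path) {
  if (!file.exists(path))
    bg_stop(sprintf("label file not found: %s", path), "bg_io")
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(tab) == 0L) bg_stop("empty label file", "bg_empty_input")
  if (tolower(tab[1, 1]) == "id") tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2L)
    bg_stop("label file needs at least two tab-separated columns (id, species)",
            "bg_io")
  out <- list(id = tab[[1]], species = tab[[2]])
  if (anyDuplicated(out$id))
    bg_stop("duplicate id(s) in label file", "bg_duplicate_id")
  if (ncol(tab) >= 3L)
    out$outgroup <- tolower(trimws(tab[[3]])) %in% c("1", "true", "yes", "outgroup")
  out
}

#' Write a labeled alignment to FASTA (+ labels TSV)
#'
#' @param aln A [labeled_alignment].
#' @param fasta_path Output FASTA path.
#' @param labels_path Optional output path for the `id/species/outgroup` TSV;
#'   when `NULL`, species labels are written into the FASTA headers instead.
#' @return `aln`, invisibly.
#' @export
write_labeled_fasta <- function(aln, fasta_path, labels_path = NULL) {
  stopifnot(inherits(aln, "labeled_alignment"))
  headers <- if (is.null(labels_path)) paste(aln$id, aln$species) else aln$id
  writeLines(paste0(">", headers, "\n", aln$seq), fasta_path)
  if (!is.null(labels_path)) {
    tab <- data.frame(id = aln$id, species = unname(aln$species),
                      outgroup = as.integer(aln$species %in% aln$outgroup))
    utils::write.table(tab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(aln)
}

#' Sequence-characteristic summary
#'
#' Per-sequence lengths are counted on ungapped residues (everything except
#' `-`); GC content is `(G + C) / (A + C + G + T)` per sequence, with `N` and
#' other ambiguity codes excluded from both numerator and denominator.
#'
#' @param aln A [labeled_alignment].
#' @return An object of class `sequence_summary` with fields `n_sequences`,
#'   `length_min`, `length_max`, `length_mean` (bp) and `gc_min`, `gc_max`,
#'   `gc_mean` (fractions).
#' @examples
#' aln <- labeled_alignment(c(a = "AC-GT", b = "AAAA-"), c("x", "y"))
#' summarize_sequences(aln)$gc_mean  # (0.5 + 0) / 2
#' @export
summarize_sequences <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  chars <- strsplit(aln$seq, "", fixed = TRUE)
  lens <- vapply(chars, function(x) sum(x != "-"), 0L)
  gc <- vapply(chars, function(x) {
    acgt <- sum(x %in% c("A", "C", "G", "T"))
    if (acgt == 0L)
      bg_stop("sequence with zero countable (A/C/G/T) residues", "bg_degenerate")
    sum(x %in% c("G", "C")) / acgt
  }, 0)
  structure(list(
    n_sequences = length(lens),
    length_min = min(lens), length_max = max(lens), length_mean = mean(lens),
    gc_min = min(gc), gc_max = max(gc), gc_mean = mean(gc),
    per_sequence = data.frame(id = aln$id, length = lens, gc = unname(gc))
  ), class = "sequence_summary")
}

#' @export
print.sequence_summary <- function(x, ...) {
  cat(sprintf("%d sequences; length %d-%d bp (mean %.1f); GC %.1f%%-%.1f%% (mean %.1f%%)\n",
              x$n_sequences, x$length_min, x$length_max, x$length_mean,
              100 * x$gc_min, 100 * x$gc_max, 100 * x$gc_mean))
  invisible(x)
}
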