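# integer encoding: A=1, C=2, G=3, T=4, everything else NA.
# with this coding a mismatch is a transition exactly when |a - b| == 2
# (A<->G and C<->T), which keeps the pair loop branch-free.
.BASE_INT <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_alignment <- function(aln) {
  if (inherits(aln, "labeled_alignment")) {
    if (!aln$aligned)
      bg_stop("sequences must be aligned (equal lengths)", "bg_not_aligned")
    seqs <- aln$seq
  } else seqs <- aln
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  im <- matrix(.BASE_INT[m], nrow = nrow(m), ncol = ncol(m))
  rownames(im) <- names(seqs)
  im
}

# core estimator on encoded site vectors
.k2p_int <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  m <- sum(ok)
  if (m == 0L)
    bg_stop("zero comparable sites: distance undefined", "bg_no_sites")
  a <- a[ok]; b <- b[ok]
  ndiff <- sum(a != b)
  nts <- sum(abs(a - b) == 2L)
  P <- nts / m
  Q <- (ndiff - nts) / m
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    bg_stop(sprintf("saturation: distance undefined (P=%.4f, Q=%.4f)", P, Q),
            "bg_saturation")
  # + 0 normalizes IEEE negative zero for identical sequences
  list(distance = -0.5 * log(w1) - 0.25 * log(w2) + 0, sites = m, P = P, Q = Q)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Over the comparable sites (both residues in `A, C, G, T`; columns holding
#' a gap, `N` or any other code in either sequence are excluded — pairwise
#' deletion), compute the transition proportion `P` (A<->G, C<->T) and the
#' transversion proportion `Q` (all other mismatches) and return
#' \deqn{d = -\tfrac{1}{2}\ln\left((1-2P-Q)\sqrt{1-2Q}\right)}
#' in expected substitutions per site.
#'
#' @param a,b Aligned residue strings of equal length.
#' @return A list with `distance`, `sites` (comparable-site count), and the
#'   internal proportions `P` and `Q`.
#' @examples
#' k2p_distance("AAAAAAAAAA", "AAAAAAAAAG")$distance  # P = 0.1, Q = 0
#' @export
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    bg_stop("sequences must have equal (aligned) length", "bg_not_aligned")
  enc <- encode_alignment(c(x = toupper(a), y = toupper(b)))
  .k2p_int(enc[1, ], enc[2, ])
}

# pairwise matrix over an encoded alignment (internal; shared with bootstrap)
.k2p_matrix_int <- function(enc, on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  n <- nrow(enc)
  ids <- rownames(enc)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(sites) <- as.integer(rowSums(!is.na(enc)))
  n_missing <- 0L
  for (i in seq_len(n - 1L)) {
    ai <- enc[i, ]
    for (j in seq.int(i + 1L, n)) {
      res <- if (on_saturation == "error") .k2p_int(ai, enc[j, ])
      else tryCatch(.k2p_int(ai, enc[j, ]), barcodegap_error = function(e) NULL)
      if (is.null(res)) {
        d[i, j] <- d[j, i] <- NA_real_
        n_missing <- n_missing + 1L
      } else {
        d[i, j] <- d[j, i] <- res$distance
        sites[i, j] <- sites[j, i] <- res$sites
      }
    }
  }
  if (n_missing > 0L)
    warning(sprintf("%d pair(s) undefined (saturation or no comparable sites); recorded as NA",
                    n_missing))
  structure(list(distance = d, sites = sites, ids = ids),
            class = "k2p_matrix")
}

#' Pairwise K2P distance matrix
#'
#' Computes [k2p_distance()] for every unordered pair of sequences under
#' pairwise deletion.
#'
#' @param aln A [labeled_alignment] with `aligned = TRUE` and at least two
#'   records.
#' @param on_saturation `"error"` (default) aborts when any pair falls beyond
#'   the K2P singularity or shares no comparable site; `"na"` records such
#'   pairs as missing with a warning.
#' @return An object of class `k2p_matrix`: list with symmetric `distance`
#'   and `sites` matrices (ids as dimnames) and `ids`.
#' @export
k2p_matrix <- function(aln, on_saturation = c("error", "na")) {
  if (inherits(aln, "labeled_alignment") && length(aln$id) < 2L)
    bg_stop("need at least 2 sequences", "bg_too_few")
  .k2p_matrix_int(encode_alignment(aln), on_saturation)
}

#' @export
print.k2p_matrix <- function(x, ...) {
  d <- x$distance[upper.tri(x$distance)]
  cat(sprintf("K2P distance matrix: %d sequences, %d pairs (range %.6f-%.6f%s)\n",
              length(x$ids), length(d), min(d, na.rm = TRUE), max(d, na.rm = TRUE),
              if (anyNA(d)) sprintf(", %d missing", sum(is.na(d))) else ""))
  invisible(x)
}

#' @export
as.matrix.k2p_matrix <- function(x, ...) x$distance

#' @export
as.dist.k2p_matrix <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$distance, diag = diag, upper = upper)

# accept k2p_matrix, matrix or dist wherever a distance matrix is expected
as_dist_matrix <- function(dm) {
  if (inherits(dm, "k2p_matrix")) return(dm$distance)
  if (inherits(dm, "dist")) return(as.matrix(dm))
  if (is.matrix(dm)) {
    if (is.null(rownames(dm)))
      dimnames(dm) <- list(paste0("t", seq_len(nrow(dm))),
                           paste0("t", seq_len(nrow(dm))))
    return(dm)
  }
  bg_stop("expected a k2p_matrix, matrix or dist object", "bg_bad_input")
}

#' Write a distance matrix as TSV or PHYLIP
#'
#' @param dm A `k2p_matrix` (or plain symmetric matrix).
#' @param path Output path.
#' @param format `"tsv"` (square matrix, ids as row/column headers) or
#'   `"phylip"` (square PHYLIP distance format).
#' @param digits Decimal places in the output (default 6).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip"),
                                  digits = 6) {
  format <- match.arg(format)
  d <- as_dist_matrix(dm)
  fmt <- formatC(d, digits = digits, format = "f")
  if (format == "tsv") {
    lines <- c(paste(c("id", rownames(d)), collapse = "\t"),
               vapply(seq_len(nrow(d)), function(i)
                 paste(c(rownames(d)[i], fmt[i, ]), collapse = "\t"), ""))
  } else {
    lines <- c(sprintf("%5d", nrow(d)),
               vapply(seq_len(nrow(d)), function(i)
                 paste(c(formatC(rownames(d)[i], width = -10), fmt[i, ]),
                       collapse = "  "), ""))
  }
  writeLines(lines, path)
  invisible(path)
}
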