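#' Scoring schemes for protein alignment
#'
#' A scoring scheme is a symmetric substitution matrix over the 20 amino
#' acids plus `X` (which scores 0 against everything, including itself)
#' together with affine gap penalties: a gap of length \eqn{k} costs
#' `gap_open + k * gap_extend`.  The default is BLOSUM62 with gap open 10 and
#' gap extend 0.5, the familiar Clustal-style defaults for proteins.
#'
#' @param matrix Square numeric substitution matrix with amino-acid
#'   dimnames covering the 20 standard residues (an `X` row/column is added
#'   or overwritten with zeros).  `NULL` means built-in BLOSUM62.
#' @param gap_open,gap_extend Non-negative penalties, `gap_extend <= gap_open`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 10, gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0) stop_kin("gap penalties must be non-negative")
  if (gap_extend > gap_open) stop_kin("'gap_extend' must not exceed 'gap_open'")
  if (is.null(matrix)) matrix <- blosum62_matrix()
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop_kin("substitution matrix must have residue dimnames")
  }
  missing <- setdiff(AA20, rownames(matrix))
  if (length(missing)) stop_kin("substitution matrix lacks residues: %s",
                                paste(missing, collapse = ", "))
  m <- matrix(0, 21, 21, dimnames = list(AAX, AAX))
  m[AA20, AA20] <- matrix[AA20, AA20]
  if (!isSymmetric(unname(m))) stop_kin("substitution matrix must be symmetric")
  structure(list(matrix = m, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

blosum62_env <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62
  }
  blosum62_env$m
}

#' @rdname scoring_scheme
#' @export
default_scheme <- function() scoring_scheme()

#' Load an NCBI-format substitution matrix
#'
#' Reads the whitespace-delimited matrix text format used by NCBI
#' (`#`-comment lines, a header row of residue letters, one labelled row per
#' residue).
#'
#' @param path Path to the matrix file.
#' @param gap_open,gap_extend Gap penalties for the resulting scheme.
#' @return A [scoring_scheme].
#' @export
read_scoring_matrix <- function(path, gap_open = 10, gap_extend = 0.5) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[`, character(1), 1)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(m) <- list(lab, header)
  scoring_scheme(m, gap_open, gap_extend)
}

res_index <- function(residues) {
  idx <- match(str_chars(residues), AAX)
  stopifnot(!anyNA(idx))
  idx
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman–Wunsch/Gotoh alignment maximizing the substitution score minus
#' affine gap costs (`gap_open + k * gap_extend` for a gap of length `k`);
#' end gaps are penalized.  Traceback is deterministic with tie preference
#' diagonal > up > left, so identical inputs always give identical
#' alignments.
#'
#' @param s1,s2 [seq_record]s (or plain residue strings).
#' @param scheme A [scoring_scheme]; default BLOSUM62, open 10, extend 0.5.
#' @return A `pairwise_alignment`: list with gapped records `a` and `b`,
#'   `score`, and `identity_pct` (percent identical positions over columns
#'   where both rows are non-gap).
#' @examples
#' aln <- global_align(seq_record("a", "MKVL"), seq_record("b", "MKL"))
#' aln$identity_pct
#' @export
global_align <- function(s1, s2, scheme = default_scheme()) {
  if (!is_seq_record(s1)) s1 <- seq_record("seq1", s1)
  if (!is_seq_record(s2)) s2 <- seq_record("seq2", s2)
  a <- res_index(s1$residues)
  b <- res_index(s2$residues)
  C <- scheme$matrix[a, b, drop = FALSE]
  res <- nw_affine_mat_cpp(C, scheme$gap_open, scheme$gap_extend)
  ca <- str_chars(s1$residues)
  cb <- str_chars(s2$residues)
  ga <- ifelse(res$ai == 0L, GAP, ca[pmax(res$ai, 1L)])
  gb <- ifelse(res$bi == 0L, GAP, cb[pmax(res$bi, 1L)])
  ra <- seq_record(s1$id, paste0(ga, collapse = ""), s1$species, s1$accession,
                   s1$description, gapped = TRUE)
  rb <- seq_record(s2$id, paste0(gb, collapse = ""), s2$species, s2$accession,
                   s2$description, gapped = TRUE)
  out <- structure(list(a = ra, b = rb, score = res$score, identity_pct = NA_real_),
                   class = "pairwise_alignment")
  out$identity_pct <- percent_identity(out)
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s / %s  score %.1f  identity %.1f%%\n",
              x$a$id, x$b$id, x$score, x$identity_pct))
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' `100 * (identical columns) / (columns where both rows are non-gap)`;
#' returns 0 when no co-aligned columns exist.
#'
#' @param aln A `pairwise_alignment`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(aln) {
  ca <- str_chars(aln$a$residues)
  cb <- str_chars(aln$b$residues)
  both <- ca != GAP & cb != GAP
  if (!any(both)) return(0)
  100 * sum(ca[both] == cb[both]) / sum(both)
}

#' p-distance between two sequences
#'
#' One minus the fractional identity of their global alignment; the distance
#' used for guide trees and the neighbor-joining phylogeny.
#'
#' @inheritParams global_align
#' @return A value in `[0, 1]`.
#' @export
p_distance <- function(s1, s2, scheme = default_scheme()) {
  1 - global_align(s1, s2, scheme)$identity_pct / 100
}
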