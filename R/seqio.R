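#' Protein sequence records
#'
#' A `seq_record` holds one protein sequence: a short unique `id`, free-text
#' `species` and `accession` fields, the residue string over the strict
#' 20-letter amino-acid alphabet plus `X` (unknown), and the original header
#' as `description`.  Aligned records additionally allow the gap character
#' `-`.  Residues are uppercased on construction; anything outside the
#' alphabet is rejected with its position, so malformed inputs fail fast.
#'
#' @param id Short unique identifier (first whitespace token of a FASTA
#'   header).
#' @param residues Residue string; lowercase accepted and normalized.
#' @param species,accession,description Optional free-text annotations.
#' @param gapped Allow the gap character `-` (aligned records).
#' @return An object of class `seq_record`.
#' @examples
#' seq_record("s1", "MKV")
#' @export
seq_record <- function(id, residues, species = "", accession = "",
                       description = "", gapped = FALSE) {
  if (!is_scalar_string(id) || !nzchar(id)) stop_kin("'id' must be a non-empty string")
  if (!is_scalar_string(residues)) stop_kin("'residues' must be a string")
  residues <- toupper(residues)
  if (!nzchar(residues)) stop_kin("record '%s': empty residue string", id)
  allowed <- if (gapped) c(AAX, GAP) else AAX
  bad <- first_bad_char(residues, allowed)
  if (bad > 0L) {
    stop_kin("record '%s': invalid residue '%s' at position %d",
             id, substr(residues, bad, bad), bad)
  }
  structure(list(id = id, species = species, accession = accession,
                 residues = residues, description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d aa)%s\n", x$id, nchar(gsub("-", "", x$residues)),
              if (nzchar(x$species)) paste0(" [", x$species, "]") else ""))
  invisible(x)
}

#' @rdname seq_record
#' @param x Object to test.
#' @export
is_seq_record <- function(x) inherits(x, "seq_record")

# residues of a record with gaps removed
degap <- function(x) gsub("-", "", if (is_seq_record(x)) x$residues else x, fixed = TRUE)

record_ids <- function(records) vapply(records, function(r) r$id, character(1))

check_unique_ids <- function(records) {
  ids <- record_ids(records)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_kin("duplicate sequence id: '%s'", dup[1])
  invisible(ids)
}

# header convention: "id [species=...] [accession=...]"; the id is the first
# whitespace-delimited token and the full header is kept as description
parse_header <- function(header) {
  id <- strsplit(trimws(header), "\\s+")[[1]][1]
  grab <- function(key) {
    m <- regmatches(header, regexec(sprintf("\\[%s=([^]]*)\\]", key), header))[[1]]
    if (length(m) == 2) m[2] else ""
  }
  list(id = id, species = grab("species"), accession = grab("accession"),
       description = trimws(header))
}

read_fasta_text <- function(lines, gapped = FALSE) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_kin("empty FASTA input")
  if (!startsWith(lines[1], ">")) stop_kin("not FASTA: first line does not start with '>'")
  starts <- which(startsWith(lines, ">"))
  ends <- c(starts[-1] - 1L, length(lines))
  records <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    h <- parse_header(sub("^>", "", lines[starts[k]]))
    if (starts[k] + 1L > ends[k]) stop_kin("record '%s': no sequence lines", h$id)
    seq <- paste0(lines[(starts[k] + 1L):ends[k]], collapse = "")
    seq <- gsub("\\s", "", seq)
    seq <- sub("\\*$", "", seq) # tolerate a trailing translation stop
    records[[k]] <- seq_record(h$id, seq, species = h$species,
                               accession = h$accession,
                               description = h$description, gapped = gapped)
  }
  check_unique_ids(records)
  records
}

#' Read protein sequences from FASTA
#'
#' Headers are parsed as `id [species=...] [accession=...]`; for plain
#' headers the first whitespace token becomes the id and the whole header the
#' description.  Residues are uppercased and a single trailing `*`
#' (translation stop) is stripped; any other character outside
#' `ACDEFGHIKLMNPQRSTVWY` + `X` is an error reported with its position.
#'
#' @param path Path to a FASTA file, or a character vector of lines.
#' @return List of [seq_record] objects in file order.
#' @export
read_fasta <- function(path) {
  lines <- if (length(path) > 1L || grepl("\n", path[1], fixed = TRUE)) {
    unlist(strsplit(path, "\n", fixed = TRUE))
  } else {
    if (!file.exists(path)) stop_kin("file not found: %s", path)
    readLines(path, warn = FALSE)
  }
  read_fasta_text(lines, gapped = FALSE)
}

#' Write sequences to FASTA
#'
#' `read_fasta(write_fasta(x))` reproduces `x` exactly, including the
#' species/accession annotations, which are emitted as bracketed key=value
#' pairs on the header line.
#'
#' @param records List of [seq_record]s (gapped records allowed).
#' @param path Output path; omit to return the lines invisibly.
#' @param width Residues per line, default 60.
#' @return The FASTA lines, invisibly.
#' @export
write_fasta <- function(records, path = NULL, width = 60) {
  if (width < 1) stop_kin("'width' must be >= 1")
  lines <- character(0)
  for (r in records) {
    ann <- c(if (nzchar(r$species)) sprintf("[species=%s]", r$species),
             if (nzchar(r$accession)) sprintf("[accession=%s]", r$accession))
    header <- paste(c(r$id, ann), collapse = " ")
    body <- substring(r$residues,
                      seq(1, nchar(r$residues), by = width),
                      pmin(seq(1, nchar(r$residues), by = width) + width - 1L,
                           nchar(r$residues)))
    lines <- c(lines, paste0(">", header), body)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a multiple alignment (aligned FASTA or Clustal)
#'
#' All rows must have equal gapped length; the gap character is `-`.
#' Clustal conservation lines are ignored (parsing is delegated to
#' [Biostrings::readAAMultipleAlignment()]).
#'
#' @param path Path (or, for `aligned-fasta`, a character vector of lines).
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return A [msa] object.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (dialect == "aligned-fasta") {
    lines <- if (length(path) > 1L || grepl("\n", path[1], fixed = TRUE)) {
      unlist(strsplit(path, "\n", fixed = TRUE))
    } else readLines(path, warn = FALSE)
    records <- read_fasta_text(lines, gapped = TRUE)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    mat <- as.character(Biostrings::unmasked(aln))
    records <- Map(function(id, s) seq_record(id, s, gapped = TRUE),
                   names(mat), unname(mat))
    names(records) <- NULL
    check_unique_ids(records)
  }
  lens <- vapply(records, function(r) nchar(r$residues), integer(1))
  if (length(unique(lens)) > 1L) {
    off <- records[[which(lens != lens[1])[1]]]$id
    stop_kin("ragged alignment: record '%s' has length %d, expected %d",
             off, nchar_of(records, off), lens[1])
  }
  new_msa(records)
}

nchar_of <- function(records, id) {
  nchar(records[[match(id, record_ids(records))]]$residues)
}
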